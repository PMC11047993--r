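// Two-dimensional incompressible two-phase flow on a uniform MAC grid.
//
// Interface capture: conservative level-set (phi in [0,1], advection +
// compression/diffusion reinitialisation).  Surface tension: continuum
// surface force, sigma * kappa * grad(phi), with cell curvatures from
// corner-averaged interface normals.  Walls: no-slip, with a static contact
// angle imposed through ghost values of phi inside solid cells.  Pressure:
// variable-coefficient Poisson equation solved by warm-started red-black SOR.
//
// Everything is nondimensional: lengths in micrometres, velocities in units
// of the inlet speed.  The R wrappers own the mapping to physical units.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double minmod(double a, double b) {
  if (a * b <= 0.0) return 0.0;
  return std::fabs(a) < std::fabs(b) ? a : b;
}

struct Grid {
  int ny, nx;
  const int *mask;          // 0 solid, 1 fluid, 2 inlet, 3 outlet
  inline int m(int i, int j) const {
    if (i < 0 || i >= ny || j < 0 || j >= nx) return 0;
    return mask[i + (size_t)ny * j];
  }
  inline bool fluid(int i, int j) const { return m(i, j) > 0; }
};

// face activity codes
enum { F_OFF = 0, F_INT = 1, F_IN = 2, F_OUT = 3 };

// [[Rcpp::export]]
List tp_advance(IntegerMatrix mask, NumericMatrix phi_, NumericMatrix u_,
                NumericMatrix v_, NumericMatrix p_, List par, int nsteps,
                double t0) {
  const int ny = mask.nrow(), nx = mask.ncol();
  Grid G{ny, nx, INTEGER(mask)};

  const double rho1 = as<double>(par["rho1"]);   // continuous phase (phi = 0)
  const double rho2 = as<double>(par["rho2"]);   // dispersed phase  (phi = 1)
  const double mu1  = as<double>(par["mu1"]);
  const double mu2  = as<double>(par["mu2"]);
  const double sigma = as<double>(par["sigma"]);
  const double costh = as<double>(par["costh"]);
  const double h    = as<double>(par["h"]);
  const double u_in = as<double>(par["u_in"]);
  const double cfl  = as<double>(par["cfl"]);
  const double eps  = as<double>(par["eps_ls"]);
  const int reinit_iters = as<int>(par["reinit_iters"]);
  const double tol_div = as<double>(par["tol_div"]);
  const int maxit = as<int>(par["poisson_maxit"]);
  const double omega = as<double>(par["omega"]);
  const bool momentum = as<bool>(par["momentum"]);
  const bool surft = as<bool>(par["surface_tension"]);
  const double dt_fixed = as<double>(par["dt_fixed"]);

  if (phi_.nrow() != ny || phi_.ncol() != nx) stop("phi dimension mismatch");
  if (u_.nrow() != ny || u_.ncol() != nx + 1) stop("u dimension mismatch");
  if (v_.nrow() != ny + 1 || v_.ncol() != nx) stop("v dimension mismatch");
  if (p_.nrow() != ny || p_.ncol() != nx) stop("p dimension mismatch");

  // raw column-major views: bounds-checked Rcpp accessors are far too slow
  // for the inner loops
  double *PHI = REAL(phi_), *U = REAL(u_), *V = REAL(v_), *P = REAL(p_);
  auto phi = [&](int i, int j) -> double& { return PHI[i + (size_t)ny * j]; };
  auto u   = [&](int i, int j) -> double& { return U[i + (size_t)ny * j]; };
  auto v   = [&](int i, int j) -> double& { return V[i + (size_t)(ny + 1) * j]; };
  auto p   = [&](int i, int j) -> double& { return P[i + (size_t)ny * j]; };

  // ---- face masks -------------------------------------------------------
  std::vector<int> ufm((size_t)ny * (nx + 1), F_OFF), vfm((size_t)(ny + 1) * nx, F_OFF);
  auto UF = [&](int i, int j) -> int& { return ufm[i + (size_t)ny * j]; };
  auto VF = [&](int i, int j) -> int& { return vfm[i + (size_t)(ny + 1) * j]; };
  bool has_outlet = false;
  for (int j = 0; j <= nx; ++j)
    for (int i = 0; i < ny; ++i) {
      int L = (j > 0) ? G.m(i, j - 1) : -1, R = (j < nx) ? G.m(i, j) : -1;
      if (j == 0) UF(i, j) = (R == 2) ? F_IN : F_OFF;
      else if (j == nx) { UF(i, j) = (L == 3) ? F_OUT : F_OFF; if (L == 3) has_outlet = true; }
      else UF(i, j) = (L > 0 && R > 0) ? F_INT : F_OFF;
    }
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i <= ny; ++i) {
      int B = (i > 0) ? G.m(i - 1, j) : -1, T = (i < ny) ? G.m(i, j) : -1;
      VF(i, j) = (i > 0 && i < ny && B > 0 && T > 0) ? F_INT : F_OFF;
    }
  // enforce boundary values on entry
  for (int j = 0; j <= nx; ++j)
    for (int i = 0; i < ny; ++i) {
      if (UF(i, j) == F_OFF) u(i, j) = 0.0;
      if (UF(i, j) == F_IN) u(i, j) = u_in;
    }
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i <= ny; ++i)
      if (VF(i, j) == F_OFF) v(i, j) = 0.0;

  // ---- work arrays ------------------------------------------------------
  std::vector<double> phin((size_t)ny * nx), kap((size_t)ny * nx, 0.0);
  std::vector<double> cnx((size_t)(ny + 1) * (nx + 1), 0.0), cny((size_t)(ny + 1) * (nx + 1), 0.0);
  std::vector<double> us((size_t)ny * (nx + 1)), vs((size_t)(ny + 1) * nx);
  std::vector<double> rhs((size_t)ny * nx, 0.0);
  std::vector<double> nxc((size_t)ny * nx, 0.0), nyc((size_t)ny * nx, 0.0);
  std::vector<double> rhoc((size_t)ny * nx, 0.0);
  std::vector<double> bx((size_t)ny * (nx + 1), 0.0), by((size_t)(ny + 1) * nx, 0.0);
  auto IDX = [&](int i, int j) { return (size_t)(i + (size_t)ny * j); };
  auto CID = [&](int i, int j) { return (size_t)(i + (size_t)(ny + 1) * j); };

  auto phiG = [&](int i, int j) -> double {   // clamped-index lookup
    if (i < 0) i = 0; if (i >= ny) i = ny - 1;
    if (j < 0) j = 0; if (j >= nx) j = nx - 1;
    return phi(i, j);
  };
  auto rho_of = [&](double f) { return rho1 + (rho2 - rho1) * f; };
  auto mu_of  = [&](double f) { return mu1 + (mu2 - mu1) * f; };

  // contact-angle ghost fill: solid cells adjacent to fluid take a biased
  // copy of their fluid neighbours so interface normals meet the wall at
  // the prescribed angle (costh measured through the dispersed phase).
  auto fill_ghosts = [&]() {
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i) {
        if (G.m(i, j) != 0) continue;
        double s = 0.0; int n = 0;
        if (G.fluid(i - 1, j)) { s += phi(i - 1, j); ++n; }
        if (G.fluid(i + 1, j)) { s += phi(i + 1, j); ++n; }
        if (G.fluid(i, j - 1)) { s += phi(i, j - 1); ++n; }
        if (G.fluid(i, j + 1)) { s += phi(i, j + 1); ++n; }
        if (!n) { phi(i, j) = 0.0; continue; }
        double f = s / n;
        double g = f + costh * f * (1.0 - f);   // |grad phi| ~ phi(1-phi)/eps, eps ~ h
        phi(i, j) = std::min(1.0, std::max(0.0, g));
      }
  };

  double t = t0, dt = 0.0, max_div = 0.0, clamp_abs = 0.0;
  double flux_out = as<double>(par["flux_out0"]);
  int iters_last = 0;

  const double nu_max = std::max(mu1 / rho1, mu2 / rho2);
  const double dt_cap = surft && sigma > 0.0
    ? std::sqrt((rho1 + rho2) * h * h * h / (4.0 * M_PI * sigma)) : 1e30;

  for (int step = 0; step < nsteps; ++step) {
    // ---- time step ------------------------------------------------------
    double umax = std::fabs(u_in);
    for (size_t k = 0; k < ufm.size(); ++k) umax = std::max(umax, std::fabs(U[k]));
    for (size_t k = 0; k < vfm.size(); ++k) umax = std::max(umax, std::fabs(V[k]));
    if (dt_fixed > 0.0) dt = dt_fixed;
    else {
      dt = cfl * h / umax;
      if (momentum) {
        dt = std::min(dt, cfl * 0.25 * h * h / nu_max);
        dt = std::min(dt, cfl * dt_cap);
      }
    }

    fill_ghosts();

    // ---- phi advection (MUSCL-limited upwind fluxes) --------------------
    std::copy(PHI, PHI + (size_t)ny * nx, phin.begin());
    // x fluxes
    for (int j = 0; j <= nx; ++j)
      for (int i = 0; i < ny; ++i) {
        int fm = UF(i, j);
        if (fm == F_OFF) continue;
        double uf = u(i, j), pf;
        if (fm == F_IN) pf = 0.0;                       // continuous phase injected
        else if (fm == F_OUT) pf = phi(i, j - 1);
        else if (uf >= 0.0) {
          double c = phiG(i, j - 1);
          pf = c + 0.5 * minmod(c - phiG(i, j - 2), phiG(i, j) - c);
        } else {
          double c = phiG(i, j);
          pf = c + 0.5 * minmod(c - phiG(i, j + 1), phiG(i, j - 1) - c);
        }
        double F = uf * pf;
        if (j > 0 && G.fluid(i, j - 1)) phin[IDX(i, j - 1)] -= dt / h * F;
        if (j < nx && G.fluid(i, j))    phin[IDX(i, j)]     += dt / h * F;
        if (fm == F_OUT) flux_out += dt * h * F;
      }
    // y fluxes
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i <= ny; ++i) {
        if (VF(i, j) == F_OFF) continue;
        double vf = v(i, j), pf;
        if (vf >= 0.0) {
          double c = phiG(i - 1, j);
          pf = c + 0.5 * minmod(c - phiG(i - 2, j), phiG(i, j) - c);
        } else {
          double c = phiG(i, j);
          pf = c + 0.5 * minmod(c - phiG(i + 1, j), phiG(i - 1, j) - c);
        }
        double F = vf * pf;
        phin[IDX(i - 1, j)] -= dt / h * F;
        phin[IDX(i, j)]     += dt / h * F;
      }
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i)
        if (G.fluid(i, j)) phi(i, j) = phin[IDX(i, j)];

    // ---- conservative reinitialisation ---------------------------------
    for (int it = 0; it < reinit_iters; ++it) {
      fill_ghosts();
      for (int j = 0; j < nx; ++j)
        for (int i = 0; i < ny; ++i) {
          double gx = (phiG(i, j + 1) - phiG(i, j - 1)) / (2 * h);
          double gy = (phiG(i + 1, j) - phiG(i - 1, j)) / (2 * h);
          double gn = std::sqrt(gx * gx + gy * gy);
          if (gn > 1e-8) { nxc[IDX(i, j)] = gx / gn; nyc[IDX(i, j)] = gy / gn; }
          else { nxc[IDX(i, j)] = 0.0; nyc[IDX(i, j)] = 0.0; }
        }
      std::copy(PHI, PHI + (size_t)ny * nx, phin.begin());
      double dtau = 0.2 * h;
      // x faces
      for (int j = 1; j < nx; ++j)
        for (int i = 0; i < ny; ++i) {
          if (!(G.fluid(i, j - 1) && G.fluid(i, j))) continue;
          double pfc = 0.5 * (phi(i, j - 1) + phi(i, j));
          double nf = 0.5 * (nxc[IDX(i, j - 1)] + nxc[IDX(i, j)]);
          double Fc = eps * (phi(i, j) - phi(i, j - 1)) / h
                    - pfc * (1.0 - pfc) * nf;
          phin[IDX(i, j - 1)] += dtau / h * Fc;
          phin[IDX(i, j)]     -= dtau / h * Fc;
        }
      // y faces
      for (int j = 0; j < nx; ++j)
        for (int i = 1; i < ny; ++i) {
          if (!(G.fluid(i - 1, j) && G.fluid(i, j))) continue;
          double pfc = 0.5 * (phi(i - 1, j) + phi(i, j));
          double nf = 0.5 * (nyc[IDX(i - 1, j)] + nyc[IDX(i, j)]);
          double Fc = eps * (phi(i, j) - phi(i - 1, j)) / h
                    - pfc * (1.0 - pfc) * nf;
          phin[IDX(i - 1, j)] += dtau / h * Fc;
          phin[IDX(i, j)]     -= dtau / h * Fc;
        }
      for (int j = 0; j < nx; ++j)
        for (int i = 0; i < ny; ++i)
          if (G.fluid(i, j)) phi(i, j) = phin[IDX(i, j)];
    }
    // clamp small over/undershoots, tracking how much was removed
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i) {
        if (!G.fluid(i, j)) continue;
        double f = phi(i, j);
        if (f < 0.0) { clamp_abs += -f * h * h; phi(i, j) = 0.0; }
        else if (f > 1.0) { clamp_abs += (f - 1.0) * h * h; phi(i, j) = 1.0; }
      }

    if (momentum) {
      // ---- curvature from corner-averaged normals -----------------------
      fill_ghosts();
      if (surft) {
        for (int j = 0; j <= nx; ++j)
          for (int i = 0; i <= ny; ++i) {
            double gx = 0.5 * ((phiG(i - 1, j) + phiG(i, j))
                             - (phiG(i - 1, j - 1) + phiG(i, j - 1))) / h;
            double gy = 0.5 * ((phiG(i, j - 1) + phiG(i, j))
                             - (phiG(i - 1, j - 1) + phiG(i - 1, j))) / h;
            double gn = std::sqrt(gx * gx + gy * gy);
            if (gn > 1e-8) { cnx[CID(i, j)] = gx / gn; cny[CID(i, j)] = gy / gn; }
            else { cnx[CID(i, j)] = 0.0; cny[CID(i, j)] = 0.0; }
          }
        for (int j = 0; j < nx; ++j)
          for (int i = 0; i < ny; ++i) {
            if (!G.fluid(i, j)) { kap[IDX(i, j)] = 0.0; continue; }
            double nxe = 0.5 * (cnx[CID(i, j + 1)] + cnx[CID(i + 1, j + 1)]);
            double nxw = 0.5 * (cnx[CID(i, j)] + cnx[CID(i + 1, j)]);
            double nyn = 0.5 * (cny[CID(i + 1, j)] + cny[CID(i + 1, j + 1)]);
            double nys = 0.5 * (cny[CID(i, j)] + cny[CID(i, j + 1)]);
            kap[IDX(i, j)] = -((nxe - nxw) / h + (nyn - nys) / h);
          }
      }

      // ---- provisional velocities u*, v* --------------------------------
      auto uval = [&](int i, int j, double uc) -> double {
        if (j < 0 || j > nx || i < 0 || i >= ny) return -uc;   // domain edge: wall mirror
        int fm = UF(i, j);
        if (fm == F_OFF) {
          // distinguish longitudinal wall (true zero at face) from a solid
          // neighbour above/below (mirror for no-slip at the cell boundary)
          return 0.0;
        }
        return u(i, j);
      };
      auto uvalT = [&](int i, int j, double uc) -> double {    // transverse neighbour
        if (i < 0 || i >= ny) return -uc;
        if (UF(i, j) == F_OFF) return -uc;
        return u(i, j);
      };
      auto vval = [&](int i, int j, double vc) -> double {
        if (i < 0 || i > ny || j < 0 || j >= nx) return -vc;
        if (VF(i, j) == F_OFF) return 0.0;
        return v(i, j);
      };
      auto vvalT = [&](int i, int j, double vc) -> double {
        if (j < 0 || j >= nx) return -vc;
        if (VF(i, j) == F_OFF) return -vc;
        return v(i, j);
      };

      std::copy(U, U + (size_t)ny * (nx + 1), us.begin());
      std::copy(V, V + (size_t)(ny + 1) * nx, vs.begin());

      for (int j = 1; j < nx; ++j)
        for (int i = 0; i < ny; ++i) {
          if (UF(i, j) != F_INT) continue;
          double uc = u(i, j);
          double vavg = 0.25 * (v(i, j - 1) + v(i, j) + v(i + 1, j - 1) + v(i + 1, j));
          double dudx = uc >= 0.0 ? (uc - uval(i, j - 1, uc)) / h
                                  : (uval(i, j + 1, uc) - uc) / h;
          double dudy = vavg >= 0.0 ? (uc - uvalT(i - 1, j, uc)) / h
                                    : (uvalT(i + 1, j, uc) - uc) / h;
          double adv = uc * dudx + vavg * dudy;

          double fE = phi(i, j), fW = phi(i, j - 1);
          double muE = mu_of(fE), muW = mu_of(fW);
          double muN = mu_of(0.25 * (phiG(i, j - 1) + phiG(i, j) + phiG(i + 1, j - 1) + phiG(i + 1, j)));
          double muS = mu_of(0.25 * (phiG(i, j - 1) + phiG(i, j) + phiG(i - 1, j - 1) + phiG(i - 1, j)));
          double visc = (muE * (uval(i, j + 1, uc) - uc) - muW * (uc - uval(i, j - 1, uc))) / (h * h)
                      + (muN * (uvalT(i + 1, j, uc) - uc) - muS * (uc - uvalT(i - 1, j, uc))) / (h * h);

          double rf = rho_of(0.5 * (fE + fW));
          double st = 0.0;
          if (surft) st = sigma * 0.5 * (kap[IDX(i, j - 1)] + kap[IDX(i, j)]) * (fE - fW) / h;
          us[i + (size_t)ny * j] = uc + dt * (-adv + (visc + st) / rf);
        }

      for (int j = 0; j < nx; ++j)
        for (int i = 1; i < ny; ++i) {
          if (VF(i, j) != F_INT) continue;
          double vc = v(i, j);
          double uavg = 0.25 * (u(i - 1, j) + u(i - 1, j + 1) + u(i, j) + u(i, j + 1));
          double dvdy = vc >= 0.0 ? (vc - vval(i - 1, j, vc)) / h
                                  : (vval(i + 1, j, vc) - vc) / h;
          double dvdx = uavg >= 0.0 ? (vc - vvalT(i, j - 1, vc)) / h
                                    : (vvalT(i, j + 1, vc) - vc) / h;
          double adv = uavg * dvdx + vc * dvdy;

          double fN = phi(i, j), fS = phi(i - 1, j);
          double muN2 = mu_of(fN), muS2 = mu_of(fS);
          double muE = mu_of(0.25 * (phiG(i - 1, j) + phiG(i, j) + phiG(i - 1, j + 1) + phiG(i, j + 1)));
          double muW = mu_of(0.25 * (phiG(i - 1, j) + phiG(i, j) + phiG(i - 1, j - 1) + phiG(i, j - 1)));
          double visc = (muE * (vvalT(i, j + 1, vc) - vc) - muW * (vc - vvalT(i, j - 1, vc))) / (h * h)
                      + (muN2 * (vval(i + 1, j, vc) - vc) - muS2 * (vc - vval(i - 1, j, vc))) / (h * h);

          double rf = rho_of(0.5 * (fN + fS));
          double st = 0.0;
          if (surft) st = sigma * 0.5 * (kap[IDX(i - 1, j)] + kap[IDX(i, j)]) * (fN - fS) / h;
          vs[i + (size_t)(ny + 1) * j] = vc + dt * (-adv + (visc + st) / rf);
        }

      // boundary faces of the provisional field
      for (int i = 0; i < ny; ++i) {
        if (UF(i, 0) == F_IN) us[i] = u_in;
        if (UF(i, nx) == F_OUT) us[i + (size_t)ny * nx] = us[i + (size_t)ny * (nx - 1)];
      }

      // ---- pressure Poisson ---------------------------------------------
      // cache densities and face coefficients: they are reused every SOR sweep
      for (int j = 0; j < nx; ++j)
        for (int i = 0; i < ny; ++i)
          rhoc[IDX(i, j)] = rho_of(phi(i, j));
      for (int j = 1; j < nx; ++j)
        for (int i = 0; i < ny; ++i)
          if (UF(i, j) == F_INT)
            bx[i + (size_t)ny * j] =
              1.0 / (0.5 * (rhoc[IDX(i, j - 1)] + rhoc[IDX(i, j)]));
      for (int j = 0; j < nx; ++j)
        for (int i = 1; i < ny; ++i)
          if (VF(i, j) == F_INT)
            by[i + (size_t)(ny + 1) * j] =
              1.0 / (0.5 * (rhoc[IDX(i - 1, j)] + rhoc[IDX(i, j)]));
      for (int j = 0; j < nx; ++j)
        for (int i = 0; i < ny; ++i) {
          if (!G.fluid(i, j)) { rhs[IDX(i, j)] = 0.0; continue; }
          double d = (us[i + (size_t)ny * (j + 1)] - us[i + (size_t)ny * j]
                    + vs[(i + 1) + (size_t)(ny + 1) * j] - vs[i + (size_t)(ny + 1) * j]) / h;
          rhs[IDX(i, j)] = d / dt;
        }

      double resid = 0.0;
      int it = 0;
      bool pinned = !has_outlet;
      for (it = 1; it <= maxit; ++it) {
        for (int colour = 0; colour < 2; ++colour)
          for (int j = 0; j < nx; ++j)
            for (int i = (j + colour) % 2; i < ny; i += 2) {
              if (!G.fluid(i, j)) continue;
              if (G.m(i, j) == 3) { p(i, j) = 0.0; continue; }   // outlet Dirichlet
              double Ap = 0.0, rhsv = rhs[IDX(i, j)], acc = 0.0;
              if (UF(i, j + 1) == F_INT) { double b = bx[i + (size_t)ny * (j + 1)]; Ap += b; acc += b * p(i, j + 1); }
              if (UF(i, j) == F_INT)     { double b = bx[i + (size_t)ny * j]; Ap += b; acc += b * p(i, j - 1); }
              if (VF(i + 1, j) == F_INT) { double b = by[(i + 1) + (size_t)(ny + 1) * j]; Ap += b; acc += b * p(i + 1, j); }
              if (VF(i, j) == F_INT)     { double b = by[i + (size_t)(ny + 1) * j]; Ap += b; acc += b * p(i - 1, j); }
              if (Ap == 0.0) { p(i, j) = 0.0; continue; }
              double pn = (acc - rhsv * h * h) / Ap;
              p(i, j) = (1.0 - omega) * p(i, j) + omega * pn;
            }
        if (it % 5 == 0 || it == maxit) {
          resid = 0.0;
          for (int j = 0; j < nx; ++j)
            for (int i = 0; i < ny; ++i) {
              if (!G.fluid(i, j) || G.m(i, j) == 3) continue;
              double Ap = 0.0, acc = 0.0;
              if (UF(i, j + 1) == F_INT) { double b = bx[i + (size_t)ny * (j + 1)]; Ap += b; acc += b * (p(i, j + 1) - p(i, j)); }
              if (UF(i, j) == F_INT)     { double b = bx[i + (size_t)ny * j]; Ap += b; acc += b * (p(i, j - 1) - p(i, j)); }
              if (VF(i + 1, j) == F_INT) { double b = by[(i + 1) + (size_t)(ny + 1) * j]; Ap += b; acc += b * (p(i + 1, j) - p(i, j)); }
              if (VF(i, j) == F_INT)     { double b = by[i + (size_t)(ny + 1) * j]; Ap += b; acc += b * (p(i - 1, j) - p(i, j)); }
              if (Ap == 0.0) continue;
              double r = rhs[IDX(i, j)] - acc / (h * h);
              resid = std::max(resid, std::fabs(r));
            }
          if (resid * dt <= tol_div / h) break;
        }
      }
      iters_last = it;
      if (pinned) {
        // anchor the nullspace of the all-Neumann problem
        double p00 = NA_REAL;
        for (int j = 0; j < nx && !R_finite(p00); ++j)
          for (int i = 0; i < ny; ++i)
            if (G.fluid(i, j)) { p00 = p(i, j); break; }
        if (R_finite(p00))
          for (int j = 0; j < nx; ++j)
            for (int i = 0; i < ny; ++i)
              if (G.fluid(i, j)) p(i, j) -= p00;
      }

      // ---- projection ----------------------------------------------------
      for (int j = 1; j < nx; ++j)
        for (int i = 0; i < ny; ++i)
          if (UF(i, j) == F_INT)
            u(i, j) = us[i + (size_t)ny * j]
                    - dt * bx[i + (size_t)ny * j] * (p(i, j) - p(i, j - 1)) / h;
      for (int j = 0; j < nx; ++j)
        for (int i = 1; i < ny; ++i)
          if (VF(i, j) == F_INT)
            v(i, j) = vs[i + (size_t)(ny + 1) * j]
                    - dt * by[i + (size_t)(ny + 1) * j] * (p(i, j) - p(i - 1, j)) / h;
      for (int i = 0; i < ny; ++i) {
        if (UF(i, 0) == F_IN) u(i, 0) = u_in;
        if (UF(i, nx) == F_OUT) u(i, nx) = u(i, nx - 1);
      }

      // ---- divergence diagnostic ----------------------------------------
      max_div = 0.0;
      for (int j = 0; j < nx; ++j)
        for (int i = 0; i < ny; ++i) {
          if (!G.fluid(i, j) || G.m(i, j) == 3) continue;
          double d = (u(i, j + 1) - u(i, j) + v(i + 1, j) - v(i, j)) / h;
          max_div = std::max(max_div, std::fabs(d));
        }
    }

    t += dt;
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i)
        if (G.fluid(i, j) && !R_finite(phi(i, j)))
          stop("two-phase solver diverged (NaN in phi) at t = %g", t);
  }

  double mass = 0.0;
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i)
      if (G.fluid(i, j)) mass += phi(i, j) * h * h;

  return List::create(
    _["t"] = t, _["dt"] = dt, _["max_div"] = max_div, _["mass"] = mass,
    _["flux_out"] = flux_out, _["clamp_abs"] = clamp_abs,
    _["poisson_iters"] = iters_last);
}
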