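#' Two-phase solver options
#'
#' Numerical controls for the incompressible two-phase solver.  The solver
#' integrates the nondimensional equations (lengths in micrometres, velocity
#' in units of the inlet speed).  The physical regime of the platform is
#' deep into the quasi-static capillary limit (capillary number
#' Ca ~ 1e-4, Reynolds number Re ~ 4e-3); interface shapes and pinch-off
#' volumes are insensitive to Ca and Re well below ~0.05 and ~1
#' respectively, so by default the solver integrates at the numerical
#' values `re_num = 1`, `ca_num = 0.003` — the same flow regime at a
#' tractable time-step — while preserving the viscosity ratio, density
#' ratio, contact angle and geometry exactly; `ca_num = 0.003` sits where
#' the two finite-Ca artefacts on droplet volume balance (see the methods
#' vignette).  Set both to 0 to force the raw physical values.
#'
#' @param re_num floor on the simulated Reynolds number (0 = physical).
#' @param ca_num floor on the simulated capillary number (0 = physical).
#' @param cfl CFL safety factor applied to the advective, viscous and
#'   capillary time-step limits.
#' @param tol_div velocity-divergence tolerance (nondimensional).
#' @param poisson_maxit,omega pressure SOR iteration cap and relaxation.
#' @param reinit_iters interface reinitialisation sweeps per step.
#' @param eps_factor interface half-thickness in cells.
#' @param momentum solve momentum (FALSE = kinematic advection only, for
#'   validation against rigid-translation solutions).
#' @param surface_tension include the capillary force.
#' @param dt_fixed fixed time step (0 = automatic).
#' @return list of class `"solver_options"`.
#' @export
solver_options <- function(re_num = 1, ca_num = 0.003, cfl = 0.4,
                           tol_div = 1e-3, poisson_maxit = 400, omega = 1.7,
                           reinit_iters = 1L, eps_factor = 1.0,
                           momentum = TRUE, surface_tension = TRUE,
                           dt_fixed = 0) {
  structure(list(re_num = re_num, ca_num = ca_num, cfl = cfl,
                 tol_div = tol_div, poisson_maxit = as.integer(poisson_maxit),
                 omega = omega, reinit_iters = as.integer(reinit_iters),
                 eps_factor = eps_factor, momentum = momentum,
                 surface_tension = surface_tension, dt_fixed = dt_fixed),
            class = "solver_options")
}

# nondimensional solver parameters from physical fluids
tp_parameters <- function(geom, fluids, opts, u_in_mps) {
  L0 <- 1e-6                                  # metre per micrometre
  re_phys <- fluids$rho_c * u_in_mps * L0 / fluids$mu_c
  ca_phys <- fluids$mu_c * u_in_mps / fluids$sigma
  re_sim <- max(re_phys, opts$re_num)
  ca_sim <- max(ca_phys, opts$ca_num)
  list(rho1 = 1, rho2 = fluids$rho_d / fluids$rho_c,
       mu1 = 1 / re_sim, mu2 = (fluids$mu_d / fluids$mu_c) / re_sim,
       sigma = 1 / (re_sim * ca_sim),
       costh = cos(fluids$theta_wall_deg * pi / 180),
       h = geom$h, u_in = 1, cfl = opts$cfl,
       eps_ls = opts$eps_factor * geom$h,
       reinit_iters = opts$reinit_iters, tol_div = opts$tol_div,
       poisson_maxit = opts$poisson_maxit, omega = opts$omega,
       momentum = opts$momentum, surface_tension = opts$surface_tension,
       dt_fixed = opts$dt_fixed,
       re_sim = re_sim, ca_sim = ca_sim,
       t_scale_s = L0 / u_in_mps)             # seconds per nondim time unit
}

#' Bespoke flow domains
#'
#' Wraps an arbitrary cell mask (0 solid, 1 fluid, 2 inlet, 3 outlet) as a
#' flow domain for the two-phase solver, bypassing the SDA rasterizer.  Used
#' for analytic validation cases (Poiseuille channels, quiescent droplets,
#' rigid advection) where the geometry is a plain channel or box.
#'
#' @param mask integer matrix of cell codes (rows = y, columns = x).
#' @param h cell size (um).
#' @return an `"sda_geometry"` with no chambers.
#' @export
flow_domain <- function(mask, h) {
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  ny <- nrow(mask); nx <- ncol(mask)
  structure(list(params = NULL, h = h, nx = nx, ny = ny,
                 x_len = nx * h, y_len = ny * h,
                 xc = (seq_len(nx) - 0.5) * h, yc = (seq_len(ny) - 0.5) * h,
                 mask = mask, region = mask,
                 chambers = data.frame()), class = "sda_geometry")
}

#' @rdname flow_domain
#' @param geom a flow domain.
#' @param phi optional initial phase-fraction matrix (default all continuous).
#' @export
flow_state <- function(geom, phi = NULL) {
  if (is.null(phi)) phi <- matrix(0, geom$ny, geom$nx)
  st <- structure(list(
    phi = phi, u = matrix(0, geom$ny, geom$nx + 1),
    v = matrix(0, geom$ny + 1, geom$nx), p = matrix(0, geom$ny, geom$nx),
    t = 0, flux_out = 0, clamp_abs = 0, diag = list(), geom = geom),
    class = "sda_state")
  st$mass0 <- sum(st$phi[geom$mask > 0L]) * geom$h^2
  st
}

#' Initial phase distribution
#'
#' The SDA structure and the front (array-adjacent) portion of the injection
#' channel start filled with the continuous phase; the remaining upstream
#' portion of the injection channel holds the dispersed (aqueous) plug that
#' the continuous-phase inflow subsequently drives through the array.
#' Velocity and pressure start at rest.
#'
#' @param geom an [build_geometry()] result.
#' @return object of class `"sda_state"`: phase fraction `phi` (1 =
#'   dispersed), MAC velocities `u`, `v`, pressure `p`, nondimensional time
#'   `t` and bookkeeping fields; the geometry rides along as `$geom`.
#' @export
init_phases <- function(geom) {
  stopifnot(inherits(geom, "sda_geometry"))
  p <- geom$params
  phi <- matrix(0, geom$ny, geom$nx)
  inj <- geom$region == SDA_REGIONS[["injection"]]
  plug <- inj & outer(rep(TRUE, geom$ny), geom$xc < (p$inlet_length - p$plug_gap))
  phi[plug] <- 1
  st <- structure(list(
    phi = phi, u = matrix(0, geom$ny, geom$nx + 1),
    v = matrix(0, geom$ny + 1, geom$nx), p = matrix(0, geom$ny, geom$nx),
    t = 0, flux_out = 0, clamp_abs = 0, diag = list(), geom = geom),
    class = "sda_state")
  st$mass0 <- sum(st$phi[geom$mask > 0L]) * geom$h^2
  st
}

#' @export
print.sda_state <- function(x, ...) {
  cat(sprintf("<sda_state> t = %.4g (nondim), dispersed area %.4g um^2, max|u| = %.3g\n",
              x$t, sum(x$phi[x$geom$mask > 0L]) * x$geom$h^2,
              max(abs(x$u), abs(x$v))))
  invisible(x)
}

#' Advance the two-phase flow
#'
#' Runs `n` time steps (or steps of fixed size `dt`) of the incompressible
#' two-phase solver: limited-upwind interface transport plus conservative
#' reinitialisation, continuum-surface-force surface tension, static
#' contact-angle walls, constant-velocity inlet and zero-gradient outflow.
#' Time steps respect the advective, viscous and capillary stability limits.
#' Divergence of the solver (NaN fields) aborts with a diagnostic.
#'
#' @param state an [init_phases()] state.
#' @param fluids a [fluid_pair()].
#' @param n number of steps.
#' @param dt fixed nondimensional time step (NULL = automatic).
#' @param opts a [solver_options()].
#' @param u_in_mps physical injection speed (m/s).
#' @return the advanced `"sda_state"`; `$diag` holds the last diagnostics
#'   (max divergence, mass, outflow flux, clamping, Poisson iterations).
#' @export
sda_step <- function(state, fluids = fluid_pair(), n = 1L, dt = NULL,
                     opts = solver_options(), u_in_mps = 3e-3) {
  stopifnot(inherits(state, "sda_state"))
  geom <- state$geom
  par <- tp_parameters(geom, fluids, opts, u_in_mps)
  if (!is.null(dt)) par$dt_fixed <- dt
  par$flux_out0 <- state$flux_out
  phi <- state$phi + 0; u <- state$u + 0; v <- state$v + 0; p <- state$p + 0
  out <- tp_advance(geom$mask, phi, u, v, p, par, as.integer(n), state$t)
  state$phi <- phi; state$u <- u; state$v <- v; state$p <- p
  state$t <- out$t
  state$flux_out <- out$flux_out
  state$clamp_abs <- state$clamp_abs + out$clamp_abs
  state$diag <- out
  state$diag$par <- par
  state
}

#' Census of dispersed-phase droplets
#'
#' Integrates the dispersed volume fraction over each chamber
#' (`area = sum(phi) * h^2`), labels connected components of the
#' `phi > threshold` field, and flags a chamber's droplet as confined when
#' its component lies entirely within the chamber rectangle (up to
#' `margin_cells` of interface smearing).
#'
#' @param state an `"sda_state"`.
#' @param threshold phase-fraction threshold defining a droplet.
#' @param margin_cells tolerated overhang of a confined component, in cells.
#' @return data.table of class `"droplet_census"` with `unit_x`, `unit_y`,
#'   `area_um2`, `chamber_area_um2`, `confined`.  Attributes: `n_droplets`
#'   (components anywhere), `outside_area_um2` (dispersed area outside all
#'   chambers), `bypass_max_phi` (peak phase fraction in bypass/jog
#'   channels), `t`.
#' @export
droplet_census <- function(state, threshold = 0.5, margin_cells = 1L) {
  geom <- state$geom
  h <- geom$h
  bin <- (state$phi > threshold) & (geom$mask > 0L)
  lab <- EBImage::bwlabel(bin * 1)
  ch <- geom$chambers
  inside_chamber <- matrix(FALSE, geom$ny, geom$nx)
  res <- vector("list", nrow(ch))
  for (k in seq_len(nrow(ch))) {
    ii <- ch$i0[k]:ch$i1[k]; jj <- ch$j0[k]:ch$j1[k]
    inside_chamber[ii, jj] <- TRUE
    area <- sum(state$phi[ii, jj]) * h^2
    labs <- setdiff(unique(as.vector(lab[ii, jj])), 0)
    confined <- FALSE
    if (length(labs)) {
      # the chamber's droplet: the component with the largest overlap
      ov <- vapply(labs, function(l) sum(lab[ii, jj] == l), numeric(1))
      main <- labs[which.max(ov)]
      cells <- which(lab == main, arr.ind = TRUE)
      pad <- margin_cells
      confined <- all(cells[, 1] >= ch$i0[k] - pad & cells[, 1] <= ch$i1[k] + pad &
                      cells[, 2] >= ch$j0[k] - pad & cells[, 2] <= ch$j1[k] + pad)
    }
    res[[k]] <- data.frame(unit_x = ch$unit_x[k], unit_y = ch$unit_y[k],
                           area_um2 = area,
                           chamber_area_um2 = ch$chamber_area_um2[k],
                           confined = confined && area > 0)
  }
  out <- data.table::as.data.table(do.call(rbind, res))
  byp <- geom$region %in% SDA_REGIONS[c("bypass", "riser")]
  data.table::setattr(out, "n_droplets", max(lab))
  data.table::setattr(out, "outside_area_um2",
                      sum(state$phi[geom$mask > 0L & !inside_chamber]) * h^2)
  data.table::setattr(out, "bypass_max_phi",
                      if (any(byp)) max(state$phi[matrix(byp, geom$ny, geom$nx)]) else 0)
  data.table::setattr(out, "t", state$t)
  data.table::setattr(out, "class", c("droplet_census", class(out)))
  out
}

#' Run the droplet simulation to steady state
#'
#' Advances the flow until every chamber's dispersed area changes by less
#' than `steady_tol` (relative) over one flush-through time (the time for
#' the inlet flow to traverse the domain), or until `t_max`.  A census is
#' recorded every `census_interval` nondimensional time units.
#'
#' @param geom an [build_geometry()] result (or [sda_geometry()] parameters).
#' @param fluids a [fluid_pair()].
#' @param opts a [solver_options()].
#' @param u_in_mps physical injection speed (m/s).
#' @param census_interval nondim time between censuses (default: 1/10 of the
#'   flush time).
#' @param steady_tol relative per-chamber area-change tolerance.
#' @param t_max nondim time cap (default: 4 domain traverses).
#' @param verbose print progress lines.
#' @return object of class `"sda_run"`: list with the final `state`, the
#'   census `history` (long data.table), the final `census`, `steady` flag
#'   and timing info.  If `t_max` is hit first, `steady` is `FALSE` and a
#'   warning is issued.
#' @export
run_to_steady <- function(geom, fluids = fluid_pair(), opts = solver_options(),
                          u_in_mps = 3e-3, census_interval = NULL,
                          steady_tol = 0.005, t_max = NULL, verbose = FALSE) {
  if (inherits(geom, "sda_params")) geom <- build_geometry(geom)
  stopifnot(inherits(geom, "sda_geometry"))
  # flush-through time: one traverse of the SDA structure at the inlet speed
  t_flush <- if (!is.null(geom$params))
    geom$params$n_units_x * geom$params$unit_pitch else geom$x_len
  if (is.null(census_interval)) census_interval <- t_flush / 10
  if (is.null(t_max)) t_max <- 2 * geom$x_len + 2 * t_flush
  state <- init_phases(geom)
  history <- list()
  prev <- list()
  steady <- FALSE
  # conservative first guess for steps per census interval; adapted from dt
  dt_guess <- 0.2 * geom$h
  while (state$t < t_max) {
    n <- max(10L, ceiling(census_interval / dt_guess))
    state <- sda_step(state, fluids, n = n, opts = opts, u_in_mps = u_in_mps)
    dt_guess <- state$diag$dt
    cen <- droplet_census(state)
    history[[length(history) + 1L]] <- data.table::data.table(
      t = state$t, cen[, c("unit_x", "unit_y", "area_um2")])
    prev[[length(prev) + 1L]] <- list(t = state$t, area = cen$area_um2)
    if (verbose)
      message(sprintf("t = %7.2f  dt = %.3g  maxdiv = %.2g  areas: %s",
                      state$t, state$diag$dt, state$diag$max_div,
                      paste(sprintf("%.2f", tapply(cen$area_um2, cen$unit_x, mean)),
                            collapse = " ")))
    # steady when all chamber areas are stable across one flush window,
    # evaluated only after the plug has had time to clear the domain
    if (state$t > t_flush + geom$x_len) {
      ref <- Find(function(z) z$t <= state$t - t_flush, rev(prev))
      if (!is.null(ref)) {
        denom <- pmax(cen$area_um2, 0.05 * cen$chamber_area_um2)
        if (all(abs(cen$area_um2 - ref$area) / denom < steady_tol)) {
          steady <- TRUE
          break
        }
      }
    }
  }
  if (!steady) warning("t_max reached before per-chamber areas stabilized")
  structure(list(state = state, history = data.table::rbindlist(history),
                 census = droplet_census(state), steady = steady,
                 geom = geom, fluids = fluids, opts = opts,
                 u_in_mps = u_in_mps,
                 t_phys_s = state$t * tp_parameters(geom, fluids, opts, u_in_mps)$t_scale_s),
            class = "sda_run")
}

#' @export
print.sda_run <- function(x, ...) {
  cm <- x$census[, list(mean_area = mean(area_um2)), by = "unit_x"]
  cat(sprintf("<sda_run> %s at t = %.3g (%.3g ms physical)\n",
              if (x$steady) "steady" else "NOT steady", x$state$t,
              1e3 * x$t_phys_s))
  cat(sprintf("  column mean areas (um^2): %s\n",
              paste(sprintf("%.3g", cm$mean_area), collapse = ", ")))
  cat(sprintf("  confined droplets: %d/%d; bypass max phi %.3g\n",
              sum(x$census$confined), nrow(x$census),
              attr(x$census, "bypass_max_phi")))
  invisible(x)
}

#' Per-column mean droplet areas
#'
#' @param census a [droplet_census()] (or an `"sda_run"`).
#' @return data.table with `unit_x` and `mean_area_um2`.
#' @export
column_means <- function(census) {
  if (inherits(census, "sda_run")) census <- census$census
  out <- census[, list(mean_area_um2 = mean(area_um2)), by = "unit_x"]
  data.table::setkey(out, unit_x)
  out
}

#' @export
as.data.frame.sda_state <- function(x, ...) {
  geom <- x$geom
  keep <- which(geom$mask > 0L, arr.ind = TRUE)
  uc <- 0.5 * (x$u[, seq_len(geom$nx)] + x$u[, seq_len(geom$nx) + 1L])
  vc <- 0.5 * (x$v[seq_len(geom$ny), ] + x$v[seq_len(geom$ny) + 1L, ])
  data.frame(x_um = geom$xc[keep[, 2]], y_um = geom$yc[keep[, 1]],
             phi = x$phi[keep], u = uc[keep], v = vc[keep], p = x$p[keep])
}

#' Render the phase field
#'
#' Base-graphics raster of the dispersed-phase fraction (solid cells grey),
#' optionally written to PNG.
#'
#' @param state an `"sda_state"`.
#' @param file optional PNG path.
#' @param ... passed to [graphics::image()].
#' @export
plot_phase <- function(state, file = NULL, ...) {
  geom <- state$geom
  z <- state$phi
  z[geom$mask == 0L] <- NA
  if (!is.null(file)) {
    grDevices::png(file, width = 4 * geom$nx, height = 4 * geom$ny)
    on.exit(grDevices::dev.off())
  }
  graphics::image(geom$xc, geom$yc, t(z), useRaster = TRUE, asp = 1,
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  xlab = "x (um)", ylab = "y (um)", ...)
  invisible(state)
}
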