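fl <- fluid_pair()

test_that("SDA parameters enforce the capillary width ordering and pitch budget", {
  expect_error(sda_geometry(valve_width = 0.5, neck_width = 0.4), "width ordering")
  expect_error(sda_geometry(neck_width = 0.8), "width ordering")
  expect_error(sda_geometry(chamber_width = 3.0), "does not fit")
  expect_error(sda_geometry(chamber_height = 2.5), "do not fit")
  p <- sda_geometry()
  expect_lt(p$valve_width, p$neck_width)
  expect_lt(p$neck_width, p$channel_width)
})

test_that("rasterized domain tiles identically and exposes chambers, inlet and outlet", {
  g <- build_geometry(sda_geometry(n_units_x = 3, n_units_y = 2, inlet_length = 4))
  expect_identical(nrow(g$chambers), 6L)
  expect_true(all(g$chambers$chamber_area_um2 > 0))
  # identical rasterization in every tile: compare region blocks across units
  P_cells <- round(g$params$unit_pitch / g$h)
  Li_cells <- round(round(g$params$inlet_length / g$h) * g$h / g$h)
  t1 <- g$region[1:P_cells, Li_cells + seq_len(P_cells)]
  t2 <- g$region[1:P_cells, Li_cells + P_cells + seq_len(P_cells)]
  expect_identical(t1, t2)
  # mirrored second row is the vertical flip of the first
  r2 <- g$region[P_cells + seq_len(P_cells), Li_cells + seq_len(P_cells)]
  expect_identical(r2, t1[rev(seq_len(P_cells)), ])
  expect_true(any(g$mask[, 1] == 2L))
  expect_true(any(g$mask[, g$nx] == 3L))
  # domain bounding box: array span plus injection and outlet extensions
  expect_equal(g$y_len, 2 * 3.16)
  expect_equal(g$x_len, round(4 / g$h) * g$h + 3 * 3.16 + round(2 / g$h) * g$h)
})

test_that("initial phases put the plug in the injection channel and nothing else", {
  g <- build_geometry(sda_geometry(n_units_x = 1, n_units_y = 1, inlet_length = 5))
  st <- init_phases(g)
  expect_true(all(st$phi >= 0 & st$phi <= 1))
  inj <- g$region == 7L
  expect_equal(sum(st$phi[!inj]), 0)
  p <- g$params
  plug_cells <- sum(inj & outer(rep(TRUE, g$ny), g$xc < p$inlet_length - p$plug_gap))
  expect_equal(st$mass0, plug_cells * g$h^2)
  expect_gt(st$mass0, g$chambers$chamber_area_um2[1])  # enough water to fill
  # zero plug length: stays single-phase under flow
  st2 <- init_phases(build_geometry(sda_geometry(n_units_x = 1, n_units_y = 1,
                                                 inlet_length = 3, plug_gap = 3)))
  expect_equal(st2$mass0, 0)
  st2 <- sda_step(st2, fl, n = 200)
  expect_equal(sum(st2$phi), 0)
})

test_that("single-phase channel flow develops the analytic parabolic profile", {
  ny <- 11; nx <- 40; h <- 0.1
  m <- matrix(0L, ny, nx); m[2:(ny - 1), ] <- 1L
  m[2:(ny - 1), 1] <- 2L; m[2:(ny - 1), nx] <- 3L
  st <- flow_state(flow_domain(m, h))
  st <- sda_step(st, fl, n = 4000, opts = solver_options(surface_tension = FALSE))
  g <- st$geom
  umid <- st$u[2:(ny - 1), 30]
  yy <- g$yc[2:(ny - 1)]
  wall0 <- g$yc[1] + h / 2; wall1 <- g$yc[ny] - h / 2
  W <- wall1 - wall0
  para <- 6 * mean(umid) * (yy - wall0) * (wall1 - yy) / W^2
  expect_lt(max(abs(umid - para)) / max(para), 0.02)
  expect_lt(st$diag$max_div, 1e-6)
})

test_that("a quiescent droplet carries the Young-Laplace pressure jump", {
  h <- 0.05; n <- 40
  gd <- flow_domain(matrix(1L, n, n), h)
  phi <- matrix(0, n, n)
  R <- 0.4
  for (j in 1:n) for (i in 1:n) {
    d <- sqrt((gd$xc[j] - 1)^2 + (gd$yc[i] - 1)^2)
    phi[i, j] <- 1 / (1 + exp((d - R) / (0.5 * h)))
  }
  st <- flow_state(gd, phi)
  opts <- solver_options()
  st <- sda_step(st, fl, n = 2000, opts = opts)
  par <- synthchip:::tp_parameters(gd, fl, opts, 3e-3)
  dist <- sqrt(outer(rep(1, n), (gd$xc - 1)^2) + outer((gd$yc - 1)^2, rep(1, n)))
  dp <- mean(st$p[dist < 0.5 * R]) - mean(st$p[dist > 1.5 * R])
  expect_lt(abs(dp - par$sigma / R) / (par$sigma / R), 0.10)
  # interface stays in place and mass is conserved
  expect_equal(sum(st$phi) * h^2, st$mass0, tolerance = 1e-6)
})

test_that("kinematic advection translates a blob with <1% area drift per traverse", {
  ny <- 20; nx <- 60; h <- 0.05
  m <- matrix(0L, ny, nx); m[2:(ny - 1), ] <- 1L
  m[2:(ny - 1), 1] <- 2L; m[2:(ny - 1), nx] <- 3L
  gd <- flow_domain(m, h)
  phi <- matrix(0, ny, nx)
  for (j in 1:nx) for (i in 2:(ny - 1)) {
    d <- sqrt((gd$xc[j] - 0.5)^2 + (gd$yc[i] - 0.5)^2)
    phi[i, j] <- 1 / (1 + exp((d - 0.25) / (0.5 * h)))
  }
  st <- flow_state(gd, phi)
  st$u[2:(ny - 1), ] <- 1      # prescribed uniform translation
  a0 <- sum(st$phi[m > 0]) * h^2
  opts <- solver_options(momentum = FALSE)
  # one traverse of 2 um at unit speed
  while (st$t < 2) st <- sda_step(st, fl, n = 200, opts = opts)
  a1 <- sum(st$phi[st$geom$mask > 0]) * h^2 + st$flux_out
  expect_lt(abs(a1 - a0) / a0, 0.01)
  # blob centroid moved with the flow
  w <- st$phi * (m > 0)
  cx <- sum(t(w) * gd$xc) / sum(w)
  expect_gt(cx, 1.8)
})

test_that("droplet census integrates chamber areas and labels confinement", {
  g <- build_geometry(sda_geometry(n_units_x = 2, n_units_y = 1, inlet_length = 4))
  st <- init_phases(g)
  ch <- g$chambers
  # hand-built field: chamber 1 half full, chamber 2 full
  st$phi[,] <- 0
  ii <- ch$i0[1]:ch$i1[1]; jj <- ch$j0[1]:ch$j1[1]
  st$phi[ii, jj[seq_len(length(jj) %/% 2)]] <- 1
  st$phi[ch$i0[2]:ch$i1[2], ch$j0[2]:ch$j1[2]] <- 1
  cen <- droplet_census(st)
  expect_equal(cen$area_um2[1], ch$chamber_area_um2[1] / 2, tolerance = 0.05)
  expect_equal(cen$area_um2[2], ch$chamber_area_um2[2])
  expect_true(all(cen$confined))
  expect_identical(attr(cen, "n_droplets"), 2L)
  # a blob in the bypass is counted outside and spoils bypass clearance
  st$phi[,] <- 0
  byp <- which(g$region == 5L, arr.ind = TRUE)
  st$phi[byp[1:20, ]] <- 1
  cen2 <- droplet_census(st)
  expect_equal(sum(cen2$area_um2), 0)
  expect_gt(attr(cen2, "outside_area_um2"), 0)
  expect_equal(attr(cen2, "bypass_max_phi"), 1)
})

test_that("the dispersed phase is conserved through a full plug transit", {
  g <- build_geometry(sda_geometry(n_units_x = 1, n_units_y = 1, inlet_length = 6))
  st <- init_phases(g)
  while (st$t < 16) st <- sda_step(st, fl, n = 1000)
  mass_now <- sum(st$phi[g$mask > 0L]) * g$h^2
  # mass + outflow accounts for the initial plug to within 2%
  expect_lt(abs(mass_now + st$flux_out - st$mass0) / st$mass0, 0.02)
  # clamping removed a negligible amount of phase
  expect_lt(st$clamp_abs / st$mass0, 0.02)
  expect_lt(st$diag$max_div, 1e-2)   # projection tolerance in nondim units
  # the single chamber kept a confined droplet; an isolated unit sees a
  # shorter pressurized filling window than a full array, so the half-chamber
  # criterion is asserted on the default 4x4 run, not here
  cen <- droplet_census(st)
  expect_true(cen$confined[1])
  expect_gt(cen$area_um2[1], 0.4 * cen$chamber_area_um2[1])
})

test_that("steady chamber areas are grid-converged within 10% under cell halving", {
  # fixed physical interface half-thickness (one coarse cell) on both grids,
  # so the comparison isolates the discretization error; run at a milder
  # capillary stiffness so the halved grid stays tractable
  areas <- vapply(c(1, 2), function(f) {
    p <- sda_geometry(n_units_x = 1, n_units_y = 1, inlet_length = 6,
                      cell_um = 3.16 / (32 * f))
    st <- init_phases(build_geometry(p))
    opts <- solver_options(ca_num = 0.01, eps_factor = f, cfl = 0.5)
    while (st$t < 12) st <- sda_step(st, fl, n = 2000, opts = opts)
    droplet_census(st)$area_um2[1]
  }, numeric(1))
  expect_lt(abs(areas[2] - areas[1]) / areas[2], 0.10)
  expect_gt(min(areas), 0)
})
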