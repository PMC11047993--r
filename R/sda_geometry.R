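#' Fluid pair for the droplet simulation
#'
#' Continuous phase defaults to the fluorocarbon oil FC-3283 (viscosity
#' 1.365e-3 Pa s, density 1820 kg/m^3); dispersed phase defaults to water at
#' standard properties.  The walls are hydrophobic: the contact angle,
#' measured through the dispersed (aqueous) phase, defaults to 135 degrees.
#' The oil/water interfacial tension is not a property of either fluid alone
#' and is configuration-exposed; the default 0.040 N/m is typical of
#' fluorocarbon/water interfaces.
#'
#' @param mu_c,rho_c continuous-phase dynamic viscosity (Pa s) and density
#'   (kg/m^3).
#' @param mu_d,rho_d dispersed-phase viscosity and density.
#' @param sigma interfacial tension (N/m).
#' @param theta_wall_deg static contact angle at walls (degrees, through the
#'   dispersed phase).
#' @return object of class `"fluid_pair"`.
#' @export
fluid_pair <- function(mu_c = 1.365e-3, rho_c = 1.82e3,
                       mu_d = 1.0e-3, rho_d = 1.0e3,
                       sigma = 0.040, theta_wall_deg = 135) {
  stopifnot(mu_c > 0, rho_c > 0, mu_d > 0, rho_d > 0, sigma > 0,
            theta_wall_deg > 0, theta_wall_deg < 180)
  structure(list(mu_c = mu_c, rho_c = rho_c, mu_d = mu_d, rho_d = rho_d,
                 sigma = sigma, theta_wall_deg = theta_wall_deg),
            class = "fluid_pair")
}

#' Static-droplet-array geometry parameters
#'
#' One SDA unit per electrode, tiled on the array pitch with adjacent rows
#' mirrored about the x-axis for compactness.  Within each 3.16 x 3.16 um
#' tile the main channel runs below the reaction chamber and dead-ends a
#' short distance past the chamber mouth; the chamber sits above it as a
#' pocket reached through a short perpendicular neck.  Displaced oil leaves
#' the filling chamber through the capillary valve, a 0.2 um slit dropping
#' from the chamber floor into the bypass channel below, which carries the
#' flow onward: the bypass leaves the main channel through a constricted
#' down-shaft just past the neck, runs under the chamber and rises through
#' an end-of-tile riser (two 90-degree bends) into the front of the next
#' unit.
#'
#' The capillary entry pressures of the non-wetting aqueous phase order the
#' routes at each junction: the wide neck corner yields first, so the
#' chamber fills while oil vents through the valve; the narrower down-shaft
#' corner yields next, diverting the flow under the filled chamber; the
#' valve never admits water.  When the plug tail recedes along the channel
#' it sweeps across the flush chamber mouth, shearing the connecting thread
#' at the neck -- one droplet stays behind in each chamber.
#'
#' Widths must satisfy `valve_width < neck_width < channel_width`, and the
#' internal shaft aperture (0.35 um) lies between valve and neck so the
#' route ordering holds.
#'
#' @param unit_pitch tile pitch (um).
#' @param valve_width capillary-valve slit width (um).
#' @param chamber_width,chamber_height reaction-chamber dimensions (um).
#' @param neck_width chamber-mouth neck width (um).
#' @param neck_length chamber-mouth neck length (um); kept short so the
#'   passing tail shears the thread with minimal back-drainage.
#' @param channel_width main/bypass channel width (um).
#' @param n_units_x,n_units_y array extent in units.
#' @param mirrored mirror adjacent rows about the x-axis.
#' @param inlet_length injection-channel length ahead of the array (um).
#' @param outlet_length outlet extension behind the array (um).
#' @param plug_gap length of the continuous-phase gap at the front of the
#'   injection channel (um); the rest of the injection channel starts as
#'   dispersed phase.
#' @param inlet_channel_width injection-channel width (um).
#' @param cell_um uniform grid cell size (um).  The default, 1/32 of the
#'   pitch, makes every tile rasterize identically; other values should
#'   divide the pitch evenly or tiles will differ by single-cell jitter.
#' @return object of class `"sda_params"`.
#' @export
sda_geometry <- function(unit_pitch = 3.16, valve_width = 0.2,
                         chamber_width = 2.0, chamber_height = 1.2,
                         neck_width = 0.45, neck_length = 0.15,
                         channel_width = 0.7,
                         n_units_x = 4L, n_units_y = 4L, mirrored = TRUE,
                         inlet_length = 12, outlet_length = 2,
                         plug_gap = 1, inlet_channel_width = 1.0,
                         cell_um = unit_pitch / 32) {
  dims <- c(unit_pitch, valve_width, chamber_width, chamber_height,
            neck_width, neck_length, channel_width, inlet_length,
            outlet_length, inlet_channel_width, cell_um)
  if (any(dims <= 0)) stop("all dimensions must be positive")
  if (!(valve_width < neck_width && neck_width < channel_width))
    stop("width ordering violated: need valve_width < neck_width < channel_width")
  if (0.35 + chamber_width + 0.6 > unit_pitch + 1e-9)
    stop("chamber does not fit on the unit pitch")
  if (0.1 + 2 * channel_width + 0.3 + chamber_height + 0.16 > unit_pitch + 1e-9)
    stop("chamber, channel and bypass do not fit on the unit pitch")
  structure(list(unit_pitch = unit_pitch, valve_width = valve_width,
                 chamber_width = chamber_width, chamber_height = chamber_height,
                 neck_width = neck_width, neck_length = neck_length,
                 channel_width = channel_width,
                 n_units_x = as.integer(n_units_x),
                 n_units_y = as.integer(n_units_y), mirrored = mirrored,
                 inlet_length = inlet_length, outlet_length = outlet_length,
                 plug_gap = plug_gap, inlet_channel_width = inlet_channel_width,
                 cell_um = cell_um),
            class = "sda_params")
}

# region codes used in the rasterized domain
SDA_REGIONS <- c(solid = 0L, conduit = 1L, chamber = 2L, neck = 3L,
                 valve = 4L, bypass = 5L, riser = 6L, injection = 7L,
                 outlet = 8L)

#' Rasterize the SDA domain
#'
#' Builds the tiled 2D domain: per-unit main channel, perpendicular neck,
#' chamber pocket and capillary-valve vent, the bypass loop (down-shaft,
#' bottom run and end-of-tile riser) and the injection channel ahead of the
#' array plus an outlet extension behind it.  Cells are labelled by region;
#' the solver mask marks solid, fluid, inlet and outlet cells.
#'
#' @param params an [sda_geometry()].
#' @return object of class `"sda_geometry"`: list with the grid size
#'   (`nx`, `ny`, `h`), the solver `mask`, the `region` label matrix, and a
#'   `chambers` table with per-unit chamber cell ranges and rasterized areas.
#' @export
build_geometry <- function(params = sda_geometry()) {
  stopifnot(inherits(params, "sda_params"))
  P <- params$unit_pitch; h <- params$cell_um
  cw <- params$channel_width; nw <- params$neck_width; vw <- params$valve_width
  cbw <- params$chamber_width; cbh <- params$chamber_height
  # snap the injection/outlet lengths to the grid so tile origins fall on
  # cell boundaries and every tile rasterizes identically
  Li <- round(params$inlet_length / h) * h
  Lo <- round(params$outlet_length / h) * h

  # tile-local layout (y measured from the bottom of the row band)
  y_b0 <- 0.10; y_b1 <- y_b0 + cw               # bypass bottom run
  y_ch0 <- y_b1 + 0.15; y_ch1 <- y_ch0 + cw     # main channel
  y_cb0 <- y_ch1 + params$neck_length           # chamber floor
  y_cb1 <- y_cb0 + cbh
  if (y_cb1 > P - 0.15 + 1e-9) stop("chamber too tall for the pitch")
  x_cb0 <- 0.35; x_cb1 <- x_cb0 + cbw           # chamber
  x_n0 <- 0.45; x_n1 <- x_n0 + nw               # neck (flush chamber mouth)
  x_s0 <- x_n1 + 0.4; x_s1 <- x_s0 + 0.35       # bypass down-shaft (0.35)
  x_cd1 <- x_s1                                 # channel dead-ends past shaft
  x_r0 <- x_cb1 + 0.35                          # end-of-tile riser
  if (x_r0 > P - 0.4 + 1e-9) stop("riser does not fit on the pitch")
  y_v0 <- y_cb0 + 0.45; y_v1 <- y_v0 + vw       # valve vent (chamber side wall)

  rects <- list(  # list of c(x0, x1, y0, y1, region) in tile-local coords
    c(0, x_cd1, y_ch0, y_ch1, SDA_REGIONS[["conduit"]]),
    c(x_n0, x_n1, y_ch1, y_cb0, SDA_REGIONS[["neck"]]),
    c(x_cb0, x_cb1, y_cb0, y_cb1, SDA_REGIONS[["chamber"]]),
    c(x_cb1, x_r0 + 0.1, y_v0, y_v1, SDA_REGIONS[["valve"]]),
    c(x_s0, x_s1, y_b1, y_ch0, SDA_REGIONS[["bypass"]]),
    c(x_s0, P, y_b0, y_b1, SDA_REGIONS[["bypass"]]),
    c(x_r0, P, y_b0, y_v1 + 0.1, SDA_REGIONS[["riser"]]))

  x_len <- Li + params$n_units_x * P + Lo
  y_len <- params$n_units_y * P
  nx <- round(x_len / h); ny <- round(y_len / h)
  region <- matrix(0L, ny, nx)
  xc <- (seq_len(nx) - 0.5) * h; yc <- (seq_len(ny) - 0.5) * h

  mark <- function(x0, x1, y0, y1, code) {
    js <- which(xc >= x0 & xc < x1); is <- which(yc >= y0 & yc < y1)
    if (length(js) && length(is)) region[is, js] <<- code
  }

  chambers <- vector("list", params$n_units_x * params$n_units_y)
  k <- 0L
  for (uy in seq_len(params$n_units_y) - 1L) {
    band0 <- uy * P
    flip <- params$mirrored && (uy %% 2L == 1L)
    ty <- function(y0, y1) if (flip) c(band0 + P - y1, band0 + P - y0) else c(band0 + y0, band0 + y1)
    # injection channel and outlet extension join the row's main channel
    icw <- params$inlet_channel_width
    ych <- ty(y_ch0, y_ch1)
    ymid_g <- mean(ych)
    mark(0, Li, ymid_g - icw / 2, ymid_g + icw / 2, SDA_REGIONS[["injection"]])
    mark(Li + params$n_units_x * P, x_len, ych[1], ych[2], SDA_REGIONS[["outlet"]])
    for (ux in seq_len(params$n_units_x) - 1L) {
      tx0 <- Li + ux * P
      for (r in rects) {
        yy <- ty(r[3], r[4])
        mark(tx0 + r[1], tx0 + r[2], yy[1], yy[2], r[5])
      }
      yy <- ty(y_cb0, y_cb1)
      k <- k + 1L
      chambers[[k]] <- data.frame(
        unit_x = ux, unit_y = uy,
        x0 = tx0 + x_cb0, x1 = tx0 + x_cb1, y0 = yy[1], y1 = yy[2])
    }
  }
  chambers <- do.call(rbind, chambers)
  chambers$j0 <- vapply(chambers$x0, function(x) min(which(xc >= x)), integer(1))
  chambers$j1 <- vapply(chambers$x1, function(x) max(which(xc < x)), integer(1))
  chambers$i0 <- vapply(chambers$y0, function(y) min(which(yc >= y)), integer(1))
  chambers$i1 <- vapply(chambers$y1, function(y) max(which(yc < y)), integer(1))
  chambers$chamber_area_um2 <-
    (chambers$j1 - chambers$j0 + 1L) * (chambers$i1 - chambers$i0 + 1L) * h^2

  mask <- matrix(0L, ny, nx)
  mask[region > 0L] <- 1L
  inlet <- region[, 1L] == SDA_REGIONS[["injection"]]
  mask[which(inlet), 1L] <- 2L
  outlet <- region[, nx] == SDA_REGIONS[["outlet"]]
  mask[which(outlet), nx] <- 3L
  if (!any(inlet)) stop("no inlet cells: injection channel missed the left edge")
  if (!any(outlet)) stop("no outlet cells: outlet extension missed the right edge")

  structure(list(params = params, h = h, nx = nx, ny = ny,
                 x_len = x_len, y_len = y_len, xc = xc, yc = yc,
                 mask = mask, region = region, chambers = chambers),
            class = "sda_geometry")
}

#' @export
print.sda_geometry <- function(x, ...) {
  cat(sprintf("<sda_geometry> %dx%d units, %.2f x %.2f um domain, %d x %d cells (h = %g um)\n",
              x$params$n_units_x, x$params$n_units_y, x$x_len, x$y_len,
              x$nx, x$ny, x$h))
  cat(sprintf("  fluid fraction %.2f; chamber area %.3g um^2 (rasterized)\n",
              mean(x$mask > 0), x$chambers$chamber_area_um2[1]))
  invisible(x)
}
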