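#' Per-unit storage-capacitor circuit parameters
#'
#' Single-pole RC abstraction of one array unit: an ideal switch with on-path
#' resistance `R_on` charges the 1 pF storage capacitor from the `V_dd` supply;
#' when deselected the capacitor self-discharges through an off-state leakage
#' resistance `R_off`.  The electrode sits on the capacitor node, so electrode
#' voltage equals capacitor voltage; electrochemical load current is not
#' modelled.
#'
#' `R_on` is not a free choice: it is calibrated so that one 80 ns pulse from
#' the 5 V supply lands exactly on the 3 V set-point (see
#' [calibrate_on_resistance()]), which simultaneously reproduces the ~1 V
#' reached after 20 ns.  `R_off` controls droop between refreshes; the default
#' 2.5e11 ohm yields ~2.5 % droop over a full 6.326 ms refresh pass, well
#' inside the 5 % envelope the design budgets for.
#'
#' @param C capacitance in farad.
#' @param V_dd supply voltage in volt.
#' @param R_on on-path resistance in ohm; `NULL` calibrates it from
#'   `(V_target, t_on_cal)`.
#' @param R_off off-state leakage resistance in ohm (may be `Inf`).
#' @param V_target,t_on_cal calibration point for `R_on`.
#' @return object of class `"rc_params"`.
#' @examples
#' p <- rc_params()
#' p$R_on / 1e3   # ~87.31 kOhm
#' @export
rc_params <- function(C = 1e-12, V_dd = 5, R_on = NULL, R_off = 2.5e11,
                      V_target = 3, t_on_cal = 80e-9) {
  stopifnot(C > 0, V_dd > 0, R_off > 0)
  if (is.null(R_on))
    R_on <- calibrate_on_resistance(V_target, t_on_cal, C = C, V_dd = V_dd)
  stopifnot(R_on > 0)
  structure(list(C = C, V_dd = V_dd, R_on = R_on, R_off = R_off,
                 V_target = V_target, t_on_cal = t_on_cal),
            class = "rc_params")
}

#' @export
print.rc_params <- function(x, ...) {
  cat(sprintf("<rc_params> C=%.3g F, V_dd=%.3g V, R_on=%.4g Ohm (tau_on=%.4g s), R_off=%.3g Ohm\n",
              x$C, x$V_dd, x$R_on, x$R_on * x$C, x$R_off))
  invisible(x)
}

#' Calibrate the on-path resistance from a printed operating point
#'
#' Solves `V_dd * (1 - exp(-t_on / (R_on * C))) = V_target` for `R_on`:
#' `R_on = t_on / (C * log(V_dd / (V_dd - V_target)))`.  With the default
#' (80 ns, 3 V, 5 V, 1 pF) point this gives tau = 87.31 ns, R_on = 87.31 kOhm.
#'
#' @param V_target voltage reached after `t_on` (V); must satisfy
#'   `0 < V_target < V_dd`.
#' @param t_on charging duration (s).
#' @param C capacitance (F).
#' @param V_dd supply voltage (V).
#' @return on-resistance in ohm.
#' @export
calibrate_on_resistance <- function(V_target = 3, t_on = 80e-9,
                                    C = 1e-12, V_dd = 5) {
  if (V_target >= V_dd)
    stop("infeasible calibration: V_target must be below the supply voltage")
  if (V_target <= 0) stop("infeasible calibration: V_target must be positive")
  stopifnot(t_on > 0, C > 0)
  t_on / (C * log(V_dd / (V_dd - V_target)))
}

#' Capacitor voltage after a charging pulse
#'
#' `V(t_on) = V_dd * (1 - exp(-t_on / (R_on * C)))` starting from `from` volt
#' (0 by default): 3.00 V after 80 ns, ~1 V after 20 ns with calibrated
#' defaults.  Monotone increasing in `t_on` and bounded by `V_dd`.
#'
#' @param t_on charging duration in seconds (scalar or vector, >= 0).
#' @param params an [rc_params()].
#' @param from initial capacitor voltage (V).
#' @return voltage in volt.
#' @export
charge_voltage <- function(t_on, params = rc_params(), from = 0) {
  if (any(t_on < 0)) stop("charging time must be non-negative")
  tau <- params$R_on * params$C
  params$V_dd - (params$V_dd - from) * exp(-t_on / tau)
}

#' Capacitor voltage after self-discharge
#'
#' `V = V0 * exp(-t_off / (R_off * C))`; with the defaults a full 6.326 ms
#' refresh pass lets 3 V droop to 2.925 V (2.50 %).
#'
#' @param V0 initial voltage (V).
#' @param t_off discharge duration in seconds (scalar or vector, >= 0).
#' @inheritParams charge_voltage
#' @return voltage in volt.
#' @export
discharge_voltage <- function(V0, t_off, params = rc_params()) {
  stopifnot(all(t_off >= 0))
  V0 * exp(-t_off / (params$R_off * params$C))
}

#' Steady-state refresh ripple
#'
#' Periodic steady state of one unit under the refresh logic: every `t_cycle`
#' the driver tops the capacitor up to the set-point `charge_voltage(t_on)`
#' (charging is voltage-gated: the fabric moves on once the set-point is
#' reached), after which the capacitor leaks for the remainder of the cycle.
#' The peak is therefore the set-point and the trough is its leakage decay over
#' `t_cycle - t_on`:
#' `droop = 100 * (1 - exp(-(t_cycle - t_on) / (R_off * C)))` percent.
#'
#' @param t_on charging duration defining the set-point (s).
#' @param t_cycle refresh period (s), the full-array scan time by default.
#' @inheritParams charge_voltage
#' @return list with `V_max`, `V_min` (volt) and `droop_pct`.
#' @examples
#' steady_state_ripple()$droop_pct   # ~2.5 %
#' @export
steady_state_ripple <- function(t_on = 80e-9, t_cycle = 6.326e-3,
                                params = rc_params()) {
  stopifnot(t_cycle > t_on)
  V_max <- charge_voltage(t_on, params)
  V_min <- discharge_voltage(V_max, t_cycle - t_on, params)
  list(V_max = V_max, V_min = V_min,
       droop_pct = 100 * (V_max - V_min) / V_max)
}

#' Voltage waveform of one unit under a refresh schedule
#'
#' Piecewise-exponential trace of a unit's electrode voltage while the fabric
#' cycles through `schedule` for `n_cycles` passes.  The unit charges toward
#' `V_dd` during the instances that select it (gated at the set-point on
#' refresh passes) and leaks through `R_off` otherwise.  A unit never selected
#' yields a flat zero trace.
#'
#' @param schedule a `"chip_schedule"`.
#' @param unit `c(row, col)` 0-based unit address.
#' @param params an [rc_params()].
#' @param n_cycles number of refresh passes.
#' @param geometry an [array_geometry()].
#' @param samples_per_segment sample points per exponential segment.
#' @return data.frame of class `"waveform"` with `time_s`, `voltage_V`.
#' @export
waveform <- function(schedule, unit, params = rc_params(), n_cycles = 5,
                     geometry = array_geometry(), samples_per_segment = 24) {
  stopifnot(inherits(schedule, "chip_schedule"), length(unit) == 2L)
  tab <- schedule$instances
  t_ns <- tab$t_charge_ns
  starts_ns <- cumsum(c(0, t_ns))[seq_len(nrow(tab))]
  cpb <- geometry$cols_per_block
  hit <- which(tab$row == unit[1L] &
                 vapply(seq_len(nrow(tab)), function(k) {
                   (unit[2L] %% cpb) == tab$offset[k] &&
                     (unit[2L] %/% cpb) %in% tab$blocks[[k]]
                 }, logical(1)))
  Tpass <- scan_time(schedule)
  if (length(hit) == 0L) {
    tt <- seq(0, n_cycles * Tpass, length.out = max(2L, n_cycles * samples_per_segment))
    return(structure(data.frame(time_s = tt, voltage_V = 0), class = c("waveform", "data.frame")))
  }
  if (length(hit) > 1L)
    stop("unit selected twice within one pass; schedules must select a unit at most once")
  t_sel <- starts_ns[hit] * 1e-9
  dt_on <- t_ns[hit] * 1e-9
  tau_on <- params$R_on * params$C
  tau_off <- params$R_off * params$C
  V_set <- charge_voltage(dt_on, params)  # set-point implied by the dwell time

  times <- numeric(0); volts <- numeric(0)
  emit <- function(t0, t1, f) {
    tt <- seq(t0, t1, length.out = samples_per_segment)
    times <<- c(times, tt); volts <<- c(volts, f(tt - t0))
  }
  V <- 0
  for (cyc in seq_len(n_cycles)) {
    base <- (cyc - 1) * Tpass
    t_on_start <- base + t_sel
    if (t_on_start > base) {
      V0 <- V
      emit(base, t_on_start, function(d) V0 * exp(-d / tau_off))
      V <- V0 * exp(-(t_on_start - base) / tau_off)
    }
    # charging: first pass runs the full dwell; refreshes gate at the set-point
    V0 <- V
    if (cyc == 1L) {
      t_chg <- dt_on
    } else {
      t_chg <- min(dt_on, tau_on * log((params$V_dd - V0) / (params$V_dd - V_set)))
    }
    emit(t_on_start, t_on_start + t_chg,
         function(d) params$V_dd - (params$V_dd - V0) * exp(-d / tau_on))
    V <- params$V_dd - (params$V_dd - V0) * exp(-t_chg / tau_on)
    # decay to end of pass
    t_end <- base + Tpass
    V0 <- V
    emit(t_on_start + t_chg, t_end, function(d) V0 * exp(-d / tau_off))
    V <- V0 * exp(-(t_end - (t_on_start + t_chg)) / tau_off)
  }
  structure(data.frame(time_s = times, voltage_V = volts),
            class = c("waveform", "data.frame"))
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples over %.4g s, peak %.4g V\n",
              nrow(x), max(x$time_s), max(x$voltage_V)))
  invisible(x)
}
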