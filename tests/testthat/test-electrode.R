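test_that("on-resistance calibration solves the printed operating point", {
  R_on <- calibrate_on_resistance(3, 80e-9, C = 1e-12, V_dd = 5)
  tau <- R_on * 1e-12
  expect_equal(tau, 80e-9 / log(5 / 2))
  expect_equal(R_on, 87312, tolerance = 1e-4)       # 87.31 kOhm
  # algebraic identity: calibrating at (V_dd/2, tau*ln 2) recovers the same tau
  R2 <- calibrate_on_resistance(2.5, tau * log(2), C = 1e-12, V_dd = 5)
  expect_equal(R2 * 1e-12, tau, tolerance = 1e-12)
  expect_error(calibrate_on_resistance(5, 80e-9), "infeasible")
  expect_error(calibrate_on_resistance(5.5, 80e-9), "infeasible")
  # vanishing targets demand enormous on-resistance (R_on -> Inf as V -> 0)
  expect_gt(calibrate_on_resistance(1e-4, 80e-9), 1e2 * R_on)
})

test_that("charge curve hits both printed operating points with one calibrated pole", {
  p <- rc_params()
  expect_equal(charge_voltage(80e-9, p), 3)
  expect_equal(charge_voltage(0, p), 0)
  v20 <- charge_voltage(20e-9, p)
  expect_equal(v20, 5 * (1 - exp(-20 / (80 / log(5 / 2)))))
  expect_equal(round(v20), 1)                       # ~1 V
  # monotone increasing, bounded by the supply
  tt <- seq(0, 500e-9, length.out = 200)
  vv <- charge_voltage(tt, p)
  expect_true(all(diff(vv) > 0))
  expect_true(all(vv >= 0 & vv <= p$V_dd))
  expect_error(charge_voltage(-1e-9, p), "non-negative")
})

test_that("discharge decays exponentially through the leakage path", {
  p <- rc_params()
  expect_equal(discharge_voltage(3, 0, p), 3)
  expect_equal(discharge_voltage(0, 1, p), 0)
  v <- discharge_voltage(3, 6.326e-3, p)
  expect_equal(v, 3 * exp(-6.326e-3 / (p$R_off * p$C)))
  expect_equal(v, 2.925, tolerance = 1e-3)
  tt <- seq(0, 1, length.out = 50)
  expect_true(all(diff(discharge_voltage(3, tt, p)) < 0))
})

test_that("steady-state ripple stays within the 5% budget and vanishes without leakage", {
  p <- rc_params()
  r <- steady_state_ripple(80e-9, 6.326e-3, p)
  expect_equal(r$V_max, 3)
  expect_equal(r$droop_pct, 2.5, tolerance = 0.01)
  expect_lte(r$droop_pct, 5)
  r0 <- steady_state_ripple(80e-9, 6.326e-3, rc_params(R_off = Inf))
  expect_equal(r0$droop_pct, 0)
  # output range sweeps ~0-3 V as the dwell sweeps 0-80 ns
  expect_equal(charge_voltage(c(0, 80e-9), p), c(0, 3))
})

test_that("closed forms match a brute-force Euler integration to <0.1%", {
  p <- rc_params()
  # one charge pulse
  v_euler <- euler_rc(data.frame(duration_s = 80e-9, on = TRUE), p)
  expect_equal(charge_voltage(80e-9, p), v_euler, tolerance = 1e-3)
  # charge then a full refresh period of decay
  segs <- data.frame(duration_s = c(80e-9, 6.326e-3 - 80e-9), on = c(TRUE, FALSE))
  v2 <- euler_rc(segs, p)
  r <- steady_state_ripple(80e-9, 6.326e-3, p)
  expect_equal(r$V_min, v2, tolerance = 1e-3)
  # droop agreement
  droop_euler <- 100 * (charge_voltage(80e-9, p) - v2) / charge_voltage(80e-9, p)
  expect_equal(r$droop_pct, droop_euler, tolerance = 1e-3)
})

test_that("waveforms track selection, top-up refresh and leakage", {
  g <- array_geometry(10, 10, 4)
  p <- rc_params()
  sch <- schedule_mask(data.frame(row = c(2, 5), col = c(4, 7)),
                       t_charge_ns = 80, geometry = g)
  wf <- waveform(sch, c(2, 4), p, n_cycles = 4, geometry = g)
  expect_true(all(wf$voltage_V >= 0 & wf$voltage_V <= p$V_dd))
  expect_equal(max(wf$voltage_V), 3, tolerance = 1e-6)
  # peaks equal across refresh cycles (voltage-gated top-up)
  Tpass <- scan_time(sch)
  peaks <- vapply(1:4, function(cy) {
    seg <- wf$voltage_V[wf$time_s >= (cy - 1) * Tpass & wf$time_s <= cy * Tpass]
    max(seg)
  }, numeric(1))
  expect_lt(max(peaks) - min(peaks), 1e-6)
  # unselected unit stays flat at zero
  wf0 <- waveform(sch, c(9, 9), p, n_cycles = 2, geometry = g)
  expect_true(all(wf0$voltage_V == 0))
  # single charge, never refreshed: rising edge then monotone decay
  one <- schedule_mask(data.frame(row = 0, col = 0), geometry = g)
  wf1 <- waveform(one, c(0, 0), p, n_cycles = 1, geometry = g)
  expect_equal(max(wf1$voltage_V), 3, tolerance = 1e-6)
})
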