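aff <- healthy_parameters()$reflex$afferent
eff <- healthy_parameters()$reflex$efferent

test_that("arterial afferent sigmoid: set-point, bounds, monotonicity", {
  # at the set-point the firing is the sigmoid midpoint
  expect_equal(arterial_afferent_static(aff$Pn, aff),
               (aff$f_min + aff$f_max) / 2)
  # saturation limits
  expect_equal(arterial_afferent_static(1e4, aff), aff$f_max, tolerance = 1e-6)
  expect_equal(arterial_afferent_static(-1e4, aff), aff$f_min, tolerance = 1e-6)
  # monotone increasing
  P <- seq(20, 180, by = 1)
  expect_true(all(diff(arterial_afferent_static(P, aff)) > 0))
})

test_that("carotid input falls by the hydrostatic column during tilt", {
  # oracle: rho*g*0.16*sin(alpha) in mmHg
  drop <- 1060 * 9.81 * 0.16 * sin(60 * pi / 180) / 133.322
  expect_equal(carotid_input_pressure(90, 60) , 90 - drop)
  expect_equal(carotid_input_pressure(90, 0), 90)
})

test_that("cardiopulmonary afferent: set-point, sign, disabled mode", {
  cp <- list(gain = 0.05, Pcv_n = 4.4, cap = 0.6)
  expect_equal(cp_afferent(4.4, cp), 0)
  # below set-point: positive drive (raises peripheral resistance downstream)
  expect_gt(cp_afferent(2, cp), 0)
  expect_lt(cp_afferent(8, cp), 0)
  expect_equal(cp_afferent(-100, cp), cp$cap)   # bounded
  off <- cp; off$gain <- 0
  expect_equal(cp_afferent(c(0, 5, 15), off), c(0, 0, 0))  # invariant to Pcv
})

test_that("efferent activities: baroreflex signs and CP wiring", {
  lo <- efferent_activities(10, eff)   # hypotension: low afferent firing
  hi <- efferent_activities(40, eff)
  expect_gt(lo$f_es, hi$f_es)          # sympathetic falls with firing
  expect_lt(lo$f_ev, hi$f_ev)          # vagal rises with firing
  # CP drive modulates only the resistance branch
  with_cp <- efferent_activities(25, eff, f_cp = 0.3)
  no_cp <- efferent_activities(25, eff, f_cp = 0)
  expect_equal(with_cp$f_es, no_cp$f_es)
  expect_equal(with_cp$f_ev, no_cp$f_ev)
  expect_equal(with_cp$x_res, no_cp$x_res + 0.3)
})

test_that("effector first-order response, desensitization, zero gain", {
  dt <- 0.01
  n <- 5000
  drive <- rep(1.5, n)           # constant drive step from reference 1.0
  y <- effector_update(drive, base = 10, gain = 0.4, x0 = 1, tau = 4, dt = dt)
  sigma <- 10 * (1 + 0.4 * 0.5)
  # converges to the static value within 5 tau to < 1%
  i5 <- round(5 * 4 / dt)
  expect_lt(abs(y[i5] - sigma) / sigma, 0.01)
  # desensitization factor 10: steady deviation from base is 1/10 of normal
  yd <- effector_update(drive, base = 10, gain = 0.4, x0 = 1, tau = 4,
                        dt = dt, kD = 10)
  expect_equal(yd[n] - 10, (y[n] - 10) / 10, tolerance = 1e-3)
  # zero gain pins the effector at its baseline
  y0 <- effector_update(drive, base = 10, gain = 0, x0 = 1, tau = 4, dt = dt)
  expect_true(all(abs(y0 - 10) < 1e-12))
  # latency shifts the response to a drive step
  step_drive <- c(rep(1, 100), rep(1.5, n))
  ys <- effector_update(step_drive, base = 10, gain = 0.4, x0 = 1, tau = 4,
                        dt = dt)
  yl <- effector_update(step_drive, base = 10, gain = 0.4, x0 = 1, tau = 4,
                        dt = dt, D = 2)
  nD <- round(2 / dt)
  expect_equal(yl[100 + nD + 50], ys[100 + 50], tolerance = 1e-6)
})

test_that("myogenic lower-body resistance law", {
  myo <- list(k_myo = 0.01, Ptm_ref = 19.6)
  expect_equal(lower_body_resistance(5.77, 19.6, myo), 5.77)   # set-point
  off <- list(k_myo = 0, Ptm_ref = 19.6)
  expect_equal(lower_body_resistance(5.77, 90, off), 5.77)     # disabled
  expect_gt(lower_body_resistance(5.77, 60, myo), 5.77)        # constriction
  expect_error(lower_body_resistance(-1, 20, myo), "positive")
})

test_that("calibrated myogenic constant doubles the lower-body resistance rise", {
  r <- healthy_pair()
  rise_lb <- r$R_lb[2] / r$R_lb[1] - 1
  rise_up <- r$R_up[2] / r$R_up[1] - 1
  expect_equal(rise_lb / rise_up, 2, tolerance = 0.15)
})
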