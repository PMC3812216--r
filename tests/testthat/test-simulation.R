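test_that("derivatives conserve total volume and reject bad input", {
  p <- healthy_parameters()
  st <- initial_state(p)$state
  d <- cvs_derivatives(p, st, phase = 0.2, alpha = 30)
  vol_idx <- 1:21
  expect_lt(abs(sum(d$deriv[vol_idx])), 1e-10)     # closed loop
  expect_error(cvs_derivatives(p, st[-1]), "length")
  expect_error(cvs_derivatives(p, st, T_beat = -1), "period")
})

test_that("finite-difference Jacobian is consistent across step sizes", {
  # two independent central-difference schemes must agree where the
  # right-hand side is smooth
  p <- healthy_parameters()
  set.seed(42)
  st <- initial_state(p)$state * runif(38, 0.97, 1.03)
  st[22:25] <- abs(st[22:25]) + 5   # valves open, away from switching
  f <- function(x) cvs_derivatives(p, x, phase = 0.55, alpha = 20)$deriv
  idx <- c(1, 5, 12, 18, 26, 36)    # representative states
  for (j in idx) {
    for (h in c(1e-3, 1e-4)) {
      xp <- st; xm <- st
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      assign(paste0("g", h), (f(xp) - f(xm)) / (2 * h))
    }
    scale <- pmax(abs(`g0.001`), 1e-4)
    expect_lt(max(abs(`g0.001` - `g1e-04`) / scale), 0.05)
  }
})

test_that("supine run settles to a periodic orbit", {
  sim <- supine_sim()
  expect_true(beats_converged(sim$beats, n = 5, tol = 1e-3))
  # stroke volume from the LV volume trace equals the aortic-flow integral
  last <- utils::tail(sim$beats, 5)
  expect_lt(max(abs(last$SV - last$SV_flow) / last$SV), 0.005)
  # cardiac output equals the sum of the six branch flows (conservation)
  qsum <- rowSums(last[, c("Q_cerebral", "Q_upper", "Q_coronary",
                           "Q_splanchnic", "Q_renal", "Q_lower")]) * 0.06
  expect_lt(max(abs(qsum - last$CO) / last$CO), 0.01)
})

test_that("two identical segments produce statistically identical beats", {
  p <- healthy_parameters()
  sim <- simulate_cvs(p, tilt_protocol(c(30, 30), c(80, 80)), record = FALSE)
  b <- sim$beats
  s1 <- b[b$t_start > 50 & b$t_start < 80, ]
  s2 <- b[b$t_start > 130 & b$t_start < 160, ]
  expect_equal(mean(s1$MAP), mean(s2$MAP), tolerance = 1e-3)
  expect_equal(mean(s1$CO), mean(s2$CO), tolerance = 1e-3)
})

test_that("supine trajectories are independent of hydrostatic distances", {
  p <- healthy_parameters()
  p0 <- p
  for (b in c("b", "u", "h", "s", "k", "lb"))
    p0 <- param_set(p0, paste0("circ.", b, ".h"), 0)
  p0 <- param_set(p0, "reflex.afferent.h_carotid", 0)
  s1 <- simulate_cvs(p, tilt_protocol(0, 20), record = TRUE)$series
  s2 <- simulate_cvs(p0, tilt_protocol(0, 20), record = TRUE)$series
  expect_equal(s1$P_sa, s2$P_sa, tolerance = 1e-12)
  expect_equal(s1$V_lbv, s2$V_lbv, tolerance = 1e-12)
})

test_that("simulation is deterministic given identical inputs", {
  p <- healthy_parameters()
  b1 <- simulate_cvs(p, tilt_protocol(c(0, 50), c(30, 30)), record = FALSE)$beats
  b2 <- simulate_cvs(p, tilt_protocol(c(0, 50), c(30, 30)), record = FALSE)$beats
  expect_identical(b1, b2)
})

test_that("beat summaries recover an imposed period and average pressures", {
  # synthetic series with known period 0.8 s (75 bpm)
  T <- 0.8
  t <- seq(0, 8, by = 0.002)
  series <- data.frame(
    t = t,
    e_v = activation(t, T),
    V_lv = 100 - 30 * sin(2 * pi * t / T)^2,
    P_sa = 90 + 10 * sin(2 * pi * t / T),
    P_la = 6, P_pa = 15, P_tv = 4,
    Q_av = pmax(0, 300 * sin(2 * pi * t / T)))
  bs <- beat_summaries(series)
  expect_true(nrow(bs) >= 3)
  expect_equal(mean(bs$HR), 75, tolerance = 0.01)
  expect_equal(mean(bs$SV), 30, tolerance = 0.01)
  expect_equal(mean(bs$MAP), 90, tolerance = 0.3)
  expect_error(beat_summaries(series[series$t < 1.7, ]), "insufficient")
})

test_that("angle sweep reports reference point and convergence flags", {
  r <- healthy_pair()
  expect_equal(r$dMAP[1], 0)
  expect_equal(r$pct_SV[1], 0)
  expect_true(all(r$converged))
  expect_error(steady_state_response(healthy_parameters(), c(20, 0)),
               "ascending")
})

test_that("halving the integration step leaves beat averages unchanged", {
  p <- healthy_parameters()
  r1 <- steady_state_response(p, c(0, 60), settle = 60, dt = 1e-3)
  r2 <- steady_state_response(p, c(0, 60), settle = 60, dt = 5e-4)
  for (v in c("MAP", "CO", "SV", "HR"))
    expect_lt(max(abs(r1[[v]] / r2[[v]] - 1)), 1e-3)
})
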