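# estimation tests run on a reduced angle grid with short settling so the
# whole file stays light; the generator and objective share those controls

test_that("synthetic measurements are deterministic and noise-scaled", {
  p <- healthy_parameters()
  m0 <- synth_measurements(p, noise_sd = c(MAP = 0, HR = 0, SV = 0, CO = 0,
                                           dMAP = 0, pct_HR = 0, pct_SV = 0,
                                           pct_CO = 0),
                           seed = 7, angles = c(0, 40), n_subjects = 3,
                           settle = est_settle, dt = est_dt)
  # noise-free measurements equal the model outputs, identical across subjects
  wide <- split(m0$value, m0$subject)
  expect_equal(wide[[1]], wide[[2]])
  resp <- attr(m0, "response")
  expect_equal(m0$value[m0$variable == "MAP"][1], resp$MAP[1])
  # same seed twice gives identical draws
  m1 <- synth_measurements(p, seed = 11, angles = c(0, 40), n_subjects = 3,
                           settle = est_settle, dt = est_dt)
  m2 <- synth_measurements(p, seed = 11, angles = c(0, 40), n_subjects = 3,
                           settle = est_settle, dt = est_dt)
  expect_identical(m1$value, m2$value)
  # sample SD across many subjects approximates the requested noise SD
  m3 <- synth_measurements(p, noise_sd = c(MAP = 4, HR = 3, SV = 4, CO = 0.3,
                                           dMAP = 2, pct_HR = 3, pct_SV = 4,
                                           pct_CO = 4),
                           seed = 5, angles = c(0, 40), n_subjects = 400,
                           settle = est_settle, dt = est_dt)
  sd_map <- sd(m3$value[m3$variable == "MAP"])
  expect_lt(abs(sd_map - 4) / 4, 0.10)
})

test_that("objective arithmetic and ordering invariance", {
  p <- healthy_parameters()
  zero_sd <- c(MAP = 0, HR = 0, SV = 0, CO = 0, dMAP = 0, pct_HR = 0,
               pct_SV = 0, pct_CO = 0)
  m <- synth_measurements(p, noise_sd = zero_sd, seed = 3, angles = c(0, 40),
                          n_subjects = 2, settle = est_settle, dt = est_dt)
  # single residual of 2 with weight 3 contributes 12
  one <- m[1, ]
  one$value <- one$value - 2
  one$weight <- 3
  resp <- attr(m, "response")
  expect_equal(estimation_objective(p, one, resp = resp), 12)
  m$value <- m$value + stats::rnorm(nrow(m), 0, 2)   # make J positive
  # doubling all weights doubles the objective
  J1 <- estimation_objective(p, m, resp = resp)
  m2 <- m; m2$weight <- 2 * m2$weight
  expect_equal(estimation_objective(p, m2, resp = resp), 2 * J1)
  # invariant to row ordering
  expect_equal(estimation_objective(p, m[sample(nrow(m)), ], resp = resp), J1)
  # model-generated noise-free data at the generating parameters: J = 0
  m0 <- synth_measurements(p, noise_sd = c(MAP = 0, HR = 0, SV = 0, CO = 0,
                                           dMAP = 0, pct_HR = 0, pct_SV = 0,
                                           pct_CO = 0),
                           seed = 1, angles = c(0, 40), n_subjects = 2,
                           settle = est_settle, dt = est_dt)
  expect_equal(estimation_objective(p, m0, settle = est_settle, dt = est_dt), 0,
               tolerance = 1e-12)
})

test_that("constraint violations measure the distance to the two targets", {
  resp <- data.frame(angle = c(0, 80), pct_V_thoracic = c(0, -20),
                     R_lb = c(5, 10), R_up = c(8, 12))
  cv <- constraint_violations(resp)
  # thoracic reduction 20%: six points short of the 26% band edge
  expect_equal(unname(cv["thoracic"]), -6)
  # lower-body rise 1.0 vs twice the upper-body rise 0.5
  expect_equal(unname(cv["lb_resistance"]), 1.0 - 2 * 0.5)
  ok <- data.frame(angle = c(0, 80), pct_V_thoracic = c(0, -28),
                   R_lb = c(5, 10), R_up = c(8, 12))
  expect_equal(unname(constraint_violations(ok)["thoracic"]), 0)
  # fitted healthy defaults satisfy both constraints
  cv0 <- constraint_violations(healthy_pair())
  expect_equal(unname(cv0["thoracic"]), 0)
  expect_lt(abs(cv0["lb_resistance"]), 0.25)
  # disabled autoregulation violates the resistance-ratio constraint
  noar <- hypothesis_toggles(healthy_parameters(), autoregulation = FALSE)
  rna <- steady_state_response(noar, c(0, 80), settle = 60, dt = est_dt)
  expect_lt(constraint_violations(rna)["lb_resistance"], -0.25)
})

test_that("sensitivity coefficients follow the +10% perturbation rule", {
  p <- healthy_parameters()
  m <- synth_measurements(p, seed = 9, angles = c(0, 40), n_subjects = 3,
                          settle = est_settle, dt = est_dt)
  sc <- sensitivity_screen(p, m, paths = c("reflex.T_base",
                                           "heart.peri.frozen_P",
                                           "reflex.eff.tau_R"),
                           settle = est_settle, dt = est_dt)
  J0 <- attr(sc, "J0")
  # coefficient equals ((J - J0)/J0)/0.1 by construction of the screen
  expect_equal(sc$S, ((sc$J - J0) / J0) / 0.1)
  # frozen-pressure parameter is inert while the pericardium is dynamic
  expect_equal(sc$S[sc$path == "heart.peri.frozen_P"], 0)
  # a steady-state-relevant baseline outranks an effector time constant
  expect_gt(abs(sc$S[sc$path == "reflex.T_base"]),
            abs(sc$S[sc$path == "reflex.eff.tau_R"]))
})

test_that("subset reduction drops the most co-dependent parameter", {
  cm <- diag(3)
  rownames(cm) <- colnames(cm) <- c("a", "b", "c")
  # identity covariance: nothing is co-dependent, nothing removed
  expect_true(is.na(cardiotilt:::pick_drop_candidate(cm)))
  # a perfectly correlated pair: one of its members is removed first
  cm2 <- cm
  cm2["a", "b"] <- cm2["b", "a"] <- 0.999
  cm2["a", "c"] <- cm2["c", "a"] <- 0.30
  expect_identical(cardiotilt:::pick_drop_candidate(cm2), "a")
})

test_that("fit recovers the generating parameters from noise-free data", {
  p <- healthy_parameters()
  m0 <- synth_measurements(p, noise_sd = c(MAP = 0, HR = 0, SV = 0, CO = 0,
                                           dMAP = 0, pct_HR = 0, pct_SV = 0,
                                           pct_CO = 0),
                           seed = 1, angles = c(0, 60), n_subjects = 2,
                           settle = est_settle, dt = est_dt)
  spec <- list(paths = c("reflex.T_base", "heart.lvf.Ees"),
               lower = c(0.5, 0.5), upper = c(2, 2))
  # starting at the truth: immediate optimum with J ~ 0
  spec$start <- c(1, 1)
  fit0 <- fit_parameters(m0, spec, base = p, settle = est_settle, dt = est_dt,
                         control = minpack.lm::nls.lm.control(maxiter = 3))
  expect_lt(fit0$J, 1e-10)
  expect_equal(unname(fit0$factors), c(1, 1), tolerance = 1e-4)
})
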