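#' Synthetic tilt-table measurement set
#'
#' Runs the model at the experimental angle grid and emits per-subject
#' observation tables with independent Gaussian noise, emulating a
#' 13-subject graded head-up-tilt dataset: supine absolutes of mean arterial
#' pressure, heart rate, stroke volume and cardiac output, plus the change
#' in MAP (mmHg) and percentage changes in HR, SV and CO at each non-zero
#' angle.
#'
#' @param true_params generating `cvs_params`
#' @param noise_sd named numeric vector of observation SDs for variables
#'   `MAP`, `HR`, `SV`, `CO` (absolute units) and `dMAP`, `pct_HR`,
#'   `pct_SV`, `pct_CO` (mmHg / percentage points); 0 = noise-free
#' @param seed RNG seed (deterministic output per seed)
#' @param angles tilt grid (must start at 0)
#' @param n_subjects number of subjects
#' @param settle,dt simulation controls passed to [steady_state_response()]
#' @param weights optional named weights per variable; default inverse
#'   squared typical scale, so residuals in mmHg, bpm, mL, L/min and
#'   percentage points are comparable
#' @return `measurement_set`: data.frame with columns
#'   `subject, angle, variable, value, weight`, with the model response and
#'   the generator settings as attributes
#' @export
synth_measurements <- function(true_params,
                               noise_sd = c(MAP = 4, HR = 3, SV = 4, CO = 0.3,
                                            dMAP = 2, pct_HR = 3, pct_SV = 4,
                                            pct_CO = 4),
                               seed = 1,
                               angles = c(0, 20, 30, 40, 50, 60, 70, 80),
                               n_subjects = 13,
                               settle = 120, dt = 5e-4,
                               weights = NULL) {
  stopifnot(all(noise_sd >= 0))
  resp <- steady_state_response(true_params, angles, settle = settle, dt = dt)
  if (is.null(weights))
    weights <- c(MAP = 1 / 90^2, HR = 1 / 70^2, SV = 1 / 70^2, CO = 1 / 5^2,
                 dMAP = 1 / 5^2, pct_HR = 1 / 30^2, pct_SV = 1 / 30^2,
                 pct_CO = 1 / 30^2)
  truth <- model_observations(resp)
  set.seed(seed)
  rows <- lapply(seq_len(n_subjects), function(s) {
    v <- truth$value + stats::rnorm(nrow(truth), 0, noise_sd[truth$variable])
    data.frame(subject = s, angle = truth$angle, variable = truth$variable,
               value = v, weight = unname(weights[truth$variable]))
  })
  out <- do.call(rbind, rows)
  attr(out, "response") <- resp
  attr(out, "noise_sd") <- noise_sd
  attr(out, "angles") <- angles
  class(out) <- c("measurement_set", "data.frame")
  out
}

# model outputs in measurement layout (one row per angle x variable)
model_observations <- function(resp) {
  sup <- data.frame(angle = 0,
                    variable = c("MAP", "HR", "SV", "CO"),
                    value = c(resp$MAP[1], resp$HR[1], resp$SV[1], resp$CO[1]))
  tl <- resp[resp$angle > 0, ]
  if (nrow(tl) == 0) return(sup)
  tilt <- do.call(rbind, lapply(seq_len(nrow(tl)), function(i) {
    data.frame(angle = tl$angle[i],
               variable = c("dMAP", "pct_HR", "pct_SV", "pct_CO"),
               value = c(tl$dMAP[i], tl$pct_HR[i], tl$pct_SV[i],
                         tl$pct_CO[i]))
  }))
  rbind(sup, tilt)
}

#' Weighted least-squares objective
#'
#' `J = sum_i w_i (y_model,i - y_meas,i)^2` over all subjects, angles and
#' variables. Simulation failures return a large penalty (with a warning)
#' so the optimizer can continue.
#'
#' @param params candidate `cvs_params`
#' @param data `measurement_set`
#' @param settle,dt simulation controls
#' @param resp optional precomputed [steady_state_response()] for `params`
#' @return non-negative scalar objective
#' @export
estimation_objective <- function(params, data, settle = 60, dt = 1e-3,
                                 resp = NULL) {
  r <- estimation_residuals(params, data, settle = settle, dt = dt,
                            resp = resp)
  sum(r^2)
}

#' Weighted residual vector (sqrt-weighted), used by the fitter
#' @inheritParams estimation_objective
#' @param constraint_weight weight of the two physiologic constraint
#'   penalties (0 disables them)
#' @param max_angle angle at which the constraints are evaluated
#' @return numeric residual vector; `sum(r^2)` is the objective
#' @export
estimation_residuals <- function(params, data, settle = 60, dt = 1e-3,
                                 resp = NULL, constraint_weight = 0,
                                 max_angle = NULL) {
  angles <- sort(unique(c(0, data$angle)))
  if (is.null(resp)) {
    resp <- tryCatch(
      steady_state_response(params, angles, settle = settle, dt = dt),
      error = function(e) {
        warning("simulation failed during fitting: ", conditionMessage(e))
        NULL
      })
  }
  if (is.null(resp)) {
    n <- nrow(data) + if (constraint_weight > 0) 2 else 0
    return(rep(1e4 / sqrt(n), n))
  }
  mod <- model_observations(resp)
  key <- paste(mod$angle, mod$variable)
  mv <- stats::setNames(mod$value, key)
  r <- sqrt(data$weight) * (mv[paste(data$angle, data$variable)] - data$value)
  if (constraint_weight > 0) {
    cv <- constraint_violations(resp, max_angle = max_angle)
    r <- c(r, sqrt(constraint_weight) * cv)
  }
  unname(r)
}

#' Physiologic constraint violations
#'
#' Two constraints used during fitting: (i) the percent reduction in
#' thoracic blood volume from supine to maximal tilt must lie in
#' `[26, 30]`%; (ii) the relative increase in lower-body resistance must be
#' twice that of the upper body (equality with tolerance).
#'
#' @param resp [steady_state_response()] table including the maximal angle
#' @param max_angle angle at which to evaluate (default: last row)
#' @return numeric length-2 vector: signed distance to the thoracic band
#'   (percentage points) and the lower/upper resistance-rise mismatch
#'   (ratio units); zero when satisfied
#' @export
constraint_violations <- function(resp, max_angle = NULL) {
  if (is.null(max_angle)) max_angle <- max(resp$angle)
  i <- which(resp$angle == max_angle)
  red <- -resp$pct_V_thoracic[i]           # percent reduction, positive
  c1 <- if (red < 26) red - 26 else if (red > 30) red - 30 else 0
  dRlb <- resp$R_lb[i] / resp$R_lb[1] - 1
  dRup <- resp$R_up[i] / resp$R_up[1] - 1
  c2 <- dRlb - 2 * dRup
  c(thoracic = c1, lb_resistance = c2)
}

#' Sensitivity screening of model parameters
#'
#' Perturbs each parameter by +10%, recomputes the objective and forms the
#' dimensionless sensitivity coefficient
#' `S = ((J - J0)/J0) / 0.1`.
#'
#' @param params baseline `cvs_params`
#' @param data `measurement_set` (use noisy data so the baseline `J0 > 0`)
#' @param paths dotted parameter paths to screen
#' @param settle,dt simulation controls
#' @return data.frame with `path`, `J`, `S`, sorted by `|S|` descending
#' @export
sensitivity_screen <- function(params, data, paths, settle = 60, dt = 1e-3) {
  J0 <- estimation_objective(params, data, settle = settle, dt = dt)
  if (J0 <= 0) stop("baseline objective must be positive; use noisy data")
  res <- lapply(paths, function(pp) {
    pj <- param_scale(params, pp, 1.1)
    J <- estimation_objective(pj, data, settle = settle, dt = dt)
    data.frame(path = pp, J = J, S = ((J - J0) / J0) / 0.1)
  })
  out <- do.call(rbind, res)
  attr(out, "J0") <- J0
  out[order(-abs(out$S)), ]
}

#' Fit free parameters to a measurement set
#'
#' Bounded Levenberg-Marquardt minimisation of the weighted least-squares
#' objective over multiplicative factors on the chosen parameter paths,
#' with the two physiologic constraints as quadratic penalties. Returns the
#' fitted bundle, the objective, and a covariance estimate from the Jacobian
#' at the optimum.
#'
#' @param data `measurement_set`
#' @param spec list with `paths` (character), optional `start` (factors,
#'   default 1), `lower`/`upper` factor bounds (default 0.2/5), and
#'   `constraint_weight` (default 0: constraints checked post-fit only)
#' @param base `cvs_params` the factors multiply
#' @param settle,dt simulation controls
#' @param control passed to [minpack.lm::nls.lm.control()]
#' @return list with `params`, `factors`, `J`, `covariance`, `correlation`,
#'   `constraints` (violations at the optimum), `converged`
#' @export
fit_parameters <- function(data, spec, base = healthy_parameters(),
                           settle = 60, dt = 1e-3,
                           control = minpack.lm::nls.lm.control(maxiter = 30,
                                                               ptol = 1e-6)) {
  paths <- spec$paths
  np <- length(paths)
  start <- if (is.null(spec$start)) rep(1, np) else spec$start
  lower <- if (is.null(spec$lower)) rep(0.2, np) else spec$lower
  upper <- if (is.null(spec$upper)) rep(5, np) else spec$upper
  stopifnot(all(is.finite(lower)), all(is.finite(upper)), all(lower < upper))
  cw <- if (is.null(spec$constraint_weight)) 0 else spec$constraint_weight
  apply_factors <- function(f) {
    p <- base
    for (i in seq_len(np)) p <- param_scale(p, paths[i], f[i])
    p
  }
  fn <- function(f) {
    estimation_residuals(apply_factors(f), data, settle = settle, dt = dt,
                         constraint_weight = cw)
  }
  # forward-difference Jacobian with a generous relative step: beat-count
  # quantisation in the periodic-orbit averages makes machine-epsilon steps
  # meaningless
  fd_step <- if (is.null(spec$fd_step)) 1e-2 else spec$fd_step
  jac <- function(f) {
    r0 <- fn(f)
    J <- matrix(0, length(r0), np)
    for (i in seq_len(np)) {
      fi <- f
      h <- fd_step * max(abs(fi[i]), 1e-3)
      fi[i] <- fi[i] + h
      J[, i] <- (fn(fi) - r0) / h
    }
    J
  }
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = fn, jac = jac, control = control)
  f <- fit$par
  names(f) <- paths
  pfit <- apply_factors(f)
  J <- fit$deviance
  # covariance from the Jacobian at the optimum
  jac <- fit$hessian      # nls.lm returns J'J in $hessian
  cov <- tryCatch({
    dof <- max(1, length(fit$fvec) - np)
    solve(jac) * J / dof
  }, error = function(e) matrix(NA_real_, np, np))
  dimnames(cov) <- list(paths, paths)
  cor <- tryCatch(suppressWarnings(stats::cov2cor(cov)), error = function(e) cov)
  respf <- steady_state_response(pfit, sort(unique(c(0, data$angle))),
                                 settle = settle, dt = dt)
  list(params = pfit, factors = f, J = J, covariance = cov,
       correlation = cor,
       constraints = constraint_violations(respf),
       converged = fit$info %in% 1:4, info = fit$info)
}

#' Covariance-guided subset selection of free parameters
#'
#' Iteratively removes the free parameter with the largest absolute pairwise
#' correlation at the optimum, refits, and stops when the objective degrades
#' by more than `threshold` (relative), returning the last acceptable free
#' set.
#'
#' @param data `measurement_set`
#' @param spec initial fit spec (see [fit_parameters()])
#' @param base base `cvs_params`
#' @param threshold relative objective increase that stops the reduction
#' @param corr_min smallest absolute pairwise correlation treated as
#'   co-dependence; below it no parameter is removed
#' @param settle,dt simulation controls
#' @return list with `paths` (reduced free set), `fit` (last accepted fit),
#'   and `trace` (data.frame of steps)
#' @export
subset_select <- function(data, spec, base = healthy_parameters(),
                          threshold = 0.10, corr_min = 0.5,
                          settle = 60, dt = 1e-3) {
  cur <- spec
  fit <- fit_parameters(data, cur, base, settle = settle, dt = dt)
  trace <- data.frame(n_params = length(cur$paths), J = fit$J,
                      removed = NA_character_)
  repeat {
    if (length(cur$paths) <= 1) break
    drop_nm <- pick_drop_candidate(fit$correlation, corr_min)
    if (is.na(drop_nm)) break
    nxt <- cur
    nxt$paths <- setdiff(cur$paths, drop_nm)
    keep <- match(nxt$paths, cur$paths)
    if (!is.null(nxt$start)) nxt$start <- cur$start[keep]
    if (!is.null(nxt$lower)) nxt$lower <- cur$lower[keep]
    if (!is.null(nxt$upper)) nxt$upper <- cur$upper[keep]
    fit2 <- fit_parameters(data, nxt, base, settle = settle, dt = dt)
    trace <- rbind(trace, data.frame(n_params = length(nxt$paths),
                                     J = fit2$J, removed = drop_nm))
    if (fit2$J > (1 + threshold) * max(fit$J, 1e-12)) break
    cur <- nxt
    fit <- fit2
  }
  list(paths = cur$paths, fit = fit, trace = trace)
}

# which member of the most-correlated pair to drop; NA when no pair exceeds
# corr_min (e.g. identity covariance: nothing is co-dependent)
pick_drop_candidate <- function(correlation, corr_min = 0.5) {
  cm <- abs(correlation)
  diag(cm) <- 0
  cm[!is.finite(cm)] <- 0
  if (max(cm) < corr_min) return(NA_character_)
  worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
  cand <- c(rownames(cm)[worst[1]], colnames(cm)[worst[2]])
  tot <- vapply(cand, function(nm) sum(cm[nm, ]), 0)
  cand[which.max(tot)]
}

#' Default free-parameter set for fitting
#'
#' Nine multiplicative factors: the four effector static gains (resistance,
#' unstressed volume, contractility, heart period... resistance uses a
#' common factor across the four branches via `gR_sp` as the lead), the
#' cardiopulmonary gain, the myogenic constant, the baseline heart period,
#' the splanchnic venous unstressed volume (venous tone scale), and total
#' blood volume.
#' @return fit spec list
#' @export
default_fit_spec <- function() {
  list(paths = c("reflex.eff.gR_sp", "reflex.eff.gVu", "reflex.eff.gE",
                 "reflex.eff.gTs", "reflex.cp.gain", "reflex.myo.k_myo",
                 "reflex.T_base", "circ.s.Vu_v", "circ.Vtot"),
       lower = rep(0.2, 9), upper = rep(5, 9))
}
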