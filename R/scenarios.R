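#' Heart-failure scenario (NYHA class III)
#'
#' Applies the heart-failure modifier set to a healthy parameter bundle:
#' LV contractility x0.2, RV contractility x0.6, pulmonary resistance x1.4,
#' baseline systemic resistance x1.25, total blood volume +600 mL, and
#' effector desensitization factor 10.
#'
#' @param base healthy `cvs_params`
#' @return modified `cvs_params`
#' @export
scenario_heart_failure <- function(base) {
  p <- base
  p <- param_scale(p, "heart.lvf.Ees", 0.2)
  p <- param_scale(p, "heart.rvf.Ees", 0.6)
  for (pp in c("circ.pul.R_pa", "circ.pul.R_pc", "circ.pul.R_pu"))
    p <- param_scale(p, pp, 1.4)
  for (br in c("b", "u", "h", "s", "k", "lb"))
    for (rr in c("R_a", "R_m", "R_v"))
      p <- param_scale(p, paste0("circ.", br, ".", rr), 1.25)
  p <- param_set(p, "circ.Vtot", param_get(p, "circ.Vtot") + 600)
  p <- param_set(p, "reflex.eff.kD", 10)
  p
}

#' Single-factor perturbation at heart-failure level
#'
#' Applies exactly one heart-failure modifier to the healthy base, leaving
#' every other parameter untouched. Factors: `E_lv` (LV contractility x0.2),
#' `E_rv` (RV x0.6), `Rsys0` (systemic resistance x1.25), `Rpul` (pulmonary
#' resistance x1.4), `Vtot` (+600 mL), `lv_stiffness` (LV end-diastolic
#' stiffness, EDPVR coefficient x2), `desensitized` (effector
#' desensitization factor 10).
#'
#' @param base healthy `cvs_params`
#' @param factor one of the names above
#' @return modified `cvs_params`
#' @export
perturb_single_factor <- function(base, factor) {
  p <- base
  switch(factor,
    E_lv = param_scale(p, "heart.lvf.Ees", 0.2),
    E_rv = param_scale(p, "heart.rvf.Ees", 0.6),
    Rsys0 = {
      for (br in c("b", "u", "h", "s", "k", "lb"))
        for (rr in c("R_a", "R_m", "R_v"))
          p <- param_scale(p, paste0("circ.", br, ".", rr), 1.25)
      p
    },
    Rpul = {
      for (pp in c("circ.pul.R_pa", "circ.pul.R_pc", "circ.pul.R_pu"))
        p <- param_scale(p, pp, 1.4)
      p
    },
    Vtot = param_set(p, "circ.Vtot", param_get(p, "circ.Vtot") + 600),
    lv_stiffness = param_scale(p, "heart.lvf.P0", 2),
    desensitized = param_set(p, "reflex.eff.kD", 10),
    stop("configuration error: unknown factor '", factor, "'")
  )
}

#' Hypothesis-test toggles
#'
#' Switches used for the mechanism experiments: remove the cardiopulmonary
#' reflex (gain to zero), remove lower-body myogenic autoregulation
#' (constant to zero), freeze the pericardial pressure at the scenario's
#' supine mean (removes diastolic ventricular interaction through the
#' pericardium), and optionally multiply the four efferent resistance gains
#' by a common factor (the retuned-resistance variant of the
#' cardiopulmonary-removal experiment).
#'
#' @param params `cvs_params`
#' @param cp_reflex keep the cardiopulmonary reflex?
#' @param autoregulation keep the lower-body myogenic response?
#' @param pericardium `"dynamic"` or `"frozen"`
#' @param resistance_gain_factor common multiplier on the four efferent
#'   resistance gains
#' @param settle supine settling time used when computing the frozen
#'   pericardial pressure (s)
#' @return modified `cvs_params`
#' @export
hypothesis_toggles <- function(params, cp_reflex = TRUE, autoregulation = TRUE,
                               pericardium = c("dynamic", "frozen"),
                               resistance_gain_factor = 1, settle = 90) {
  pericardium <- match.arg(pericardium)
  p <- params
  if (!cp_reflex) p <- param_set(p, "reflex.cp.gain", 0)
  if (!autoregulation) p <- param_set(p, "reflex.myo.k_myo", 0)
  if (resistance_gain_factor != 1) {
    for (gg in c("gR_up", "gR_sp", "gR_kp", "gR_lb"))
      p <- param_scale(p, paste0("reflex.eff.", gg), resistance_gain_factor)
  }
  if (pericardium == "frozen") p <- freeze_pericardium(p, settle = settle)
  p
}

#' Freeze the pericardium at its supine mean pressure
#'
#' Runs the scenario supine to steady state, computes the beat-averaged
#' pericardial pressure, and returns a parameter set whose pericardium
#' returns that constant regardless of heart volume.
#'
#' @param params `cvs_params` (dynamic pericardium)
#' @param settle supine simulation length (s)
#' @param dt integration step (s)
#' @return `cvs_params` with `heart.peri.dynamic = 0` and the frozen value
#' @export
freeze_pericardium <- function(params, settle = 90, dt = 5e-4) {
  sim <- simulate_cvs(params, tilt_protocol(0, settle), dt = dt,
                      record = FALSE)
  nb <- nrow(sim$beats)
  pfrozen <- mean(sim$beats$P_peri[max(1, nb - 4):nb])
  p <- param_set(params, "heart.peri.dynamic", 0)
  param_set(p, "heart.peri.frozen_P", pfrozen)
}

#' Calibrate the retuned-resistance variant of the CP-removal experiment
#'
#' Finds the common multiplier on the four efferent resistance gains such
#' that, without the cardiopulmonary reflex, the controlled resistances match
#' the CP-intact run at supine and at the maximal tilt angle.
#'
#' @param params healthy `cvs_params` (CP intact)
#' @param max_angle maximal tilt angle (degrees)
#' @param settle per-angle settling (s)
#' @param dt integration step (s)
#' @return list with `factor` and the two resistance tables compared
#' @export
retune_resistance_gains <- function(params, max_angle = 80, settle = 100,
                                    dt = 1e-3) {
  angles <- c(0, max_angle)
  ref <- steady_state_response(params, angles, settle = settle, dt = dt)
  target <- ref$R_sp[2] / ref$R_sp[1]   # tilt-induced relative rise, CP intact
  noCP <- hypothesis_toggles(params, cp_reflex = FALSE)
  f <- stats::uniroot(function(fac) {
    pf <- noCP
    for (gg in c("gR_up", "gR_sp", "gR_kp", "gR_lb"))
      pf <- param_scale(pf, paste0("reflex.eff.", gg), fac)
    r <- steady_state_response(pf, angles, settle = settle, dt = dt)
    r$R_sp[2] / r$R_sp[1] - target
  }, lower = 1, upper = 12, tol = 0.05)$root
  list(factor = f, reference = ref)
}

#' Run a preset scenario by name
#' @param name `"healthy"`, `"heart_failure"`, or a single-factor name
#'   accepted by [perturb_single_factor()]
#' @param base optional healthy base parameters
#' @return `cvs_params`
#' @export
scenario_params <- function(name, base = healthy_parameters()) {
  if (name == "healthy") return(base)
  if (name == "heart_failure") return(scenario_heart_failure(base))
  perturb_single_factor(base, name)
}
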