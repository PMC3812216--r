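#' Static arterial afferent firing
#'
#' Bounded sigmoid of the (dynamically filtered) carotid-level pressure.
#' During tilt the input pressure is the large-artery pressure minus the
#' carotid hydrostatic column (default 16 cm above heart level).
#'
#' @param P filtered input pressure (mmHg)
#' @param params list with `Pn` (set-point), `k_a` (slope), `f_min`, `f_max`
#' @return afferent firing (spikes/s), bounded in `[f_min, f_max]`
#' @export
arterial_afferent_static <- function(P, params) {
  params$f_min + (params$f_max - params$f_min) *
    stats::plogis((P - params$Pn) / params$k_a)
}

#' Carotid-level input pressure to the arterial baroreceptors
#' @param P_sa large-artery pressure at heart level (mmHg)
#' @param alpha tilt angle (degrees)
#' @param h_carotid carotid height above the heart (cm)
#' @param rho,g blood density and gravity
#' @export
carotid_input_pressure <- function(P_sa, alpha, h_carotid = 16,
                                   rho = 1060, g = 9.81) {
  P_sa - hydrostatic_pressure(h_carotid, alpha, rho, g)
}

#' Cardiopulmonary afferent drive
#'
#' Bounded linear deviation of the (filtered) central venous pressure from
#' its set-point. A positive output (low filling pressure) raises the
#' peripheral resistance effectors; the pathway is wired to the resistances
#' only. With `gain = 0` the pathway is disabled and the output is invariant
#' to `P_cv`.
#'
#' @param P_cv central venous pressure (mmHg)
#' @param params list with `gain` (1/mmHg), `Pcv_n` (set-point, mmHg),
#'   `cap` (saturation of the dimensionless drive)
#' @return dimensionless resistance drive
#' @export
cp_afferent <- function(P_cv, params) {
  pmin(pmax(params$gain * (params$Pcv_n - P_cv), -params$cap), params$cap)
}

#' Efferent sympathetic and vagal activities
#'
#' Sympathetic activity decays exponentially with afferent firing; vagal
#' activity is a rising sigmoid. The cardiopulmonary drive modulates only the
#' resistance-directed sympathetic branch.
#'
#' @param f_ab arterial afferent firing (spikes/s)
#' @param params efferent parameter list (`fes_inf`, `fes_0`, `k_es`,
#'   `fes_min`, `fev_0`, `fev_inf`, `k_ev`, `fab_0`)
#' @param f_cp cardiopulmonary drive (dimensionless), added to the
#'   resistance branch only
#' @return list with `f_es` (sympathetic, spikes/s), `f_ev` (vagal),
#'   `x_s` (log-transformed sympathetic drive), `x_res` (resistance drive
#'   including the cardiopulmonary term)
#' @export
efferent_activities <- function(f_ab, params, f_cp = 0) {
  f_es <- params$fes_inf + (params$fes_0 - params$fes_inf) *
    exp(-params$k_es * f_ab)
  ev <- exp((f_ab - params$fab_0) / params$k_ev)
  f_ev <- (params$fev_0 + params$fev_inf * ev) / (1 + ev)
  x_s <- log(pmax(f_es - params$fes_min + 1, 1e-6))
  list(f_es = f_es, f_ev = f_ev, x_s = x_s, x_res = x_s + f_cp)
}

#' First-order effector response to a drive trajectory
#'
#' Discrete-time simulation of one effector arm: the static characteristic
#' `sigma(t) = base (1 + gain (x(t - D) - x0) / kD)` low-pass filtered with
#' time constant `tau`. The desensitization factor `kD` divides the static
#' gain.
#'
#' @param drive numeric vector of the drive `x(t)` sampled at `dt`
#' @param base baseline (supine) effector value
#' @param gain relative static gain
#' @param x0 supine reference drive
#' @param tau time constant (s)
#' @param dt sample interval (s), must be positive
#' @param D latency (s)
#' @param kD desensitization factor (1 = intact)
#' @param init initial value (defaults to `base`)
#' @return numeric vector: effector value trajectory
#' @export
effector_update <- function(drive, base, gain, x0, tau, dt, D = 0, kD = 1,
                            init = base) {
  if (dt <= 0) stop("dt must be positive")
  nD <- round(D / dt)
  n <- length(drive)
  y <- numeric(n)
  cur <- init
  for (i in seq_len(n)) {
    xd <- if (i - nD >= 1) drive[i - nD] else drive[1]
    sigma <- base * (1 + gain * (xd - x0) / kD)
    cur <- cur + dt * (sigma - cur) / tau
    y[i] <- cur
  }
  y
}

#' Lower-body resistance with myogenic autoregulation
#'
#' Scales the sympathetically set lower-body resistance by a factor linear in
#' the deviation of the local arterial transmural pressure from its supine
#' set-point. At the set-point, or with `k_myo = 0`, the sympathetic value is
#' returned unchanged.
#'
#' @param R_sym sympathetically controlled lower-body resistance
#'   (mmHg.s/mL), positive
#' @param P_tm transmural pressure across the lower-body arteries (mmHg)
#' @param params list with `k_myo` (1/mmHg) and `Ptm_ref` (mmHg)
#' @return effective lower-body resistance (mmHg.s/mL)
#' @export
lower_body_resistance <- function(R_sym, P_tm, params) {
  if (any(R_sym <= 0)) stop("R_sym must be positive")
  R_sym * pmax(1 + params$k_myo * (P_tm - params$Ptm_ref), 0.2)
}
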