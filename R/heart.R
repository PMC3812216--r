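#' Time-varying activation of a heart chamber
#'
#' Periodic raised-cosine drive `e(t)` that blends the end-diastolic
#' (exponential) and end-systolic (linear) pressure-volume laws: a single
#' systolic lobe of width `s_sys` of the beat, peak 1, exactly 0 through
#' diastole.
#'
#' @param t_in_beat time since beat onset (s); may exceed `T` (wraps)
#' @param T heart period (s)
#' @param s_sys systolic fraction of the beat (duration of the lobe)
#' @return activation in `[0, 1]`
#' @export
activation <- function(t_in_beat, T, s_sys = 0.45) {
  if (any(T <= 0)) stop("invalid parameter: heart period T must be > 0")
  s <- (t_in_beat / T) %% 1
  ifelse(s < s_sys, 0.5 * (1 - cos(2 * pi * s / s_sys)), 0)
}

#' Instantaneous chamber pressure
#'
#' Blends the linear end-systolic law `Ees (V - V0)` and the exponential
#' end-diastolic law `P0 (exp(lam (V - V0)) - 1)` with the activation, and
#' adds the external (pericardial) pressure.
#'
#' @param V chamber volume (mL)
#' @param e activation in `[0, 1]`
#' @param params list with `Ees`, `V0`, `P0`, `lam`
#' @param P_ext external pressure (mmHg), e.g. pericardial
#' @return pressure (mmHg)
#' @export
chamber_pressure <- function(V, e, params, P_ext = 0) {
  P_ext + e * params$Ees * (V - params$V0) +
    (1 - e) * params$P0 * expm1(params$lam * (V - params$V0))
}

#' Septal displacement volume
#'
#' Solves the transseptal pressure balance
#' `P_spt(Vspt) = P_lvf(Vlv - Vspt) - P_rvf(Vrv + Vspt)` by Newton iteration.
#' Positive displacement bulges the septum into the right ventricle.
#'
#' @param Vlv,Vrv total ventricular volumes (mL)
#' @param e shared activation
#' @param heart list with chamber parameter lists `lvf`, `rvf`, `spt`
#' @param tol residual tolerance (mmHg)
#' @return septal volume (mL)
#' @export
solve_septum <- function(Vlv, Vrv, e, heart, tol = 1e-10) {
  if (Vlv <= 0 || Vrv <= 0) stop("ventricular volumes must be positive")
  dch <- function(cc, V) {
    e * cc$Ees + (1 - e) * cc$P0 * cc$lam * exp(cc$lam * (V - cc$V0))
  }
  Vs <- 0
  for (it in seq_len(60)) {
    r <- chamber_pressure(Vs, e, heart$spt) -
      chamber_pressure(Vlv - Vs, e, heart$lvf) +
      chamber_pressure(Vrv + Vs, e, heart$rvf)
    if (abs(r) < tol) return(Vs)
    dr <- dch(heart$spt, Vs) + dch(heart$lvf, Vlv - Vs) + dch(heart$rvf, Vrv + Vs)
    Vs <- Vs - max(min(r / dr, 20), -20)
  }
  stop("septum solve did not converge: Vlv=", Vlv, " Vrv=", Vrv, " e=", e,
       " residual=", r)
}

#' Pericardial pressure
#'
#' Passive exponential pressure-volume law of the pericardial sac in
#' `dynamic` mode; a fixed value in `frozen` mode (used to switch off
#' diastolic ventricular interaction through the pericardium).
#'
#' @param V_heart_total total heart volume including myocardium (mL)
#' @param params list with `P0`, `lam`, `V0`, `dynamic` (1/0), `frozen_P`
#' @return pericardial pressure (mmHg)
#' @export
pericardial_pressure <- function(V_heart_total, params) {
  if (any(V_heart_total <= 0)) stop("total heart volume must be positive")
  if (params$dynamic > 0.5) {
    params$P0 * expm1(params$lam * (V_heart_total - params$V0))
  } else {
    rep_len(params$frozen_P, length(V_heart_total))
  }
}

#' Valve flow dynamics
#'
#' Inertial valve: while open, `dQ/dt = (dP - R Q)/L`; the valve closes when
#' flow decelerates through zero and re-opens only under a positive pressure
#' gradient.
#'
#' @param dP pressure gradient across the valve (mmHg)
#' @param valve list with `R` (mmHg.s/mL), `L` (mmHg.s^2/mL), `Q` (mL/s)
#' @return list with `dQdt` (mL/s^2) and `open` (logical)
#' @export
valve_dynamics <- function(dP, valve) {
  open <- valve$Q > 1e-9 || dP > 0
  dQdt <- if (open) (dP - valve$R * valve$Q) / valve$L else 0
  list(dQdt = dQdt, open = open)
}
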