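#' Healthy default parameter bundle
#'
#' Builds the full parameter set of the closed-loop model: heart chambers
#' (end-systolic linear / end-diastolic exponential pressure-volume laws,
#' septum, pericardium, inertial valves), the six-branch systemic plus
#' pulmonary circulation (compliances, unstressed volumes, resistances,
#' hydrostatic distances), and the reflex/autoregulation block (arterial and
#' cardiopulmonary afferents, efferent activities, four effector arms,
#' lower-body myogenic law).
#'
#' Chamber and valve constants follow the published minimal heart model this
#' model family builds on; circulation values are derived from the supine
#' flow and volume distribution of the six vascular districts (total systemic
#' resistance 1.06 mmHg.s/mL, compliance 118 mL/mmHg; pulmonary 0.13 and 32)
#' and then calibrated so the healthy supine beat averages land on the
#' reference hemodynamics (MAP ~88 mmHg, HR ~69 bpm, SV ~69 mL, CO ~4.8
#' L/min). `scripts/calibrate.R` in the source repository regenerates the
#' calibrated entries.
#'
#' @param tweaks named list of dotted-path overrides, e.g.
#'   `list("reflex.eff.gE" = 0.5)`.
#' @return nested named list of class `cvs_params`.
#' @export
healthy_parameters <- function(tweaks = NULL) {
  p <- list(
    heart = list(
      lvf = list(Ees = 4.20, V0 = 5, P0 = 0.94, lam = 0.0255),
      rvf = list(Ees = 1.00, V0 = 5, P0 = 0.23, lam = 0.019),
      spt = list(Ees = 48.754, V0 = 0, P0 = 1.1101, lam = 0.435),
      la  = list(Ees = 0.10, V0 = -74.6, P0 = 0.44, lam = 0.018),
      ra  = list(Ees = 0.07, V0 = -95.8, P0 = 0.35, lam = 0.016),
      peri = list(P0 = 2.37, lam = 0.012, V0 = 150, Vmyo = 30,
                  dynamic = 1, frozen_P = 0),
      act = list(s_sys_v = 0.48, atrial_offset = 0.16, d_a = 0.25),
      mt = list(R = 0.0080, L = 7.6967e-5),
      av = list(R = 0.0100, L = 1.2189e-4),
      tc = list(R = 0.0120, L = 8.0093e-5),
      pv = list(R = 0.0055, L = 1.4868e-4)
    ),
    circ = list(
      env = list(rho = 1060, g = 9.81, collapse_k = 10),
      sa = list(C = 1.6, Vu = 280),
      tv = list(C = 12, Vu = 296.2, R = 0.008),
      # branch order: cerebral (b), upper (u), coronary (h),
      # splanchnic (s), renal (k), lower body (lb)
      b  = list(C_p = 0.35, Vu_p = 40,  C_v = 14.8, Vu_v = 137.4,
                R_a = 5.73,  R_m = 0.84,  R_v = 0.42, h = -38),
      u  = list(C_p = 0.50, Vu_p = 60,  C_v = 7,  Vu_v = 317.5,
                R_a = 8.72,  R_m = 1.28,  R_v = 0.64, h = -15),
      h  = list(C_p = 0.18, Vu_p = 15,  C_v = 3,  Vu_v = 74.2,
                R_a = 17.09, R_m = 2.50,  R_v = 1.25, h = 0),
      s  = list(C_p = 1.20, Vu_p = 180, C_v = 40, Vu_v = 901.0,
                R_a = 2.757, R_m = 0.403, R_v = 0.202, h = 12,
                P_dist = 12, k_dist = 1),
      k  = list(C_p = 0.40, Vu_p = 45,  C_v = 9,  Vu_v = 237.7,
                R_a = 3.488, R_m = 0.510, R_v = 0.255, h = 17),
      lb = list(C_p = 2.40, Vu_p = 186.6, C_v = 17, Vu_v = 460,
                R_a = 5.77,  R_m = 0.845, R_v = 0.422, h = 65,
                Vmax = 700),
      pul = list(C_pa = 4, Vu_pa = 30, R_pa = 0.07,
                 C_pc = 4, Vu_pc = 65, R_pc = 0.04,
                 C_pu = 6, Vu_pu = 465, R_pu = 0.02),
      Vtot = 5160
    ),
    reflex = list(
      afferent = list(Pn = 88.4, k_a = 11.758, f_min = 2.52, f_max = 47.78,
                      tau_p = 2.076, tau_z = 1.0, h_carotid = 16),
      efferent = list(fes_inf = 2.10, fes_0 = 16.11, k_es = 0.0675,
                      fes_min = 2.66, fev_0 = 3.2, fev_inf = 6.3,
                      k_ev = 7.06, fab_0 = 25),
      cp = list(gain = 0.038, Pcv_n = 4.4, cap = 0.6, tau = 5),
      eff = list(gR_up = 1.7, gR_sp = 0.85, gR_kp = 1.7, gR_lb = 1.7,
                 gVu = -0.02, gE = 0.06, gTs = -0.32, gTv = 0.08,
                 tau_R = 8, tau_Vu = 20, tau_E = 8, tau_T = 2,
                 D_s = 0.5, D_v = 0.2, kD = 1,
                 x_ref = 1.225444, fev_ref = 4.565093),
      myo = list(k_myo = 0.010, Ptm_ref = 19.6),
      T_base = 0.872
    )
  )
  class(p) <- "cvs_params"
  if (!is.null(tweaks)) {
    for (nm in names(tweaks)) p <- param_set(p, nm, tweaks[[nm]])
  }
  validate_params(p)
  p
}

#' Flatten a parameter bundle to the named vector the compiled core expects
#' @param p `cvs_params` object
#' @return named numeric vector with dotted names
#' @export
flatten_params <- function(p) {
  v <- unlist(p, use.names = TRUE)
  storage.mode(v) <- "double"
  v
}

#' Read a parameter by dotted path
#' @param p `cvs_params` object
#' @param path dotted path such as `"circ.lb.Vmax"`
#' @export
param_get <- function(p, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- p
  for (k in parts) {
    if (is.null(node[[k]])) stop("unknown parameter path: ", path)
    node <- node[[k]]
  }
  node
}

#' Set a parameter by dotted path
#' @inheritParams param_get
#' @param value new numeric value
#' @export
param_set <- function(p, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, k) call("[[", acc, k), parts, init = quote(p))
  # verify path exists
  param_get(p, path)
  value <- unname(value)
  eval(call("<-", expr, value), envir = environment())
  class(p) <- "cvs_params"
  p
}

#' Multiply a parameter by a factor (scenario modifiers)
#' @inheritParams param_get
#' @param factor multiplicative change
#' @export
param_scale <- function(p, path, factor) {
  param_set(p, path, param_get(p, path) * factor)
}

#' Validate a parameter bundle
#'
#' Checks positivity and structural invariants (positive elastances and
#' diastolic coefficients, positive compliances and resistances, lower-body
#' unstressed volume below its maximum volume, tilt-independent constants).
#' @param p `cvs_params` object
#' @return invisibly `p`; stops on violation
#' @export
validate_params <- function(p) {
  for (ch in c("lvf", "rvf", "spt", "la", "ra")) {
    cc <- p$heart[[ch]]
    if (cc$Ees <= 0 || cc$lam <= 0 || cc$P0 < 0)
      stop("invalid chamber parameters for ", ch)
  }
  if (p$reflex$T_base <= 0) stop("heart period must be positive")
  for (br in c("b", "u", "h", "s", "k", "lb")) {
    b <- p$circ[[br]]
    if (b$C_p <= 0 || b$C_v <= 0 || b$R_a <= 0 || b$R_m <= 0 || b$R_v <= 0)
      stop("invalid circulation parameters for branch ", br)
    if (b$Vu_p < 0 || b$Vu_v < 0) stop("negative unstressed volume in ", br)
  }
  if (p$circ$lb$Vu_v >= p$circ$lb$Vmax)
    stop("lower-body unstressed volume must be below Vmax")
  if (p$circ$Vtot <= 0) stop("total blood volume must be positive")
  with(p$reflex$afferent, {
    if (tau_p <= 0 || tau_z <= 0) stop("afferent time constants must be > 0")
  })
  invisible(p)
}

#' Supine initial state for the integrator
#'
#' Distributes the configured total blood volume over the compartments using
#' the supine volume shares the default calibration targets, then absorbs any
#' remainder into the splanchnic venous reservoir. Effector states start at
#' their baselines.
#'
#' @param p `cvs_params` object
#' @return list with `state` (length-38 numeric), `T` (first beat period, s),
#'   `phase` (time into beat, s)
#' @export
initial_state <- function(p) {
  ci <- p$circ
  MAP <- p$reflex$afferent$Pn
  shares <- c(b = 0.149, u = 0.098, h = 0.050, s = 0.310, k = 0.245,
              lb = 0.148)
  q <- shares * (MAP - 4.4) / 1.042   # supine branch flows, mL/s
  vols <- numeric(21)
  names(vols) <- c("Vlv", "Vrv", "Vla", "Vra", "Vsa",
                   "Vbp", "Vbv", "Vup", "Vuv", "Vhp", "Vhv", "Vsp", "Vsv",
                   "Vkp", "Vkv", "Vlbp", "Vlbv", "Vtv", "Vpa", "Vpc", "Vpu")
  vols["Vlv"] <- 100; vols["Vrv"] <- 100
  vols["Vla"] <- 60; vols["Vra"] <- 60
  vols["Vsa"] <- ci$sa$Vu + ci$sa$C * MAP
  brn <- c("b", "u", "h", "s", "k", "lb")
  for (i in seq_along(brn)) {
    b <- ci[[brn[i]]]
    Pp <- MAP - q[i] * b$R_a
    Pv <- Pp - q[i] * b$R_m
    vols[5 + 2 * i - 1] <- b$Vu_p + b$C_p * Pp
    if (brn[i] == "lb") {
      cap <- b$Vmax - b$Vu_v
      stressed <- (2 * cap / pi) * atan(pi * b$C_v * Pv / (2 * cap))
      vols[5 + 2 * i] <- b$Vu_v + stressed
    } else {
      vols[5 + 2 * i] <- b$Vu_v + b$C_v * Pv
    }
  }
  Ptv <- 4.4
  vols["Vtv"] <- ci$tv$Vu + ci$tv$C * Ptv
  CO <- sum(q)
  Pla <- 6.7
  Ppa <- Pla + CO * (ci$pul$R_pa + ci$pul$R_pc + ci$pul$R_pu)
  Ppc <- Ppa - CO * ci$pul$R_pa
  Ppu <- Pla + CO * ci$pul$R_pu
  vols["Vpa"] <- ci$pul$Vu_pa + ci$pul$C_pa * Ppa
  vols["Vpc"] <- ci$pul$Vu_pc + ci$pul$C_pc * Ppc
  vols["Vpu"] <- ci$pul$Vu_pu + ci$pul$C_pu * Ppu
  # absorb the remainder into the splanchnic venous reservoir
  vols["Vsv"] <- vols["Vsv"] + (ci$Vtot - sum(vols))
  if (vols["Vsv"] <= ci$s$Vu_v * 0.2)
    stop("total blood volume too low for the configured unstressed volumes")
  ref <- p$reflex
  state <- c(unname(vols),
             0, 0, 0, 0,                       # valve flows
             ref$afferent$Pn,                  # afferent dynamic block
             p$circ$u$R_a, p$circ$s$R_a, p$circ$k$R_a, p$circ$lb$R_a,
             p$circ$u$Vu_v, p$circ$s$Vu_v, p$circ$k$Vu_v, p$circ$lb$Vu_v,
             p$heart$lvf$Ees, p$heart$rvf$Ees,
             ref$T_base,
             ref$cp$Pcv_n)
  list(state = state, T = ref$T_base, phase = 0)
}

#' Names of the integrator state vector
#' @return character vector of length 38
#' @export
state_names <- function() {
  c("V_lv", "V_rv", "V_la", "V_ra", "V_sa",
    "V_bp", "V_bv", "V_up", "V_uv", "V_hp", "V_hv", "V_sp", "V_sv",
    "V_kp", "V_kv", "V_lbp", "V_lbv", "V_tv", "V_pa", "V_pc", "V_pu",
    "Q_mt", "Q_av", "Q_tc", "Q_pv",
    "P_tilde",
    "R_up", "R_sp", "R_kp", "R_lb",
    "Vu_uv", "Vu_sv", "Vu_kv", "Vu_lbv",
    "E_lv", "E_rv", "T_eff", "P_cv_filt")
}
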