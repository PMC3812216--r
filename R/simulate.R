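#' Tilt protocol
#'
#' Ordered sequence of (angle, duration) segments. Transitions are linear
#' ramps in `sin(alpha)` of `ramp_time` seconds (steady-state focus: the ramp
#' shape is immaterial but discontinuities hurt the integrator).
#'
#' @param angles tilt angles in degrees, each in `[0, 90]`
#' @param durations segment durations (s), recycled; each must exceed
#'   `ramp_time`
#' @param ramp_time transition ramp (s)
#' @return `tilt_protocol` object
#' @export
tilt_protocol <- function(angles, durations = 150, ramp_time = 2) {
  durations <- rep_len(durations, length(angles))
  if (any(angles < 0 | angles > 90)) stop("tilt angles must be in [0, 90]")
  if (any(durations <= ramp_time)) stop("durations must exceed ramp_time")
  structure(list(angles = angles, durations = durations,
                 ramp_time = ramp_time),
            class = "tilt_protocol")
}

#' Simulate the closed-loop model through a tilt protocol
#'
#' Integrates the full system (volumes, valve flows, reflex and effector
#' states) with a fixed-step fourth-order Runge-Kutta scheme and valve
#' zero-crossing handling. Deterministic given identical inputs.
#'
#' @param params `cvs_params` object
#' @param protocol `tilt_protocol`; default 60 s supine
#' @param dt integration step (s)
#' @param out_dt output sampling interval (s); default 5 ms (200 Hz)
#' @param record keep the full time series (set `FALSE` to return only
#'   beat summaries; faster and lighter)
#' @param init optional initial condition as returned in `$final` of a
#'   previous run (continuation); default: cold start from the supine
#'   distribution followed by the protocol as given
#' @return list of class `cvs_sim` with `beats` (one row per beat),
#'   `series` (data.frame, if recorded), and `final` (continuation info)
#' @export
simulate_cvs <- function(params, protocol = tilt_protocol(0, 60),
                         dt = 5e-4, out_dt = 5e-3, record = TRUE,
                         init = NULL) {
  validate_params(params)
  if (is.null(init)) {
    ini <- initial_state(params)
  } else {
    ini <- list(state = init$state, T = init$T, phase = init$phase)
  }
  pm <- cbind(protocol$angles, protocol$durations)
  res <- cvs_core_simulate(flatten_params(params), pm,
                           list(dt = dt, out_dt = out_dt,
                                ramp_time = protocol$ramp_time,
                                record = record,
                                init_state = ini$state,
                                init_T = ini$T, init_phase = ini$phase))
  beats <- as.data.frame(res$beats)
  out <- list(beats = beats,
              final = list(state = res$final_state, T = res$final_T,
                           phase = res$final_phase),
              duration = res$duration,
              params = params, protocol = protocol, dt = dt)
  if (record) out$series <- as.data.frame(res$series)
  class(out) <- "cvs_sim"
  out
}

#' @export
print.cvs_sim <- function(x, ...) {
  cat("<cvs_sim>", nrow(x$beats), "beats over", x$duration, "s\n")
  if (nrow(x$beats)) {
    last <- x$beats[nrow(x$beats), ]
    cat(sprintf("  last beat: HR %.1f bpm, MAP %.1f mmHg, SV %.1f mL, CO %.2f L/min\n",
                last$HR, last$MAP, last$SV, last$CO))
  }
  invisible(x)
}

#' Evaluate the model derivatives at a given state
#'
#' Pure function of (state, beat phase, tilt angle): returns the time
#' derivative of all volumes, valve flows, reflex and effector states, plus
#' instantaneous pressures. Used for diagnostics and Jacobian checks.
#'
#' @param params `cvs_params` object
#' @param state numeric state vector (see [state_names()])
#' @param phase fraction of the current beat elapsed, in `[0, 1)`
#' @param T_beat current beat period (s)
#' @param alpha tilt angle (degrees)
#' @return list with `deriv` (named numeric) and `aux` (pressures, flows)
#' @export
cvs_derivatives <- function(params, state, phase = 0, T_beat = NULL,
                            alpha = 0) {
  if (is.null(T_beat)) T_beat <- params$reflex$T_base
  r <- cvs_core_rhs(flatten_params(params), state, phase, T_beat, alpha)
  names(r$deriv) <- state_names()
  r
}

#' Per-beat summaries of a recorded time series
#'
#' Delimits beats by ventricular activation onsets (upward crossings of the
#' activation through 0.05), then reports per beat: heart rate, time-averaged
#' pressures, stroke volume from the LV volume trace, and the aortic-flow
#' integral as an independent stroke-volume estimate.
#'
#' @param series data.frame with columns `t`, `e_v`, `V_lv`, `P_sa`, `P_la`,
#'   `P_pa`, `P_tv`, `Q_av` (as produced by [simulate_cvs()])
#' @return data.frame, one row per complete beat
#' @export
beat_summaries <- function(series) {
  ev <- series$e_v
  on <- which(ev[-1] >= 0.05 & ev[-length(ev)] < 0.05) + 1
  if (length(on) < 4)
    stop("insufficient data: series must span at least 3 complete beats")
  out <- vector("list", length(on) - 1)
  for (b in seq_len(length(on) - 1)) {
    i <- on[b]:(on[b + 1] - 1)
    T <- series$t[on[b + 1]] - series$t[on[b]]
    edv <- max(series$V_lv[i]); esv <- min(series$V_lv[i])
    dtloc <- diff(series$t[c(i, on[b + 1])])
    out[[b]] <- data.frame(
      t_start = series$t[on[b]], T = T, HR = 60 / T,
      MAP = sum(series$P_sa[i] * dtloc) / T,
      P_la = sum(series$P_la[i] * dtloc) / T,
      P_pa = sum(series$P_pa[i] * dtloc) / T,
      P_cv = sum(series$P_tv[i] * dtloc) / T,
      LV_EDV = edv, LV_ESV = esv, SV = edv - esv,
      SV_flow = sum(series$Q_av[i] * dtloc),
      CO = (edv - esv) * (60 / T) / 1000)
  }
  do.call(rbind, out)
}

#' Check periodic-orbit convergence over trailing beats
#'
#' Relative beat-to-beat variation of beat-averaged MAP and CO below `tol`
#' over `n` consecutive beats.
#' @param beats beat table (as in `cvs_sim$beats`)
#' @param n number of trailing beats
#' @param tol relative tolerance
#' @return logical
#' @export
beats_converged <- function(beats, n = 5, tol = 1e-3) {
  if (nrow(beats) < 2 * n) return(FALSE)
  w2 <- beats[(nrow(beats) - n + 1):nrow(beats), ]
  w1 <- beats[(nrow(beats) - 2 * n + 1):(nrow(beats) - n), ]
  rel <- function(a, b) abs(mean(a) - mean(b)) / max(abs(mean(b)), 1e-9)
  rel(w2$MAP, w1$MAP) < tol && rel(w2$CO, w1$CO) < tol
}

#' Steady-state beat-averaged response across tilt angles
#'
#' Simulates the protocol `angles` (ascending, starting at 0), lets each
#' angle settle, then averages the trailing beats. Emits absolute values and
#' percentage changes versus supine. Non-converged angles are flagged, not
#' errored.
#'
#' @param params `cvs_params` object
#' @param angles tilt angles (degrees), ascending, starting at 0
#' @param settle seconds per angle before the averaging window (first angle
#'   additionally absorbs the cold-start transient)
#' @param n_avg number of trailing beats to average
#' @param dt integration step (s)
#' @param init optional continuation state
#' @return data.frame, one row per angle, with beat-averaged variables,
#'   `pct_*` change columns, and a `converged` flag
#' @export
steady_state_response <- function(params, angles = c(0, 20, 30, 40, 50, 60, 70, 80),
                                  settle = 120, n_avg = 12, dt = 5e-4,
                                  init = NULL) {
  if (is.unsorted(angles) || angles[1] != 0)
    stop("angles must be ascending and start at 0")
  durs <- rep_len(settle, length(angles))
  durs[1] <- durs[1] + 60  # absorb cold-start transient
  prot <- tilt_protocol(angles, durs)
  sim <- simulate_cvs(params, prot, dt = dt, record = FALSE, init = init)
  bounds <- cumsum(durs)
  rows <- vector("list", length(angles))
  for (j in seq_along(angles)) {
    hi <- bounds[j]
    seg <- sim$beats[sim$beats$t_start >= (if (j == 1) 0 else bounds[j - 1]) &
                       sim$beats$t_start < hi - 1e-9, ]
    conv <- beats_converged(seg, n = 5)
    tail_b <- seg[max(1, nrow(seg) - n_avg + 1):nrow(seg), ]
    row <- as.data.frame(as.list(colMeans(tail_b)))
    row$angle <- angles[j]
    row$converged <- conv
    rows[[j]] <- row
  }
  out <- do.call(rbind, rows)
  sup <- out[1, ]
  pct <- function(x, x0) 100 * (x - x0) / x0
  out$dMAP <- out$MAP - sup$MAP
  out$pct_HR <- pct(out$HR, sup$HR)
  out$pct_SV <- pct(out$SV, sup$SV)
  out$pct_CO <- pct(out$CO, sup$CO)
  out$pct_EDV <- pct(out$LV_EDV, sup$LV_EDV)
  for (v in c("V_thoracic", "V_upper", "V_splanchnic", "V_renal", "V_lower",
              "V_cerebral", "V_coronary", "Q_cerebral", "Q_upper",
              "Q_coronary", "Q_splanchnic", "Q_renal", "Q_lower")) {
    out[[paste0("pct_", v)]] <- pct(out[[v]], sup[[v]])
  }
  attr(out, "sim_final") <- sim$final
  out
}

#' Export a tilt-response table as CSV
#'
#' Long-format regional summary with columns
#' `{angle, compartment, volume_mL, flow_L_min, pct_change}`.
#' @param resp result of [steady_state_response()]
#' @param file output path
#' @return the long-format data.frame, invisibly
#' @export
write_regional_csv <- function(resp, file) {
  comps <- c("cerebral", "upper", "coronary", "splanchnic", "renal", "lower")
  rows <- list()
  for (cp in comps) {
    vcol <- paste0("V_", cp); qcol <- paste0("Q_", cp)
    rows[[cp]] <- data.frame(
      angle = resp$angle, compartment = cp,
      volume_mL = resp[[vcol]],
      flow_L_min = resp[[qcol]] * 0.06,
      pct_change = resp[[paste0("pct_", vcol)]])
  }
  long <- do.call(rbind, rows)
  utils::write.csv(long, file, row.names = FALSE)
  invisible(long)
}
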