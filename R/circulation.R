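#' Hydrostatic pressure of a compartment during tilt
#'
#' Pressure of the blood column between a compartment and the hydrostatic
#' indifference point (at heart level), `rho g (h/100) sin(alpha)` converted
#' to mmHg (1 mmHg = 133.322 Pa). Positive below the heart.
#'
#' @param h distance from the hydrostatic indifference point (cm; negative
#'   above the heart)
#' @param alpha tilt angle from supine (degrees)
#' @param rho blood density (kg/m^3)
#' @param g gravitational acceleration (m/s^2)
#' @return hydrostatic pressure (mmHg)
#' @export
hydrostatic_pressure <- function(h, alpha, rho = 1060, g = 9.81) {
  if (any(alpha < 0 | alpha > 90)) stop("tilt angle outside [0, 90]")
  rho * g * (h / 100) * sin(alpha * pi / 180) / 133.322
}

#' Linear compartment pressure
#'
#' `P = (V - Vu)/C + P_hyd`. The engine composes this with the hydrostatic
#' term so that flow nodes are heart-referenced while the transmural term
#' `(V - Vu)/C` sets the stored volume.
#'
#' @param V compartment volume (mL)
#' @param params list with `C` (mL/mmHg) and `Vu` (mL)
#' @param P_hyd additive hydrostatic term (mmHg)
#' @return pressure (mmHg)
#' @export
compartment_pressure <- function(V, params, P_hyd = 0) {
  (V - params$Vu) / params$C + P_hyd
}

#' Nonlinear lower-body pressure-volume law
#'
#' Arctangent capacity law of the lower-body venous compartment: local
#' compliance equals `C0` at the unstressed volume and falls to zero as the
#' volume approaches `Vmax`, where the transmural pressure diverges.
#'
#' @param V compartment volume (mL), `Vu <= V < Vmax`
#' @param params list with `C0` (mL/mmHg), `Vu` (mL), `Vmax` (mL)
#' @param P_hyd additive hydrostatic term (mmHg)
#' @return pressure (mmHg)
#' @export
lower_body_pressure <- function(V, params, P_hyd = 0) {
  if (any(V >= params$Vmax))
    stop("lower-body volume reached Vmax (", params$Vmax, " mL)")
  cap <- params$Vmax - params$Vu
  x <- (V - params$Vu) / cap
  P <- ifelse(x <= 0,
              (V - params$Vu) / params$C0,
              (2 * cap / (pi * params$C0)) * tan(pi * x / 2))
  P + P_hyd
}

#' Flow through a linear resistance
#' @param P_up,P_down upstream and downstream pressures (mmHg)
#' @param R resistance (mmHg.s/mL), must be positive
#' @return flow (mL/s); negative = retrograde
#' @export
linear_flow <- function(P_up, P_down, R) {
  if (any(R <= 0)) stop("resistance must be positive")
  (P_up - P_down) / R
}

#' Flow through a venous valve (ideal diode in series with a resistance)
#' @inheritParams linear_flow
#' @return non-negative flow (mL/s)
#' @export
venous_valve_flow <- function(P_up, P_down, R) {
  pmax(0, linear_flow(P_up, P_down, R))
}

#' Volume balance of a compartment network
#'
#' Given named inflows and outflows per compartment, returns `dV/dt` and
#' checks closure of the loop.
#'
#' @param inflow,outflow named numeric vectors (mL/s) over the same
#'   compartment names
#' @return named numeric vector `dV/dt` (mL/s)
#' @export
volume_balance <- function(inflow, outflow) {
  if (!setequal(names(inflow), names(outflow)))
    stop("configuration error: dangling compartment in volume balance")
  dv <- inflow - outflow[names(inflow)]
  dv
}
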