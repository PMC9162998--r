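#' Shape constants of the circulatory-equilibrium model
#'
#' Fixed constants describing the logarithmic Frank-Starling curves of the two
#' ventricles and the planar venous return surface.  Left and right cardiac
#' output curves are \eqn{CO = S \, (\ln(P_{atrium} - P_0) + k)} and the venous
#' return surface is \eqn{CO = (V - G_L P_{LA} - G_R P_{RA}) / W}.  All flows
#' and volumes are normalized per kg body weight.
#'
#' The shipped defaults are package calibration: they were chosen so that a
#' drug-free canine heart-failure baseline (mean AP 87 mmHg, P_LA 17 mmHg,
#' P_RA 9.1 mmHg, CO 118 ml min^-1 kg^-1) is a feasible equilibrium with a
#' stressed blood volume near 25 ml kg^-1.  They are configuration, not
#' universal physiology; override them for a different subject.
#'
#' @param P0_L,k_L Left Frank-Starling curve: preload offset (mmHg) and
#'   additive constant (dimensionless).
#' @param P0_R,k_R Right-side analogues.
#' @param W Venous-return cardiac-output coefficient (min).
#' @param G_L,G_R Venous-return pressure coefficients (ml kg^-1 mmHg^-1) for
#'   left and right atrial pressure.
#' @return An object of class \code{"model_constants"}.
#' @examples
#' mc <- model_constants()
#' frank_starling_co(30, 17, mc$P0_L, mc$k_L)
#' @export
model_constants <- function(P0_L = 2.03, k_L = 0.80,
                            P0_R = 2.13, k_R = 1.90,
                            W = 0.129, G_L = 0.22, G_R = 0.64) {
  stopifnot(W > 0, G_L >= 0, G_R >= 0, P0_L >= 0, P0_R >= 0)
  structure(list(P0_L = P0_L, k_L = k_L, P0_R = P0_R, k_R = k_R,
                 W = W, G_L = G_L, G_R = G_R),
            class = "model_constants")
}

#' One time-point of measured or simulated hemodynamics
#'
#' @param t Time (min).
#' @param AP Mean arterial pressure (mmHg).
#' @param CO Cardiac output (ml min^-1 kg^-1).
#' @param P_LA Mean left atrial pressure (mmHg).
#' @param P_RA Mean right atrial pressure (mmHg).
#' @param HR Heart rate (beats min^-1); informational, not used by the
#'   equilibrium model.
#' @return An object of class \code{"hemo_state"}.
#' @export
hemo_state <- function(t = 0, AP, CO, P_LA, P_RA, HR = NA_real_) {
  stopifnot(is.numeric(AP), is.numeric(CO), is.numeric(P_LA), is.numeric(P_RA))
  if (AP <= P_RA) stop("invalid hemodynamic state: AP must exceed P_RA")
  if (P_RA < 0 || CO < 0) stop("invalid hemodynamic state: negative CO or P_RA")
  structure(list(t = t, AP = AP, CO = CO, P_LA = P_LA, P_RA = P_RA, HR = HR),
            class = "hemo_state")
}

#' The four mechanistic parameters of the circulatory equilibrium
#'
#' @param S_L,S_R Slopes of the left and right Frank-Starling curves
#'   (ml min^-1 kg^-1 per unit of the logarithmic preload term).
#' @param R Systemic vascular resistance (mmHg min kg ml^-1), defined over the
#'   arterio-venous pressure drop \eqn{(AP - P_{RA})/CO}.
#' @param V Stressed blood volume (ml kg^-1).
#' @return An object of class \code{"eq_params"}.
#' @export
eq_params <- function(S_L, S_R, R, V) {
  stopifnot(S_L > 0, S_R > 0, R > 0, V > 0)
  structure(list(S_L = S_L, S_R = S_R, R = R, V = V), class = "eq_params")
}

#' @export
print.eq_params <- function(x, ...) {
  cat(sprintf(
    "Circulatory-equilibrium parameters:\n  S_L = %.4g  S_R = %.4g  R = %.4g  V = %.4g\n",
    x$S_L, x$S_R, x$R, x$V))
  invisible(x)
}

#' @export
print.hemo_state <- function(x, ...) {
  cat(sprintf(
    "Hemodynamic state (t = %.3g min): AP %.4g  CO %.4g  P_LA %.4g  P_RA %.4g  HR %.4g\n",
    x$t, x$AP, x$CO, x$P_LA, x$P_RA, x$HR))
  invisible(x)
}

#' Frank-Starling cardiac output curve
#'
#' Logarithmic pump-function law \eqn{CO = S (\ln(P_{atrium} - P_0) + k)}:
#' cardiac output as a saturating function of atrial (preload) pressure, linear
#' in the slope \code{S}.
#'
#' @param S Curve slope (> 0).
#' @param P_atrium Atrial pressure (mmHg), must exceed \code{P0}.
#' @param P0 Preload offset of the curve (mmHg).
#' @param k Additive constant (dimensionless).
#' @return Cardiac output (ml min^-1 kg^-1).
#' @export
frank_starling_co <- function(S, P_atrium, P0, k) {
  if (any(S <= 0)) stop("Frank-Starling slope S must be positive")
  if (any(P_atrium <= P0))
    stop("preload below curve offset: P_atrium must exceed P0")
  S * (log(P_atrium - P0) + k)
}

#' Venous return surface
#'
#' Planar venous-return relation \eqn{CO = (V - G_L P_{LA} - G_R P_{RA}) / W}:
#' the cardiac output returned to the heart given the stressed blood volume and
#' both atrial pressures.
#'
#' @param V Stressed blood volume (ml kg^-1).
#' @param P_LA,P_RA Atrial pressures (mmHg).
#' @param constants A [model_constants()] object.
#' @return Venous return (ml min^-1 kg^-1); errors if it would be negative.
#' @export
venous_return_co <- function(V, P_LA, P_RA, constants = model_constants()) {
  co <- (V - constants$G_L * P_LA - constants$G_R * P_RA) / constants$W
  if (any(co < 0))
    stop("negative venous return: V below G_L*P_LA + G_R*P_RA")
  co
}

#' Estimate equilibrium parameters from one hemodynamic state
#'
#' Closed-form inversion of the circulatory-equilibrium model: from measured
#' AP, CO, P_LA and P_RA it computes the two Frank-Starling slopes, systemic
#' vascular resistance and stressed blood volume,
#' \deqn{S_L = CO / (\ln(P_{LA} - P_{0L}) + k_L), \quad
#'       S_R = CO / (\ln(P_{RA} - P_{0R}) + k_R),}
#' \deqn{R = (AP - P_{RA}) / CO, \quad
#'       V = W \cdot CO + G_L P_{LA} + G_R P_{RA}.}
#' It is the exact inverse of [solve_equilibrium()].
#'
#' @param state A [hemo_state()] (or list with fields AP, CO, P_LA, P_RA).
#' @param constants A [model_constants()] object.
#' @return An [eq_params()] object.
#' @export
estimate_parameters <- function(state, constants = model_constants()) {
  AP <- state$AP; CO <- state$CO; P_LA <- state$P_LA; P_RA <- state$P_RA
  if (CO <= 0) stop("parameter estimation requires CO > 0")
  if (AP <= P_RA) stop("parameter estimation requires AP > P_RA")
  if (P_LA <= constants$P0_L)
    stop("P_LA at or below left Frank-Starling offset P0_L")
  if (P_RA <= constants$P0_R)
    stop("P_RA at or below right Frank-Starling offset P0_R")
  den_L <- log(P_LA - constants$P0_L) + constants$k_L
  den_R <- log(P_RA - constants$P0_R) + constants$k_R
  if (den_L <= 0 || den_R <= 0)
    stop("non-positive Frank-Starling log term; state outside model domain")
  eq_params(S_L = CO / den_L,
            S_R = CO / den_R,
            R   = (AP - P_RA) / CO,
            V   = constants$W * CO + constants$G_L * P_LA + constants$G_R * P_RA)
}

# Invert both Frank-Starling curves for the atrial pressures implied by a
# trial CO; the equilibrium residual in volume units is then monotone in CO.
.preloads_of_co <- function(CO, params, constants) {
  list(P_LA = constants$P0_L + exp(CO / params$S_L - constants$k_L),
       P_RA = constants$P0_R + exp(CO / params$S_R - constants$k_R))
}

#' Solve the circulatory equilibrium
#'
#' Finds the unique (CO, P_LA, P_RA) at which both Frank-Starling curves and
#' the venous return surface intersect, then AP = R*CO + P_RA.  The
#' three-equation system is reduced to a one-dimensional root in CO (both
#' Frank-Starling curves invert in closed form), which is bracketed and solved
#' with Brent's method; the volume residual
#' \eqn{W CO + G_L P_{LA}(CO) + G_R P_{RA}(CO) - V}
#' is strictly increasing in CO so the bracketed root is unique.
#'
#' @param params An [eq_params()] object.
#' @param constants A [model_constants()] object.
#' @param tol Root tolerance passed to [stats::uniroot()] (CO units).
#' @return A [hemo_state()]; equation residuals are below 1e-8 CO units.
#' @export
solve_equilibrium <- function(params, constants = model_constants(),
                              tol = 1e-12) {
  residual <- function(CO) {
    p <- .preloads_of_co(CO, params, constants)
    constants$W * CO + constants$G_L * p$P_LA + constants$G_R * p$P_RA - params$V
  }
  if (residual(0) >= 0)
    stop("no feasible equilibrium: stressed volume too small for zero flow")
  hi <- 1
  while (residual(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e9)
      stop("equilibrium solver failed to bracket a root (CO > 1e9)")
  }
  CO <- stats::uniroot(residual, lower = 0, upper = hi, tol = tol)$root
  p <- .preloads_of_co(CO, params, constants)
  res <- c(CO - frank_starling_co(params$S_L, p$P_LA, constants$P0_L, constants$k_L),
           CO - frank_starling_co(params$S_R, p$P_RA, constants$P0_R, constants$k_R),
           CO - venous_return_co(params$V, p$P_LA, p$P_RA, constants))
  if (max(abs(res)) > 1e-8)
    stop(sprintf("equilibrium residual %.3g exceeds tolerance", max(abs(res))))
  hemo_state(t = 0, AP = params$R * CO + p$P_RA, CO = CO,
             P_LA = p$P_LA, P_RA = p$P_RA)
}

#' Determine target parameters from pressure goals
#'
#' Given the clinician-set targets AP* and P_LA*, the subject's right
#' Frank-Starling slope S_R and systemic resistance R (both assumed unchanged
#' by the intervention), solves the coupled pair
#' \deqn{CO^* = (AP^* - P_{RA}^*)/R, \qquad
#'       P_{RA}^* = P_{0R} + \exp(CO^*/S_R - k_R)}
#' for the implied target cardiac output and right atrial pressure, then
#' derives the target left Frank-Starling slope and stressed volume
#' \deqn{S_L^* = CO^*/(\ln(P_{LA}^* - P_{0L}) + k_L), \qquad
#'       V^* = W CO^* + G_L P_{LA}^* + G_R P_{RA}^*.}
#' Safety clamps are applied first: AP* is raised to \code{ap_floor} (default
#' 70 mmHg) and P_LA* lowered to \code{pla_cap} (default 18 mmHg) when the
#' requested values violate them; the returned object records whether a clamp
#' fired.
#'
#' @param AP_star Target mean arterial pressure (mmHg).
#' @param P_LA_star Target mean left atrial pressure (mmHg).
#' @param S_R Right Frank-Starling slope (held at its measured value).
#' @param R Systemic vascular resistance.
#' @param constants A [model_constants()] object.
#' @param ap_floor Lowest admissible AP* (mmHg).
#' @param pla_cap Highest admissible P_LA* (mmHg).
#' @return An object of class \code{"control_targets"} with fields
#'   \code{AP_star}, \code{P_LA_star}, \code{S_L_star}, \code{V_star},
#'   \code{CO_star}, \code{P_RA_star}, \code{S_R_star} and clamp flags.
#' @export
compute_targets <- function(AP_star, P_LA_star, S_R, R,
                            constants = model_constants(),
                            ap_floor = 70, pla_cap = 18) {
  stopifnot(S_R > 0, R > 0)
  clamped_AP <- AP_star < ap_floor
  clamped_PLA <- P_LA_star > pla_cap
  if (clamped_AP) AP_star <- ap_floor
  if (clamped_PLA) P_LA_star <- pla_cap
  if (P_LA_star <= constants$P0_L)
    stop("infeasible target: P_LA* at or below left curve offset")

  g <- function(CO) {
    R * CO + constants$P0_R + exp(CO / S_R - constants$k_R) - AP_star
  }
  if (g(0) >= 0)
    stop("infeasible target: no positive CO* reaches AP*")
  hi <- 1
  while (g(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e9) stop("target solver failed to bracket CO*")
  }
  CO_star <- stats::uniroot(g, lower = 0, upper = hi, tol = 1e-12)$root
  P_RA_star <- constants$P0_R + exp(CO_star / S_R - constants$k_R)
  den_L <- log(P_LA_star - constants$P0_L) + constants$k_L
  if (den_L <= 0)
    stop("infeasible target: non-positive left Frank-Starling log term")
  structure(list(
    AP_star = AP_star, P_LA_star = P_LA_star,
    S_L_star = CO_star / den_L,
    V_star = constants$W * CO_star + constants$G_L * P_LA_star +
      constants$G_R * P_RA_star,
    CO_star = CO_star, P_RA_star = P_RA_star, S_R_star = S_R,
    clamped_AP = clamped_AP, clamped_PLA = clamped_PLA),
    class = "control_targets")
}

#' @export
print.control_targets <- function(x, ...) {
  cat(sprintf(
    paste0("Control targets: AP* %.4g mmHg%s  P_LA* %.4g mmHg%s\n",
           "  implied: S_L* %.4g  V* %.4g  CO* %.4g  P_RA* %.4g\n"),
    x$AP_star, if (x$clamped_AP) " (clamped to floor)" else "",
    x$P_LA_star, if (x$clamped_PLA) " (clamped to cap)" else "",
    x$S_L_star, x$V_star, x$CO_star, x$P_RA_star))
  invisible(x)
}
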