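#' Proportional-integral controller for landiolol infusion
#'
#' Discrete PI law mapping the left Frank-Starling slope error
#' \eqn{\Delta S_L = S_L - S_L^*} to a landiolol infusion rate.  Positive
#' error (contractility above target) yields positive infusion.  Output is
#' clamped to \code{[u_min, u_max]} with conditional-integration anti-windup:
#' the integral is frozen on steps where the raw output is saturated and the
#' current error would push it further into saturation.
#'
#' @param Kp Proportional gain ((ug min^-1 kg^-1) per slope unit).
#' @param Ki Integral gain ((ug min^-1 kg^-1) per slope-unit minute).
#' @param u_max Maximum landiolol rate (ug min^-1 kg^-1).
#' @param u_min Minimum rate (default 0; infusion cannot be negative).
#' @param integral Initial accumulated error (slope-unit min).
#' @return An object of class \code{"pi_controller"}.
#' @export
pi_controller <- function(Kp, Ki, u_max = 100, u_min = 0, integral = 0) {
  stopifnot(Kp >= 0, Ki >= 0, u_max >= u_min)
  structure(list(Kp = Kp, Ki = Ki, u_max = u_max, u_min = u_min,
                 integral = integral),
            class = "pi_controller")
}

#' Advance the PI controller by one control step
#'
#' @param ctrl A [pi_controller()].
#' @param error Current slope error \eqn{S_L - S_L^*}.
#' @param dt Control interval (min), > 0.
#' @return A list with \code{rate} (clamped infusion rate) and
#'   \code{controller} (updated state).
#' @export
pi_update <- function(ctrl, error, dt) {
  stopifnot(dt > 0)
  int_new <- ctrl$integral + error * dt
  u_raw <- ctrl$Kp * error + ctrl$Ki * int_new
  windup_hi <- u_raw > ctrl$u_max && error > 0
  windup_lo <- u_raw < ctrl$u_min && error < 0
  if (windup_hi || windup_lo) {
    # saturated and the error would push further in: freeze the integral
    u_raw <- ctrl$Kp * error + ctrl$Ki * ctrl$integral
  } else {
    ctrl$integral <- int_new
  }
  list(rate = min(max(u_raw, ctrl$u_min), ctrl$u_max), controller = ctrl)
}

#' Nonlinear volume controller configuration
#'
#' Dead-band law for the stressed-volume error \eqn{\Delta V = V - V^*}.
#' A volume deficit beyond \code{dead_band_deficit} drives a proportional,
#' rate-limited dextran infusion; a volume excess beyond \code{dead_band}
#' triggers a fixed furosemide bolus, at most once per lockout interval.  The
#' two dead bands may differ: the bolus branch is quantized and needs a wide
#' guard against estimate noise, while the proportional dextran branch can
#' safely re-center the volume with a narrow one.  By default both equal
#' \code{dead_band} (a symmetric dead band).
#'
#' @param dead_band Excess-side threshold on Delta V (ml kg^-1) above which a
#'   furosemide bolus is considered.
#' @param dextran_gain Dextran rate per ml kg^-1 of deficit beyond the deficit
#'   dead band ((ml min^-1 kg^-1) / (ml kg^-1)).
#' @param dextran_max Maximum dextran infusion rate (ml min^-1 kg^-1).
#' @param furosemide_bolus Fixed bolus dose (mg).
#' @param furosemide_lockout Minimum interval between boluses (min).
#' @param dead_band_deficit Deficit-side threshold (ml kg^-1); defaults to
#'   \code{dead_band}.
#' @param bolus_effect Nominal volume loss the controller expects one bolus to
#'   eventually produce (ml kg^-1); used for diuresis-on-board compensation.
#' @param effect_onset Nominal first-order rate (min^-1) at which that loss is
#'   expressed.
#' @return An object of class \code{"volume_controller"}.
#' @export
volume_controller <- function(dead_band = 0.5, dextran_gain = 0.3,
                              dextran_max = 1, furosemide_bolus = 5,
                              furosemide_lockout = 10,
                              dead_band_deficit = dead_band,
                              bolus_effect = 1.5, effect_onset = 0.35) {
  stopifnot(dead_band >= 0, dead_band_deficit >= 0, dextran_gain >= 0,
            dextran_max >= 0, furosemide_bolus >= 0, furosemide_lockout >= 0,
            bolus_effect >= 0, effect_onset >= 0)
  structure(list(dead_band = dead_band, dead_band_deficit = dead_band_deficit,
                 dextran_gain = dextran_gain, dextran_max = dextran_max,
                 furosemide_bolus = furosemide_bolus,
                 furosemide_lockout = furosemide_lockout,
                 bolus_effect = bolus_effect, effect_onset = effect_onset),
            class = "volume_controller")
}

#' One step of the nonlinear volume controller
#'
#' The decision variable is the measured volume error minus the
#' diuresis-on-board term \code{pending}: volume loss already commanded via
#' earlier boluses but not yet expressed by the kidneys.  Without this
#' compensation a second bolus can fire against excess that a pending bolus
#' will remove anyway.  Callers maintain \code{pending} by decaying it at the
#' nominal onset rate (see [pending_decay()]) and passing the value returned
#' here back in at the next step.
#'
#' @param cfg A [volume_controller()].
#' @param delta_V Stressed-volume error \eqn{V - V^*} (ml kg^-1).
#' @param t Current time (min).
#' @param last_bolus_t Time of the last furosemide bolus (min; \code{-Inf} if
#'   none yet).
#' @param pending Expected still-unexpressed volume loss from earlier boluses
#'   (ml kg^-1).
#' @return A list with \code{dextran_rate} (ml min^-1 kg^-1),
#'   \code{furosemide} (mg, 0 if no bolus), \code{last_bolus_t} and
#'   \code{pending} (both updated).  Dextran and furosemide are never
#'   commanded on the same step.
#' @export
volume_update <- function(cfg, delta_V, t = 0, last_bolus_t = -Inf,
                          pending = 0) {
  dextran <- 0
  furo <- 0
  eff <- delta_V - pending
  if (eff < -cfg$dead_band_deficit) {
    dextran <- min(cfg$dextran_gain * (-eff - cfg$dead_band_deficit),
                   cfg$dextran_max)
  } else if (eff > cfg$dead_band &&
             t - last_bolus_t >= cfg$furosemide_lockout) {
    furo <- cfg$furosemide_bolus
    last_bolus_t <- t
    pending <- pending + cfg$bolus_effect
  }
  list(dextran_rate = dextran, furosemide = furo, last_bolus_t = last_bolus_t,
       pending = pending)
}

#' Decay the controller's diuresis-on-board estimate by one step
#'
#' @param cfg A [volume_controller()].
#' @param pending Current pending volume loss (ml kg^-1).
#' @param dt Step (min).
#' @return The decayed pending value.
#' @export
pending_decay <- function(cfg, pending, dt) {
  pending * exp(-cfg$effect_onset * dt)
}
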