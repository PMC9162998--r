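#' Performance error of a controlled variable
#'
#' Signed percentage error of the measured value against its target,
#' \eqn{PE = (Variable - Target)/Variable \times 100}; the denominator is the
#' measured variable, so PE is invariant to a common rescaling of value and
#' target.
#'
#' @param value Measured value(s); must be non-zero.
#' @param target Target value(s).
#' @return PE in percent.
#' @export
performance_error <- function(value, target) {
  if (any(value == 0)) stop("PE undefined: measured value is zero")
  (value - target) / value * 100
}

.window_pe <- function(t, pe, window, min_n = 1L) {
  stopifnot(length(t) == length(pe))
  keep <- t >= window[1] - 1e-9 & t <= window[2] + 1e-9
  if (sum(keep) < min_n)
    stop(sprintf("fewer than %d samples in window [%g, %g]",
                 min_n, window[1], window[2]))
  list(t = t[keep], pe = pe[keep])
}

#' Median performance error (bias)
#'
#' @param t Sample times (min).
#' @param pe PE series (percent), as from [performance_error()].
#' @param window Two-element time window (min), boundaries inclusive; the
#'   default 15-60 min skips the initial stabilisation transient.
#' @return MDPE in percent.  Even-length windows use the mean-of-central-pair
#'   median convention.
#' @export
mdpe <- function(t, pe, window = c(15, 60)) {
  stats::median(.window_pe(t, pe, window)$pe)
}

#' Median absolute performance error (accuracy)
#'
#' @inheritParams mdpe
#' @return MDAPE in percent.
#' @export
mdape <- function(t, pe, window = c(15, 60)) {
  stats::median(abs(.window_pe(t, pe, window)$pe))
}

#' Wobble (intra-subject variability of PE)
#'
#' Median absolute deviation of PE from MDPE, both computed on the same
#' window.
#'
#' @inheritParams mdpe
#' @return Wobble in percent.
#' @export
wobble <- function(t, pe, window = c(15, 60)) {
  w <- .window_pe(t, pe, window)
  stats::median(abs(w$pe - stats::median(w$pe)))
}

#' Divergence (time trend of the absolute PE)
#'
#' Ordinary least-squares slope of |PE| against time in minutes.
#'
#' @inheritParams mdpe
#' @return Divergence in percent per minute.
#' @export
divergence <- function(t, pe, window = c(15, 60)) {
  w <- .window_pe(t, pe, window, min_n = 2L)
  if (length(unique(w$t)) < 2L)
    stop("divergence undefined: all sample times equal")
  unname(stats::coef(stats::lm(abs(w$pe) ~ w$t))[2])
}

#' Percentage of time within the acceptable range
#'
#' One-sided safety band around the target: for a lower bound (AP) a sample is
#' in range when \code{value >= target - margin}; for an upper bound (P_LA)
#' when \code{value <= target + margin}.  The boundary counts as in range.
#'
#' @param values Measured signal.
#' @param target Target value.
#' @param side \code{"lower_bound"} or \code{"upper_bound"}.
#' @param margin Band width (same units as the signal).
#' @return Percent of samples in range.
#' @export
time_in_acceptable_range <- function(values, target,
                                     side = c("lower_bound", "upper_bound"),
                                     margin) {
  side <- match.arg(side)
  stopifnot(length(values) >= 1L, margin >= 0)
  ok <- if (side == "lower_bound") values >= target - margin
        else values <= target + margin
  100 * mean(ok)
}

#' Varvel performance report for one signal
#'
#' @param t Sample times (min).
#' @param values Measured signal.
#' @param target Target value.
#' @param window PE window (min) for MDPE/MDAPE/wobble/divergence.
#' @param side,margin Acceptable-range definition, see
#'   [time_in_acceptable_range()].
#' @param tir_window Window for time-in-range (default: all samples).
#' @return An object of class \code{"metrics_report"}: a list with
#'   \code{time_in_range}, \code{MDPE}, \code{MDAPE}, \code{wobble},
#'   \code{divergence}, and the windows used.
#' @export
varvel_metrics <- function(t, values, target, window = c(15, 60),
                           side = "lower_bound", margin = 5,
                           tir_window = range(t)) {
  pe <- performance_error(values, target)
  keep <- t >= tir_window[1] - 1e-9 & t <= tir_window[2] + 1e-9
  structure(list(
    time_in_range = time_in_acceptable_range(values[keep], target,
                                             side = side, margin = margin),
    MDPE = mdpe(t, pe, window),
    MDAPE = mdape(t, pe, window),
    wobble = wobble(t, pe, window),
    divergence = divergence(t, pe, window),
    window = window, tir_window = tir_window),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    paste0("Controller performance (PE window %g-%g min):\n",
           "  time in range %.1f%%  MDAPE %.2f%%  MDPE %.2f%%",
           "  wobble %.2f%%  divergence %.4f %%/min\n"),
    x$window[1], x$window[2], x$time_in_range, x$MDAPE, x$MDPE,
    x$wobble, x$divergence))
  invisible(x)
}

#' Per-signal performance table for a closed-loop run
#'
#' Scores mean AP (lower-bound band, margin 5 mmHg) and mean P_LA
#' (upper-bound band, margin 2 mmHg) of a [run_closed_loop()] result against
#' its own targets, mirroring the columns of a closed-loop performance table:
#' time in acceptable range, MDAPE, MDPE, wobble, divergence.
#'
#' @param run A \code{"cvloop_run"} (or data frame with t, AP, P_LA columns).
#' @param targets A \code{"control_targets"}; defaults to the run's own.
#' @param window PE window (min).
#' @param tir_window Time-in-range window (min); default the full run.
#' @return A data frame with one row per signal.
#' @export
run_metrics <- function(run, targets = run_targets(run), window = c(15, 60),
                        tir_window = range(run$t)) {
  ap <- varvel_metrics(run$t, run$AP, targets$AP_star, window = window,
                       side = "lower_bound", margin = 5,
                       tir_window = tir_window)
  pla <- varvel_metrics(run$t, run$P_LA, targets$P_LA_star, window = window,
                        side = "upper_bound", margin = 2,
                        tir_window = tir_window)
  as_row <- function(m) {
    data.frame(time_in_range = m$time_in_range, MDAPE = m$MDAPE,
               MDPE = m$MDPE, wobble = m$wobble, divergence = m$divergence)
  }
  out <- rbind(as_row(ap), as_row(pla))
  rownames(out) <- c("AP", "P_LA")
  out
}
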