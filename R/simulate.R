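#' Run the closed-loop drug-delivery simulation
#'
#' Wires the full system against a virtual heart-failure patient: a baseline
#' observation window fixes the pressure targets (AP* a configured drop below
#' baseline AP but never below the 70 mmHg floor; P_LA* at baseline P_LA but
#' never above the 18 mmHg cap) and, through [compute_targets()], the
#' parameter targets S_L* and V*.  Thereafter, at every control interval the
#' loop measures the plant, smooths the measurements with a moving average,
#' estimates (S_L, S_R, R, V) by [estimate_parameters()], and feeds the errors
#' to the landiolol PI controller ([pi_update()]) and the nonlinear volume
#' controller ([volume_update()]); the commanded rates act on the plant over
#' the next interval ([plant_step()]).  Targets are computed once at
#' activation by default; set \code{protocol$recompute_targets} to refresh
#' S_L*/V* every step from the current S_R and R estimates.
#'
#' @param config A run configuration, see [default_config()].
#' @param seed Integer seed controlling every stochastic element of the run.
#' @param noise Add measurement noise?  \code{FALSE} gives the deterministic
#'   noise-free loop.
#' @param patient Optional pre-built [make_hf_patient()]; by default the
#'   patient is built from \code{config}.
#' @param duration Override of \code{config$protocol$duration} (min).
#' @return A data frame of class \code{"cvloop_run"}, one row per control
#'   step (t = 0 is activation), with measured and true hemodynamics,
#'   parameter estimates, errors, drug commands and cumulative doses.
#'   Attributes: \code{targets}, \code{config}, \code{seed}, \code{noise},
#'   \code{patient}, \code{config_hash}.
#' @examples
#' run <- run_closed_loop(duration = 5, seed = 1)
#' summary(run)
#' @export
run_closed_loop <- function(config = default_config(), seed = 1L,
                            noise = TRUE, patient = NULL, duration = NULL) {
  set.seed(seed)
  if (is.null(patient)) patient <- make_hf_patient(config)
  proto <- config$protocol
  if (is.null(duration)) duration <- proto$duration
  dt <- proto$dt
  n_steps <- round(duration / dt)
  w <- max(1L, round(proto$smoothing_window / dt))
  n_base <- max(1L, round(proto$baseline_window / dt))

  plant <- plant_init(patient)

  # Pre-activation observation: the resting plant measured n_base times.
  base_obs <- matrix(NA_real_, n_base, 4,
                     dimnames = list(NULL, c("AP", "CO", "P_LA", "P_RA")))
  for (i in seq_len(n_base)) {
    st <- plant_step(patient, plant, 0, 0, 0, dt, noise = noise)
    plant <- st$plant
    base_obs[i, ] <- c(st$measured$AP, st$measured$CO,
                       st$measured$P_LA, st$measured$P_RA)
  }
  base_mean <- colMeans(base_obs)
  base_state <- hemo_state(t = 0, AP = base_mean[["AP"]], CO = base_mean[["CO"]],
                           P_LA = base_mean[["P_LA"]], P_RA = base_mean[["P_RA"]])
  base_par <- estimate_parameters(base_state, patient$constants)
  targets <- compute_targets(AP_star = base_mean[["AP"]] - proto$ap_drop,
                             P_LA_star = base_mean[["P_LA"]],
                             S_R = base_par$S_R, R = base_par$R,
                             constants = patient$constants,
                             ap_floor = proto$ap_floor,
                             pla_cap = proto$pla_cap)

  pi_ctrl <- do.call(pi_controller, config$controller$pi)
  vol_ctrl <- do.call(volume_controller, config$controller$volume)
  last_bolus_t <- -Inf
  pending_est <- 0

  # Smoothing buffer carries the pre-activation history.
  buf <- base_obs[max(1, n_base - w + 2):n_base, , drop = FALSE]

  nr <- n_steps + 1L
  log_cols <- c("t", "AP", "CO", "P_LA", "P_RA", "HR",
                "AP_true", "CO_true", "P_LA_true", "P_RA_true", "HR_true",
                "S_L_true", "V_true", "C_landiolol",
                "S_L_hat", "S_R_hat", "R_hat", "V_hat",
                "delta_S_L", "delta_V",
                "landiolol_rate", "dextran_rate", "furosemide_bolus")
  out <- matrix(NA_real_, nr, length(log_cols),
                dimnames = list(NULL, log_cols))

  st <- plant_step(patient, plant, 0, 0, 0, dt, noise = noise)  # activation sample
  plant <- st$plant
  for (i in seq_len(nr)) {
    t_i <- (i - 1L) * dt
    m <- st$measured
    buf <- rbind(buf, c(m$AP, m$CO, m$P_LA, m$P_RA))
    if (nrow(buf) > w) buf <- buf[(nrow(buf) - w + 1):nrow(buf), , drop = FALSE]
    sm <- colMeans(buf)
    est <- tryCatch(
      estimate_parameters(hemo_state(t = t_i, AP = sm[["AP"]], CO = sm[["CO"]],
                                     P_LA = sm[["P_LA"]], P_RA = sm[["P_RA"]]),
                          patient$constants),
      error = function(e)
        stop(sprintf("simulation fault at t = %.2f min: %s",
                     t_i, conditionMessage(e)), call. = FALSE))

    if (isTRUE(proto$recompute_targets) && i > 1L) {
      targets <- compute_targets(targets$AP_star, targets$P_LA_star,
                                 S_R = est$S_R, R = est$R,
                                 constants = patient$constants,
                                 ap_floor = proto$ap_floor,
                                 pla_cap = proto$pla_cap)
    }
    d_SL <- est$S_L - targets$S_L_star
    d_V <- est$V - targets$V_star

    upd <- pi_update(pi_ctrl, d_SL, dt)
    pi_ctrl <- upd$controller
    pending_est <- pending_decay(vol_ctrl, pending_est, dt)
    vol <- volume_update(vol_ctrl, d_V, t = t_i, last_bolus_t = last_bolus_t,
                         pending = pending_est)
    last_bolus_t <- vol$last_bolus_t
    pending_est <- vol$pending

    out[i, ] <- c(t_i, m$AP, m$CO, m$P_LA, m$P_RA, m$HR,
                  st$true$AP, st$true$CO, st$true$P_LA, st$true$P_RA,
                  st$true$HR, plant$S_L_current, plant$V_current, plant$C,
                  est$S_L, est$S_R, est$R, est$V, d_SL, d_V,
                  upd$rate, vol$dextran_rate, vol$furosemide)

    if (i <= n_steps) {
      st <- plant_step(patient, plant, landiolol_rate = upd$rate,
                       dextran_rate = vol$dextran_rate,
                       furosemide = vol$furosemide, dt = dt, noise = noise)
      plant <- st$plant
    }
  }

  df <- as.data.frame(out)
  df$landiolol_cum <- cumsum(c(0, df$landiolol_rate[-nr] * dt))
  df$dextran_cum <- cumsum(c(0, df$dextran_rate[-nr] * dt))
  df$furosemide_cum <- cumsum(df$furosemide_bolus)
  structure(df,
            class = c("cvloop_run", "data.frame"),
            targets = targets, config = config, seed = seed, noise = noise,
            patient = patient, config_hash = config_hash(config))
}

#' Targets of a closed-loop run
#'
#' @param run A \code{"cvloop_run"}.
#' @return The \code{"control_targets"} attribute.
#' @export
run_targets <- function(run) attr(run, "targets")

#' Run a seed ensemble of closed-loop simulations
#'
#' Repeats [run_closed_loop()] under distinct seeds; used to summarise
#' performance statistics across measurement-noise realisations (and, with
#' \code{ensemble_patients = TRUE}, across log-normally perturbed baselines).
#'
#' @param config A run configuration.
#' @param seeds Integer vector of seeds, one run each.
#' @param ensemble_patients Draw a perturbed patient per seed?
#' @param ... Passed to [run_closed_loop()].
#' @return A list of \code{"cvloop_run"} objects, one per seed.
#' @export
run_ensemble <- function(config = default_config(), seeds = 1:20,
                         ensemble_patients = FALSE, ...) {
  lapply(seeds, function(s) {
    patient <- if (ensemble_patients) {
      make_hf_patient(config, seed = s, ensemble = TRUE)
    } else NULL
    run_closed_loop(config, seed = s, patient = patient, ...)
  })
}

#' @export
print.cvloop_run <- function(x, ...) {
  tg <- run_targets(x)
  cat(sprintf(
    "Closed-loop run: %d control steps over %.3g min (dt = %.3g min), seed %s, noise %s\n",
    nrow(x) - 1L, max(x$t), x$t[2] - x$t[1], attr(x, "seed"),
    if (attr(x, "noise")) "on" else "off"))
  cat(sprintf("  targets: AP* %.4g mmHg, P_LA* %.4g mmHg (S_L* %.4g, V* %.4g)\n",
              tg$AP_star, tg$P_LA_star, tg$S_L_star, tg$V_star))
  cat(sprintf("  final: AP %.4g mmHg, P_LA %.4g mmHg, HR %.4g bpm\n",
              x$AP[nrow(x)], x$P_LA[nrow(x)], x$HR[nrow(x)]))
  cat(sprintf("  doses: landiolol %.4g ug/kg, dextran %.4g ml/kg, furosemide %.4g mg\n",
              x$landiolol_cum[nrow(x)], x$dextran_cum[nrow(x)],
              x$furosemide_cum[nrow(x)]))
  invisible(x)
}

#' @export
summary.cvloop_run <- function(object, window = c(15, 60), ...) {
  print(object)
  cat("\nController performance (PE window",
      sprintf("%g-%g min):\n", window[1], window[2]))
  print(run_metrics(object, window = window), digits = 3)
  invisible(object)
}

#' Plot a closed-loop run
#'
#' Four-panel base-graphics view: pressures against their targets and
#' acceptable-range bounds, drug commands, and the controlled parameters S_L
#' and V against S_L* and V*.
#'
#' @param x A \code{"cvloop_run"}.
#' @param ... Unused.
#' @export
plot.cvloop_run <- function(x, ...) {
  tg <- run_targets(x)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$AP, type = "l", col = "navy",
                 xlab = "time (min)", ylab = "mean AP (mmHg)", main = "AP")
  graphics::abline(h = tg$AP_star, col = "red")
  graphics::abline(h = tg$AP_star - 5, col = "red", lty = 3)
  graphics::plot(x$t, x$P_LA, type = "l", col = "navy",
                 xlab = "time (min)", ylab = "mean P_LA (mmHg)", main = "P_LA")
  graphics::abline(h = tg$P_LA_star, col = "red")
  graphics::abline(h = tg$P_LA_star + 2, col = "red", lty = 3)
  graphics::plot(x$t, x$landiolol_rate, type = "l", col = "darkgreen",
                 xlab = "time (min)", ylab = "landiolol (ug/min/kg)",
                 main = "drug commands")
  graphics::lines(x$t, x$dextran_rate * 10, col = "orange")
  graphics::points(x$t[x$furosemide_bolus > 0],
                   rep(0, sum(x$furosemide_bolus > 0)), pch = 17, col = "brown")
  graphics::plot(x$t, x$S_L_hat, type = "l", col = "navy",
                 xlab = "time (min)", ylab = "S_L (solid), V (dashed)",
                 main = "controlled parameters",
                 ylim = range(c(x$S_L_hat, x$V_hat, tg$S_L_star, tg$V_star)))
  graphics::lines(x$t, x$V_hat, col = "navy", lty = 2)
  graphics::abline(h = c(tg$S_L_star, tg$V_star), col = "red", lty = c(1, 2))
  invisible(x)
}
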