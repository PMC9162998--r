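#' Construct a virtual canine heart-failure patient
#'
#' Builds an in-silico plant whose drug-free equilibrium reproduces a
#' configured heart-failure baseline (default: mean AP 87 mmHg, P_LA 17 mmHg,
#' P_RA 9.1 mmHg, CO 118 ml min^-1 kg^-1, HR 129 bpm).  The baseline
#' equilibrium parameters are obtained by [estimate_parameters()], so the
#' resting plant is an exact fixed point of the model.  Landiolol follows
#' one-compartment pharmacokinetics with Emax pharmacodynamics on the left
#' Frank-Starling slope (negative inotropy) and on heart rate (negative
#' chronotropy); dextran expands and furosemide-induced diuresis shrinks the
#' stressed blood volume.
#'
#' With \code{ensemble = TRUE} the four baseline hemodynamics are perturbed by
#' independent log-normal factors (coefficient of variation
#' \code{config$patient$ensemble_cv}) drawn from the current RNG state, giving
#' a population of plausible subjects.
#'
#' @param config A run configuration, see [default_config()].
#' @param seed Optional integer; when non-NULL the RNG is seeded before any
#'   ensemble draw, making construction fully reproducible.
#' @param ensemble Perturb the baseline log-normally?
#' @return An object of class \code{"virtual_patient"}.
#' @export
make_hf_patient <- function(config = default_config(), seed = NULL,
                            ensemble = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  pc <- config$patient
  constants <- do.call(model_constants, config$constants)
  base <- pc$baseline
  if (ensemble && pc$ensemble_cv > 0) {
    sdlog <- sqrt(log(1 + pc$ensemble_cv^2))
    f <- exp(stats::rnorm(4, -sdlog^2 / 2, sdlog))
    base$AP <- base$AP * f[1]; base$CO <- base$CO * f[2]
    base$P_LA <- base$P_LA * f[3]; base$P_RA <- base$P_RA * f[4]
  }
  baseline_state <- hemo_state(t = 0, AP = base$AP, CO = base$CO,
                               P_LA = base$P_LA, P_RA = base$P_RA,
                               HR = base$HR)
  params <- estimate_parameters(baseline_state, constants)
  structure(list(
    baseline_state = baseline_state,
    params = params,
    constants = constants,
    pk = pc$pk, pd = pc$pd,
    dextran_fraction = pc$dextran_fraction,
    furo = pc$furo,
    noise_sd = pc$noise_sd,
    HR_base = base$HR),
    class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat("Virtual heart-failure patient\n  baseline: ")
  print(x$baseline_state)
  cat("  ")
  print(x$params)
  invisible(x)
}

#' Initial internal plant state of a virtual patient
#'
#' @param patient A [make_hf_patient()] object.
#' @return A list with landiolol concentration \code{C}, current stressed
#'   volume \code{V_current}, unexpressed diuresis \code{pending_diuresis},
#'   and drug-modified \code{S_L_current}, \code{HR_current}.
#' @export
plant_init <- function(patient) {
  list(C = 0,
       V_current = patient$params$V,
       pending_diuresis = 0,
       S_L_current = patient$params$S_L,
       HR_current = patient$HR_base)
}

#' Advance the virtual patient by one interval
#'
#' Pharmacokinetics use the exact one-compartment solution for a constant
#' infusion over the step, \eqn{dC/dt = rate/V_d - k_e C}.  Pharmacodynamics
#' scale the baseline left Frank-Starling slope and heart rate by
#' \eqn{1 - E_{max} C/(C + EC_{50})}.  A furosemide bolus adds
#' \code{gain * dose} to a pending-diuresis pool that drains the stressed
#' volume first order at the onset rate; dextran adds
#' \code{dextran_fraction * rate * dt} to it.  The observable state is the
#' circulatory equilibrium of the drug-modified parameters (S_R and R held at
#' baseline), with optional zero-mean Gaussian measurement noise.
#'
#' @param patient A [make_hf_patient()] object.
#' @param plant Internal state from [plant_init()] or a previous step.
#' @param landiolol_rate Landiolol infusion rate (ug min^-1 kg^-1) over the step.
#' @param dextran_rate Dextran infusion rate (ml min^-1 kg^-1) over the step.
#' @param furosemide Furosemide bolus (mg) given at the start of the step.
#' @param dt Step length (min), > 0.
#' @param noise Add measurement noise (drawn from the current RNG state)?
#' @return A list with \code{plant} (advanced internal state), \code{true}
#'   (noise-free [hemo_state()]) and \code{measured} (noisy copy).
#' @export
plant_step <- function(patient, plant, landiolol_rate = 0, dextran_rate = 0,
                       furosemide = 0, dt = 1 / 6, noise = TRUE) {
  stopifnot(dt > 0, landiolol_rate >= 0, dextran_rate >= 0, furosemide >= 0)
  pk <- patient$pk
  if (pk$k_e > 0) {
    decay <- exp(-pk$k_e * dt)
    C <- plant$C * decay + landiolol_rate / (pk$k_e * pk$Vd) * (1 - decay)
  } else {
    C <- plant$C + landiolol_rate * dt / pk$Vd
  }
  pending <- plant$pending_diuresis + patient$furo$gain * furosemide
  drained <- pending * (1 - exp(-patient$furo$onset * dt))
  pending <- pending - drained
  V <- plant$V_current + patient$dextran_fraction * dextran_rate * dt - drained
  if (V <= 0) stop("simulation fault: stressed volume depleted")

  pd <- patient$pd
  S_L <- patient$params$S_L * (1 - pd$Emax_SL * C / (C + pd$EC50_SL))
  HR <- patient$HR_base * (1 - pd$Emax_HR * C / (C + pd$EC50_HR))

  true <- tryCatch(
    solve_equilibrium(eq_params(S_L = S_L, S_R = patient$params$S_R,
                                R = patient$params$R, V = V),
                      patient$constants),
    error = function(e) stop(sprintf("simulation fault: %s", conditionMessage(e)),
                             call. = FALSE))
  true$HR <- HR

  measured <- true
  if (noise) {
    sd <- patient$noise_sd
    measured$AP <- true$AP + stats::rnorm(1, 0, sd$AP)
    measured$CO <- max(true$CO + stats::rnorm(1, 0, sd$CO), 0)
    measured$P_LA <- true$P_LA + stats::rnorm(1, 0, sd$P_LA)
    measured$P_RA <- true$P_RA + stats::rnorm(1, 0, sd$P_RA)
    measured$HR <- true$HR + stats::rnorm(1, 0, sd$HR)
  }
  list(plant = list(C = C, V_current = V, pending_diuresis = pending,
                    S_L_current = S_L, HR_current = HR),
       true = true, measured = measured)
}
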