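#' Default run configuration
#'
#' A fully serializable nested list describing one closed-loop run: model
#' constants, virtual-patient definition (baseline hemodynamics, landiolol
#' PK/PD, volume handling, measurement noise), controller settings, and the
#' control protocol.  All defaults together constitute the shipped
#' heart-failure scenario; every entry can be overridden and round-trips
#' losslessly through [write_config()] / [read_config()].
#'
#' Units: pressures mmHg, flows ml min^-1 kg^-1, volumes ml kg^-1, landiolol
#' rates ug min^-1 kg^-1, landiolol concentration ug ml^-1, furosemide mg,
#' times min.
#'
#' @return A nested list of class \code{"cvloop_config"}.
#' @export
default_config <- function() {
  structure(list(
    constants = list(P0_L = 2.03, k_L = 0.80, P0_R = 2.13, k_R = 1.90,
                     W = 0.129, G_L = 0.22, G_R = 0.64),
    patient = list(
      baseline = list(AP = 87, P_LA = 17, P_RA = 9.1, CO = 118, HR = 129),
      pk = list(k_e = log(2) / 4, Vd = 300),
      pd = list(Emax_SL = 0.4, EC50_SL = 1.5, Emax_HR = 0.5, EC50_HR = 0.8),
      dextran_fraction = 1,
      furo = list(gain = 0.3, onset = 0.35),
      noise_sd = list(AP = 1, P_LA = 0.5, P_RA = 0.5, CO = 3, HR = 1),
      ensemble_cv = 0.05),
    controller = list(
      pi = list(Kp = 4, Ki = 1.4, u_max = 100),
      volume = list(dead_band = 0.8, dead_band_deficit = 0.1,
                    dextran_gain = 0.3, dextran_max = 1,
                    furosemide_bolus = 5, furosemide_lockout = 6,
                    bolus_effect = 1.5, effect_onset = 0.35)),
    protocol = list(duration = 60, dt = 1 / 6,
                    smoothing_window = 1, baseline_window = 10,
                    ap_drop = 10, ap_floor = 70, pla_cap = 18,
                    recompute_targets = FALSE)),
    class = "cvloop_config")
}

# Recursively overlay user values onto defaults so partial configs are valid.
.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a run configuration from JSON
#'
#' Entries absent from the file keep their [default_config()] values.
#'
#' @param path Path to a JSON file.
#' @return A \code{"cvloop_config"} list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- .merge_config(unclass(default_config()), user)
  structure(cfg, class = "cvloop_config")
}

#' Write a run configuration to JSON
#'
#' @param config A \code{"cvloop_config"} list.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  # digits = I(17): doubles survive the JSON round trip bit-exactly
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

# Stable content hash of a configuration (md5 of its canonical JSON).
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = I(17))
  unname(tools::md5sum(tmp))
}
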