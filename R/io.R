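#' Write a run time-series table (with metadata sidecar)
#'
#' The table is plain comma-separated text with a header row, '.' decimal,
#' UTF-8, one row per control step.  A JSON sidecar \code{<path>.meta.json}
#' records the resolved configuration, its hash, the seed, the targets and
#' the package version, so any table can be re-scored later.
#'
#' @param run A \code{"cvloop_run"}.
#' @param path Output CSV path.
#' @param sidecar Write the metadata sidecar?
#' @return \code{path}, invisibly.
#' @export
write_run <- function(run, path, sidecar = TRUE) {
  utils::write.csv(as.data.frame(run), path, row.names = FALSE)
  if (sidecar) {
    tg <- run_targets(run)
    meta <- list(
      config = unclass(attr(run, "config")),
      config_hash = attr(run, "config_hash"),
      seed = attr(run, "seed"),
      noise = attr(run, "noise"),
      targets = unclass(tg),
      package_version = as.character(utils::packageVersion("cvloop")))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  invisible(path)
}

#' Read a hemodynamic time-series table
#'
#' Expects a delimited text table with at least the columns \code{t, AP, CO,
#' P_LA, P_RA} (a \code{HR} column and any extra columns are tolerated).
#'
#' @param path CSV path.
#' @param require_cols Columns that must be present.
#' @return A data frame.
#' @export
read_run_table <- function(path,
                           require_cols = c("t", "AP", "CO", "P_LA", "P_RA")) {
  if (!file.exists(path)) stop(sprintf("table not found: %s", path))
  df <- utils::read.csv(path)
  missing <- setdiff(require_cols, names(df))
  if (length(missing))
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  df
}

#' Row-wise parameter estimation over a recorded table
#'
#' Applies [estimate_parameters()] to every row of a hemodynamic time-series
#' table and appends the parameter estimates as columns.  Rows violating the
#' model domain (e.g. atrial pressure at or below the curve offset) are kept
#' and flagged, with \code{NA} estimates and the failure reason in
#' \code{flag}.
#'
#' @param table Data frame with columns t, AP, CO, P_LA, P_RA.
#' @param constants A [model_constants()] object.
#' @return The input with extra columns \code{S_L_hat, S_R_hat, R_hat,
#'   V_hat, flag}.
#' @export
estimate_table <- function(table, constants = model_constants()) {
  n <- nrow(table)
  est <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("S_L_hat", "S_R_hat", "R_hat", "V_hat")))
  flag <- character(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      estimate_parameters(list(AP = table$AP[i], CO = table$CO[i],
                               P_LA = table$P_LA[i], P_RA = table$P_RA[i]),
                          constants),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      flag[i] <- res
    } else {
      est[i, ] <- c(res$S_L, res$S_R, res$R, res$V)
    }
  }
  cbind(table, as.data.frame(est), flag = flag)
}

#' Generate the canned test fixtures
#'
#' Writes small deterministic inputs exercised by the test suite and useful
#' as worked examples: a hand-computable PE series whose absolute error falls
#' on the line |PE| = 10 - 0.1 t, a five-row hemodynamic state table generated
#' from known equilibrium parameters, a miniature (3 min) closed-loop run,
#' and the default configuration.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir = ".", seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  # PE worked-example series: value/target chosen so |PE| = 10 - 0.1 t.
  t <- 1:5
  abs_pe <- 10 - 0.1 * t
  target <- 80
  value <- target / (1 - abs_pe / 100)   # inverts PE = (v - T)/v * 100
  pe_path <- file.path(dir, "pe_series.csv")
  utils::write.csv(data.frame(t = t, value = value, target = target,
                              pe = performance_error(value, target)),
                   pe_path, row.names = FALSE)
  files <- c(files, pe_path)

  # Five states on the model manifold from randomized valid parameters.
  set.seed(seed)
  mc <- model_constants()
  rows <- lapply(1:5, function(i) {
    p <- eq_params(S_L = stats::runif(1, 20, 45), S_R = stats::runif(1, 20, 45),
                   R = stats::runif(1, 0.4, 1), V = stats::runif(1, 20, 30))
    s <- solve_equilibrium(p, mc)
    data.frame(t = i - 1, AP = s$AP, CO = s$CO, P_LA = s$P_LA, P_RA = s$P_RA,
               S_L = p$S_L, S_R = p$S_R, R = p$R, V = p$V)
  })
  st_path <- file.path(dir, "states.csv")
  utils::write.csv(do.call(rbind, rows), st_path, row.names = FALSE)
  files <- c(files, st_path)

  # Miniature closed-loop run.
  mini <- run_closed_loop(default_config(), seed = seed, duration = 3)
  mini_path <- file.path(dir, "mini_run.csv")
  write_run(mini, mini_path, sidecar = TRUE)
  files <- c(files, mini_path, paste0(mini_path, ".meta.json"))

  cfg_path <- file.path(dir, "config.json")
  write_config(default_config(), cfg_path)
  files <- c(files, cfg_path)
  invisible(files)
}
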