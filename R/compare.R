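#' Full pairwise-vs-calibration comparison workflow
#'
#' Runs the complete analysis on one plate: per-set efficiencies by
#' both methods, the Monte-Carlo precision comparison (both arms drawn
#' with the same seed, hence on identical samplings), the maximal
#' replicate-ratio error analysis, and the dilution-ratio accuracy
#' table. Optionally writes the report tables as CSV plus a run
#' metadata file; two runs with identical inputs and config produce
#' byte-identical reports.
#'
#' @param plate A [qpcr_plate()] with fluorescence (and, if available,
#'   Cq) data.
#' @param window RFU window `c(lower, upper)`.
#' @param cq Optional `well`,`cq` tibble; if neither this nor
#'   `plate$cq` exists, Cqs are called from the fluorescence at
#'   `cq_threshold`.
#' @param cq_threshold RFU threshold for [call_cq()] when no Cq values
#'   are supplied.
#' @param n_samplings,n_per_sampling,seed Monte-Carlo settings.
#' @param outlier_removal Apply the frequency-based outlier rule in the
#'   pairwise arm.
#' @param out_dir Optional directory to write `efficiencies.csv`,
#'   `precision.csv`, `accuracy_groups.csv`, `max_error.csv` and
#'   `run_metadata.json` into (created if missing).
#' @return A `qpcr_comparison` list: `efficiencies` (per set, both
#'   methods), `precision` (Monte-Carlo comparison, one row per
#'   method), `accuracy` (an `accuracy_table`), `max_error`, `config`.
#' @export
#' @examples
#' plate <- simulate_plate(seed = 1)
#' cmp <- run_full_comparison(plate, cq_threshold = 31.07, seed = 1)
#' cmp$precision
run_full_comparison <- function(plate, window = c(20, 180), cq = NULL,
                                cq_threshold = 31.07, n_samplings = 100,
                                n_per_sampling = 3, seed = 1,
                                outlier_removal = TRUE, out_dir = NULL) {
  stopifnot(inherits(plate, "qpcr_plate"))
  cq <- cq %||% plate$cq %||% call_cq(plate, cq_threshold)

  pw <- suppressWarnings(
    plate_efficiencies(plate, window = window,
                       outlier_removal = outlier_removal)
  )
  cal <- calibrate_plate(plate, cq = cq)
  eff <- left_join(
    select(pw, "set_id", e_pairwise = "e", e_pairwise_raw = "e_raw",
           "n_total", "n_retained", "skew", "kurtosis_excess"),
    select(cal, "set_id", e_calibration = "e", "slope", "r_squared"),
    by = "set_id"
  )

  mc_pw <- monte_carlo_precision(pw, n_per_sampling = n_per_sampling,
                                 n_samplings = n_samplings, seed = seed,
                                 method = "pairwise")
  mc_cal <- monte_carlo_precision(cal, n_per_sampling = n_per_sampling,
                                  n_samplings = n_samplings, seed = seed,
                                  method = "calibration")
  precision <- bind_rows(glance(mc_cal), glance(mc_pw))

  max_err <- bind_rows(
    max_error_analysis(plate, e = max(cal$e), method = "pfaffl_cq",
                       window = window, cq = cq),
    max_error_analysis(plate, e = max(pw$e), method = "f0_based",
                       window = window, cq = cq)
  )

  accuracy <- dilution_accuracy_table(plate, window = window, cq = cq,
                                      outlier_removal = outlier_removal)

  config <- list(window = window, cq_threshold = cq_threshold,
                 n_samplings = n_samplings, n_per_sampling = n_per_sampling,
                 seed = seed, outlier_removal = outlier_removal,
                 base = plate$base)
  out <- structure(
    list(efficiencies = eff, precision = precision, accuracy = accuracy,
         max_error = max_err, mc = list(pairwise = mc_pw, calibration = mc_cal),
         config = config),
    class = "qpcr_comparison"
  )
  if (!is.null(out_dir)) write_comparison(out, out_dir)
  out
}

#' @export
print.qpcr_comparison <- function(x, ...) {
  cat("<qpcr_comparison> ", nrow(x$efficiencies), " dilution sets\n", sep = "")
  cat("\nMonte-Carlo precision (", x$config$n_samplings, " samplings of ",
      x$config$n_per_sampling, "):\n", sep = "")
  print(x$precision)
  cat("\nMaximal replicate-ratio error:\n")
  print(x$max_error)
  cat("\nDilution-ratio accuracy: |error| F0-based ",
      signif(x$accuracy$avg_error_f0_pct, 3), "%, Cq-based ",
      signif(x$accuracy$avg_error_cq_pct, 3), "%\n", sep = "")
  invisible(x)
}

write_comparison <- function(cmp, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(cmp$efficiencies, file.path(out_dir, "efficiencies.csv"))
  readr::write_csv(cmp$precision, file.path(out_dir, "precision.csv"))
  readr::write_csv(cmp$accuracy$groups, file.path(out_dir, "accuracy_groups.csv"))
  readr::write_csv(cmp$max_error, file.path(out_dir, "max_error.csv"))
  meta <- c(cmp$config,
            list(package = "pairqpcr",
                 version = as.character(utils::packageVersion("pairqpcr")),
                 r_version = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
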