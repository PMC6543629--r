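#' Monte-Carlo precision of replicate efficiency estimates
#'
#' The resampling harness used to compare estimators: from the pool of
#' per-set efficiency estimates (one per replicate dilution set), each
#' "sampling" draws `n_per_sampling` distinct sets uniformly without
#' replacement -- mirroring the wet-lab practice of running a
#' calibration in triplicate -- and records the mean of the drawn
#' estimates. Samplings are independent of one another (sets can recur
#' across samplings). Precision is the sample standard deviation (n-1
#' denominator) of the sampling means; the max, min, range and mean
#' over sampling means are reported alongside.
#'
#' @param estimates A data frame with columns `set_id` and an
#'   efficiency column (default `e`), e.g. from [plate_efficiencies()]
#'   or [calibrate_plate()]; or a plain numeric vector of per-set
#'   estimates.
#' @param n_per_sampling Sets per sampling (default 3).
#' @param n_samplings Number of samplings (default 100).
#' @param seed Integer seed; identical inputs and seed give a
#'   bit-identical result.
#' @param method Optional tag recorded in the result (e.g. "pairwise",
#'   "calibration").
#' @param e_col Name of the efficiency column when `estimates` is a
#'   data frame.
#' @return An `mc_result`: `sampling_means`, `sd`, `e_max`, `e_min`,
#'   `range`, `mean`, plus the settings. `glance()` gives the one-row
#'   comparison-table shape.
#' @export
#' @examples
#' e <- c(0.79, 0.82, 0.80, 0.78, 0.81, 0.83, 0.80, 0.79)
#' monte_carlo_precision(e, seed = 1)
monte_carlo_precision <- function(estimates, n_per_sampling = 3,
                                  n_samplings = 100, seed = NULL,
                                  method = NULL, e_col = "e") {
  if (is.data.frame(estimates)) {
    if (!e_col %in% names(estimates)) {
      abort(paste0("`estimates` has no column `", e_col, "`."))
    }
    e <- estimates[[e_col]]
  } else {
    e <- as.numeric(estimates)
  }
  if (anyNA(e)) abort("Missing efficiency estimates.")
  n <- length(e)
  if (n_per_sampling < 1 || n_per_sampling > n) {
    abort("`n_per_sampling` must be between 1 and the number of sets.")
  }
  if (n_samplings < 2) abort("`n_samplings` must be at least 2.")
  if (!is.null(seed)) local_seed_scoped(seed)
  means <- vapply(seq_len(n_samplings), function(k) {
    mean(e[sample.int(n, n_per_sampling)])
  }, numeric(1))
  structure(
    list(sampling_means = means, sd = sd(means), e_max = max(means),
         e_min = min(means), range = max(means) - min(means),
         mean = mean(means), method = method %||% NA_character_,
         seed = seed %||% NA_integer_, n_sets = n,
         n_per_sampling = n_per_sampling, n_samplings = n_samplings),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat("<mc_result>", if (!is.na(x$method)) paste0(" [", x$method, "]"),
      " ", x$n_samplings, " samplings of ", x$n_per_sampling, " from ",
      x$n_sets, " sets\n", sep = "")
  cat("  SD = ", signif(x$sd, 4), ", mean E = ", signif(x$mean, 4),
      ", range ", signif(x$e_min, 4), "-", signif(x$e_max, 4),
      " (", signif(x$range, 4), ")\n", sep = "")
  invisible(x)
}

#' @rdname monte_carlo_precision
#' @param x An `mc_result`.
#' @param ... Unused.
#' @export
glance.mc_result <- function(x, ...) {
  tibble(method = x$method, sd = x$sd, e_max = x$e_max, e_min = x$e_min,
         range = x$range, mean = x$mean, n_sets = x$n_sets,
         n_per_sampling = x$n_per_sampling, n_samplings = x$n_samplings)
}

#' @rdname monte_carlo_precision
#' @export
tidy.mc_result <- function(x, ...) {
  tibble(sampling = seq_along(x$sampling_means), mean_e = x$sampling_means)
}
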