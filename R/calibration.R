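#' Classical calibration-curve efficiency
#'
#' The standard-curve baseline: ordinary least squares of Cq on
#' log10(concentration) across a dilution set, with efficiency
#' \deqn{E = 10^{-1/slope} - 1.}
#' The regression is always on the decimal log with the 10-based
#' formula regardless of the dilution base -- fitting on
#' \eqn{\log_b} with \eqn{E = b^{-1/slope_b} - 1} is the identical
#' quantity by change of base. When no concentrations are given they
#' derive from the dilution step as \eqn{b^{-D}} (arbitrary units;
#' rescaling all concentrations changes only the intercept, never the
#' slope or E).
#'
#' @param data Data frame with a `cq` column and either a
#'   `concentration` or a `dilution_step` column.
#' @param base Dilution base b used when concentrations derive from
#'   dilution steps.
#' @return A `calibration_fit` object wrapping the `lm` fit, with
#'   elements `slope`, `intercept`, `r_squared`, `efficiency`, `n`.
#'   `glance()` returns the one-row summary, `tidy()` the coefficient
#'   table.
#' @export
#' @examples
#' d <- tibble::tibble(dilution_step = 0:5,
#'                     cq = 15 + (0:5) / log2(1.8))
#' calibration_efficiency(d)  # recovers E = 0.8
calibration_efficiency <- function(data, base = 2) {
  data <- as_tibble(data)
  if (!"cq" %in% names(data)) abort("`data` needs a cq column.")
  conc <- data[["concentration"]]
  if (is.null(conc) || all(is.na(conc))) {
    if (!"dilution_step" %in% names(data)) {
      abort("`data` needs concentration or dilution_step.")
    }
    conc <- base^(-data$dilution_step)
  }
  keep <- !is.na(conc) & !is.na(data$cq)
  d <- tibble(cq = data$cq[keep], log_conc = log10(conc[keep]))
  if (dplyr::n_distinct(d$log_conc) < 2L) {
    abort("Need at least 2 distinct concentrations with Cq values.")
  }
  fit <- lm(cq ~ log_conc, data = d)
  slope <- unname(coef(fit)[2])
  if (slope == 0) abort("Zero slope: no dilution response.")
  # direct R^2: summary.lm() warns on the exact fits of noiseless data
  ss_tot <- sum((d$cq - mean(d$cq))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]),
         r_squared = r2,
         efficiency = 10^(-1 / slope) - 1,
         n = nrow(d), fit = fit),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit> E = ", signif(x$efficiency, 5),
      " (slope ", signif(x$slope, 5), ", R2 ", signif(x$r_squared, 4),
      ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @rdname calibration_efficiency
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         efficiency = x$efficiency, n = x$n)
}

#' @rdname calibration_efficiency
#' @export
tidy.calibration_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "log10_concentration"),
         estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' Calibration-curve efficiency for every dilution set
#'
#' @param plate A [qpcr_plate()]; Cq values are taken from the plate or
#'   supplied explicitly.
#' @param cq Optional tibble `well`, `cq` overriding `plate$cq`.
#' @return A tibble with one row per set: `set_id`, `slope`,
#'   `intercept`, `r_squared`, `e`, `n_wells`.
#' @export
calibrate_plate <- function(plate, cq = NULL) {
  stopifnot(inherits(plate, "qpcr_plate"))
  cq <- cq %||% plate$cq
  if (is.null(cq)) abort("No Cq values: supply `cq` or call call_cq() first.")
  cq <- validate_cq(cq)
  d <- inner_join(plate$layout, cq, by = "well")
  purrr::map_dfr(split(d, d$set_id), function(g) {
    fit <- calibration_efficiency(g, base = plate$base)
    tibble(set_id = g$set_id[1], slope = fit$slope, intercept = fit$intercept,
           r_squared = fit$r_squared, e = fit$efficiency, n_wells = fit$n)
  })
}
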