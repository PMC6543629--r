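#' Admit in-window readings of a dilution set
#'
#' Collects every fluorescence reading of the set's wells that lies
#' inside the exponential-phase window `[lower, upper]` (closed
#' interval). Each admitted reading carries its well, cycle and
#' dilution step; readings with non-positive RFU are inadmissible (a
#' logarithm is taken downstream), though a positive lower bound
#' normally excludes them anyway.
#'
#' @param plate A [qpcr_plate()] with fluorescence data.
#' @param set_id Which dilution set to use (a value of
#'   `plate$layout$set_id`); alternatively give `wells` directly.
#' @param window Numeric length-2, `c(lower, upper)` in RFU,
#'   `0 < lower < upper`.
#' @param wells Optional character vector of wells overriding `set_id`.
#' @return A tibble with columns `well`, `cycle`, `rfu`,
#'   `dilution_step`, carrying the window and set id as attributes.
#'   Errors with "empty window" if nothing is admitted.
#' @export
admit_readings <- function(plate, set_id = NULL, window = c(20, 180),
                           wells = NULL) {
  stopifnot(inherits(plate, "qpcr_plate"))
  if (is.null(plate$fluorescence)) abort("Plate has no fluorescence data.")
  check_window(window)
  if (is.null(wells)) {
    if (is.null(set_id)) abort("Give either `set_id` or `wells`.")
    wells <- plate$layout$well[plate$layout$set_id == set_id]
    if (!length(wells)) abort(paste0("Unknown set_id: ", set_id))
  }
  missing <- setdiff(wells, unique(plate$fluorescence$well))
  if (length(missing)) {
    abort(paste0("Wells without fluorescence series: ",
                 paste(missing, collapse = ", ")))
  }
  out <- filter(plate$fluorescence, .data$well %in% wells,
                .data$rfu >= window[1], .data$rfu <= window[2],
                .data$rfu > 0)
  out <- inner_join(out, plate$layout[c("well", "dilution_step")], by = "well")
  if (nrow(out) == 0L) abort("empty window: no readings admitted.")
  structure(out, set_id = set_id, window = window)
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 2L ||
      !(0 < window[1] && window[1] < window[2])) {
    abort("`window` must be c(lower, upper) with 0 < lower < upper.")
  }
  invisible(window)
}

#' Pairwise amplification efficiency of two readings
#'
#' For two fluorescence readings \eqn{F_i} (cycle i, dilution step
#' \eqn{D_1}) and \eqn{F_j} (cycle j, step \eqn{D_2}) of the same
#' dilution set, the efficiency implied by the classical kinetic model
#' is
#' \deqn{E_{i,j} = b^{\frac{\log_b F_j - \log_b F_i + (D_2 - D_1)}{j - i}} - 1.}
#' The value is orientation-invariant (swapping the two readings gives
#' the same E) and applies equally to same-curve pairs (\eqn{D_1 = D_2})
#' and cross-curve pairs. All arguments are vectorised.
#'
#' @param rfu_a,rfu_b Positive fluorescence readings.
#' @param cycle_a,cycle_b Cycle numbers (must differ pairwise).
#' @param step_a,step_b Dilution steps D of the two readings.
#' @param base Dilution base b.
#' @return Numeric vector of efficiencies (each > -1).
#' @export
#' @examples
#' pairwise_efficiency(100, 20, 0, 200, 21, 0) # exact doubling -> 1
pairwise_efficiency <- function(rfu_a, cycle_a, step_a, rfu_b, cycle_b, step_b,
                                base = 2) {
  if (any(cycle_a == cycle_b)) {
    abort("Readings on the same cycle cannot form a pair.")
  }
  if (any(rfu_a <= 0) || any(rfu_b <= 0)) {
    abort("Fluorescence readings must be positive.")
  }
  base^((log(rfu_b, base) - log(rfu_a, base) + (step_b - step_a)) /
          (cycle_b - cycle_a)) - 1
}

#' Enumerate all valid reading pairs of a dilution set
#'
#' Forms every unordered pair of admitted readings -- same-curve and
#' cross-curve alike -- excluding only pairs whose two readings fall on
#' the same cycle number, and computes the pairwise efficiency of each.
#' With n admitted readings of which \eqn{n_c} share cycle c, the
#' number of pairs is \eqn{\binom{n}{2} - \sum_c \binom{n_c}{2}}.
#'
#' @param readings A tibble as returned by [admit_readings()] (columns
#'   `well`, `cycle`, `rfu`, `dilution_step`).
#' @param base Dilution base b.
#' @param cross_well_only If `TRUE`, additionally drop same-well pairs
#'   (sensitivity analysis; the default keeps them).
#' @return A `pairwise_e_array`: a tibble with one row per pair
#'   (`value` plus the provenance of both readings), carrying `base`,
#'   `set_id` and `window` attributes.
#' @export
enumerate_pairs <- function(readings, base = 2, cross_well_only = FALSE) {
  readings <- as_tibble(readings)
  n <- nrow(readings)
  if (n < 2L) abort("Need at least 2 readings to form pairs.")
  idx <- combn(n, 2L)
  keep <- readings$cycle[idx[1, ]] != readings$cycle[idx[2, ]]
  if (cross_well_only) {
    keep <- keep & readings$well[idx[1, ]] != readings$well[idx[2, ]]
  }
  i <- idx[1, keep]; j <- idx[2, keep]
  if (!length(i)) {
    warn("No valid pairs (all readings share a cycle).")
    vals <- tibble(value = numeric(),
                   well_a = character(), cycle_a = integer(),
                   rfu_a = numeric(), step_a = integer(),
                   well_b = character(), cycle_b = integer(),
                   rfu_b = numeric(), step_b = integer())
  } else {
    vals <- tibble(
      value = pairwise_efficiency(readings$rfu[i], readings$cycle[i],
                                  readings$dilution_step[i],
                                  readings$rfu[j], readings$cycle[j],
                                  readings$dilution_step[j], base = base),
      well_a = readings$well[i], cycle_a = readings$cycle[i],
      rfu_a = readings$rfu[i], step_a = readings$dilution_step[i],
      well_b = readings$well[j], cycle_b = readings$cycle[j],
      rfu_b = readings$rfu[j], step_b = readings$dilution_step[j]
    )
  }
  structure(vals, base = base,
            set_id = attr(readings, "set_id", exact = TRUE),
            window = attr(readings, "window", exact = TRUE),
            class = c("pairwise_e_array", class(vals)))
}

#' Distribution diagnostics of a pairwise-efficiency array
#'
#' Computes the moment and histogram diagnostics used to judge
#' normality of the per-pair efficiency values: adjusted
#' Fisher--Pearson skewness and bias-corrected excess kurtosis (the
#' spreadsheet conventions, `e1071` type 2), a fixed-width histogram
#' anchored at 0 (half-open bins `[k w, (k+1) w)`), and a chi-square
#' goodness-of-fit test against a normal with the sample mean and sd.
#' The chi-square statistic sums over bins whose expected count reaches
#' `min_expected`, with df = (number of such bins) - 3; tail
#' probability mass beyond the outermost bins is folded into them. The
#' test requires at least 50 values; with fewer, the chi-square fields
#' are `NA` with a warning. The share of bins with small expected
#' counts is reported as an annotation, not a gate.
#'
#' @param x A `pairwise_e_array` or numeric vector of efficiencies.
#' @param bin_width Histogram interval length (default 0.05).
#' @param alpha Significance level for the normality decision.
#' @param min_expected Expected-count threshold for a bin to enter the
#'   chi-square sum (default 5).
#' @return A `distribution_stats` object; see [glance.distribution_stats()]
#'   for the one-row summary and [tidy.distribution_stats()] for the
#'   histogram.
#' @export
distribution_stats <- function(x, bin_width = 0.05, alpha = 0.05,
                               min_expected = 5) {
  values <- if (is.numeric(x)) x else x$value
  n <- length(values)
  if (n < 3L) abort("Need at least 3 values for distribution diagnostics.")
  skew <- e1071::skewness(values, type = 2)
  kurt <- e1071::kurtosis(values, type = 2)
  hist <- e_histogram(values, bin_width)
  m <- mean(values); s <- sd(values)
  chi2_stat <- chi2_df <- chi2_p <- NA_real_
  normal_rejected <- NA
  pct_expected_below <- NA_real_
  expected <- rep(NA_real_, nrow(hist))
  if (n >= 50L && s > 0) {
    p <- pnorm(hist$upper, m, s) - pnorm(hist$lower, m, s)
    p[1] <- p[1] + pnorm(hist$lower[1], m, s)
    p[length(p)] <- p[length(p)] + pnorm(hist$upper[length(p)], m, s,
                                         lower.tail = FALSE)
    expected <- n * p
    keep <- expected >= min_expected
    pct_expected_below <- 100 * mean(!keep)
    if (sum(keep) > 3L) {
      chi2_stat <- sum((hist$count[keep] - expected[keep])^2 / expected[keep])
      chi2_df <- sum(keep) - 3L
      chi2_p <- pchisq(chi2_stat, chi2_df, lower.tail = FALSE)
      normal_rejected <- chi2_p < alpha
    } else {
      warn("Too few well-populated bins for the chi-square test.")
    }
  } else if (n < 50L) {
    warn("Fewer than 50 values: chi-square goodness-of-fit not computed.")
  }
  hist$expected <- expected
  structure(
    list(n = n, mean = m, sd = s, skew = skew, kurtosis_excess = kurt,
         bin_width = bin_width, histogram = hist, chi2_stat = chi2_stat,
         chi2_df = chi2_df, chi2_p = chi2_p, normal_rejected = normal_rejected,
         pct_expected_below = pct_expected_below, alpha = alpha,
         min_expected = min_expected),
    class = "distribution_stats"
  )
}

# half-open histogram [k*w, (k+1)*w) anchored at 0
e_histogram <- function(values, bin_width) {
  lo <- floor(min(values) / bin_width)
  hi <- floor(max(values) / bin_width) + 1L
  breaks <- (lo:hi) * bin_width
  counts <- tabulate(findInterval(values, breaks), nbins = length(breaks) - 1L)
  tibble(lower = breaks[-length(breaks)], upper = breaks[-1], count = counts)
}

#' @export
print.distribution_stats <- function(x, ...) {
  cat("<distribution_stats> n = ", x$n,
      ", skew = ", signif(x$skew, 4),
      ", excess kurtosis = ", signif(x$kurtosis_excess, 4), "\n", sep = "")
  if (!is.na(x$chi2_stat)) {
    cat("  chi-square vs normal: X2 = ", signif(x$chi2_stat, 4),
        ", df = ", x$chi2_df, ", p = ", format.pval(x$chi2_p),
        if (isTRUE(x$normal_rejected)) "  (normality rejected)", "\n", sep = "")
  }
  invisible(x)
}

#' @rdname distribution_stats
#' @param ... Unused.
#' @export
glance.distribution_stats <- function(x, ...) {
  tibble(n = x$n, mean = x$mean, sd = x$sd, skew = x$skew,
         kurtosis_excess = x$kurtosis_excess, chi2_stat = x$chi2_stat,
         chi2_df = x$chi2_df, chi2_p = x$chi2_p,
         normal_rejected = x$normal_rejected,
         pct_expected_below = x$pct_expected_below)
}

#' @rdname distribution_stats
#' @export
tidy.distribution_stats <- function(x, ...) x$histogram

#' Frequency-based outlier exclusion and set-level efficiency
#'
#' Applies the histogram-frequency rule: starting from the modal bin of
#' the 0.05-wide efficiency histogram and scanning outward, the first
#' bin below the mode whose count falls under `min_count` sets the low
#' cutoff at that bin's upper edge, and the first such bin above the
#' mode sets the high cutoff at its lower edge. Values beyond the
#' cutoffs are excluded as statistically unreliable and the set-level
#' efficiency is the arithmetic mean of the retained values. If every
#' bin is sparse the distribution is left untouched with a warning.
#'
#' @param array A `pairwise_e_array` from [enumerate_pairs()].
#' @param stats Optional precomputed [distribution_stats()] (must use
#'   the same values and bin width); computed if missing.
#' @param min_count Frequency threshold below which a bin is considered
#'   unreliable (default 5).
#' @return An `efficiency_estimate` object; see [tidy.efficiency_estimate()].
#' @export
exclude_outliers <- function(array, stats = NULL, min_count = 5) {
  values <- array$value
  if (is.null(stats)) {
    stats <- suppressWarnings(distribution_stats(array))
  }
  hist <- stats$histogram
  low_cut <- high_cut <- NA_real_
  if (max(hist$count) < min_count) {
    warn("distribution too sparse: every bin below the frequency threshold; no exclusion.")
  } else {
    modal <- which.max(hist$count)
    below <- rev(seq_len(modal - 1L))
    first_low <- below[hist$count[below] < min_count][1]
    if (!is.na(first_low)) low_cut <- hist$upper[first_low]
    above <- seq_len(nrow(hist))[-seq_len(modal)]
    first_high <- above[hist$count[above] < min_count][1]
    if (!is.na(first_high)) high_cut <- hist$lower[first_high]
  }
  keep <- rep(TRUE, length(values))
  if (!is.na(low_cut)) keep <- keep & values >= low_cut
  if (!is.na(high_cut)) keep <- keep & values <= high_cut
  new_efficiency_estimate(
    e = mean(values[keep]), e_raw = mean(values), method = "pairwise",
    set_id = attr(array, "set_id", exact = TRUE),
    window = attr(array, "window", exact = TRUE),
    base = attr(array, "base", exact = TRUE),
    n_total = length(values), n_retained = sum(keep),
    excluded_low_cutoff = low_cut, excluded_high_cutoff = high_cut,
    stats = stats
  )
}

new_efficiency_estimate <- function(e, e_raw, method, set_id, window, base,
                                    n_total, n_retained,
                                    excluded_low_cutoff = NA_real_,
                                    excluded_high_cutoff = NA_real_,
                                    stats = NULL) {
  structure(
    list(e = e, e_raw = e_raw, method = method,
         set_id = set_id %||% NA_character_, window = window, base = base,
         n_total = n_total, n_retained = n_retained,
         excluded_low_cutoff = excluded_low_cutoff,
         excluded_high_cutoff = excluded_high_cutoff, stats = stats),
    class = "efficiency_estimate"
  )
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat("<efficiency_estimate> ", x$method,
      if (!is.na(x$set_id)) paste0(", set ", x$set_id), "\n", sep = "")
  cat("  E = ", signif(x$e, 5),
      if (x$n_retained < x$n_total)
        paste0(" (raw ", signif(x$e_raw, 5), "; ",
               x$n_total - x$n_retained, " of ", x$n_total, " pairs excluded)")
      else paste0(" from ", x$n_total, " pairs"),
      "\n", sep = "")
  invisible(x)
}

#' Tidy an efficiency estimate
#'
#' @param x An `efficiency_estimate`.
#' @param ... Unused.
#' @return One-row tibble with the estimate, the pre-exclusion mean,
#'   pair counts, exclusion cutoffs, and (when available) the
#'   distribution moments.
#' @export
tidy.efficiency_estimate <- function(x, ...) {
  tibble(
    set_id = x$set_id, method = x$method, e = x$e, e_raw = x$e_raw,
    n_total = x$n_total, n_retained = x$n_retained,
    cutoff_low = x$excluded_low_cutoff, cutoff_high = x$excluded_high_cutoff,
    skew = if (!is.null(x$stats)) x$stats$skew else NA_real_,
    kurtosis_excess = if (!is.null(x$stats)) x$stats$kurtosis_excess else NA_real_
  )
}

#' @rdname tidy.efficiency_estimate
#' @export
glance.efficiency_estimate <- function(x, ...) tidy(x)

#' Set-level pairwise efficiency
#'
#' The full pairwise pipeline for one dilution set: admit in-window
#' readings, enumerate all valid pairs, run distribution diagnostics,
#' and (optionally) exclude low-frequency outliers before averaging.
#'
#' @inheritParams admit_readings
#' @inheritParams enumerate_pairs
#' @inheritParams exclude_outliers
#' @param outlier_removal Apply the frequency rule (default `TRUE`).
#'   Exclusion needs at least 50 pairs; below that the raw mean is
#'   returned with a warning.
#' @param bin_width Histogram interval length for the diagnostics.
#' @return An `efficiency_estimate`.
#' @export
#' @examples
#' plate <- simulate_plate(n_sets = 1, noise_sd = 0, seed = 1)
#' set_efficiency(plate, plate$layout$set_id[1], window = c(20, 180))
set_efficiency <- function(plate, set_id, window = c(20, 180),
                           outlier_removal = TRUE, cross_well_only = FALSE,
                           bin_width = 0.05, min_count = 5) {
  readings <- admit_readings(plate, set_id = set_id, window = window)
  array <- enumerate_pairs(readings, base = plate$base,
                           cross_well_only = cross_well_only)
  n <- nrow(array)
  if (n < 2L) abort("Too few pairs to estimate an efficiency.")
  stats <- suppressWarnings(distribution_stats(array, bin_width = bin_width))
  if (outlier_removal && n >= 50L) {
    exclude_outliers(array, stats, min_count = min_count)
  } else {
    if (outlier_removal && n < 50L) {
      warn("Fewer than 50 pairs: outlier exclusion skipped.")
    }
    new_efficiency_estimate(
      e = mean(array$value), e_raw = mean(array$value), method = "pairwise",
      set_id = set_id, window = window, base = plate$base,
      n_total = n, n_retained = n, stats = stats
    )
  }
}

#' Pairwise efficiencies for every dilution set of a plate
#'
#' @inheritParams set_efficiency
#' @param plate A [qpcr_plate()] with fluorescence data.
#' @return A tibble with one row per set (columns of
#'   [tidy.efficiency_estimate()]).
#' @export
plate_efficiencies <- function(plate, window = c(20, 180),
                               outlier_removal = TRUE,
                               cross_well_only = FALSE,
                               bin_width = 0.05, min_count = 5) {
  sets <- unique(plate$layout$set_id)
  purrr::map_dfr(sets, function(s) {
    tidy(set_efficiency(plate, s, window = window,
                        outlier_removal = outlier_removal,
                        cross_well_only = cross_well_only,
                        bin_width = bin_width, min_count = min_count))
  })
}
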