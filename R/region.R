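#' Early-cycle noise profile of a plate
#'
#' Pools the fluorescence readings of the given cycles across all wells
#' to characterise the instrument's reading noise: before any signal is
#' detectable the readings scatter around zero (negative values
#' included), and their span tells where a safe lower window boundary
#' lies.
#'
#' @param plate A [qpcr_plate()] with fluorescence data.
#' @param cycles Integer cycle range to pool (default `1:10`).
#' @param bin_width Histogram bin width in RFU (default 1).
#' @return A `noise_profile` object: pooled values, min/max/mean/sd and
#'   a histogram. `glance()` gives the one-row summary, `tidy()` the
#'   histogram.
#' @export
noise_profile <- function(plate, cycles = 1:10, bin_width = 1) {
  stopifnot(inherits(plate, "qpcr_plate"))
  if (is.null(plate$fluorescence)) abort("Plate has no fluorescence data.")
  if (length(cycles) == 0L) abort("Empty cycle range.")
  max_cycle <- max(plate$fluorescence$cycle)
  if (any(cycles < 1L) || any(cycles > max_cycle)) {
    abort(paste0("Cycle range must lie within 1..", max_cycle, "."))
  }
  values <- plate$fluorescence$rfu[plate$fluorescence$cycle %in% cycles]
  hist <- e_histogram(values, bin_width)
  structure(
    list(values = values, n = length(values), min = min(values),
         max = max(values), mean = mean(values), sd = sd(values),
         cycles = cycles, histogram = hist),
    class = "noise_profile"
  )
}

#' @export
print.noise_profile <- function(x, ...) {
  cat("<noise_profile> cycles ", min(x$cycles), "-", max(x$cycles), ": ",
      x$n, " readings, range [", signif(x$min, 4), ", ", signif(x$max, 4),
      "] RFU, sd ", signif(x$sd, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname noise_profile
#' @param x A `noise_profile`.
#' @param ... Unused.
#' @export
glance.noise_profile <- function(x, ...) {
  tibble(n = x$n, min = x$min, max = x$max, mean = x$mean, sd = x$sd,
         first_cycle = min(x$cycles), last_cycle = max(x$cycles))
}

#' @rdname noise_profile
#' @export
tidy.noise_profile <- function(x, ...) x$histogram

#' First-outlier takeoff detection
#'
#' Finds the first cycle whose reading rises significantly above the
#' background trend, used to place a tentative lower boundary on the
#' exponential region. For each candidate cycle c an ordinary linear
#' trend is fitted to cycles 1..(c-1) and the studentized prediction
#' residual of reading c is compared with the one-sided t quantile at
#' `alpha`. To keep the per-series false-detection rate low across the
#' many sequential looks, a flag must be confirmed: the next cycle's
#' residual against the same background fit must also exceed the
#' quantile (amplification, unlike a noise spike, is sustained). Set
#' `confirm = FALSE` for the single-look rule.
#'
#' @param rfu Numeric vector of per-cycle readings (cycle 1 first), at
#'   least 8 cycles.
#' @param alpha One-sided significance level (default 0.01).
#' @param min_background Minimum number of background cycles fitted
#'   before testing starts (default 4).
#' @param confirm Require the following cycle to confirm the flag
#'   (default `TRUE`).
#' @return The first flagged cycle, or `NA_integer_` when no
#'   amplification is detected.
#' @export
first_outlier_cycle <- function(rfu, alpha = 0.01, min_background = 4,
                                confirm = TRUE) {
  n <- length(rfu)
  if (n < 8L) abort("Need at least 8 cycles.")
  for (c in (min_background + 1L):n) {
    m <- c - 1L
    x <- seq_len(m); y <- rfu[x]
    t_c <- prediction_t(x, y, c, rfu[c])
    if (is.na(t_c)) next
    crit <- qt(1 - alpha, df = m - 2L)
    if (t_c > crit) {
      if (!confirm || c == n) return(c)
      t_next <- prediction_t(x, y, c + 1L, rfu[c + 1L])
      if (!is.na(t_next) && t_next > crit) return(c)
    }
  }
  NA_integer_
}

# studentized prediction residual of (x0, y0) against a linear fit on (x, y)
prediction_t <- function(x, y, x0, y0) {
  m <- length(x)
  if (m < 3L) return(NA_real_)
  xbar <- mean(x)
  sxx <- sum((x - xbar)^2)
  b1 <- sum((x - xbar) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * xbar
  res <- y - b0 - b1 * x
  s2 <- sum(res^2) / (m - 2L)
  if (s2 <= 0) return(NA_real_)
  se <- sqrt(s2 * (1 + 1 / m + (x0 - xbar)^2 / sxx))
  (y0 - (b0 + b1 * x0)) / se
}

#' First-outlier cycles for every well
#'
#' @param plate A [qpcr_plate()] with fluorescence data.
#' @inheritParams first_outlier_cycle
#' @return A tibble with columns `well`, `cycle` (NA when no
#'   amplification is detected) and `rfu` at that cycle.
#' @export
first_outlier_cycles <- function(plate, alpha = 0.01, min_background = 4,
                                 confirm = TRUE) {
  stopifnot(inherits(plate, "qpcr_plate"))
  purrr::map_dfr(split(plate$fluorescence, plate$fluorescence$well), function(d) {
    cyc <- first_outlier_cycle(d$rfu[order(d$cycle)], alpha = alpha,
                               min_background = min_background,
                               confirm = confirm)
    tibble(well = d$well[1], cycle = cyc,
           rfu = if (is.na(cyc)) NA_real_ else d$rfu[order(d$cycle)][cyc])
  })
}

#' First Derivative Maximum (FDM)
#'
#' The cycle of steepest fluorescence increase, computed as the maximum
#' of the centered finite difference `(F(c+1) - F(c-1)) / 2` on the raw
#' readings (no smoothing); ties break to the earliest cycle. The
#' fluorescence at the FDM cycle bounds the exponential region from
#' above. The result is invariant to adding a constant to all readings.
#'
#' @param rfu Numeric vector of per-cycle readings, at least 3 cycles.
#' @return A list with elements `cycle`, `rfu` (reading at that cycle)
#'   and `derivative`.
#' @export
fdm_cycle <- function(rfu) {
  n <- length(rfu)
  if (n < 3L) abort("Need at least 3 cycles.")
  d <- (rfu[3:n] - rfu[1:(n - 2L)]) / 2
  c_star <- which.max(d) + 1L
  list(cycle = c_star, rfu = rfu[c_star], derivative = max(d))
}

#' FDM cycles for every well
#'
#' @param plate A [qpcr_plate()] with fluorescence data.
#' @return A tibble with columns `well`, `cycle`, `rfu`, `derivative`.
#' @export
fdm_cycles <- function(plate) {
  stopifnot(inherits(plate, "qpcr_plate"))
  purrr::map_dfr(split(plate$fluorescence, plate$fluorescence$well), function(d) {
    f <- fdm_cycle(d$rfu[order(d$cycle)])
    tibble(well = d$well[1], cycle = f$cycle, rfu = f$rfu,
           derivative = f$derivative)
  })
}

#' Per-cycle efficiency scan under a candidate initial fluorescence
#'
#' Under the classical model, a candidate initial fluorescence
#' \eqn{F_0} implies a per-cycle efficiency
#' \eqn{E(i) = b^{(\log_b F_i - \log_b F_0)/i} - 1} at every cycle with
#' a detected (positive, above `detect_threshold`) reading. If the
#' candidate is right and the reaction is still exponential, E(i) is
#' flat; saturation makes it decline; a wrong candidate makes it drift.
#' The stable span is the longest initial run of detected cycles whose
#' E standard deviation stays within `sd_tol`.
#'
#' @param rfu Numeric vector of per-cycle readings.
#' @param f0 Candidate initial fluorescence (> 0).
#' @param base Dilution base b (the log base of the model).
#' @param sd_tol Stability tolerance on the E standard deviation
#'   (default 0.01).
#' @param detect_threshold Readings at or below this are treated as
#'   undetected (default 0, i.e. any positive reading counts).
#' @return A `stable_region_scan` object: `e_values` (tibble `cycle`,
#'   `rfu`, `e`), `stable_span` (first and last cycle), `span_sd`.
#' @export
stable_region_scan <- function(rfu, f0, base = 2, sd_tol = 0.01,
                               detect_threshold = 0) {
  if (f0 <= 0) abort("`f0` must be positive.")
  cycles <- seq_along(rfu)
  det <- which(rfu > max(0, detect_threshold))
  if (!length(det)) abort("No detected (positive) readings.")
  e_all <- base^((log(rfu[det], base) - log(f0, base)) / cycles[det]) - 1
  ev <- tibble(cycle = cycles[det], rfu = rfu[det], e = e_all)
  # longest initial run of consecutive detected cycles within tolerance
  run_end <- 1L
  while (run_end < nrow(ev) &&
         ev$cycle[run_end + 1L] == ev$cycle[run_end] + 1L &&
         sd(ev$e[1:(run_end + 1L)]) <= sd_tol) {
    run_end <- run_end + 1L
  }
  span <- c(ev$cycle[1], ev$cycle[run_end])
  span_sd <- if (run_end > 1L) sd(ev$e[1:run_end]) else 0
  structure(
    list(e_values = ev, stable_span = span, span_sd = span_sd, f0 = f0,
         base = base, sd_tol = sd_tol),
    class = "stable_region_scan"
  )
}

#' @export
print.stable_region_scan <- function(x, ...) {
  cat("<stable_region_scan> f0 = ", signif(x$f0, 4), ": stable span cycles ",
      x$stable_span[1], "-", x$stable_span[2], " (sd ", signif(x$span_sd, 4),
      ")\n", sep = "")
  invisible(x)
}

#' @rdname stable_region_scan
#' @param x A `stable_region_scan`.
#' @param ... Unused.
#' @export
tidy.stable_region_scan <- function(x, ...) x$e_values

#' @rdname stable_region_scan
#' @export
glance.stable_region_scan <- function(x, ...) {
  tibble(f0 = x$f0, span_first = x$stable_span[1],
         span_last = x$stable_span[2], span_sd = x$span_sd)
}

#' Clamp a window's lower boundary above the noise band
#'
#' If a noise profile shows readings reaching beyond the proposed lower
#' boundary, the boundary is raised to the noise maximum (at least 10
#' RFU for noise spanning +/-10), with a warning -- data points inside
#' the noise band carry no reliable signal.
#'
#' @param window `c(lower, upper)` in RFU.
#' @param noise A [noise_profile()].
#' @return The (possibly clamped) window.
#' @export
clamp_window <- function(window, noise) {
  check_window(window)
  floor_rfu <- max(abs(noise$min), noise$max)
  if (window[1] < floor_rfu) {
    warn(paste0("Lower boundary ", window[1], " RFU is inside the noise band; ",
                "clamped to ", signif(floor_rfu, 4), " RFU."))
    window[1] <- floor_rfu
    check_window(window)
  }
  window
}

#' Grid search over candidate exponential-window boundaries
#'
#' Evaluates candidate `[lower, upper]` RFU windows by the Monte-Carlo
#' precision of the pairwise efficiency they produce: for each window,
#' every set's pairwise E is computed, then replicate sets are
#' resampled with [monte_carlo_precision()] and the SD over sampling
#' means is recorded. The same seed (hence the same samplings) is used
#' for every window so that windows are compared on identical draws. A
#' window leaving any set with fewer than 2 admitted readings is marked
#' infeasible rather than erroring.
#'
#' @param plate A [qpcr_plate()] with fluorescence data.
#' @param windows Data frame with columns `lower`, `upper` (one row per
#'   candidate window).
#' @param n_per_sampling,n_samplings,seed Passed to
#'   [monte_carlo_precision()].
#' @param outlier_removal Passed to [plate_efficiencies()].
#' @return A tibble with one row per window (`lower`, `upper`,
#'   `feasible`, `sd`, `mean_e`, `min_e`, `max_e`), feasible rows
#'   sorted by ascending SD.
#' @export
boundary_grid_search <- function(plate, windows, n_per_sampling = 3,
                                 n_samplings = 100, seed = NULL,
                                 outlier_removal = TRUE) {
  stopifnot(inherits(plate, "qpcr_plate"))
  windows <- as_tibble(windows)
  if (!all(c("lower", "upper") %in% names(windows))) {
    abort("`windows` needs columns lower, upper.")
  }
  n_sets <- dplyr::n_distinct(plate$layout$set_id)
  if (n_sets < 4L) abort("Need at least 4 replicate sets.")
  rows <- purrr::pmap_dfr(windows[c("lower", "upper")], function(lower, upper) {
    window <- c(lower, upper)
    check_window(window)
    est <- tryCatch(
      suppressWarnings(plate_efficiencies(plate, window = window,
                                          outlier_removal = outlier_removal)),
      error = function(e) NULL
    )
    if (is.null(est) || nrow(est) < n_sets || anyNA(est$e)) {
      return(tibble(lower = lower, upper = upper, feasible = FALSE,
                    sd = NA_real_, mean_e = NA_real_, min_e = NA_real_,
                    max_e = NA_real_))
    }
    mc <- monte_carlo_precision(est, n_per_sampling = n_per_sampling,
                                n_samplings = n_samplings, seed = seed,
                                method = "pairwise")
    tibble(lower = lower, upper = upper, feasible = TRUE, sd = mc$sd,
           mean_e = mc$mean, min_e = mc$e_min, max_e = mc$e_max)
  })
  arrange(rows, dplyr::desc(.data$feasible), .data$sd)
}
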