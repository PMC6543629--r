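#' Back-calculate initial fluorescence F0
#'
#' Under the classical model every in-window reading implies
#' \eqn{F_0 = F_i / (1+E)^i}; the per-well estimate is the arithmetic
#' mean over the well's in-window readings. F0 is the
#' fluorescence-equivalent of the starting template amount and scales
#' linearly with it, so ratios of F0 values are concentration ratios.
#'
#' @param plate A [qpcr_plate()] with fluorescence data.
#' @param e Amplification efficiency to invert with (> -1).
#' @param window `c(lower, upper)` RFU window whose readings are used.
#' @param wells Optional character vector restricting the wells; with
#'   the default (`NULL`, all wells) wells without in-window readings
#'   are dropped with a warning, whereas an explicitly requested well
#'   without in-window readings is an error.
#' @return A tibble with columns `well`, `f0`, `n_readings`,
#'   `dilution_step`.
#' @export
#' @examples
#' plate <- simulate_plate(n_sets = 1, noise_sd = 0, plateau = Inf, seed = 1)
#' estimate_f0(plate, e = 0.8)
estimate_f0 <- function(plate, e, window = c(20, 180), wells = NULL) {
  stopifnot(inherits(plate, "qpcr_plate"))
  if (is.null(plate$fluorescence)) abort("Plate has no fluorescence data.")
  if (!is.numeric(e) || length(e) != 1L || e <= -1) {
    abort("`e` must be a single number > -1.")
  }
  check_window(window)
  explicit <- !is.null(wells)
  wells <- wells %||% unique(plate$fluorescence$well)
  d <- filter(plate$fluorescence, .data$well %in% wells,
              .data$rfu >= window[1], .data$rfu <= window[2], .data$rfu > 0)
  out <- summarise(group_by(d, .data$well),
                   f0 = mean(.data$rfu / (1 + e)^.data$cycle),
                   n_readings = dplyr::n(), .groups = "drop")
  missing <- setdiff(wells, out$well)
  if (length(missing)) {
    msg <- paste0("Wells with no in-window reading: ",
                  paste(missing, collapse = ", "))
    if (explicit) abort(msg) else warn(msg)
  }
  left_join(out, plate$layout[c("well", "dilution_step")], by = "well")
}

#' Efficiency-corrected expression ratio from Cq values
#'
#' The classical efficiency-corrected ratio between a sample and a
#' control measured at the same threshold:
#' \deqn{ratio = (1+E)^{Cq_{control} - Cq_{sample}},}
#' where 1+E is the per-cycle amplification factor (E fractional, e.g.
#' 0.8). Reciprocity holds: swapping sample and control inverts the
#' ratio.
#'
#' @param e Amplification efficiency (> -1).
#' @param cq_sample,cq_control Quantification cycles (vectorised).
#' @return Numeric ratio(s).
#' @export
#' @examples
#' pfaffl_ratio(0.882, 20, 21) # one cycle earlier control -> 1.882
pfaffl_ratio <- function(e, cq_sample, cq_control) {
  if (any(e <= -1)) abort("`e` must be > -1.")
  (1 + e)^(cq_control - cq_sample)
}

#' Maximal replicate-to-replicate ratio error
#'
#' Replicate wells holding the same template amount should yield a
#' ratio of exactly 1 against each other; the spread actually observed
#' bounds the ratio error a user could incur. Two arms are computed on
#' a replicate group: the Cq-based arm takes the most extreme Cq pair
#' among the replicate wells through [pfaffl_ratio()] (error is
#' largest at the largest efficiency, so pass the maximal per-set E),
#' and the F0-based arm takes max(F0)/min(F0) over the same wells from
#' [estimate_f0()].
#'
#' @param plate A [qpcr_plate()].
#' @param e Efficiency used by both arms (typically the maximal per-set
#'   estimate of the respective method).
#' @param method `"both"`, `"pfaffl_cq"` or `"f0_based"`.
#' @param wells Replicate wells at identical template amount; default:
#'   the wells carrying the plate's maximal nominal concentration (or
#'   dilution step 0 when the layout has no concentrations).
#' @param window RFU window for the F0 arm.
#' @param cq Optional `well`,`cq` tibble for the Cq arm (default
#'   `plate$cq`).
#' @return A tibble with columns `method`, `ratio`, `error_pct`
#'   (`100 * (ratio - 1)`), `n_wells`.
#' @export
max_error_analysis <- function(plate, e,
                               method = c("both", "pfaffl_cq", "f0_based"),
                               wells = NULL, window = c(20, 180), cq = NULL) {
  stopifnot(inherits(plate, "qpcr_plate"))
  method <- match.arg(method)
  if (is.null(wells)) {
    lay <- plate$layout
    wells <- if (all(is.na(lay$concentration))) {
      lay$well[lay$dilution_step == 0L]
    } else {
      lay$well[!is.na(lay$concentration) &
                 lay$concentration == max(lay$concentration, na.rm = TRUE)]
    }
  }
  if (length(wells) < 2L) abort("Need at least 2 comparable replicate wells.")
  rows <- list()
  if (method %in% c("both", "pfaffl_cq")) {
    cq <- cq %||% plate$cq
    if (is.null(cq)) abort("Cq values required for the pfaffl_cq arm.")
    cq <- validate_cq(cq)
    v <- cq$cq[cq$well %in% wells]
    if (sum(!is.na(v)) < 2L) abort("Need at least 2 Cq values among the wells.")
    # worst pair among replicates: latest Cq as control, earliest as sample
    ratio <- pfaffl_ratio(e, cq_sample = min(v, na.rm = TRUE),
                          cq_control = max(v, na.rm = TRUE))
    rows <- c(rows, list(tibble(method = "pfaffl_cq", ratio = ratio,
                                error_pct = 100 * (ratio - 1),
                                n_wells = sum(!is.na(v)))))
  }
  if (method %in% c("both", "f0_based")) {
    f0 <- estimate_f0(plate, e = e, window = window, wells = wells)
    if (nrow(f0) < 2L) abort("Need at least 2 F0 estimates among the wells.")
    ratio <- max(f0$f0) / min(f0$f0)
    rows <- c(rows, list(tibble(method = "f0_based", ratio = ratio,
                                error_pct = 100 * (ratio - 1),
                                n_wells = nrow(f0))))
  }
  bind_rows(rows)
}

#' Dilution-ratio accuracy table
#'
#' Uses the known fold-dilutions between groups of replicate sets as an
#' external standard of accuracy. Sets are grouped by the nominal
#' concentration of their least-dilute (start) well; the group at the
#' highest concentration is the reference (expected fold 1). Per group
#' and per method:
#' * F0-based fold: mean F0 over the reference sets' start wells
#'   divided by the mean over the group's start wells, each well's F0
#'   back-calculated with its own set's pairwise efficiency;
#' * Cq-based fold: [pfaffl_ratio()] on the group-mean start-well Cqs
#'   with the group's mean calibration-curve efficiency.
#'
#' The per-group error is `100 * (observed - expected) / observed`, and
#' the per-method average error is the mean absolute error over the
#' non-reference groups.
#'
#' @param plate A [qpcr_plate()] whose layout carries concentrations
#'   spanning more than one start amount (e.g. the default
#'   [simulate_plate()] layout).
#' @param window RFU window for the pairwise and F0 computations.
#' @param cq Optional `well`,`cq` tibble (default `plate$cq`).
#' @param outlier_removal Passed to [set_efficiency()].
#' @return An `accuracy_table`: `groups` (per-group folds and errors),
#'   `sets` (per-set efficiencies and F0), `avg_error_f0_pct`,
#'   `avg_error_cq_pct`. `tidy()` returns the group table, `glance()`
#'   the average errors.
#' @export
dilution_accuracy_table <- function(plate, window = c(20, 180), cq = NULL,
                                    outlier_removal = TRUE) {
  stopifnot(inherits(plate, "qpcr_plate"))
  cq <- cq %||% plate$cq
  if (is.null(cq)) abort("Cq values required for the Cq arm.")
  lay <- plate$layout
  if (all(is.na(lay$concentration))) {
    abort("Layout has no concentrations: cannot form accuracy groups.")
  }
  start <- summarise(group_by(lay, .data$set_id),
                     well = .data$well[which.max(.data$concentration)],
                     concentration = max(.data$concentration),
                     .groups = "drop")
  pw <- suppressWarnings(
    plate_efficiencies(plate, window = window,
                       outlier_removal = outlier_removal)
  )
  cal <- calibrate_plate(plate, cq = cq)
  cqt <- validate_cq(cq)
  sets <- left_join(start, pw[c("set_id", "e")], by = "set_id")
  sets <- rename(sets, e_pairwise = "e")
  sets <- left_join(sets, setNames(cal[c("set_id", "e")],
                                   c("set_id", "e_calibration")),
                    by = "set_id")
  sets <- left_join(sets, cqt, by = "well")
  sets$f0 <- purrr::map2_dbl(sets$well, sets$e_pairwise, function(w, e) {
    estimate_f0(plate, e = e, window = window, wells = w)$f0
  })

  conc_ref <- max(sets$concentration)
  groups <- summarise(group_by(sets, .data$concentration),
                      n_sets = dplyr::n(),
                      mean_f0 = mean(.data$f0),
                      mean_cq = mean(.data$cq),
                      e_cal_group = mean(.data$e_calibration),
                      .groups = "drop")
  groups <- arrange(groups, dplyr::desc(.data$concentration))
  ref <- groups[1, ]
  groups <- mutate(groups,
    expected_fold = conc_ref / .data$concentration,
    fold_f0 = ref$mean_f0 / .data$mean_f0,
    fold_cq = pfaffl_ratio(.data$e_cal_group, cq_sample = ref$mean_cq,
                           cq_control = .data$mean_cq),
    error_f0_pct = 100 * (.data$fold_f0 - .data$expected_fold) / .data$fold_f0,
    error_cq_pct = 100 * (.data$fold_cq - .data$expected_fold) / .data$fold_cq
  )
  non_ref <- groups$concentration < conc_ref
  structure(
    list(groups = select(groups, "concentration", "n_sets", "expected_fold",
                         "fold_f0", "error_f0_pct", "fold_cq", "error_cq_pct"),
         sets = sets,
         avg_error_f0_pct = mean(abs(groups$error_f0_pct[non_ref])),
         avg_error_cq_pct = mean(abs(groups$error_cq_pct[non_ref])),
         window = window),
    class = "accuracy_table"
  )
}

#' @export
print.accuracy_table <- function(x, ...) {
  cat("<accuracy_table> ", nrow(x$groups), " concentration groups\n", sep = "")
  print(x$groups)
  cat("average |error|: F0-based ", signif(x$avg_error_f0_pct, 3),
      "%, Cq-based ", signif(x$avg_error_cq_pct, 3), "%\n", sep = "")
  invisible(x)
}

#' @rdname dilution_accuracy_table
#' @param x An `accuracy_table`.
#' @param ... Unused.
#' @export
tidy.accuracy_table <- function(x, ...) x$groups

#' @rdname dilution_accuracy_table
#' @export
glance.accuracy_table <- function(x, ...) {
  tibble(avg_error_f0_pct = x$avg_error_f0_pct,
         avg_error_cq_pct = x$avg_error_cq_pct,
         n_groups = nrow(x$groups))
}
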