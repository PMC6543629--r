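#' Assemble a qPCR plate run
#'
#' A `qpcr_plate` bundles everything one run produces: the per-well,
#' per-cycle baseline-subtracted fluorescence table, the plate layout
#' (which well belongs to which dilution set, at which dilution step),
#' and optionally the instrument's quantification-cycle (Cq) calls.
#'
#' @param fluorescence Data frame with columns `well`, `cycle`, `rfu`
#'   (Relative Fluorescence Units, baseline subtracted; negative values
#'   are legitimate noise). Every well must carry the same complete
#'   cycle sequence `1, 2, ..., n`. May be `NULL` when only Cq data are
#'   available.
#' @param layout Data frame with columns `well`, `set_id`,
#'   `dilution_step` and optionally `concentration` (nominal, e.g. ng).
#'   `dilution_step` is the integer exponent D of the fold-dilution at
#'   base `base`; D = 0 is the undiluted sample. Steps must be distinct
#'   within a set.
#' @param cq Optional data frame with columns `well`, `cq`.
#' @param base Dilution base b (> 1); 2 for two-fold series, 10 for
#'   ten-fold.
#' @param cq_threshold Optional RFU threshold the Cq values were called
#'   at (metadata only).
#'
#' @return An object of class `qpcr_plate`: a list with elements
#'   `fluorescence`, `layout`, `cq`, `base`, `cq_threshold`.
#' @seealso [read_fluorescence()], [read_layout()], [simulate_plate()]
#' @export
#' @examples
#' fl <- tibble::tibble(
#'   well = rep(c("A1", "A2"), each = 3),
#'   cycle = rep(1:3, 2),
#'   rfu = c(1, 2, 4, 0.5, 1, 2)
#' )
#' lay <- tibble::tibble(well = c("A1", "A2"), set_id = "S1",
#'                       dilution_step = 0:1)
#' qpcr_plate(fl, lay)
qpcr_plate <- function(fluorescence = NULL, layout, cq = NULL, base = 2,
                       cq_threshold = NULL) {
  if (!is.numeric(base) || length(base) != 1L || base <= 1) {
    abort("`base` must be a single number > 1.")
  }
  layout <- validate_layout(layout)
  if (!is.null(fluorescence)) fluorescence <- validate_fluorescence(fluorescence)
  if (!is.null(cq)) cq <- validate_cq(cq)
  if (is.null(fluorescence) && is.null(cq)) {
    abort("A plate needs fluorescence data, Cq data, or both.")
  }
  covered <- if (!is.null(fluorescence)) fluorescence$well else cq$well
  missing_wells <- setdiff(layout$well, covered)
  if (length(missing_wells)) {
    abort(paste0("Layout wells without data: ",
                 paste(missing_wells, collapse = ", ")))
  }
  structure(
    list(fluorescence = fluorescence, layout = layout, cq = cq,
         base = base, cq_threshold = cq_threshold),
    class = "qpcr_plate"
  )
}

#' @export
print.qpcr_plate <- function(x, ...) {
  n_wells <- nrow(x$layout)
  n_sets <- dplyr::n_distinct(x$layout$set_id)
  cat("<qpcr_plate> ", n_wells, " wells, ", n_sets, " dilution set(s), base ",
      x$base, "\n", sep = "")
  if (!is.null(x$fluorescence)) {
    cat("  fluorescence: ", dplyr::n_distinct(x$fluorescence$well),
        " series x ", max(x$fluorescence$cycle), " cycles\n", sep = "")
  }
  if (!is.null(x$cq)) {
    cat("  cq: ", sum(!is.na(x$cq$cq)), " values",
        if (!is.null(x$cq_threshold)) paste0(" (threshold ", x$cq_threshold, " RFU)"),
        "\n", sep = "")
  }
  invisible(x)
}

validate_fluorescence <- function(df) {
  df <- as_tibble(df)
  need <- c("well", "cycle", "rfu")
  if (!all(need %in% names(df))) {
    abort("Fluorescence table needs columns well, cycle, rfu.")
  }
  if (!is.numeric(df$rfu) || anyNA(df$rfu)) {
    abort("Non-numeric or missing rfu values.")
  }
  if (!is.numeric(df$cycle) || anyNA(df$cycle) || any(df$cycle != round(df$cycle))) {
    abort("Cycle numbers must be integers.")
  }
  df$cycle <- as.integer(df$cycle)
  if (anyDuplicated(df[c("well", "cycle")])) {
    abort("Duplicate (well, cycle) readings.")
  }
  df <- arrange(df, .data$well, .data$cycle)
  chk <- summarise(group_by(df, .data$well),
                   ok = identical(.data$cycle, seq_len(dplyr::n())),
                   len = dplyr::n(), .groups = "drop")
  if (!all(chk$ok)) {
    abort(paste0("Missing cycle: wells must have cycles 1..n with no gaps (",
                 paste(chk$well[!chk$ok], collapse = ", "), ")."))
  }
  if (dplyr::n_distinct(chk$len) > 1L) {
    abort("All wells must have the same number of cycles.")
  }
  df[need]
}

validate_layout <- function(df) {
  df <- as_tibble(df)
  need <- c("well", "set_id", "dilution_step")
  if (!all(need %in% names(df))) {
    abort("Layout needs columns well, set_id, dilution_step.")
  }
  if (!"concentration" %in% names(df)) df$concentration <- NA_real_
  if (anyNA(df$dilution_step) || any(df$dilution_step < 0) ||
      any(df$dilution_step != round(df$dilution_step))) {
    abort("dilution_step must be a non-negative integer (0 = undiluted).")
  }
  df$dilution_step <- as.integer(df$dilution_step)
  if (anyDuplicated(df$well)) abort("Duplicate wells in layout.")
  dup <- summarise(group_by(df, .data$set_id),
                   dup = anyDuplicated(.data$dilution_step) > 0L,
                   .groups = "drop")
  if (any(dup$dup)) {
    abort(paste0("Repeated dilution_step within set(s): ",
                 paste(dup$set_id[dup$dup], collapse = ", ")))
  }
  if (!is.numeric(df$concentration)) {
    abort("concentration must be numeric (or absent).")
  }
  arrange(df[c(need, "concentration")], .data$set_id, .data$dilution_step)
}

validate_cq <- function(df) {
  df <- as_tibble(df)
  if (!all(c("well", "cq") %in% names(df))) {
    abort("Cq table needs columns well, cq.")
  }
  if (!is.numeric(df$cq) || any(is.nan(df$cq))) {
    abort("Non-numeric Cq values.")
  }
  if (any(df$cq < 0, na.rm = TRUE)) abort("Negative Cq values.")
  if (anyDuplicated(df$well)) abort("Duplicate wells in Cq table.")
  df[c("well", "cq")]
}

#' Read a long-format fluorescence table
#'
#' The native interchange format is a plain CSV with header exactly
#' `well,cycle,rfu`, one row per reading, UTF-8, `.` decimal separator.
#' Row order in the file is irrelevant.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble with columns `well`, `cycle`, `rfu`,
#'   sorted by well and cycle.
#' @export
read_fluorescence <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(),
    cycle = readr::col_integer(),
    rfu = readr::col_double()
  ), progress = FALSE)
  validate_fluorescence(df)
}

#' Read a plate-layout table
#'
#' Header `well,set_id,dilution_step,concentration`; the concentration
#' column is optional and may be empty.
#'
#' @param path Path to the CSV file.
#' @return A validated layout tibble.
#' @export
read_layout <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(),
    set_id = readr::col_character(),
    dilution_step = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE)
  validate_layout(df)
}

#' Read a Cq table
#'
#' Header `well,cq`; Cq values are fractional cycle numbers.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `well`, `cq` (empty, with a warning,
#'   if the file has no rows).
#' @export
read_cq <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(),
    cq = readr::col_double()
  ), progress = FALSE)
  if (nrow(df) == 0L) warn("Cq table is empty.")
  validate_cq(df)
}

#' Write plate tables to CSV
#'
#' Inverse of the readers; writing then reading yields an identical
#' table.
#'
#' @param x A tibble as produced by the matching reader (or the
#'   corresponding element of a [qpcr_plate()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fluorescence <- function(x, path) {
  readr::write_csv(validate_fluorescence(x), path)
  invisible(path)
}

#' @rdname write_fluorescence
#' @export
write_layout <- function(x, path) {
  readr::write_csv(validate_layout(x), path)
  invisible(path)
}

#' @rdname write_fluorescence
#' @export
write_cq <- function(x, path) {
  readr::write_csv(validate_cq(x), path)
  invisible(path)
}

#' List the dilution sets of a plate
#'
#' @param x A [qpcr_plate()] or a layout data frame.
#' @return A tibble with one row per set: `set_id`, `n_wells`, and
#'   list-columns `wells` and `steps` ordered by dilution step.
#' @export
dilution_sets <- function(x) {
  layout <- if (inherits(x, "qpcr_plate")) x$layout else validate_layout(x)
  layout <- arrange(layout, .data$set_id, .data$dilution_step)
  summarise(group_by(layout, .data$set_id),
            n_wells = dplyr::n(),
            wells = list(.data$well),
            steps = list(.data$dilution_step),
            .groups = "drop")
}

# readings of one well as a tibble(cycle, rfu); internal
well_series <- function(plate, well) {
  stopifnot(inherits(plate, "qpcr_plate"), !is.null(plate$fluorescence))
  out <- filter(plate$fluorescence, .data$well == !!well)
  if (nrow(out) == 0L) abort(paste0("No fluorescence series for well ", well, "."))
  out
}
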