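#' Simulate a qPCR plate of replicate dilution sets
#'
#' Generates per-well amplification curves from the classical kinetic
#' model \eqn{F_i = (F_0 / b^D) (1 + E)^i}, with logistic saturation and
#' additive Gaussian reading noise, arranged as replicate dilution sets
#' on a 96-well-style plate. The defaults emulate the study design the
#' package's validation is built around: 16 replicate six-step two-fold
#' dilution sets read over 33 cycles, efficiency 0.8, reading noise of
#' sd 3 RFU (so the early-cycle noise spans roughly -10..10 RFU), and a
#' saturation ceiling of 2000 RFU.
#'
#' Saturation: each cycle's increment is damped by `(1 - F/plateau)`,
#' i.e. \eqn{F_{i} = F_{i-1} + E F_{i-1} (1 - F_{i-1}/plateau)}. With
#' `plateau = Inf` and `noise_sd = 0` the curve is exactly the
#' closed-form exponential.
#'
#' Plate geometry: each set occupies consecutive columns of one row
#' half (set ids like `"A1-6"`, `"A7-12"`). `set_offsets` shifts whole
#' sets down the dilution ladder, emulating plates whose replicate
#' series start at different template amounts; the default for the
#' canonical 16 x 6 design uses start offsets 0,0,1,1,3,3,5,5 cycles of
#' two-fold per row pair (nominal 100/50/12.5/3.125 ng), which is what
#' the dilution-ratio accuracy analysis expects. Nominal concentration
#' is recorded in the layout as `100 / base^(offset + step)`.
#'
#' @param e_true True amplification efficiency E, in (0, 1.1].
#' @param f0 Fluorescence-equivalent of the undiluted template (RFU).
#' @param base Dilution base b.
#' @param steps Integer dilution steps of each set (default `0:5`).
#' @param n_sets Number of replicate sets.
#' @param n_cycles Number of PCR cycles read.
#' @param plateau Saturation ceiling (RFU); `Inf` disables saturation.
#' @param noise_sd Sd of additive Gaussian reading noise (RFU).
#' @param noise_mean Mean of the reading noise (the real instrument's
#'   early-cycle noise peaks slightly off zero; default 0).
#' @param f0_jitter_sd Sd of an optional per-well multiplicative
#'   log-normal jitter on the starting amount (pipetting error); 0
#'   disables it.
#' @param set_offsets Integer vector (length `n_sets`) of whole-set
#'   dilution offsets; `NULL` picks the canonical default above.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#'   Identical parameters and seed give a bit-identical plate.
#' @return A [qpcr_plate()] with fluorescence and layout filled in.
#' @export
#' @examples
#' plate <- simulate_plate(n_sets = 2, noise_sd = 0, seed = 1)
#' plate
simulate_plate <- function(e_true = 0.8, f0 = 0.004, base = 2, steps = 0:5,
                           n_sets = 16, n_cycles = 33, plateau = 2000,
                           noise_sd = 3, noise_mean = 0, f0_jitter_sd = 0,
                           set_offsets = NULL, seed = NULL) {
  if (!is.numeric(e_true) || e_true <= 0 || e_true > 1.1) {
    abort("`e_true` must lie in (0, 1.1].")
  }
  if (n_cycles < 2) abort("`n_cycles` must be at least 2.")
  if (f0 <= 0) abort("`f0` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (any(steps < 0) || anyDuplicated(steps)) {
    abort("`steps` must be distinct non-negative integers.")
  }
  if (is.null(set_offsets)) {
    set_offsets <- if (n_sets == 16L && identical(as.integer(steps), 0:5)) {
      rep(c(0L, 0L, 1L, 1L, 3L, 3L, 5L, 5L), each = 2L)
    } else {
      rep(0L, n_sets)
    }
  }
  if (length(set_offsets) != n_sets) {
    abort("`set_offsets` must have one entry per set.")
  }
  if (!is.null(seed)) local_seed_scoped(seed)

  layout <- plate_geometry(n_sets, steps)
  layout$concentration <- 100 / base^(set_offsets[layout$set_index] + layout$dilution_step)

  n_wells <- nrow(layout)
  jitter <- if (f0_jitter_sd > 0) exp(rnorm(n_wells, 0, f0_jitter_sd)) else rep(1, n_wells)
  f0_well <- f0 * jitter / base^(set_offsets[layout$set_index] + layout$dilution_step)

  clean <- vapply(f0_well, amplification_curve, numeric(n_cycles),
                  e = e_true, n_cycles = n_cycles, plateau = plateau)
  noise <- if (noise_sd > 0 || noise_mean != 0) {
    matrix(rnorm(n_cycles * n_wells, noise_mean, noise_sd), n_cycles, n_wells)
  } else {
    0
  }
  readings <- clean + noise

  fl <- tibble(
    well = rep(layout$well, each = n_cycles),
    cycle = rep(seq_len(n_cycles), n_wells),
    rfu = as.vector(readings)
  )
  qpcr_plate(fl, layout[c("well", "set_id", "dilution_step", "concentration")],
             base = base)
}

# deterministic logistic-damped amplification curve, cycles 1..n
amplification_curve <- function(f0, e, n_cycles, plateau) {
  out <- numeric(n_cycles)
  x <- f0
  for (i in seq_len(n_cycles)) {
    damp <- if (is.finite(plateau)) max(0, 1 - x / plateau) else 1
    x <- x + e * x * damp
    out[i] <- x
  }
  out
}

# row-half plate geometry: each set on consecutive columns of one row
plate_geometry <- function(n_sets, steps) {
  k <- length(steps)
  sets_per_row <- max(1L, 12L %/% k)
  rows <- rep(LETTERS, each = sets_per_row)[seq_len(n_sets)]
  slot <- (seq_len(n_sets) - 1L) %% sets_per_row
  purrr::map_dfr(seq_len(n_sets), function(s) {
    cols <- slot[s] * k + seq_len(k)
    tibble(
      well = paste0(rows[s], cols),
      set_id = paste0(rows[s], cols[1], "-", cols[k]),
      dilution_step = as.integer(sort(steps)),
      set_index = s
    )
  })
}

#' Call quantification cycles by threshold crossing
#'
#' Cq is the fractional cycle at which a well's fluorescence first
#' reaches `threshold`, interpolated log-linearly between the two
#' flanking cycles (exact for pure exponentials). If the reading below
#' the crossing is not positive the interpolation falls back to linear.
#' Wells that never reach the threshold get `NA` with a warning.
#'
#' @param plate A [qpcr_plate()] with fluorescence data.
#' @param threshold Positive RFU threshold.
#' @return A tibble with columns `well`, `cq`.
#' @export
#' @examples
#' plate <- simulate_plate(n_sets = 1, noise_sd = 0, plateau = Inf, seed = 1)
#' call_cq(plate, threshold = 31.07)
call_cq <- function(plate, threshold) {
  stopifnot(inherits(plate, "qpcr_plate"))
  if (is.null(plate$fluorescence)) abort("Plate has no fluorescence data.")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("`threshold` must be a single positive number.")
  }
  out <- summarise(group_by(plate$fluorescence, .data$well),
                   cq = cq_one(.data$rfu, threshold), .groups = "drop")
  if (anyNA(out$cq)) {
    warn(paste0("Wells never reaching the threshold: ",
                paste(out$well[is.na(out$cq)], collapse = ", ")))
  }
  out
}

cq_one <- function(rfu, threshold) {
  c1 <- which(rfu >= threshold)[1]
  if (is.na(c1)) return(NA_real_)
  if (c1 == 1L) return(1)
  lo <- rfu[c1 - 1L]; hi <- rfu[c1]
  if (lo > 0) {
    (c1 - 1) + (log(threshold) - log(lo)) / (log(hi) - log(lo))
  } else {
    (c1 - 1) + (threshold - lo) / (hi - lo)
  }
}
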