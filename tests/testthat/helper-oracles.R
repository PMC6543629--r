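# Independent oracles and small fixture builders used across the suite.

# closed-form exponential curve (no saturation), cycles 1..n
oracle_curve <- function(f0, e, n) f0 * (1 + e)^(1:n)

# brute-force double loop over all unordered pairs, excluding same-cycle
# pairs; returns list(count, values) computed with plain log2 arithmetic
oracle_pairs <- function(readings, base = 2, cross_well_only = FALSE) {
  n <- nrow(readings)
  count <- 0L
  values <- numeric(0)
  if (n >= 2) {
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        if (readings$cycle[a] == readings$cycle[b]) next
        if (cross_well_only && readings$well[a] == readings$well[b]) next
        count <- count + 1L
        num <- log(readings$rfu[b], base) - log(readings$rfu[a], base) +
          (readings$dilution_step[b] - readings$dilution_step[a])
        values <- c(values, base^(num / (readings$cycle[b] - readings$cycle[a])) - 1)
      }
    }
  }
  list(count = count, values = values)
}

# random admitted-readings table: up to max_n readings over a handful of
# wells/cycles, positive RFU, dilution steps 0..5
random_readings <- function(max_n = 50) {
  n <- sample(2:max_n, 1)
  wells <- paste0("W", sample(1:6, n, replace = TRUE))
  steps <- as.integer(substr(wells, 2, 2)) - 1L
  tibble::tibble(
    well = wells,
    cycle = sample(1:12, n, replace = TRUE),
    rfu = exp(stats::runif(n, -2, 6)),
    dilution_step = steps
  )
}

# one-set plate built from explicit per-well readings
plate_from_curves <- function(curves, steps = seq_along(curves) - 1, base = 2) {
  n <- length(curves[[1]])
  wells <- paste0("A", seq_along(curves))
  fl <- purrr::map_dfr(seq_along(curves), function(k) {
    tibble::tibble(well = wells[k], cycle = 1:n, rfu = curves[[k]])
  })
  lay <- tibble::tibble(well = wells, set_id = "S1",
                        dilution_step = as.integer(steps))
  qpcr_plate(fl, lay, base = base)
}
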