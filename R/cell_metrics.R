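#' Shannon diversity index of T-cell subset composition
#'
#' `H = -sum(p_i * log(p_i))` over the subset proportions, with
#' `0 * log(0) == 0`. Computed over the four T-cell subsets only (not
#' "other" nucleated cells), so `H` ranges from 0 (one subset dominates
#' completely) to `log(4)` (all four subsets equally abundant). Counts and
#' proportions give identical results (scale invariance).
#'
#' @param counts non-negative counts (or proportions) over subsets; at
#'   least one must be positive.
#' @param base logarithm base; the default natural log reports H in nats.
#' @return the diversity index (scalar).
#' @export
shannon_diversity <- function(counts, base = exp(1)) {
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("cannot compute diversity of an empty population", call. = FALSE)
  }
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Per-core subset profile: counts, frequencies, ratios and diversity
#'
#' Cell frequencies are cell counts over the total number of nucleated
#' cells. Also reported: the total CD3+ T-cell frequency, each T subset as
#' a percentage of CD3+ cells, the helper/cytotoxic ratio, the
#' late/early-differentiation (CD57+/CD57-) ratio, and the Shannon
#' diversity of the four T subsets. Ratios whose denominator count is zero
#' are reported as `NA` (missing), never as 0 or infinity.
#'
#' @param cells a `cell_table` from [classify_cells()] (one core).
#' @return a one-row data.frame (class `subset_profile`) with columns
#'   `patient_id`, `core_id`, `region`, `total_nucleated`,
#'   `n_<class>` and `freq_<class>` for the five classes, `cd3_frequency`,
#'   `pct_cd3_<subset>`, `th_tc_ratio`, `t57pos_t57neg_ratio`, `sdi`.
#' @export
subset_profile <- function(cells) {
  if (!nrow(cells)) stop("empty cell table", call. = FALSE)
  stopifnot(all(c("class", "core_id", "patient_id", "region") %in%
                  names(cells)))
  counts <- table(factor(cells$class, levels = CELL_CLASSES))
  total <- sum(counts)
  freqs <- as.numeric(counts) / total
  names(freqs) <- CELL_CLASSES
  tcounts <- as.numeric(counts[TCELL_SUBSETS])
  names(tcounts) <- TCELL_SUBSETS
  n_cd3 <- sum(tcounts)
  pct_cd3 <- if (n_cd3 > 0) tcounts / n_cd3 else rep(NA_real_, 4)
  n_th <- tcounts[["TH_57neg"]] + tcounts[["TH_57pos"]]
  n_tc <- tcounts[["TC_57neg"]] + tcounts[["TC_57pos"]]
  n_57pos <- tcounts[["TH_57pos"]] + tcounts[["TC_57pos"]]
  n_57neg <- tcounts[["TH_57neg"]] + tcounts[["TC_57neg"]]
  out <- data.frame(
    patient_id = cells$patient_id[1], core_id = cells$core_id[1],
    region = cells$region[1], total_nucleated = total,
    t(setNames(as.numeric(counts), paste0("n_", CELL_CLASSES))),
    t(setNames(freqs, paste0("freq_", CELL_CLASSES))),
    cd3_frequency = n_cd3 / total,
    t(setNames(pct_cd3, paste0("pct_cd3_", TCELL_SUBSETS))),
    th_tc_ratio = if (n_tc > 0) n_th / n_tc else NA_real_,
    t57pos_t57neg_ratio = if (n_57neg > 0) n_57pos / n_57neg else NA_real_,
    sdi = if (n_cd3 > 0) shannon_diversity(tcounts) else NA_real_
  )
  class(out) <- c("subset_profile", "data.frame")
  out
}

#' Aggregate per-core profiles to per-patient profiles
#'
#' Duplicate tissue cores per patient are aggregated by the arithmetic mean
#' of each frequency/ratio column. The Shannon diversity is reported both
#' recomputed from pooled subset counts (`sdi_pooled`) and as the mean of
#' per-core values (`sdi_mean`); the two coincide when cores share one
#' composition.
#'
#' @param profiles data.frame of stacked [subset_profile()] rows.
#' @param by grouping columns, default patient and region.
#' @return data.frame with one row per group: summed counts, mean
#'   frequencies/ratios, `sdi_mean`, `sdi_pooled`, `n_cores`.
#' @export
aggregate_by_patient <- function(profiles, by = c("patient_id", "region")) {
  stopifnot(all(by %in% names(profiles)))
  key <- interaction(profiles[by], drop = TRUE)
  mean_cols <- c(paste0("freq_", CELL_CLASSES), "cd3_frequency",
                 paste0("pct_cd3_", TCELL_SUBSETS),
                 "th_tc_ratio", "t57pos_t57neg_ratio")
  sum_cols <- c("total_nucleated", paste0("n_", CELL_CLASSES))
  rows <- lapply(levels(key), function(k) {
    g <- profiles[key == k, , drop = FALSE]
    out <- g[1, by, drop = FALSE]
    for (cc in sum_cols) out[[cc]] <- sum(g[[cc]])
    for (cc in mean_cols) out[[cc]] <- mean(g[[cc]], na.rm = TRUE)
    pooled <- as.numeric(out[paste0("n_", TCELL_SUBSETS)])
    out$sdi_mean <- mean(g$sdi, na.rm = TRUE)
    out$sdi_pooled <- if (sum(pooled) > 0) shannon_diversity(pooled) else NA_real_
    out$n_cores <- nrow(g)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
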