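# Downstream quantification helpers: TPM normalization, per-gene
# z-scores for expression heatmaps, control-corrected mortality and
# relative qPCR expression.

#' Transcripts-per-million normalization
#'
#' Per sample: `rate_g = count_g / (length_g / 1000)` and
#' `TPM_g = rate_g / sum(rates) * 1e6`, so every sample column sums to one
#' million and within-sample abundances are comparable across samples.
#'
#' @param counts Tibble with a gene id column, a `length` column (effective
#'   gene length in bases, supplied by the caller) and one numeric column
#'   of raw counts per sample.
#' @param gene Name of the gene id column.
#' @param length Name of the length column.
#' @return A tibble of the same shape with counts replaced by TPM.
#' @export
tpm <- function(counts, gene = "gene", length = "length") {
  if (!all(c(gene, length) %in% names(counts))) {
    abort(paste0("count table must have '", gene, "' and '", length,
                 "' columns"))
  }
  len <- counts[[length]]
  if (any(!is.finite(len) | len <= 0)) {
    abort("gene lengths must be positive")
  }
  samples <- setdiff(names(counts), c(gene, length))
  if (length(samples) == 0) abort("no sample columns found")
  out <- counts
  for (s in samples) {
    x <- counts[[s]]
    if (any(x < 0, na.rm = TRUE)) abort("negative counts are not allowed")
    rate <- x / (len / 1000)
    tot <- sum(rate)
    if (!is.finite(tot) || tot <= 0) {
      abort(paste0("sample '", s, "' has no nonzero counts"))
    }
    out[[s]] <- rate / tot * 1e6
  }
  out
}

#' Per-gene z-transform across samples
#'
#' Centers and scales each gene's values across samples,
#' `(x - mean(x)) / sd(x)`; genes with zero variance become all zeros with
#' a warning. Used to put genes with very different absolute expression on
#' one heatmap color scale.
#'
#' @inheritParams tpm
#' @param tpm_matrix Tibble of TPM values: gene id column plus >= 2 sample
#'   columns.
#' @return A tibble of the same shape with z-scores.
#' @export
zscore_by_gene <- function(tpm_matrix, gene = "gene", length = "length") {
  samples <- setdiff(names(tpm_matrix), c(gene, length))
  if (length(samples) < 2) abort("z-transform needs at least 2 samples")
  m <- as.matrix(tpm_matrix[samples])
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  flat <- s == 0
  if (any(flat)) {
    warn(paste0(sum(flat), " gene(s) with zero variance set to 0"))
    s[flat] <- 1
  }
  z <- (m - mu) / s
  z[flat, ] <- 0
  out <- tpm_matrix
  out[samples] <- as.data.frame(z)
  out
}

#' Schneider-Orelli corrected mortality
#'
#' Control-corrected mortality in percent,
#' `100 * (treated - control) / (100 - control)`. Treated mortality below
#' the control is clipped at 0 with a warning.
#'
#' @param treated_pct,control_pct Observed mortality in the treated and
#'   control arms, percent in \[0, 100\]; `control_pct` must be < 100.
#' @return Corrected mortality, percent (vectorized).
#' @export
schneider_orelli <- function(treated_pct, control_pct) {
  if (any(treated_pct < 0 | treated_pct > 100 |
          control_pct < 0 | control_pct > 100)) {
    abort("mortalities must lie in [0, 100]")
  }
  if (any(control_pct >= 100)) {
    abort("control mortality of 100% leaves nothing to correct")
  }
  out <- 100 * (treated_pct - control_pct) / (100 - control_pct)
  if (any(out < 0)) {
    warn("treated mortality below control; clipping corrected value at 0")
    out[out < 0] <- 0
  }
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_reference` within each condition,
#' `ddCt = dCt_treated - dCt_control`, fold change `efficiency^(-ddCt)`
#' (the textbook 2^-ddCt with a perfectly doubling primer pair; a
#' dilution-series efficiency estimate can be supplied instead). Knockdown
#' percent is reported when the fold change is below 1.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Cycle-threshold values (vectorized).
#' @param efficiency Per-cycle amplification factor (default 2).
#' @return Tibble with `delta_delta_ct`, `fold_change`, `knockdown_pct`
#'   (NA when expression did not decrease).
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control, efficiency = 2) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control,
           ct_ref_control)
  if (any(!is.finite(cts) | cts <= 0)) {
    abort("Ct values must be finite and positive")
  }
  if (any(efficiency <= 1)) abort("efficiency must exceed 1")
  dd <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  fold <- efficiency^(-dd)
  tibble(delta_delta_ct = dd, fold_change = fold,
         knockdown_pct = ifelse(fold < 1, 100 * (1 - fold), NA_real_))
}
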