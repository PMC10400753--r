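# Count normalization, coverage filtering and a simplified DE engine.
#
# TMM normalization and cpm computation are delegated to edgeR (the standard
# implementation, with published defaults: 30% two-sided trim on M, 5% on A,
# precision-weighted M mean, reference sample by upper-quartile closeness);
# factors are rescaled so their geometric mean is 1. The DE engine is a
# deliberately simple stand-in — Welch t on log2(cpm + 0.5) with BH
# adjustment — because the downstream ageing classification consumes any
# table with the DEG columns, including externally produced ones.

#' TMM-normalise a count matrix
#'
#' @param counts Non-negative integer matrix, genes x samples (rownames =
#'   gene ids, colnames = sample ids).
#' @return An object of class `norm_counts`: `factors` tibble (`sample`,
#'   `lib_size`, `tmm_factor`, geometric mean of factors 1), `cpm` matrix
#'   (counts per million against factor-adjusted library sizes).
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative.")
  if (ncol(counts) < 2) abort("need at least 2 samples.")
  lib <- colSums(counts)
  if (any(lib == 0)) abort("sample(s) with zero library size.")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  f <- f / exp(mean(log(f)))
  cpm <- edgeR::cpm(counts, lib.size = lib * f)
  structure(list(factors = tibble(sample = colnames(counts) %||%
                                    paste0("s", seq_along(f)),
                                  lib_size = unname(lib),
                                  tmm_factor = unname(f)),
                 cpm = cpm, counts = counts),
            class = "norm_counts")
}

#' @export
print.norm_counts <- function(x, ...) {
  cat(sprintf("TMM-normalised counts: %d genes x %d samples\n",
              nrow(x$cpm), ncol(x$cpm)))
  print(x$factors, n = 6)
  invisible(x)
}

#' Coverage-based gene filter
#'
#' Retains a gene when at least one group has strictly more than `min_samples`
#' samples with cpm above `cpm_threshold` (default: cpm > 0.5 in more than 3
#' samples in a genotype x age group).
#'
#' @param norm A [normalize_counts()] result.
#' @param samples Tibble with `sample` plus the grouping columns.
#' @param group_by Character vector of grouping columns (default
#'   `c("genotype", "age")`).
#' @param cpm_threshold,min_samples Filter parameters (strict inequalities).
#' @return A tibble (`gene_id`, `keep`) with attribute `"summary"`:
#'   `n_total`, `n_retained`, `pct_retained`.
#' @export
filter_genes <- function(norm, samples, group_by = c("genotype", "age"),
                         cpm_threshold = 0.5, min_samples = 3) {
  stopifnot(inherits(norm, "norm_counts"))
  samples <- as_tibble(samples)
  if (!all(samples$sample %in% colnames(norm$cpm))) {
    abort("`samples$sample` must match cpm column names.")
  }
  key <- do.call(paste, c(samples[group_by], sep = "\r"))
  keep <- rep(FALSE, nrow(norm$cpm))
  for (g in unique(key)) {
    cols <- samples$sample[key == g]
    if (length(cols) <= min_samples) next
    n_above <- rowSums(norm$cpm[, cols, drop = FALSE] > cpm_threshold)
    keep <- keep | (n_above > min_samples)
  }
  out <- tibble(gene_id = rownames(norm$cpm), keep = unname(keep))
  attr(out, "summary") <- list(n_total = nrow(out), n_retained = sum(keep),
                               pct_retained = percent_of(sum(keep), nrow(out)))
  out
}

#' Differential expression between two sample groups
#'
#' logFC is the difference of group means of `log2(cpm + 0.5)`; p-values are
#' two-sided Welch t on the same values, BH-adjusted within the comparison.
#' A gene is flagged DE when `|logFC| > 1` and adjusted p `< 0.05` (strict
#' inequalities). Genes with zero variance in both groups get a variance
#' floor (the smallest nonzero per-gene pooled variance) and are flagged in
#' `var_floored`.
#'
#' @param norm A [normalize_counts()] result.
#' @param samples_a,samples_b Character vectors of sample ids (each >= 2).
#' @param comparison Label stored in the `comparison` column.
#' @param genes Optional gene ids to restrict to (e.g. a [filter_genes()]
#'   retained set).
#' @param lfc_threshold,alpha DEG criteria (strict).
#' @return A tibble of class `deg_table`: `gene_id`, `comparison`, `logfc`,
#'   `p`, `adj_p`, `is_deg`, `var_floored`.
#' @export
differential_expression <- function(norm, samples_a, samples_b,
                                    comparison = "A_vs_B", genes = NULL,
                                    lfc_threshold = 1, alpha = 0.05) {
  stopifnot(inherits(norm, "norm_counts"))
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    abort("both groups need at least 2 samples.")
  }
  cpm <- norm$cpm
  if (!is.null(genes)) cpm <- cpm[rownames(cpm) %in% genes, , drop = FALSE]
  la <- log2(cpm[, samples_a, drop = FALSE] + 0.5)
  lb <- log2(cpm[, samples_b, drop = FALSE] + 0.5)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1)
  vb <- rowSums((lb - mb)^2) / (nb - 1)
  pooled <- va / na + vb / nb
  floored <- pooled == 0
  if (any(floored)) {
    floor_val <- if (all(floored)) 1e-8 else min(pooled[!floored])
    pooled[floored] <- floor_val
    va[va == 0 & floored] <- floor_val * na / 2
    vb[vb == 0 & floored] <- floor_val * nb / 2
  }
  tstat <- (ma - mb) / sqrt(pooled)
  df <- pooled^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  df[!is.finite(df) | df <= 0] <- na + nb - 2
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  adj <- p.adjust(p, method = "BH")
  logfc <- ma - mb
  out <- tibble(gene_id = rownames(cpm), comparison = comparison,
                logfc = unname(logfc), p = unname(p), adj_p = unname(adj),
                is_deg = abs(logfc) > lfc_threshold & adj < alpha,
                var_floored = unname(floored))
  class(out) <- c("deg_table", class(out))
  out
}

#' DEG gene set of a comparison
#'
#' @param deg A `deg_table` (from [differential_expression()] or any data
#'   frame with `gene_id` and `is_deg`).
#' @return Character vector of flagged gene ids.
#' @export
deg_genes <- function(deg) {
  stopifnot(all(c("gene_id", "is_deg") %in% names(deg)))
  deg$gene_id[deg$is_deg]
}
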