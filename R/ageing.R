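# The ageing/aged classification of differential-expression results,
# contribution statistics, Fisher over-representation and rank-normalised PCA.

#' Classify cardiac-ageing genes from per-age DEG sets
#'
#' Given the wild-type DEG sets of the five age comparisons (6, 8, 10, 12 and
#' 14 months, each versus 4 months), partitions the oldest-age DEGs into
#'
#' * `aged_only` — DEGs found only at 14 months
#'   (`DEG(14) \ union of younger sets`): genes of the aged heart;
#' * `ageing` — DEGs found at 14 months and at least one younger age
#'   (`DEG(14) intersect union of younger sets`): genes of the ageing heart;
#' * `cardiac_ageing` — their union, i.e. all of `DEG(14)`.
#'
#' The same classification applies verbatim to over-represented-process term
#' ids per age group ("processes of the ageing/aged heart").
#'
#' @param deg_sets Named list of character vectors; names must include
#'   `"6"`, `"8"`, `"10"`, `"12"`, `"14"` (empty sets allowed).
#' @return An object of class `ageing_partition`: list with `aged_only`,
#'   `ageing`, `cardiac_ageing` (character vectors). Disjointness and the
#'   union identity are checked on every call.
#' @export
#' @examples
#' classify_ageing_genes(list(`6` = c("a"), `8` = character(), `10` = "b",
#'                            `12` = character(), `14` = c("a", "b", "c")))
classify_ageing_genes <- function(deg_sets) {
  required <- c("6", "8", "10", "12", "14")
  missing <- setdiff(required, names(deg_sets))
  if (length(missing)) {
    abort(paste("missing comparison(s):", paste(missing, collapse = ", ")))
  }
  old <- unique(deg_sets[["14"]])
  younger <- unique(unlist(deg_sets[c("6", "8", "10", "12")], use.names = FALSE))
  aged_only <- setdiff(old, younger)
  ageing <- intersect(old, younger)
  stopifnot(length(intersect(aged_only, ageing)) == 0,
            setequal(union(aged_only, ageing), old))
  structure(list(aged_only = aged_only, ageing = ageing, cardiac_ageing = old),
            class = "ageing_partition")
}

#' @export
print.ageing_partition <- function(x, ...) {
  cat(sprintf("cardiac ageing genes: %d (aged-only %d + ageing %d)\n",
              length(x$cardiac_ageing), length(x$aged_only), length(x$ageing)))
  invisible(x)
}

#' @export
tidy.ageing_partition <- function(x, ...) {
  dplyr::bind_rows(tibble(gene_id = x$aged_only, class = "aged_only"),
                   tibble(gene_id = x$ageing, class = "ageing"))
}

#' @export
glance.ageing_partition <- function(x, ...) {
  tibble(n_cardiac_ageing = length(x$cardiac_ageing),
         n_aged_only = length(x$aged_only), n_ageing = length(x$ageing))
}

#' Contribution of cardiac-ageing genes to a heart-failure DEG set
#'
#' Share (in percent) of a transgenic-vs-wild-type DEG set that belongs to
#' the cardiac-ageing partition. Genes absent from both sets do not affect
#' the value.
#'
#' @param partition An [classify_ageing_genes()] result.
#' @param hf_degs Character vector of DEGs from one Tg-vs-FVB comparison.
#' @return A one-row tibble: `n_hf`, `n_overlap`, `percent`.
#' @export
contribution_fraction <- function(partition, hf_degs) {
  stopifnot(inherits(partition, "ageing_partition"))
  hf_degs <- unique(hf_degs)
  if (length(hf_degs) == 0) {
    warn("empty heart-failure DEG set: contribution undefined.")
    return(tibble(n_hf = 0L, n_overlap = 0L, percent = NA_real_))
  }
  ov <- length(intersect(partition$cardiac_ageing, hf_degs))
  tibble(n_hf = length(hf_degs), n_overlap = ov,
         percent = 100 * ov / length(hf_degs))
}

#' Fisher over-representation analysis
#'
#' One-sided (enrichment) Fisher exact test per annotation term on the 2x2
#' table (query-in-term, query-not-in-term, rest-in-term, rest), computed as
#' the hypergeometric upper tail; BH adjustment across terms. Terms are
#' intersected with the background first.
#'
#' @param query Character vector, a subset of `background`.
#' @param background Character vector of all testable genes.
#' @param annotation Named list: term id -> character vector of genes (e.g.
#'   from [read_gmt()]).
#' @param alpha Flag threshold (default 0.05).
#' @param adjust Apply the flag to BH-adjusted (`TRUE`, default) or raw
#'   p-values.
#' @return A tibble of class `ora_result`: `term`, `term_size`, `query_size`,
#'   `overlap`, `p`, `adj_p`, `over_represented`.
#' @export
overrepresentation <- function(query, background, annotation, alpha = 0.05,
                               adjust = TRUE) {
  background <- unique(background)
  if (length(background) == 0) abort("empty background.")
  query <- unique(query)
  if (!all(query %in% background)) abort("`query` must be a subset of `background`.")
  N <- length(background)
  q <- length(query)
  rows <- purrr::imap(annotation, function(genes, term) {
    tg <- intersect(unique(genes), background)
    k <- length(intersect(tg, query))
    m <- length(tg)
    p <- phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    tibble(term = term, term_size = m, query_size = q, overlap = k, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$adj_p <- p.adjust(out$p, method = "BH")
  out$over_represented <- (if (adjust) out$adj_p else out$p) < alpha
  class(out) <- c("ora_result", class(out))
  out
}

#' Annotation coverage of a gene set
#'
#' @param genes Character vector of gene ids.
#' @param annotation Named list: term -> genes.
#' @return A one-row tibble: `n_genes`, `n_annotated`, `pct_annotated`.
#' @export
annotation_coverage <- function(genes, annotation) {
  genes <- unique(genes)
  annotated <- intersect(genes, unique(unlist(annotation, use.names = FALSE)))
  tibble(n_genes = length(genes), n_annotated = length(annotated),
         pct_annotated = percent_of(length(annotated), length(genes)))
}

#' Rank-normalised PCA of a gene subset
#'
#' Per gene: mid-rank across samples, inverse-normal (Blom-type) transform
#' `qnorm((rank - 0.5) / n)`, then z-scoring; PCA of the samples x genes
#' matrix by singular value decomposition (column-centred scores). Genes
#' constant across samples carry no rank information and are dropped with a
#' warning.
#'
#' @param norm A [normalize_counts()] result (the cpm matrix is used) or a
#'   plain genes x samples matrix.
#' @param genes Gene ids to use (at least 2), e.g. the cardiac-ageing set.
#' @return An object of class `ageing_pca`: `scores` tibble (`sample`,
#'   `PC1`, ...), `var_explained` (fractions, non-increasing), `genes_used`.
#' @export
ageing_pca <- function(norm, genes) {
  x <- if (inherits(norm, "norm_counts")) norm$cpm else as.matrix(norm)
  genes <- intersect(unique(genes), rownames(x))
  if (length(genes) < 2) abort("need at least 2 genes present in the matrix.")
  if (ncol(x) < 3) abort("need at least 3 samples.")
  x <- x[genes, , drop = FALSE]
  constant <- apply(x, 1, function(v) length(unique(v)) == 1)
  if (any(constant)) {
    warn(sprintf("dropping %d constant gene(s) before rank normalisation.",
                 sum(constant)))
    x <- x[!constant, , drop = FALSE]
    if (nrow(x) < 2) abort("fewer than 2 informative genes remain.")
  }
  n <- ncol(x)
  z <- t(apply(x, 1, function(v) {
    r <- rank(v, ties.method = "average")
    q <- qnorm((r - 0.5) / n)
    (q - mean(q)) / stats::sd(q)
  }))
  pc <- prcomp(t(z), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble(sample = colnames(x)), scores)
  structure(list(scores = scores, var_explained = ve,
                 genes_used = rownames(x), rotation = pc$rotation),
            class = "ageing_pca")
}

#' @export
print.ageing_pca <- function(x, ...) {
  cat(sprintf("rank-normalised PCA: %d genes, %d samples; PC1 %.1f%%, PC2 %.1f%%\n",
              length(x$genes_used), nrow(x$scores),
              100 * x$var_explained[1], 100 * x$var_explained[2]))
  invisible(x)
}

#' @export
tidy.ageing_pca <- function(x, ...) x$scores

#' @export
glance.ageing_pca <- function(x, ...) {
  tibble(n_genes = length(x$genes_used), n_samples = nrow(x$scores),
         pc1_var = x$var_explained[1], pc2_var = x$var_explained[2])
}
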