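# Negative-binomial RNA-seq count simulator with planted age/genotype effects.

#' Configuration for the count-matrix generator
#'
#' Emulates a two-genotype (wild-type FVB vs transgenic Tgaq*44) ageing
#' design: genotype x age groups, negative-binomial counts parameterised by
#' (mean, dispersion) with `variance = mean + dispersion * mean^2`, and four
#' kinds of planted differential-expression sets (all disjoint):
#'
#' * `aged_only` — genes shifted (both genotypes) at 14 months only, so they
#'   are DE exclusively in the oldest wild-type comparison;
#' * `ageing` — genes shifted from an onset age (cycled over 6/8/10/12
#'   months) onwards, so they are DE at 14 months and at least one younger
#'   age;
#' * `hf_persistent` — genes shifted in the transgenic genotype at every age;
#' * `hf_age_specific` — genes shifted in the transgenic genotype at a single
#'   age (cycled over the ages present).
#'
#' The default design mirrors the sequenced-cohort structure: 54,532
#' reference genes, ages 4-14 months in 2-month steps for both genotypes,
#' n = 5 per group (per-group sizes being a modelling choice).
#'
#' @param n_genes Number of genes.
#' @param groups Tibble/data frame with columns `genotype`, `age`, `n`
#'   (samples per group, each at least 2).
#' @param lib_size_meanlog,lib_size_sdlog Log-normal library-size parameters.
#' @param nb_dispersion NB dispersion (positive).
#' @param planted Named list of planted sets; each element is
#'   `list(n = <genes>, lfc = <log2 fold change>)`. Names among `aged_only`,
#'   `ageing`, `hf_persistent`, `hf_age_specific`. Use `n = 0` to omit a set.
#' @param planted_min_cpm Baseline expression floor (cpm) for planted genes:
#'   a differential signature is only a meaningful ground truth in genes
#'   expressed above the detection floor, so planted genes get at least this
#'   baseline abundance (default 5 cpm).
#' @param seed Integer seed.
#' @return A list of class `count_sim_config`.
#' @export
count_sim_config <- function(n_genes = 54532,
                             groups = tidyr::expand_grid(
                               genotype = c("FVB", "Tg"),
                               age = c(4, 6, 8, 10, 12, 14)) |>
                               dplyr::mutate(n = 5L),
                             lib_size_meanlog = log(2e6), lib_size_sdlog = 0.15,
                             nb_dispersion = 0.05,
                             planted = list(aged_only = list(n = 50, lfc = 2.5),
                                            ageing = list(n = 50, lfc = 2.5),
                                            hf_persistent = list(n = 0, lfc = 2.5),
                                            hf_age_specific = list(n = 0, lfc = 2.5)),
                             planted_min_cpm = 5, seed = 1) {
  groups <- as_tibble(groups)
  stopifnot(all(c("genotype", "age", "n") %in% names(groups)))
  if (any(groups$n < 2)) abort("each group needs n >= 2.")
  check_number(nb_dispersion, "nb_dispersion", 0, strict = TRUE)
  bad <- setdiff(names(planted),
                 c("aged_only", "ageing", "hf_persistent", "hf_age_specific"))
  if (length(bad)) abort(paste("unknown planted set(s):", paste(bad, collapse = ", ")))
  total_planted <- sum(vapply(planted, function(p) p$n, numeric(1)))
  if (total_planted > n_genes / 2) abort("too many planted genes for `n_genes`.")
  for (p in planted) if (!is.finite(p$lfc)) abort("planted logFC must be finite.")
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 lib_size_meanlog = lib_size_meanlog,
                 lib_size_sdlog = lib_size_sdlog,
                 nb_dispersion = nb_dispersion, planted = planted,
                 planted_min_cpm = planted_min_cpm, seed = seed),
            class = "count_sim_config")
}

#' Generate an NB count matrix with planted differential expression
#'
#' Per-gene baseline relative abundances are drawn from a gamma distribution,
#' per-sample library sizes from a log-normal; counts are negative-binomial
#' with `mu = abundance * lib_size * 2^lfc` on planted genes in their target
#' conditions and `size = 1 / dispersion`.
#'
#' @param config A [count_sim_config()].
#' @return A list with `counts` (integer matrix, genes x samples), `samples`
#'   (tibble: `sample`, `genotype`, `age`) and `truth` (a [truth_record()]
#'   with a `planted` tibble: `gene_id`, `set`, `lfc`, `onset_age` /
#'   `target_age` where applicable).
#' @export
sim_count_matrix <- function(config) {
  stopifnot(inherits(config, "count_sim_config"))
  withr::with_seed(substream_seed(config$seed, "counts"), {
    ng <- config$n_genes
    gene_ids <- sprintf("gene%06d", seq_len(ng))
    groups <- config$groups
    samples <- tidyr::uncount(groups, weights = .data$n) |>
      dplyr::group_by(.data$genotype, .data$age) |>
      dplyr::mutate(rep = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::mutate(sample = sprintf("%s_%02dm_r%d", .data$genotype, .data$age, .data$rep)) |>
      dplyr::select("sample", "genotype", "age")
    ns <- nrow(samples)

    abund <- rgamma(ng, shape = 0.45, rate = 1)
    abund <- abund / sum(abund)
    libs <- rlnorm(ns, config$lib_size_meanlog, config$lib_size_sdlog)

    # assign planted genes (disjoint blocks at the top of the gene list)
    ages <- sort(unique(groups$age))
    young <- setdiff(ages, c(min(ages), max(ages)))
    planted <- list()
    nxt <- 1L
    take <- function(k) {
      idx <- seq.int(nxt, length.out = k)
      nxt <<- nxt + k
      idx
    }
    pl <- config$planted
    add <- function(set, idx, lfc, onset = NA_real_, target = NA_real_) {
      tibble(gene_id = gene_ids[idx], gene_index = idx, set = set, lfc = lfc,
             onset_age = onset, target_age = target)
    }
    rows <- list()
    if (!is.null(pl$aged_only) && pl$aged_only$n > 0) {
      idx <- take(pl$aged_only$n)
      rows <- c(rows, list(add("aged_only", idx, pl$aged_only$lfc,
                               onset = max(ages))))
    }
    if (!is.null(pl$ageing) && pl$ageing$n > 0) {
      idx <- take(pl$ageing$n)
      onset <- rep(young, length.out = length(idx))
      rows <- c(rows, list(add("ageing", idx, pl$ageing$lfc, onset = onset)))
    }
    if (!is.null(pl$hf_persistent) && pl$hf_persistent$n > 0) {
      idx <- take(pl$hf_persistent$n)
      rows <- c(rows, list(add("hf_persistent", idx, pl$hf_persistent$lfc)))
    }
    if (!is.null(pl$hf_age_specific) && pl$hf_age_specific$n > 0) {
      idx <- take(pl$hf_age_specific$n)
      rows <- c(rows, list(add("hf_age_specific", idx, pl$hf_age_specific$lfc,
                               target = rep(ages, length.out = length(idx)))))
    }
    planted <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble(gene_id = character(), gene_index = integer(), set = character(),
             lfc = numeric(), onset_age = numeric(), target_age = numeric())

    # planted genes are expressed genes: enforce the baseline cpm floor
    if (nrow(planted) && config$planted_min_cpm > 0) {
      floor_ab <- config$planted_min_cpm / 1e6
      abund[planted$gene_index] <- pmax(abund[planted$gene_index], floor_ab)
      abund <- abund / sum(abund)
    }

    # per-gene x per-sample log2 effects
    lfc_mat <- matrix(0, ng, ns)
    if (nrow(planted)) {
      for (r in seq_len(nrow(planted))) {
        g <- planted$gene_index[r]
        on <- switch(planted$set[r],
          aged_only = samples$age == max(ages),
          ageing = samples$age >= planted$onset_age[r],
          hf_persistent = samples$genotype != "FVB",
          hf_age_specific = samples$genotype != "FVB" &
            samples$age == planted$target_age[r])
        lfc_mat[g, on] <- planted$lfc[r]
      }
    }

    mu <- (abund %o% libs) * 2^lfc_mat
    counts <- matrix(rnbinom(ng * ns, mu = mu, size = 1 / config$nb_dispersion),
                     ng, ns, dimnames = list(gene_ids, samples$sample))
    truth <- truth_record("count_matrix",
                          planted = planted[setdiff(names(planted), "gene_index")],
                          lib_sizes = setNames(libs, samples$sample),
                          nb_dispersion = config$nb_dispersion,
                          seed = config$seed)
    list(counts = counts, samples = samples, truth = truth)
  })
}
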