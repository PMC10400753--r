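# Count simulation, TMM normalization, filtering and the simplified DE engine.

test_that("simulated counts are non-negative integers, deterministic per
           seed, and NB moments check out", {
  cfg <- count_sim_config(n_genes = 300,
                          groups = tibble::tibble(genotype = "FVB", age = 4, n = 200),
                          planted = list(), nb_dispersion = 0.2,
                          lib_size_sdlog = 0, seed = 8)
  sim <- sim_count_matrix(cfg)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  sim2 <- sim_count_matrix(cfg)
  expect_identical(sim$counts, sim2$counts)

  # moment check at n = 200: var ~ mean + 0.2 mean^2 for well-expressed genes
  mu <- rowMeans(sim$counts)
  v <- apply(sim$counts, 1, var)
  hi <- mu > 50
  ratio <- v[hi] / (mu[hi] + 0.2 * mu[hi]^2)
  expect_gt(length(ratio), 20)
  expect_equal(median(ratio), 1, tolerance = 0.15)
})

test_that("null simulations show no systematic group difference", {
  cfg <- count_sim_config(n_genes = 400,
                          groups = tibble::tibble(genotype = "FVB",
                                                  age = c(4, 14), n = 30),
                          planted = list(), nb_dispersion = 0.05, seed = 2)
  sim <- sim_count_matrix(cfg)
  norm <- normalize_counts(sim$counts)
  de <- differential_expression(
    norm, sim$samples$sample[sim$samples$age == 14],
    sim$samples$sample[sim$samples$age == 4])
  expect_lt(mean(abs(de$logfc), na.rm = TRUE), 0.15)
  expect_lt(mean(de$is_deg), 0.01)
})

test_that("TMM factors are 1 for identical and purely scaled libraries, and
           match a hand computation of the trimmed weighted M-mean", {
  x <- matrix(rpois(600, 40), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  same <- x[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  f_same <- normalize_counts(same)$factors$tmm_factor
  expect_equal(f_same, rep(1, 3), tolerance = 1e-9)

  scaled <- cbind(a = x[, 1], b = 2 * x[, 1])
  f_scaled <- normalize_counts(scaled)$factors$tmm_factor
  expect_equal(f_scaled, rep(1, 2), tolerance = 1e-9)

  # independent hand computation on a 2-sample matrix (published defaults:
  # 30% two-sided trim on M, 5% on A, precision weights)
  withr::with_seed(21, {
    y <- matrix(rnbinom(60, mu = 200, size = 5) + 1, 30, 2,
                dimnames = list(sprintf("g%02d", 1:30), c("a", "b")))
  })
  y[1:5, 2] <- y[1:5, 2] * 6 # composition bias
  Na <- sum(y[, 1]); Nb <- sum(y[, 2])
  M <- log2((y[, 2] / Nb) / (y[, 1] / Na))
  A <- 0.5 * log2((y[, 2] / Nb) * (y[, 1] / Na))
  w <- (Nb - y[, 2]) / (Nb * y[, 2]) + (Na - y[, 1]) / (Na * y[, 1])
  n <- length(M)
  loM <- floor(n * 0.30) + 1; hiM <- n - floor(n * 0.30)
  loA <- floor(n * 0.05) + 1; hiA <- n - floor(n * 0.05)
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  f_b_over_a <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  want <- sqrt(c(1 / f_b_over_a, f_b_over_a)) # geometric mean 1
  got <- normalize_counts(y)$factors$tmm_factor
  expect_equal(got, unname(want), tolerance = 1e-6)
})

test_that("cpm filter retains exactly the genes passing the rule and the
           summary percentage is exact", {
  # toy matrix with constructed cpm patterns (a large filler gene fixes the
  # library scale so cpm ~ count), evaluated against a brute-force reading
  # of the rule
  counts <- matrix(0L, 20, 10,
                   dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  counts[1:6, 1:5] <- 400L   # above threshold in > 3 samples of group A
  counts[7, 1:3] <- 400L     # only 3 samples above -> fails (needs > 3)
  counts[8, 6:9] <- 400L     # 4 samples of group B -> passes
  counts[9, c(4, 5, 6, 7)] <- 400L # 2 + 2 split across groups -> fails
  counts[10, 1:5] <- 1L      # cpm ~ 1 > 0.5 -> passes
  counts[20, ] <- 1000000L   # filler: library ~ 1e6
  samples <- tibble::tibble(sample = colnames(counts),
                            genotype = rep(c("FVB", "Tg"), each = 5),
                            age = 4)
  norm <- normalize_counts(counts)
  flt <- filter_genes(norm, samples)
  brute <- sapply(rownames(counts), function(g) {
    any(sapply(split(samples$sample, paste(samples$genotype, samples$age)),
               function(cols) sum(norm$cpm[g, cols] > 0.5) > 3))
  })
  expect_equal(flt$keep, unname(brute))
  sm <- attr(flt, "summary")
  expect_equal(sm$pct_retained, round(100 * sum(brute) / 20, 2))
  expect_false(flt$keep[flt$gene_id == "g07"])
  expect_false(flt$keep[flt$gene_id == "g09"])
  expect_true(all(flt$keep[c(1:6, 8, 10)]))
  expect_false(flt$keep[flt$gene_id == "g11"]) # all-zero gene removed
})

test_that("the DEG rule is strict: |logFC| exactly 1 is not flagged", {
  # exact cpm values constructed directly: cpm_a + 0.5 = 21 and
  # cpm_b + 0.5 = 42 give logFC = 1 exactly
  cpm <- rbind(gexact = c(20.5, 20.5, 20.5, 41.5, 41.5, 41.5),
               gother = c(10, 11, 12, 10, 11, 12))
  colnames(cpm) <- paste0("s", 1:6)
  norm <- structure(list(cpm = cpm), class = "norm_counts")
  de <- differential_expression(norm, paste0("s", 4:6), paste0("s", 1:3))
  row <- de[de$gene_id == "gexact", ]
  expect_equal(row$logfc, 1, tolerance = 1e-12)
  expect_true(row$var_floored)
  expect_lt(row$adj_p, 0.05)
  expect_false(row$is_deg) # strict inequality on |logFC|
})

test_that("planted fold changes of 3 log2 units are flagged in >= 95% of
           planted genes", {
  cfg <- count_sim_config(n_genes = 1500,
                          groups = tibble::tibble(genotype = "FVB",
                                                  age = c(4, 14), n = 6),
                          planted = list(aged_only = list(n = 60, lfc = 3)),
                          nb_dispersion = 0.05, seed = 1)
  sim <- sim_count_matrix(cfg)
  norm <- normalize_counts(sim$counts)
  flt <- filter_genes(norm, sim$samples, min_samples = 3)
  de <- differential_expression(
    norm, sim$samples$sample[sim$samples$age == 14],
    sim$samples$sample[sim$samples$age == 4],
    genes = flt$gene_id[flt$keep])
  hits <- deg_genes(de)
  planted <- sim$truth$planted$gene_id
  expect_gte(mean(planted %in% hits), 0.95)
})

test_that("zero-library samples and undersized groups error", {
  counts <- matrix(c(0L, 0L, 5L, 7L), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  counts[, 1] <- 0L
  expect_error(normalize_counts(counts), "zero library")
  ok <- matrix(rpois(40, 20), 10, 4,
               dimnames = list(sprintf("g%d", 1:10), paste0("s", 1:4)))
  norm <- normalize_counts(ok)
  expect_error(differential_expression(norm, "s1", c("s2", "s3")), "at least 2")
})
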