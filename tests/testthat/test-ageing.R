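# Ageing/aged partition, contribution statistics, Fisher ORA, rank PCA.

test_that("the ageing partition follows the set logic and its invariants", {
  mk <- function(g) sprintf("gene%04d", g)
  # 454 genes exclusive to the oldest comparison, 481 shared with younger
  excl <- mk(1:454)
  shared <- mk(455:935)
  deg14 <- c(excl, shared)
  degs <- list(`6` = shared[1:200], `8` = shared[150:300],
               `10` = shared[250:400], `12` = shared[350:481],
               `14` = deg14)
  part <- classify_ageing_genes(degs)
  expect_equal(length(part$cardiac_ageing), 935)
  expect_equal(length(part$aged_only), 454)
  expect_equal(length(part$ageing), 481)
  expect_length(intersect(part$aged_only, part$ageing), 0)
  expect_setequal(union(part$aged_only, part$ageing), part$cardiac_ageing)

  # degenerate cases forced by the set algebra
  empty <- classify_ageing_genes(list(`6` = mk(1:5), `8` = character(),
                                      `10` = character(), `12` = character(),
                                      `14` = character()))
  expect_length(empty$cardiac_ageing, 0)
  sub <- classify_ageing_genes(list(`6` = mk(1:10), `8` = character(),
                                    `10` = character(), `12` = character(),
                                    `14` = mk(1:4)))
  expect_length(sub$aged_only, 0)
  expect_setequal(sub$ageing, mk(1:4))
  expect_error(classify_ageing_genes(list(`6` = mk(1), `14` = mk(1))),
               "missing comparison")
})

test_that("partition invariants hold over randomly generated DEG lists", {
  withr::with_seed(10, {
    for (i in 1:25) {
      pool <- sprintf("g%04d", 1:400)
      degs <- lapply(setNames(1:5, c("6", "8", "10", "12", "14")),
                     function(j) sample(pool, rpois(1, 60)))
      part <- classify_ageing_genes(degs)
      expect_length(intersect(part$aged_only, part$ageing), 0)
      expect_setequal(union(part$aged_only, part$ageing), unique(degs[["14"]]))
      expect_true(all(part$cardiac_ageing %in% degs[["14"]]))
    }
  })
})

test_that("contribution fractions count overlaps and ignore absent genes", {
  part <- classify_ageing_genes(list(
    `6` = sprintf("a%d", 1:26), `8` = character(), `10` = character(),
    `12` = character(),
    `14` = c(sprintf("a%d", 1:26), sprintf("b%d", 1:8))))
  # a 156-gene persistent set containing all 8 aged-only and 26 ageing genes
  hf <- c(sprintf("b%d", 1:8), sprintf("a%d", 1:26), sprintf("x%d", 1:122))
  got <- contribution_fraction(part, hf)
  expect_equal(got$n_overlap, 34)
  expect_equal(got$n_hf, 156)
  expect_equal(got$percent, 100 * 34 / 156)
  # disjoint and nested cases
  expect_equal(contribution_fraction(part, sprintf("z%d", 1:10))$percent, 0)
  expect_equal(contribution_fraction(part, sprintf("a%d", 1:5))$percent, 100)
  # genes absent from both sets leave the value unchanged
  with_extra <- contribution_fraction(part, hf)
  expect_equal(with_extra$percent, got$percent)
  expect_warning(und <- contribution_fraction(part, character()), "empty")
  expect_true(is.na(und$percent))
})

test_that("Fisher enrichment p-values match hypergeometric enumeration and
           BH behaves", {
  bg <- sprintf("g%02d", 1:10)
  ann <- list(t1 = bg[1:4])
  # overlap 4 of term 4, query 5: p = C(4,4) C(6,1) / C(10,5) = 6/252
  res <- overrepresentation(bg[1:5], bg, ann)
  expect_equal(res$p, 6 / 252, tolerance = 1e-12)
  expect_equal(res$adj_p, res$p) # BH identity for a single term
  # zero overlap: one-sided p = 1
  res0 <- overrepresentation(bg[5:8], bg, list(t1 = bg[1:4]))
  expect_equal(res0$p, 1)
  expect_error(overrepresentation(c("zz"), bg, ann), "subset")
  expect_error(overrepresentation(bg[1], character(), ann), "empty")
})

test_that("BH adjustment is invariant to the order of the input terms", {
  withr::with_seed(4, {
    bg <- sprintf("g%03d", 1:100)
    ann <- lapply(setNames(1:12, paste0("t", 1:12)),
                  function(i) sample(bg, 25))
    q <- sample(bg, 30)
    r1 <- overrepresentation(q, bg, ann)
    r2 <- overrepresentation(q, bg, ann[sample(12)])
    m <- match(r1$term, r2$term)
    expect_equal(r1$adj_p, r2$adj_p[m], tolerance = 1e-12)
  })
})

test_that("annotation coverage reports the annotated percentage", {
  genes <- sprintf("g%d", 1:50)
  ann <- list(a = genes[1:30], b = genes[20:42])
  cov <- annotation_coverage(genes, ann)
  expect_equal(cov$n_annotated, 42)
  expect_equal(cov$pct_annotated, 84)
})

test_that("rank-normalised PCA is invariant to monotone transforms and
           duplicates map to equal scores", {
  withr::with_seed(6, {
    x <- matrix(rlnorm(30 * 12, 5, 1), 30, 12,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12)))
  })
  p1 <- ageing_pca(x, rownames(x))
  p2 <- ageing_pca(exp(x / 100), rownames(x)) # monotone transform
  expect_equal(p1$scores$PC1, p2$scores$PC1, tolerance = 1e-9)
  expect_equal(p1$var_explained, p2$var_explained, tolerance = 1e-9)
  # scores are centred, variance fractions non-increasing
  expect_lt(abs(mean(p1$scores$PC1)), 1e-9)
  expect_true(all(diff(p1$var_explained) <= 1e-12))
  # duplicate sample -> equal scores
  xd <- cbind(x, dup = x[, 1])
  pd <- ageing_pca(xd, rownames(x))
  expect_equal(unlist(pd$scores[pd$scores$sample == "dup", -1]),
               unlist(pd$scores[pd$scores$sample == "s01", -1]),
               tolerance = 1e-9)
  # constant gene dropped with warning
  xc <- x; xc[1, ] <- 7
  expect_warning(pc <- ageing_pca(xc, rownames(x)), "constant")
  expect_false("g01" %in% pc$genes_used)
})

test_that("two planted sample clusters separate on PC1", {
  withr::with_seed(9, {
    base <- matrix(rlnorm(40 * 10, 4, 0.3), 40, 10,
                   dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:10)))
    base[1:20, 6:10] <- base[1:20, 6:10] * 8
  })
  pc <- ageing_pca(base, rownames(base))
  side <- sign(pc$scores$PC1)
  expect_true(all(side[1:5] == side[1]) && all(side[6:10] == -side[1]))
})
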