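# a classifier whose hidden layer is kept in its linear region, so the
# class-2 logit is exactly w'x + const
linear_classifier <- function(w, shift = 100) {
  d <- length(w)
  list(params = list(W1 = diag(d), b1 = rep(shift, d),
                     W2 = cbind(0, w), b2 = c(0, 0)),
       levels = c("a", "b"), center = NULL, scale = NULL)
}

test_that("expected gradients recover the exact linear closed form", {
  set.seed(1)
  m <- 6
  w <- rnorm(m)
  cls <- linear_classifier(w)
  x <- matrix(runif(3 * m, 0, 2), 3)
  base <- matrix(runif(5 * m, 0, 2), 5)
  res <- gradient_attribution(NULL, cls, x, base,
                              target_class = rep(2L, 3),
                              n_baselines = 5L, n_points = 4L, seed = 2)
  want <- sweep(x, 2L, colMeans(base), "-") * rep(w, each = 3)
  expect_equal(res$attributions, want, tolerance = 1e-9)
})

test_that("zero-influence inputs receive zero attribution", {
  w <- c(1.5, 0, -2)
  cls <- linear_classifier(w)
  x <- matrix(runif(4 * 3, 0, 2), 4)
  base <- matrix(runif(6 * 3, 0, 2), 6)
  res <- gradient_attribution(NULL, cls, x, base, target_class = rep(2L, 4),
                              n_baselines = 6L, n_points = 3L, seed = 1)
  expect_equal(res$attributions[, 2], rep(0, 4))
})

test_that("attributions satisfy completeness for the linear score", {
  set.seed(4)
  m <- 5
  w <- rnorm(m)
  cls <- linear_classifier(w)
  x <- matrix(runif(2 * m, 0, 2), 2)
  base <- matrix(runif(8 * m, 0, 2), 8)
  res <- gradient_attribution(NULL, cls, x, base, target_class = rep(2L, 2),
                              n_baselines = 8L, n_points = 5L, seed = 3)
  score <- function(xm) as.numeric(xm %*% w)
  want <- score(x) - mean(score(base))
  expect_equal(rowSums(res$attributions), want, tolerance = 1e-9)
})

test_that("attribution flows through the SNP encoder and is finite", {
  tp <- tiny_pipeline(3)
  ds <- tp$ds
  z <- snp_latents(tp$pipeline, ds$genotypes$G[ds$train_idx, ])
  cls <- mlp_train(z, ds$labels$nose_protrusion[ds$train_idx], epochs = 50L)
  res <- gradient_attribution(tp$pipeline$snp, cls,
                              ds$genotypes$G[ds$test_idx[1:3], ],
                              ds$genotypes$G[ds$train_idx, ],
                              n_baselines = 2L, n_points = 2L, seed = 1)
  expect_equal(dim(res$attributions), c(3L, 30L))
  expect_true(all(is.finite(res$attributions)))
  expect_length(res$mean_abs, 30L)
})

test_that("top-k selection is deterministic with documented tie-breaks", {
  expect_identical(select_top_snps(c(3, 1, 2), 3L), 1:3)
  expect_identical(select_top_snps(c(3, 1, 2), 2L), c(1L, 3L))
  expect_identical(select_top_snps(rep(1, 5), 3L), 1:3)
  expect_error(select_top_snps(c(1, 2), 0L), "positive")
  expect_error(select_top_snps(c(1, 2), 5L), "panel")
  # independent-loci filter keeps the best-scoring SNP per locus
  sc <- c(5, 9, 1, 7)
  tags <- c("L1", "L1", "L2", "L2")
  expect_identical(select_top_snps(sc, 2L, locus_tags = tags), c(2L, 4L))
})

test_that("hypergeometric p-values match exhaustive subset enumeration", {
  # panel 10, |gwas| = 5, |top| = 5, overlap 5 -> 1 / choose(10, 5)
  r <- hypergeometric_enrichment(1:5, 1:5, 10L)
  expect_equal(r$overlap, 5L)
  expect_equal(r$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(hypergeometric_enrichment(6:10, 1:5, 10L)$p_value, 1)
  # exhaustive oracle on all panels <= 12: enumerate every k-subset
  for (case in list(c(8, 3, 4), c(10, 5, 3), c(12, 6, 5))) {
    panel <- case[1]; ng <- case[2]; nt <- case[3]
    gwas <- seq_len(ng)
    subsets <- utils::combn(panel, nt)
    for (ov_target in 0:min(ng, nt)) {
      ge_count <- sum(apply(subsets, 2, function(s) {
        length(intersect(s, gwas)) >= ov_target
      }))
      want <- ge_count / ncol(subsets)
      top <- c(seq_len(ov_target),
               seq(ng + 1, length.out = nt - ov_target))
      got <- hypergeometric_enrichment(top, gwas, panel)
      expect_equal(got$overlap, ov_target)
      expect_equal(got$p_value, want, tolerance = 1e-12)
    }
  }
  expect_warning(r0 <- hypergeometric_enrichment(integer(0), 1:3, 10L), "empty")
  expect_equal(r0$p_value, 1)
})

test_that("larger-panel tail probabilities match a direct PMF sum", {
  # panel 100, |gwas| = 10, |top| = 10, overlap 3
  want <- sum(stats::dhyper(3:10, 10, 90, 10))
  got <- hypergeometric_enrichment(c(1:3, 51:57), 1:10, 100L)
  expect_equal(got$overlap, 3L)
  expect_equal(got$p_value, want, tolerance = 1e-12)
})
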