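test_that("panel subsampling retains exactly floor(f*m) columns", {
  set.seed(1)
  G <- matrix(sample(0:2, 20 * 10, TRUE), 20)
  for (f in c(0.1, 0.35, 0.5, 0.9, 1)) {
    sub <- subsample_panel(G, f, seed = 3)
    expect_equal(sub$count, floor(f * 10))
    expect_length(sub$retained, floor(f * 10))
  }
  expect_equal(subsample_panel(G, 0.7, seed = 1, impute_means = colMeans(G))$count,
               floor(0.7 * 10))
  expect_error(subsample_panel(G, 0), "fraction")
  expect_error(subsample_panel(G, 1.2), "fraction")
})

test_that("the printed panel arithmetic holds: 70% of 7842 SNPs is 5489", {
  G1 <- matrix(0, 1, 7842)
  expect_equal(subsample_panel(G1, 0.7, seed = 1)$count, 5489L)
})

test_that("full retention is the identity and masking is deterministic", {
  set.seed(2)
  G <- matrix(sample(0:2, 8 * 10, TRUE), 8)
  expect_equal(subsample_panel(G, 1, seed = 5)$G, G, ignore_attr = TRUE)
  s1 <- subsample_panel(G, 0.5, seed = 9)
  s2 <- subsample_panel(G, 0.5, seed = 9)
  expect_identical(s1$retained, s2$retained)
  expect_identical(s1$G, s2$G)
  # dropped columns hold the imputation value
  dropped <- setdiff(seq_len(10), s1$retained)
  for (j in dropped) expect_true(all(s1$G[, j] == mean(G[, j])))
  # training-set means can be supplied
  mu <- rep(0.5, 10)
  s3 <- subsample_panel(G, 0.5, seed = 9, impute_means = mu)
  for (j in dropped) expect_true(all(s3$G[, j] == 0.5))
})

test_that("the dropout curve runs the generation path per fraction and region", {
  tp <- tiny_pipeline(4)
  pipe <- tp$pipeline
  curve <- dropout_curve(pipe, tp$ds, fractions = c(0.6, 0.3), seeds = 1L)
  expect_setequal(unique(curve$fraction), c(1, 0.6, 0.3))
  expect_setequal(unique(curve$region), c("whole", "nose", "eyes", "face"))
  expect_true(all(curve$mean_error_mm >= 0))
  expect_equal(curve$count[curve$fraction == 0.6][1], floor(0.6 * 30))
  # a full-retention-only curve equals the unmasked generation evaluation
  curve1 <- dropout_curve(pipe, tp$ds, fractions = numeric(0), seeds = 1L)
  gen <- generate_faces(pipe, tp$ds$genotypes$G[tp$ds$test_idx, ], seed = 1001L)
  true <- tp$ds$shapes[tp$ds$test_idx, , , drop = FALSE]
  manual <- mean(vapply(seq_len(dim(gen)[1]), function(i) {
    mean(sqrt(rowSums((gen[i, , ] - true[i, , ])^2)))
  }, numeric(1)))
  expect_equal(curve1$mean_error_mm[curve1$fraction == 1 &
                                      curve1$region == "whole"],
               manual, tolerance = 1e-9)
})

test_that("generation from genotypes is deterministic given the seed", {
  tp <- tiny_pipeline(5)
  G <- tp$ds$genotypes$G[1:3, ]
  g1 <- generate_faces(tp$pipeline, G, seed = 11)
  g2 <- generate_faces(tp$pipeline, G, seed = 11)
  expect_identical(g1, g2)
  expect_equal(dim(g1), c(3L, 42L, 3L))
})
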