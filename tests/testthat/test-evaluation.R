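test_that("identification rates behave at the extremes", {
  expect_equal(identification_rates(diag(10), 1)[["R1"]], 100)
  N <- 100
  anti <- matrix(0, N, N)
  anti[cbind(1:N, N:1)] <- 1  # best match always wrong
  expect_equal(identification_rates(anti, 1)[["R1"]], 0)
  set.seed(2)
  r <- identification_rates(matrix(rnorm(100^2), 100), 100)
  expect_equal(r[["R100"]], 100)
})

test_that("random scores give chance-level rank-k rates", {
  set.seed(7)
  sim <- matrix(rnorm(500 * 500), 500)
  r <- identification_rates(sim, 10)[["R10"]]
  expect_lt(abs(r - 10), 4)  # ~3 binomial sd
})

test_that("verification metrics hit the separable and degenerate limits", {
  sim <- matrix(-1, 5, 5); diag(sim) <- 1
  v <- verification_metrics(sim)
  expect_equal(v[["EER"]], 0)
  expect_equal(v[["AUC"]], 100)
  expect_equal(verification_metrics(matrix(0.3, 4, 4)),
               c(EER = 50, AUC = 50))
  set.seed(1)
  vv <- verification_metrics(list(genuine = rnorm(4000), impostor = rnorm(4000)))
  expect_lt(abs(vv[["AUC"]] - 50), 2.5)
  expect_lt(abs(vv[["EER"]] - 50), 2.5)
})

test_that("a hand-built 4x4 score matrix matches an exhaustive threshold oracle", {
  sim <- rbind(c(0.9, 0.2, 0.1, 0.4),
               c(0.3, 0.6, 0.5, 0.2),
               c(0.1, 0.7, 0.8, 0.3),
               c(0.2, 0.1, 0.6, 0.55))
  genuine <- diag(sim)
  impostor <- sim[row(sim) != col(sim)]
  # oracle ROC over all thresholds (step function), trapezoid AUC
  thr <- sort(unique(c(genuine, impostor)), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(s) mean(genuine >= s), numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(s) mean(impostor >= s), numeric(1)), 1)
  auc_o <- 100 * sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  got <- verification_metrics(sim)
  expect_equal(got[["AUC"]], auc_o, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  roc <- pROC::roc(c(rep(1, 4), rep(0, 12)), c(genuine, impostor),
                   quiet = TRUE)
  expect_equal(got[["AUC"]], 100 * as.numeric(pROC::auc(roc)),
               tolerance = 1e-9)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  sim <- matrix(rnorm(30 * 30), 30)
  a <- verification_metrics(sim)
  b <- verification_metrics(tanh(sim / 2) * 3 + 1)
  expect_equal(a[["AUC"]], b[["AUC"]], tolerance = 1e-9)
  expect_equal(a[["EER"]], b[["EER"]], tolerance = 1e-9)
})

test_that("geometry errors: zero, rigid offset, chamfer oracle", {
  m <- tetra_mesh()
  e0 <- geometry_errors(m, m)
  expect_equal(e0$mean, 0)
  expect_equal(e0$rmse, 0)
  expect_equal(e0$chamfer, 0)
  shifted <- m$vertices + matrix(rep(c(3, 0, 0), each = 4), 4)
  e1 <- geometry_errors(shifted, m$vertices)
  expect_equal(e1$mean, 3, tolerance = 1e-12)
  expect_equal(e1$rmse, 3, tolerance = 1e-12)
  set.seed(3)
  a <- matrix(rnorm(15), 5)
  b <- matrix(rnorm(15), 5)
  # brute-force all-pairs chamfer oracle
  D <- as.matrix(dist(rbind(a, b)))[1:5, 6:10]
  want <- (mean(apply(D, 1, min)) + mean(apply(D, 2, min))) / 2
  expect_equal(chamfer_distance(a, b), want, tolerance = 1e-9)
  expect_error(geometry_errors(a, matrix(rnorm(12), 4)), "topology")
})

test_that("landmark error table reports per-landmark distances", {
  m <- tetra_mesh()
  shifted <- m$vertices
  shifted[2, ] <- shifted[2, ] + c(0, 4, 0)
  ge <- geometry_errors(shifted, m$vertices, landmarks = c(apex = 2L, base = 3L))
  expect_equal(ge$landmark_table$error_mm, c(4, 0))
})

test_that("DPP diversity follows the kernel determinant", {
  expect_equal(dpp_diversity(matrix(1:3, 1), jitter = 0), 1)
  two_same <- list(matrix(0, 4, 3), matrix(0, 4, 3))
  expect_equal(dpp_diversity(two_same, jitter = 0), 0)
  # two items at mesh distance 1: det [[1, .5], [.5, 1]] = 0.75
  a <- matrix(0, 4, 3)
  b <- a; b[, 1] <- 1
  expect_equal(dpp_diversity(list(a, b), jitter = 0), 0.75, tolerance = 1e-12)
  # permutation invariance and monotonicity in separation
  set.seed(5)
  items <- lapply(1:4, function(i) matrix(rnorm(12), 4))
  d1 <- dpp_diversity(items, jitter = 0)
  d2 <- dpp_diversity(items[c(3, 1, 4, 2)], jitter = 0)
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_lte(d1, 1)
  far <- list(a, b + 9)
  expect_gt(dpp_diversity(far, jitter = 0), 0.75)
})

test_that("feature classification separates separable labels and not shuffled ones", {
  set.seed(8)
  z_tr <- matrix(rnorm(300 * 4), 300)
  z_te <- matrix(rnorm(150 * 4), 150)
  lab_tr <- data.frame(sep = factor(ifelse(z_tr[, 1] > 0, "pos", "neg")))
  lab_te <- data.frame(sep = factor(ifelse(z_te[, 1] > 0, "pos", "neg")))
  fc <- feature_classification(z_tr, lab_tr, z_te, z_te, lab_te,
                               epochs = 200L, seed = 1)
  expect_gt(fc$acc_real, 95)
  expect_equal(fc$acc_real, fc$acc_gen)
  shuf <- data.frame(sep = sample(lab_tr$sep))
  fc2 <- feature_classification(z_tr, shuf, z_te, z_te,
                                data.frame(sep = sample(lab_te$sep)),
                                epochs = 120L, seed = 1)
  expect_lt(fc2$acc_real, 65)
  lab1 <- data.frame(mono = factor(rep("only", 300)))
  expect_warning(
    fc3 <- feature_classification(z_tr, lab1, z_te, z_te,
                                  data.frame(mono = factor(rep("only", 150)))),
    "single class")
  expect_null(fc3)
})
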