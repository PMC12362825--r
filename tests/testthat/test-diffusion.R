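test_that("schedules satisfy their invariants", {
  s <- make_schedule(1L, beta_start = 0.5, beta_end = 0.5)
  expect_equal(s$alpha_bars, 0.5)
  s <- make_schedule(1000L)
  expect_lt(s$alpha_bars[1000], 1e-4)
  expect_true(all(diff(s$alpha_bars) < 0))
  expect_true(all(s$betas > 0 & s$betas < 1))
  sc <- make_schedule(100L, kind = "cosine")
  expect_true(all(diff(sc$alpha_bars) < 0))
  expect_error(make_schedule(0L), "T")
})

test_that("q_sample returns z0 exactly at t = 0 and is seed-deterministic", {
  s <- make_schedule(10L)
  z0 <- matrix(1:6 / 2, 2)
  expect_equal(q_sample(z0, 0L, s), z0)
  expect_identical(q_sample(z0, 5L, s, seed = 9), q_sample(z0, 5L, s, seed = 9))
})

test_that("q_sample moments match the closed-form marginal", {
  s <- make_schedule(50L)
  t <- 20L
  z0 <- 1.7
  n <- 1e5
  set.seed(4)
  draws <- q_sample(matrix(z0, n, 1), rep(t, n), s,
                    noise = matrix(rnorm(n), n))
  ab <- s$alpha_bars[t]
  expect_lt(abs(mean(draws) - sqrt(ab) * z0), 4 * sqrt(1 - ab) / sqrt(n))
  expect_lt(abs(stats::var(draws) - (1 - ab)) / (1 - ab), 0.05)
})

test_that("iterating the stepwise corruption matches the one-shot marginal", {
  s <- make_schedule(5L, beta_start = 0.05, beta_end = 0.3)
  n <- 1e5
  z0 <- 0.9
  set.seed(11)
  z <- rep(z0, n)
  for (t in 1:5) {
    z <- sqrt(1 - s$betas[t]) * z + sqrt(s$betas[t]) * rnorm(n)
  }
  ab <- s$alpha_bars[5]
  expect_lt(abs(mean(z) - sqrt(ab) * z0), 4 * sqrt(1 - ab) / sqrt(n))
  expect_lt(abs(stats::var(z) - (1 - ab)) / (1 - ab), 0.05)
})

test_that("posterior mean collapses correctly on noise-free points", {
  s <- make_schedule(30L)
  z0 <- matrix(c(0.3, -1.2, 2), 1)
  for (t in c(2L, 15L, 30L)) {
    zt <- sqrt(s$alpha_bars[t]) * z0
    post <- posterior_params(z0, zt, t, s)
    expect_equal(post$mean, sqrt(s$alpha_bars[t - 1]) * z0, tolerance = 1e-12)
    expect_lte(post$var, s$betas[t])
  }
  # t = 1 returns the predicted clean state deterministically
  p1 <- posterior_params(z0, z0 * 0.5, 1L, s)
  expect_equal(p1$mean, z0)
  expect_equal(p1$var, 0)
})

test_that("posterior matches brute-force linear-Gaussian conditioning at T = 2", {
  b1 <- 0.2; b2 <- 0.45
  s <- make_schedule(2L, beta_start = b1, beta_end = b2)
  z0 <- 0.8; z2 <- -0.35
  # z1 | z0 ~ N(sqrt(1-b1) z0, b1); z2 | z1 ~ N(sqrt(1-b2) z1, b2)
  mu1 <- sqrt(1 - b1) * z0
  S11 <- b1
  S12 <- sqrt(1 - b2) * b1
  S22 <- (1 - b2) * b1 + b2
  mu2 <- sqrt(1 - b2) * mu1
  want_mean <- mu1 + S12 / S22 * (z2 - mu2)
  want_var <- S11 - S12^2 / S22
  post <- posterior_params(matrix(z0, 1), matrix(z2, 1), 2L, s)
  expect_equal(as.numeric(post$mean), want_mean, tolerance = 1e-12)
  expect_equal(post$var, want_var, tolerance = 1e-12)
})

test_that("prior loss is zero for an oracle net and reproducible by seed", {
  psp <- prior_spec(latent = 4L, model_dim = 8L, depth = 1L, heads = 2L)
  net <- prior_init(psp, seed = 1)
  s <- make_schedule(20L)
  z0 <- matrix(rnorm(12), 3)
  y <- matrix(rnorm(12), 3)
  local_mocked_bindings(
    prior_forward = function(net, p, zt, t, y = NULL, covariates = NULL,
                             training = FALSE) ad_const(z0)
  )
  expect_equal(prior_loss(net, z0, y, s, seed = 5), 0)
  local_mocked_bindings(
    prior_forward = function(net, p, zt, t, y = NULL, covariates = NULL,
                             training = FALSE) ad_const(z0 * 0)
  )
  l1 <- prior_loss(net, z0, y, s, seed = 5)
  l2 <- prior_loss(net, z0, y, s, seed = 5)
  expect_identical(l1, l2)
  # predicting zero leaves approximately the mean square of z0
  expect_equal(l1, mean(z0^2), tolerance = 1e-12)
})

test_that("ancestral sampling degenerates to the oracle constant", {
  psp <- prior_spec(latent = 3L, model_dim = 8L, depth = 1L, heads = 2L)
  net <- prior_init(psp, seed = 2)
  s <- make_schedule(15L)
  cvec <- matrix(c(0.4, -1, 2), 1)
  local_mocked_bindings(
    prior_predict = function(net, params, zt, t, y = NULL, covariates = NULL) {
      cvec[rep(1, nrow(zt)), , drop = FALSE]
    }
  )
  out <- sample_prior(net, matrix(0, 1, 3), s, seed = 3)
  expect_equal(out, cvec, ignore_attr = TRUE)
})

test_that("sampling is deterministic and matches the autodiff forward", {
  psp <- prior_spec(latent = 3L, model_dim = 8L, depth = 2L, heads = 2L)
  net <- prior_init(psp, seed = 2)
  net$ema <- net$params
  s <- make_schedule(15L)
  set.seed(4)
  y <- matrix(rnorm(6), 2, 3)
  s1 <- sample_prior(net, y, s, seed = 7)
  s2 <- sample_prior(net, y, s, seed = 7)
  expect_identical(s1, s2)
  # the plain-matrix eval forward equals the autodiff forward exactly
  zt <- matrix(rnorm(6), 2, 3)
  fast <- facegen:::prior_predict(net, net$params, zt, c(3L, 9L), y)
  slow <- facegen:::ad_value(facegen:::prior_forward(
    net, facegen:::ad_wrap_consts(net$params), facegen:::ad_const(zt),
    c(3L, 9L), facegen:::ad_const(y), NULL, training = FALSE))
  expect_equal(fast, slow, tolerance = 1e-12)
  # with covariate conditioning too
  psp2 <- prior_spec(latent = 3L, model_dim = 8L, depth = 1L, heads = 2L,
                     conditions = c("snps", "age", "sex", "bmi"))
  net2 <- prior_init(psp2, seed = 5)
  covs <- data.frame(age = c(0.3, -1), sex = c(0L, 1L), bmi = c(1.2, 0))
  fast2 <- facegen:::prior_predict(net2, net2$params, zt, c(1L, 15L), y, covs)
  slow2 <- facegen:::ad_value(facegen:::prior_forward(
    net2, facegen:::ad_wrap_consts(net2$params), facegen:::ad_const(zt),
    c(1L, 15L), facegen:::ad_const(y), covs, training = FALSE))
  expect_equal(fast2, slow2, tolerance = 1e-12)
})

test_that("sampling aborts with the step index on numerical blow-up", {
  psp <- prior_spec(latent = 2L, model_dim = 8L, depth = 1L, heads = 2L)
  net <- prior_init(psp, seed = 2)
  s <- make_schedule(9L)
  local_mocked_bindings(
    prior_predict = function(net, params, zt, t, y = NULL, covariates = NULL) {
      matrix(NaN, nrow(zt), 2)
    }
  )
  expect_error(sample_prior(net, matrix(0, 1, 2), s, seed = 1), "t = 9")
})

test_that("prior training clips gradients and maintains the EMA", {
  set.seed(1)
  z_f <- matrix(rnorm(40 * 4), 40)
  z_s <- z_f + matrix(rnorm(40 * 4, 0, 0.1), 40)
  psp <- prior_spec(latent = 4L, model_dim = 8L, depth = 1L, heads = 2L)
  net <- prior_init(psp, seed = 3)
  s <- make_schedule(25L)
  cfg <- prior_config(lr = 2e-3, wd = 1e-4, batch_size = 16L, steps = 60L,
                      clip = 0.5, ema_beta = 0, ema_every = 1L, seed = 4)
  res <- train_prior(z_f, z_s, net, s, cfg)
  expect_true(all(res$grad_norms <= 0.5 + 1e-6))
  # EMA with beta = 0 refreshed every step equals the current weights
  for (nm in names(res$net$params)) {
    expect_equal(res$net$ema[[nm]], res$net$params[[nm]])
  }
})
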