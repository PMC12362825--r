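tiny_align_setup <- function(seed = 1) {
  ds <- make_paired_dataset(n = 24, m = 20, level = 1, n_causal = 8L,
                            effect_mm = 1.2, noise_sd = 0.05, seed = seed)
  fspec <- face_ae_spec(V = 42L, channels = c(4L, 6L), pool_factors = c(2L, 2L),
                        latent = 6L, spiral_lengths = c(6L, 6L),
                        spiral_dilations = c(1L, 1L))
  face <- face_ae_init(ds$template$mesh, fspec, seed = seed)
  sspec <- snp_encoder_spec(m = 20L, chunk = 10L, model_dim = 16L, ff_dim = 32L,
                            layers = 1L, heads = 2L, latent = 6L)
  snp <- snp_encoder_init(sspec, seed = seed + 1L)
  list(ds = ds, face = face, snp = snp)
}

test_that("alignment training is deterministic given the seed", {
  s <- tiny_align_setup(3)
  cfg <- align_config(lr_core = 1e-3, wd_core = 1e-4, lr_decoder = 1e-3,
                      wd_decoder = 1e-4, batch_size = 8L, epochs = 2L, seed = 7)
  h1 <- train_alignment(s$ds, s$face, s$snp, cfg)$history
  h2 <- train_alignment(s$ds, s$face, s$snp, cfg)$history
  expect_identical(h1, h2)
})

test_that("oversized batches fall back to one full batch per epoch", {
  s <- tiny_align_setup(4)
  cfg <- align_config(lr_core = 1e-3, wd_core = 0, lr_decoder = 1e-3,
                      wd_decoder = 0, batch_size = 999L, epochs = 1L, seed = 1)
  res <- train_alignment(s$ds, s$face, s$snp, cfg)
  expect_equal(nrow(res$history), 1L)
  expect_true(is.finite(res$history$loss_total))
})

test_that("training reduces the joint loss and logs JSONL records", {
  s <- tiny_align_setup(5)
  log <- file.path(withr::local_tempdir(), "log.jsonl")
  ck <- file.path(withr::local_tempdir(), "ck.rds")
  cfg <- align_config(lr_core = 3e-3, wd_core = 1e-4, lr_decoder = 3e-3,
                      wd_decoder = 1e-4, batch_size = 19L, epochs = 12L,
                      seed = 2)
  res <- train_alignment(s$ds, s$face, s$snp, cfg, log_path = log,
                         checkpoint_path = ck)
  h <- res$history
  expect_lt(h$loss_total[12], h$loss_total[1])
  expect_lt(h$loss_con[12], h$loss_con[1])
  # learning rate decays multiplicatively per epoch
  expect_equal(h$lr_core, cfg$lr_core * cfg$lr_decay^(0:11))
  lines <- readLines(log)
  expect_length(lines, 12L)
  rec <- jsonlite::fromJSON(lines[3])
  expect_equal(rec$epoch, 3L)
  expect_true(file.exists(ck))
  ckpt <- load_checkpoint(ck)
  expect_equal(ckpt$face$enc, res$face$enc)
})
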