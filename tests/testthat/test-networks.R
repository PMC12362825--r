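test_that("spiral convolution matches a brute-force gather-concat oracle", {
  set.seed(6)
  mesh <- random_small_mesh(6)  # 42 vertices
  sp <- build_spirals(mesh, 5L)
  V <- nrow(mesh$vertices)
  C <- 4; Cp <- 3
  x <- matrix(rnorm(V * C), V)
  W <- matrix(rnorm(5 * C * Cp), 5 * C)
  b <- rnorm(Cp)
  got <- spiral_conv(x, sp, W, b)
  # oracle: per vertex, gather spiral features (zeros for pads), concat, matmul
  want <- matrix(0, V, Cp)
  for (v in seq_len(V)) {
    feat <- numeric(0)
    for (k in seq_len(5)) {
      s <- sp$sequences[v, k]
      feat <- c(feat, if (s == 0L) rep(0, C) else x[s, ])
    }
    want[v, ] <- feat %*% W + b
  }
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("slot-averaging weights preserve constants; slot-0 selector is the identity", {
  mesh <- random_small_mesh(2)
  l <- 4L
  sp <- build_spirals(mesh, l)
  # interior icosphere vertices have full spirals (no pads)
  expect_true(all(sp$sequences > 0))
  C <- 3
  W_avg <- do.call(rbind, replicate(l, diag(C) / l, simplify = FALSE))
  const <- matrix(rep(c(1.5, -2, 0.5), each = nrow(mesh$vertices)), ncol = C)
  expect_equal(spiral_conv(const, sp, W_avg), const, tolerance = 1e-12)
  W_sel <- rbind(diag(C), matrix(0, (l - 1) * C, C))
  set.seed(1)
  x <- matrix(rnorm(nrow(mesh$vertices) * C), ncol = C)
  expect_equal(spiral_conv(x, sp, W_sel), x, tolerance = 1e-12)
  expect_error(spiral_conv(x, sp, diag(3)), "mismatch")
})

test_that("the face autoencoder meets its shape and determinism contracts", {
  tm <- template_mesh(1)
  spec <- face_ae_spec(V = 42L, channels = c(4L, 8L), pool_factors = c(2L, 2L),
                       latent = 8L, spiral_lengths = c(6L, 6L),
                       spiral_dilations = c(1L, 1L))
  fm <- face_ae_init(tm$mesh, spec, seed = 4)
  z <- face_encode(fm, tm$mesh$vertices)
  expect_equal(dim(z), c(1L, 8L))
  expect_true(all(is.finite(z)))
  # identical meshes -> identical embeddings; batched and single paths agree
  batch <- array(0, c(2, 42, 3))
  batch[1, , ] <- tm$mesh$vertices
  batch[2, , ] <- tm$mesh$vertices
  zb <- face_encode(fm, batch)
  expect_equal(zb[1, ], zb[2, ], tolerance = 1e-12)
  expect_equal(zb[1, ], z[1, ], tolerance = 1e-10)
  expect_error(face_encode(fm, matrix(0, 30, 3)), "vertex-count")
  # decoding: finite output for the zero latent, deterministic repeats
  x0 <- face_decode(fm, rep(0, 8))
  expect_true(all(is.finite(x0)))
  expect_equal(dim(x0), c(42L, 3L))
  set.seed(2)
  zz <- matrix(rnorm(16), 2)
  expect_identical(face_decode(fm, zz), face_decode(fm, zz))
  expect_error(face_decode(fm, rep(0, 5)), "latent")
})

test_that("autoencoder weights can overfit a few shapes (sanity of gradients)", {
  tm <- template_mesh(1)
  spec <- face_ae_spec(V = 42L, channels = c(6L, 8L), pool_factors = c(2L, 2L),
                       latent = 6L, spiral_lengths = c(6L, 6L),
                       spiral_dilations = c(1L, 1L))
  fm <- face_ae_init(tm$mesh, spec, seed = 1)
  set.seed(3)
  B <- 4L
  shapes <- array(rep(tm$mesh$vertices, each = B), c(B, 42, 3)) +
    array(rnorm(B * 42 * 3, 0, 0.5), c(B, 42, 3))
  xb <- aperm(shapes, c(2, 1, 3)); dim(xb) <- c(B * 42L, 3L)
  enc <- fm$enc; dec <- fm$dec
  oe <- facegen:::adamw_new(enc); od <- facegen:::adamw_new(dec)
  losses <- numeric(60)
  for (it in 1:60) {
    en <- facegen:::ad_wrap_params(enc); dn <- facegen:::ad_wrap_params(dec)
    zf <- facegen:::face_enc_forward(fm, en, facegen:::ad_const(xb), B)
    xh <- facegen:::face_dec_forward(fm, dn, zf, B)
    loss <- facegen:::ad_l1_loss(xh, xb)
    facegen:::ad_backward(loss)
    ge <- lapply(en, function(nd) nd$grad)
    gd <- lapply(dn, function(nd) nd$grad)
    r <- facegen:::adamw_step(enc, ge, oe, lr = 5e-3); enc <- r$params; oe <- r$state
    r <- facegen:::adamw_step(dec, gd, od, lr = 5e-3); dec <- r$params; od <- r$state
    losses[it] <- facegen:::ad_value(loss)
  }
  expect_lt(losses[60], 0.6 * losses[1])
})

test_that("the SNP encoder meets its contracts", {
  spec <- snp_encoder_spec(m = 24L, chunk = 8L, model_dim = 16L, ff_dim = 32L,
                           layers = 2L, heads = 2L, latent = 8L)
  sm <- snp_encoder_init(spec, seed = 5)
  z0 <- snp_encode(sm, rep(0, 24))
  expect_equal(dim(z0), c(1L, 8L))
  expect_true(all(is.finite(z0)))
  expect_error(snp_encode(sm, rep(0, 20)), "panel size")
  set.seed(6)
  g <- sample(0:2, 24, replace = TRUE)
  z1 <- snp_encode(sm, g)
  expect_identical(snp_encode(sm, g), z1)
  # permuting SNPs within one chunk changes the embedding
  g2 <- g
  g2[1:8] <- g2[c(3:8, 1:2)]
  expect_gt(max(abs(snp_encode(sm, g2) - z1)), 1e-8)
  # permuting whole chunks changes it too (positional encodings)
  g3 <- c(g[9:16], g[1:8], g[17:24])
  expect_gt(max(abs(snp_encode(sm, g3) - z1)), 1e-8)
})

test_that("checkpoints round-trip models through a single archive", {
  tp <- tiny_pipeline(2)
  path <- file.path(withr::local_tempdir(), "ckpt.rds")
  save_checkpoint(list(face = tp$pipeline$face, snp = tp$pipeline$snp), path)
  back <- load_checkpoint(path)
  expect_equal(back$face$enc, tp$pipeline$face$enc)
  expect_equal(back$snp$params, tp$pipeline$snp$params)
  z <- face_encode(back$face, tp$ds$template$mesh$vertices)
  expect_true(all(is.finite(z)))
  expect_error(load_checkpoint(file.path(tempdir(), "nope.rds")), "not found")
})
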