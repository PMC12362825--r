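# The three parameterized function families: spiral-convolution face
# encoder, mirrored face decoder, and transformer SNP encoder.
#
# Paper-scale architecture: encoder 3 x {Conv(32) -> Pool(4)} -> {Conv(64)
# -> Pool(4)} -> FC(128) with ReLU after each conv and spiral lengths
# [9,9,9,9]; decoder is the reverse with unpooling and one extra conv with
# output dimension 3; SNP encoder is a 2-layer post-LN transformer (model
# dim 128, ff 512, 8 heads, dropout 0.1, layer-norm eps 1e-5) over a token
# sequence built by chunking the SNP vector through per-chunk linear maps,
# with a learned pooling token read out as the embedding. All sizes are
# config-driven so a desk-scale model (642 vertices, latent 32) shares the
# code path.

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

#' Default face autoencoder configuration
#' @param V fine-level vertex count (informational).
#' @param channels conv output channels per encoder stage.
#' @param pool_factors per-stage pooling factors.
#' @param latent latent dimension.
#' @param spiral_lengths spiral length per stage.
#' @param spiral_dilations spiral dilation per stage.
#' @return a config list.
#' @export
face_ae_spec <- function(V = 7906L, channels = c(32L, 32L, 32L, 64L),
                         pool_factors = c(4L, 4L, 4L, 4L), latent = 128L,
                         spiral_lengths = c(9L, 9L, 9L, 9L),
                         spiral_dilations = c(1L, 1L, 1L, 1L)) {
  stopifnot(length(channels) == length(pool_factors),
            length(spiral_lengths) == length(channels))
  list(V = V, channels = channels, pool_factors = pool_factors,
       latent = latent, spiral_lengths = spiral_lengths,
       spiral_dilations = spiral_dilations)
}

#' Default SNP encoder configuration
#' @param m panel size; @param chunk SNPs per token; @param model_dim
#'   transformer dimension; @param ff_dim feed-forward hidden dimension;
#' @param layers encoder layers; @param heads attention heads; @param
#'   dropout dropout rate; @param layernorm_eps layer-norm epsilon;
#' @param latent output embedding dimension.
#' @return a config list.
#' @export
snp_encoder_spec <- function(m = 7842L, chunk = 128L, model_dim = 128L,
                             ff_dim = 512L, layers = 2L, heads = 8L,
                             dropout = 0.1, layernorm_eps = 1e-5,
                             latent = 128L) {
  list(m = m, chunk = chunk, model_dim = model_dim, ff_dim = ff_dim,
       layers = layers, heads = heads, dropout = dropout,
       layernorm_eps = layernorm_eps, latent = latent)
}

# ---- spiral convolution ----------------------------------------------------

# base slot selection matrices (V x V), one per spiral position; padded
# entries give all-zero rows (zero feature semantics)
spiral_slot_mats <- function(spirals, V) {
  lapply(seq_len(spirals$length), function(k) {
    s <- spirals$sequences[, k]
    keep <- which(s > 0L)
    Matrix::sparseMatrix(i = keep, j = s[keep], x = 1, dims = c(V, V))
  })
}

# batch-expanded constant matrices, cached in `env` by key
batch_kron <- function(A, B, env, key) {
  full_key <- paste0(key, "#B", B)
  hit <- get0(full_key, envir = env)
  if (!is.null(hit)) return(hit)
  M <- if (B == 1L) A else Matrix::kronecker(Matrix::Diagonal(B), A)
  assign(full_key, M, envir = env)
  M
}

# differentiable spiral convolution on a batch: x is (B*V) x C (sample-major
# rows), idx a slot-major batch gather index; returns (B*V) x C'
ad_spiral_conv <- function(x, idx, l, W, b) {
  ad_add_bias(ad_matmul(ad_gather_concat(x, idx, l), W), b)
}

# slot-major batch gather index for a spiral table (0 = pad)
spiral_batch_idx <- function(spirals, V, B) {
  s <- spirals$sequences  # V x l
  l <- spirals$length
  offs <- rep((0:(B - 1)) * V, each = V)
  unlist(lapply(seq_len(l), function(k) {
    sk <- rep(s[, k], B)
    ifelse(sk == 0L, 0L, sk + offs)
  }), use.names = FALSE)
}

#' Spiral convolution (single field)
#'
#' Applies one spiral convolution to a V x C vertex-feature field: for each
#' vertex the features of its ordered spiral neighborhood are gathered,
#' concatenated, and mapped through a linear layer (the MLP gamma). Padded
#' spiral slots contribute zeros.
#'
#' @param features V x C matrix.
#' @param spirals a `spiral_table` for the same mesh.
#' @param W weight matrix, (l*C) x C'.
#' @param b bias vector, length C'.
#' @return V x C' matrix.
#' @export
spiral_conv <- function(features, spirals, W, b = NULL) {
  V <- nrow(features); C <- ncol(features); l <- spirals$length
  if (nrow(W) != l * C) stop("spiral length / weight shape mismatch: W has ",
                             nrow(W), " rows, expected ", l * C)
  if (is.null(b)) b <- numeric(ncol(W))
  mats <- spiral_slot_mats(spirals, V)
  g <- do.call(cbind, lapply(mats, function(G) as.matrix(G %*% features)))
  sweep(g %*% W, 2L, b, "+")
}

# ---- face encoder ----------------------------------------------------------

#' Initialize a face autoencoder (encoder + decoder)
#'
#' Builds the pooling hierarchy and spiral tables for each level and
#' initializes encoder and decoder weights (Glorot uniform, seeded).
#'
#' @param mesh fine-level template `tri_mesh`.
#' @param spec from [face_ae_spec()].
#' @param seed RNG seed for initialization.
#' @param hierarchy optional precomputed `mesh_hierarchy`.
#' @param cache_dir optional hierarchy cache directory.
#' @return a `face_ae` model list.
#' @export
face_ae_init <- function(mesh, spec, seed = 1L, hierarchy = NULL,
                         cache_dir = NULL) {
  n_stage <- length(spec$channels)
  if (is.null(hierarchy)) {
    hierarchy <- build_hierarchy(mesh, spec$pool_factors, cache_dir = cache_dir)
  }
  spirals <- lapply(seq_len(n_stage), function(i) {
    build_spirals(hierarchy$levels[[i]], spec$spiral_lengths[i],
                  spec$spiral_dilations[i])
  })
  set.seed(seed)
  ch <- c(3L, spec$channels)
  enc <- list()
  for (i in seq_len(n_stage)) {
    fi <- spec$spiral_lengths[i] * ch[i]
    enc[[paste0("conv", i, ".W")]] <- glorot(fi, ch[i + 1])
    enc[[paste0("conv", i, ".b")]] <- numeric(ch[i + 1])
  }
  V_last <- nrow(hierarchy$levels[[n_stage + 1L]]$vertices)
  C_last <- spec$channels[n_stage]
  enc[["fc.W"]] <- glorot(V_last * C_last, spec$latent)
  enc[["fc.b"]] <- numeric(spec$latent)
  dec <- list()
  dec[["fc.W"]] <- glorot(spec$latent, V_last * C_last)
  dec[["fc.b"]] <- numeric(V_last * C_last)
  dch <- c(C_last, rev(spec$channels)[-1], rev(spec$channels)[n_stage])
  # decoder conv i operates at level (n_stage + 1 - i) after unpooling
  for (i in seq_len(n_stage)) {
    lev <- n_stage + 1L - i
    fi <- spec$spiral_lengths[lev] * dch[i]
    dec[[paste0("conv", i, ".W")]] <- glorot(fi, dch[i + 1])
    dec[[paste0("conv", i, ".b")]] <- numeric(dch[i + 1])
  }
  fi <- spec$spiral_lengths[1] * dch[n_stage + 1L]
  dec[["out.W"]] <- glorot(fi, 3L)
  dec[["out.b"]] <- numeric(3L)
  structure(list(spec = spec, hierarchy = hierarchy, spirals = spirals,
                 enc = enc, dec = dec, ref = mesh$vertices,
                 cache = new.env(parent = emptyenv()), seed = seed),
            class = "face_ae")
}

# reshape (B*V) x C sample-major features to B x (V*C) per-sample rows
ad_mesh_flatten <- function(x, B, V) {
  xv <- ad_value(x)
  C <- ncol(xv)
  y <- aperm(array(xv, c(V, B, C)), c(2, 1, 3))
  dim(y) <- c(B, V * C)
  ad_node(y, list(x), function(g) {
    dim(g) <- c(B, V, C)
    gx <- aperm(g, c(2, 1, 3))
    dim(gx) <- c(B * V, C)
    list(gx)
  })
}

ad_mesh_unflatten <- function(x, B, V) {
  xv <- ad_value(x)
  C <- ncol(xv) / V
  y <- array(xv, c(B, V, C))
  y <- aperm(y, c(2, 1, 3))
  dim(y) <- c(B * V, C)
  ad_node(y, list(x), function(g) {
    dim(g) <- c(V, B, C)
    gx <- aperm(g, c(2, 1, 3))
    dim(gx) <- c(B, V * C)
    list(gx)
  })
}

# template coordinates tiled across a batch (cached); the networks operate
# on displacements from the template so activations stay O(effect size)
ref_rep <- function(model, B) {
  key <- paste0("ref#B", B)
  hit <- get0(key, envir = model$cache)
  if (!is.null(hit)) return(hit)
  r <- do.call(rbind, replicate(B, model$ref, simplify = FALSE))
  assign(key, r, envir = model$cache)
  r
}

# internal differentiable encoder forward; x (B*V)x3 constant or node,
# absolute coordinates (mm)
face_enc_forward <- function(model, params, x, B) {
  spec <- model$spec
  h <- model$hierarchy
  n_stage <- length(spec$channels)
  out <- ad_sub(x, ad_const(ref_rep(model, B)))
  for (i in seq_len(n_stage)) {
    out <- ad_relu(ad_spiral_conv(out, get_spiral_idx(model, i, B),
                                  spec$spiral_lengths[i],
                                  params[[paste0("conv", i, ".W")]],
                                  params[[paste0("conv", i, ".b")]]))
    D <- batch_kron(h$down_maps[[i]], B, model$cache, paste0("down", i))
    out <- ad_spmm(D, out)
  }
  V_last <- nrow(h$levels[[n_stage + 1L]]$vertices)
  flat <- ad_mesh_flatten(out, B, V_last)
  ad_add_bias(ad_matmul(flat, params[["fc.W"]]), params[["fc.b"]])
}

face_dec_forward <- function(model, params, z, B) {
  spec <- model$spec
  h <- model$hierarchy
  n_stage <- length(spec$channels)
  V_last <- nrow(h$levels[[n_stage + 1L]]$vertices)
  out <- ad_add_bias(ad_matmul(z, params[["fc.W"]]), params[["fc.b"]])
  out <- ad_mesh_unflatten(out, B, V_last)
  for (i in seq_len(n_stage)) {
    lev <- n_stage + 1L - i
    U <- batch_kron(h$up_maps[[lev]], B, model$cache, paste0("up", lev))
    out <- ad_spmm(U, out)
    out <- ad_relu(ad_spiral_conv(out, get_spiral_idx(model, lev, B),
                                  spec$spiral_lengths[lev],
                                  params[[paste0("conv", i, ".W")]],
                                  params[[paste0("conv", i, ".b")]]))
  }
  out <- ad_spiral_conv(out, get_spiral_idx(model, 1L, B),
                        spec$spiral_lengths[1],
                        params[["out.W"]], params[["out.b"]])
  ad_add(out, ad_const(ref_rep(model, B)))
}

get_spiral_idx <- function(model, level, B) {
  key <- paste0("sidx", level, "#B", B)
  hit <- get0(key, envir = model$cache)
  if (!is.null(hit)) return(hit)
  V_l <- nrow(model$hierarchy$levels[[level]]$vertices)
  idx <- spiral_batch_idx(model$spirals[[level]], V_l, B)
  assign(key, idx, envir = model$cache)
  idx
}

# coerce mesh batch input (V x 3 matrix, B x V x 3 array, or list of
# meshes/matrices) to sample-major (B*V) x 3 plus B
mesh_batch_input <- function(x, V) {
  if (is.list(x)) {
    x <- lapply(x, function(e) if (inherits(e, "tri_mesh")) e$vertices else e)
    B <- length(x)
    return(list(x = do.call(rbind, x), B = B))
  }
  if (inherits(x, "tri_mesh")) x <- x$vertices
  if (is.matrix(x)) return(list(x = x, B = 1L))
  stopifnot(length(dim(x)) == 3L)
  B <- dim(x)[1]
  # row (b-1)*V + v of the result must be x[b, v, ]
  xm <- aperm(x, c(2, 1, 3))
  dim(xm) <- c(B * dim(x)[2], 3L)
  list(x = xm, B = B)
}

#' Encode faces to embeddings
#'
#' @param model a `face_ae`.
#' @param x a V x 3 matrix, `tri_mesh`, B x V x 3 array, or list thereof.
#' @return B x latent embedding matrix.
#' @export
face_encode <- function(model, x) {
  inp <- mesh_batch_input(x, model$spec$V)
  V_fine <- nrow(model$hierarchy$levels[[1]]$vertices)
  if (nrow(inp$x) != inp$B * V_fine) {
    stop("vertex-count mismatch with the model's fine level")
  }
  node <- face_enc_forward(model, ad_wrap_params(model$enc),
                           ad_const(inp$x), inp$B)
  ad_value(node)
}

#' Decode embeddings to faces
#'
#' @param model a `face_ae`.
#' @param z B x latent matrix (or a single latent vector).
#' @return B x V x 3 array of vertex coordinates (V x 3 matrix for B = 1).
#' @export
face_decode <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, 1)
  if (ncol(z) != model$spec$latent) stop("latent dimension mismatch")
  B <- nrow(z)
  node <- face_dec_forward(model, ad_wrap_params(model$dec), ad_const(z), B)
  V <- nrow(model$hierarchy$levels[[1]]$vertices)
  out <- ad_value(node)
  if (B == 1L) return(out)
  arr <- array(0, dim = c(B, V, 3))
  for (b in seq_len(B)) arr[b, , ] <- out[((b - 1) * V + 1):(b * V), ]
  arr
}

# ---- SNP encoder -----------------------------------------------------------

#' Initialize the transformer SNP encoder
#'
#' The m-dimensional dosage vector is partitioned into contiguous chunks,
#' each linearly projected to the model dimension (the per-chunk MLP
#' dimensionality reduction); learned positional encodings and a learned
#' pooling token are added, the sequence runs through post-LN transformer
#' layers, and the pooling token's output is mapped to the latent embedding.
#'
#' @param spec from [snp_encoder_spec()].
#' @param seed RNG seed.
#' @return a `snp_encoder` model list.
#' @export
snp_encoder_init <- function(spec, seed = 1L) {
  set.seed(seed)
  d <- spec$model_dim
  n_tok <- ceiling(spec$m / spec$chunk)
  p <- list()
  for (j in seq_len(n_tok)) {
    lo <- (j - 1L) * spec$chunk + 1L
    hi <- min(j * spec$chunk, spec$m)
    p[[paste0("tok", j, ".W")]] <- glorot(hi - lo + 1L, d)
    p[[paste0("tok", j, ".b")]] <- numeric(d)
  }
  p[["cls"]] <- matrix(stats::rnorm(d, 0, 0.02), 1)
  p[["pos"]] <- matrix(stats::rnorm((n_tok + 1L) * d, 0, 0.02), n_tok + 1L)
  for (L in seq_len(spec$layers)) {
    pref <- paste0("layer", L, ".")
    p[[paste0(pref, "Wq")]] <- glorot(d, d); p[[paste0(pref, "bq")]] <- numeric(d)
    p[[paste0(pref, "Wk")]] <- glorot(d, d); p[[paste0(pref, "bk")]] <- numeric(d)
    p[[paste0(pref, "Wv")]] <- glorot(d, d); p[[paste0(pref, "bv")]] <- numeric(d)
    p[[paste0(pref, "Wo")]] <- glorot(d, d); p[[paste0(pref, "bo")]] <- numeric(d)
    p[[paste0(pref, "ln1.g")]] <- rep(1, d); p[[paste0(pref, "ln1.b")]] <- numeric(d)
    p[[paste0(pref, "ff.W1")]] <- glorot(d, spec$ff_dim)
    p[[paste0(pref, "ff.b1")]] <- numeric(spec$ff_dim)
    p[[paste0(pref, "ff.W2")]] <- glorot(spec$ff_dim, d)
    p[[paste0(pref, "ff.b2")]] <- numeric(d)
    p[[paste0(pref, "ln2.g")]] <- rep(1, d); p[[paste0(pref, "ln2.b")]] <- numeric(d)
  }
  p[["out.W"]] <- glorot(d, spec$latent)
  p[["out.b"]] <- numeric(spec$latent)
  structure(list(spec = spec, params = p, n_tok = n_tok, seed = seed),
            class = "snp_encoder")
}

ad_add_pos <- function(x, P) {
  xv <- ad_value(x); Pv <- ad_value(P)
  dims <- dim(xv)
  y <- xv + rep(Pv, each = dims[1])
  ad_node(y, list(x, P), function(g) {
    gP <- apply(g, c(2, 3), sum)
    list(g, gP)
  })
}

ad_rep_row <- function(b, B) {
  bv <- ad_value(b)
  d <- length(bv)
  ad_node(matrix(as.numeric(bv), B, d, byrow = TRUE), list(b), function(g) {
    list(matrix(colSums(g), 1))
  })
}

transformer_layer <- function(x, p, pref, spec, training) {
  a <- ad_mha(x, p[[paste0(pref, "Wq")]], p[[paste0(pref, "bq")]],
              p[[paste0(pref, "Wk")]], p[[paste0(pref, "bk")]],
              p[[paste0(pref, "Wv")]], p[[paste0(pref, "bv")]],
              p[[paste0(pref, "Wo")]], p[[paste0(pref, "bo")]],
              spec$heads, spec$dropout, training)
  x <- ad_layernorm(ad_add(x, ad_dropout(a, spec$dropout, training)),
                    p[[paste0(pref, "ln1.g")]], p[[paste0(pref, "ln1.b")]],
                    spec$layernorm_eps)
  f <- ad_linear3(ad_relu(ad_linear3(x, p[[paste0(pref, "ff.W1")]],
                                     p[[paste0(pref, "ff.b1")]])),
                  p[[paste0(pref, "ff.W2")]], p[[paste0(pref, "ff.b2")]])
  ad_layernorm(ad_add(x, ad_dropout(f, spec$dropout, training)),
               p[[paste0(pref, "ln2.g")]], p[[paste0(pref, "ln2.b")]],
               spec$layernorm_eps)
}

snp_enc_forward <- function(model, p, G, training = FALSE) {
  spec <- model$spec
  B <- nrow(ad_value(G))
  toks <- list(ad_rep_row(p[["cls"]], B))
  for (j in seq_len(model$n_tok)) {
    lo <- (j - 1L) * spec$chunk + 1L
    hi <- min(j * spec$chunk, spec$m)
    Gj <- ad_slice_cols(G, lo, hi)
    toks[[j + 1L]] <- ad_add_bias(ad_matmul(Gj, p[[paste0("tok", j, ".W")]]),
                                  p[[paste0("tok", j, ".b")]])
  }
  x <- ad_add_pos(ad_stack_tokens(toks), p[["pos"]])
  for (L in seq_len(spec$layers)) {
    x <- transformer_layer(x, p, paste0("layer", L, "."), spec, training)
  }
  cls_out <- ad_slice_token(x, 1L)
  ad_add_bias(ad_matmul(cls_out, p[["out.W"]]), p[["out.b"]])
}

ad_slice_cols <- function(x, lo, hi) {
  xv <- ad_value(x)
  ad_node(xv[, lo:hi, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[, lo:hi] <- g
    list(gx)
  })
}

#' Encode genotype vectors to SNP embeddings
#'
#' @param model a `snp_encoder`.
#' @param G B x m dosage matrix (or a single m-vector).
#' @return B x latent embedding matrix.
#' @export
snp_encode <- function(model, G) {
  if (is.null(dim(G))) G <- matrix(G, 1)
  if (ncol(G) != model$spec$m) {
    stop("panel size mismatch: got ", ncol(G), ", expected ", model$spec$m)
  }
  node <- snp_enc_forward(model, ad_wrap_params(model$params), ad_const(G),
                          training = FALSE)
  ad_value(node)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint is a single RDS archive holding the model list(s) (config +
#' weights) plus a fingerprint of the mesh hierarchy when one is attached.
#'
#' @param models named list of model objects.
#' @param path output file.
#' @export
save_checkpoint <- function(models, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  models <- lapply(models, function(m) {
    if (is.list(m) && !is.null(m$cache)) m$cache <- NULL
    m
  })
  saveRDS(models, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  models <- readRDS(path)
  lapply(models, function(m) {
    if (inherits(m, "face_ae")) m$cache <- new.env(parent = emptyenv())
    m
  })
}
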