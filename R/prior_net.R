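# Conditional diffusion prior network: a small attention network over a
# token sequence [conditioning tokens..., timestep token, noisy-embedding
# token, learned query token]; the prediction of the clean face embedding is
# read from the query token (x0 parameterization, no conditional dropout).
# Covariates (age/sex/BMI) enter as extra conditioning tokens: age and BMI
# through linear embeddings of their standardized values, sex through a
# learned two-row table. A condition mask fixed at init supports the
# ablations (SNPs only; SNPs + sex; SNPs + sex + age + BMI; covariates only).

#' Diffusion prior configuration
#'
#' @param latent dimension of the embeddings being modeled.
#' @param model_dim hidden embedding dimension of the attention network.
#' @param depth number of attention layers.
#' @param heads attention heads (head dim = model_dim / heads).
#' @param ff_mult feed-forward expansion multiplier.
#' @param dropout dropout rate for attention and feed-forward.
#' @param conditions character subset of c("snps", "age", "sex", "bmi").
#' @param ema_beta EMA decay for the weight average used at sampling time.
#' @return config list.
#' @export
prior_spec <- function(latent = 128L, model_dim = 128L, depth = 4L,
                       heads = 4L, ff_mult = 2L, dropout = 0.1,
                       conditions = "snps", ema_beta = 0.98) {
  stopifnot(model_dim %% heads == 0,
            all(conditions %in% c("snps", "age", "sex", "bmi")),
            length(conditions) >= 1)
  list(latent = latent, model_dim = model_dim, depth = depth, heads = heads,
       ff_mult = ff_mult, dropout = dropout, conditions = conditions,
       ema_beta = ema_beta, layernorm_eps = 1e-5,
       ff_dim = model_dim * ff_mult)
}

#' Initialize the diffusion prior network
#' @param spec from [prior_spec()].
#' @param seed RNG seed.
#' @return a `prior_net` model list (params + NULL EMA).
#' @export
prior_init <- function(spec, seed = 1L) {
  set.seed(seed)
  d <- spec$model_dim
  p <- list()
  p[["proj_z.W"]] <- glorot(spec$latent, d); p[["proj_z.b"]] <- numeric(d)
  p[["time.W"]] <- glorot(d, d); p[["time.b"]] <- numeric(d)
  if ("snps" %in% spec$conditions) {
    p[["proj_y.W"]] <- glorot(spec$latent, d); p[["proj_y.b"]] <- numeric(d)
  }
  if ("age" %in% spec$conditions) p[["age.W"]] <- glorot(1, d, c(1, d))
  if ("sex" %in% spec$conditions) p[["sex.T"]] <- matrix(stats::rnorm(2 * d, 0, 0.02), 2)
  if ("bmi" %in% spec$conditions) p[["bmi.W"]] <- glorot(1, d, c(1, d))
  p[["query"]] <- matrix(stats::rnorm(d, 0, 0.02), 1)
  n_tok <- n_prior_tokens(spec)
  p[["pos"]] <- matrix(stats::rnorm(n_tok * d, 0, 0.02), n_tok)
  for (L in seq_len(spec$depth)) {
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
  p[["out.W"]] <- glorot(d, spec$latent); p[["out.b"]] <- numeric(spec$latent)
  structure(list(spec = spec, params = p, ema = NULL, seed = seed),
            class = "prior_net")
}

n_prior_tokens <- function(spec) {
  1L + sum(c("snps", "age", "sex", "bmi") %in% spec$conditions) + 2L
  # conditioning tokens + time token + z_t token + query token
}

# sinusoidal timestep features, B x d
time_features <- function(t, d) {
  half <- d %/% 2
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / max(half - 1, 1))
  ang <- outer(t, freqs)
  emb <- cbind(sin(ang), cos(ang))
  if (ncol(emb) < d) emb <- cbind(emb, matrix(0, length(t), d - ncol(emb)))
  emb
}

# differentiable forward; z_t node/const (B x latent), t integer vector,
# y node/const or NULL, covariates data.frame or NULL
prior_forward <- function(net, p, zt, t, y = NULL, covariates = NULL,
                          training = FALSE) {
  spec <- net$spec
  B <- nrow(ad_value(zt))
  toks <- list()
  if ("snps" %in% spec$conditions) {
    if (is.null(y)) stop("model was built with SNP conditioning; y is required")
    toks[[length(toks) + 1L]] <-
      ad_add_bias(ad_matmul(y, p[["proj_y.W"]]), p[["proj_y.b"]])
  }
  for (cv in c("age", "sex", "bmi")) {
    if (!(cv %in% spec$conditions)) next
    if (is.null(covariates) || is.null(covariates[[cv]])) {
      stop("model conditions on '", cv, "' but it is missing from covariates")
    }
    val <- covariates[[cv]]
    toks[[length(toks) + 1L]] <- if (cv == "sex") {
      ad_gather_rows(p[["sex.T"]], as.integer(val) + 1L)
    } else {
      ad_matmul(ad_const(matrix(as.numeric(val), B, 1)), p[[paste0(cv, ".W")]])
    }
  }
  tf <- ad_const(time_features(t, spec$model_dim))
  toks[[length(toks) + 1L]] <- ad_add_bias(ad_matmul(tf, p[["time.W"]]),
                                           p[["time.b"]])
  toks[[length(toks) + 1L]] <- ad_add_bias(ad_matmul(zt, p[["proj_z.W"]]),
                                           p[["proj_z.b"]])
  toks[[length(toks) + 1L]] <- ad_rep_row(p[["query"]], B)
  x <- ad_add_pos(ad_stack_tokens(toks), p[["pos"]])
  for (L in seq_len(spec$depth)) {
    x <- transformer_layer(x, p, paste0("layer", L, "."), spec, training)
  }
  q_out <- ad_slice_token(x, length(toks))
  ad_add_bias(ad_matmul(q_out, p[["out.W"]]), p[["out.b"]])
}

#' Prior training configuration
#'
#' Defaults follow the reference model's settings (lr 0.31e-4, weight decay
#' 0.752, gradient-norm clip 0.5, EMA beta 0.98 refreshed every 100 steps).
#'
#' @param lr learning rate; @param wd weight decay; @param batch_size batch
#'   size; @param steps optimizer steps; @param clip max gradient norm;
#' @param ema_beta EMA decay; @param ema_every EMA refresh interval (steps);
#' @param cond_noise sd of Gaussian noise added to the conditioning
#'   embedding during training (augmentation against overfitting small
#'   embedding sets; 0 disables);
#' @param seed RNG seed.
#' @return config list.
#' @export
prior_config <- function(lr = 0.31e-4, wd = 0.752, batch_size = 64L,
                         steps = 2000L, clip = 0.5, ema_beta = 0.98,
                         ema_every = 100L, cond_noise = 0, seed = 1L) {
  list(lr = lr, wd = wd, batch_size = as.integer(batch_size),
       steps = as.integer(steps), clip = clip, ema_beta = ema_beta,
       ema_every = as.integer(ema_every), cond_noise = cond_noise,
       seed = as.integer(seed))
}

#' Train the conditional diffusion prior
#'
#' The stage-1 encoders are frozen: training operates on precomputed face
#' embeddings z_f (targets) and SNP embeddings z_s (conditioning). Applies
#' AdamW with gradient-norm clipping and maintains an EMA copy of the
#' weights used for sampling.
#'
#' @param z_f N x latent face embeddings (targets).
#' @param z_s N x latent SNP embeddings (conditioning; may be NULL for the
#'   covariates-only ablation).
#' @param net a `prior_net`.
#' @param schedule a `diffusion_schedule`.
#' @param cfg from [prior_config()].
#' @param covariates optional covariate data.frame (N rows).
#' @param log_path optional JSONL log.
#' @param verbose print progress.
#' @return list(net, history); `net$ema` holds the EMA weights.
#' @export
train_prior <- function(z_f, z_s, net, schedule, cfg = prior_config(),
                        covariates = NULL, log_path = NULL, verbose = FALSE) {
  set.seed(cfg$seed)
  N <- nrow(z_f)
  p <- net$params
  opt <- adamw_new(p)
  ema <- p
  history <- numeric(cfg$steps)
  grad_norms <- numeric(cfg$steps)
  if (!is.null(log_path)) {
    dir.create(dirname(log_path), recursive = TRUE, showWarnings = FALSE)
    file.create(log_path)
  }
  for (step in seq_len(cfg$steps)) {
    idx <- sample.int(N, min(cfg$batch_size, N))
    B <- length(idx)
    z0 <- z_f[idx, , drop = FALSE]
    t <- sample.int(schedule$T_steps, B, replace = TRUE)
    noise <- matrix(stats::rnorm(B * ncol(z0)), B)
    zt <- q_sample(z0, t, schedule, noise = noise)
    nodes <- ad_wrap_params(p)
    cn <- cfg$cond_noise %||% 0
    y_node <- if (is.null(z_s)) NULL else {
      yb <- z_s[idx, , drop = FALSE]
      if (cn > 0) yb <- yb + matrix(stats::rnorm(length(yb), 0, cn), nrow(yb))
      ad_const(yb)
    }
    cov_b <- if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE]
    pred <- prior_forward(net, nodes, ad_const(zt), t, y_node, cov_b,
                          training = TRUE)
    loss <- ad_mse_loss(pred, z0)
    if (!is.finite(ad_value(loss))) {
      stop("non-finite diffusion loss at step ", step)
    }
    ad_backward(loss)
    g <- lapply(nodes, function(nd) nd$grad %||% (nd$value * 0))
    g <- clip_grad_norm(g, cfg$clip)
    grad_norms[step] <- min(attr(g, "norm"), cfg$clip)
    res <- adamw_step(p, g, opt, lr = cfg$lr, wd = cfg$wd)
    p <- res$params; opt <- res$state
    if (step %% cfg$ema_every == 0L) {
      ema <- ema_update(ema, p, cfg$ema_beta)
    }
    history[step] <- ad_value(loss)
    if (!is.null(log_path) && step %% 50L == 0L) {
      cat(jsonlite::toJSON(list(step = step, loss = history[step]),
                           auto_unbox = TRUE, digits = NA),
          "\n", sep = "", file = log_path, append = TRUE)
    }
    if (verbose && step %% 200L == 0L) {
      message(sprintf("step %5d  loss %.5f", step, history[step]))
    }
  }
  net$params <- p
  net$ema <- ema
  list(net = net, history = history, grad_norms = grad_norms)
}

# Plain-matrix forward pass of the prior in eval mode (no gradient
# bookkeeping, no dropout). Mirrors prior_forward() exactly; used by the
# ancestral sampling chain where thousands of forward evaluations dominate
# run time. Equality with prior_forward is asserted in the tests.
prior_predict <- function(net, params, zt, t, y = NULL, covariates = NULL) {
  spec <- net$spec
  p <- params
  B <- nrow(zt)
  d <- spec$model_dim
  toks <- list()
  if ("snps" %in% spec$conditions) {
    if (is.null(y)) stop("model was built with SNP conditioning; y is required")
    toks[[length(toks) + 1L]] <- sweep(y %*% p[["proj_y.W"]], 2L,
                                       p[["proj_y.b"]], "+")
  }
  for (cv in c("age", "sex", "bmi")) {
    if (!(cv %in% spec$conditions)) next
    val <- covariates[[cv]]
    toks[[length(toks) + 1L]] <- if (cv == "sex") {
      p[["sex.T"]][as.integer(val) + 1L, , drop = FALSE]
    } else {
      matrix(as.numeric(val), B, 1) %*% p[[paste0(cv, ".W")]]
    }
  }
  tf <- time_features(t, d)
  toks[[length(toks) + 1L]] <- sweep(tf %*% p[["time.W"]], 2L, p[["time.b"]], "+")
  toks[[length(toks) + 1L]] <- sweep(zt %*% p[["proj_z.W"]], 2L,
                                     p[["proj_z.b"]], "+")
  toks[[length(toks) + 1L]] <- matrix(p[["query"]], B, d, byrow = TRUE)
  n <- length(toks)
  # rows token-major: row (i-1)*B + b holds token i of sample b
  x2 <- do.call(rbind, toks) + p[["pos"]][rep(seq_len(n), each = B), ]
  ln <- function(x, g, b) {
    mu <- rowMeans(x)
    xc <- x - mu
    sdv <- sqrt(rowMeans(xc^2) + spec$layernorm_eps)
    sweep(sweep(xc / sdv, 2L, as.numeric(g), "*"), 2L, as.numeric(b), "+")
  }
  heads <- spec$heads
  dh <- d %/% heads
  scale <- 1 / sqrt(dh)
  for (L in seq_len(spec$depth)) {
    pref <- paste0("layer", L, ".")
    Q <- sweep(x2 %*% p[[paste0(pref, "Wq")]], 2L, p[[paste0(pref, "bq")]], "+")
    K <- sweep(x2 %*% p[[paste0(pref, "Wk")]], 2L, p[[paste0(pref, "bk")]], "+")
    V <- sweep(x2 %*% p[[paste0(pref, "Wv")]], 2L, p[[paste0(pref, "bv")]], "+")
    O <- matrix(0, B * n, d)
    for (h in seq_len(heads)) {
      cs <- ((h - 1) * dh + 1):(h * dh)
      # S[b, i, j] over token pairs, vectorized across the batch
      S <- array(0, dim = c(B, n, n))
      for (i in seq_len(n)) {
        Qi <- Q[((i - 1) * B + 1):(i * B), cs, drop = FALSE]
        for (j in seq_len(n)) {
          Kj <- K[((j - 1) * B + 1):(j * B), cs, drop = FALSE]
          S[, i, j] <- rowSums(Qi * Kj) * scale
        }
      }
      for (i in seq_len(n)) {
        Si <- matrix(S[, i, ], B, n)
        mx <- do.call(pmax, lapply(seq_len(n), function(j) Si[, j]))
        E <- exp(Si - mx)
        A <- E / rowSums(E)
        acc <- matrix(0, B, dh)
        for (j in seq_len(n)) {
          acc <- acc + V[((j - 1) * B + 1):(j * B), cs, drop = FALSE] * A[, j]
        }
        O[((i - 1) * B + 1):(i * B), cs] <- acc
      }
    }
    a <- sweep(O %*% p[[paste0(pref, "Wo")]], 2L, p[[paste0(pref, "bo")]], "+")
    x2 <- ln(x2 + a, p[[paste0(pref, "ln1.g")]], p[[paste0(pref, "ln1.b")]])
    hdn <- sweep(x2 %*% p[[paste0(pref, "ff.W1")]], 2L,
                 p[[paste0(pref, "ff.b1")]], "+")
    hdn[hdn < 0] <- 0
    f <- sweep(hdn %*% p[[paste0(pref, "ff.W2")]], 2L,
               p[[paste0(pref, "ff.b2")]], "+")
    x2 <- ln(x2 + f, p[[paste0(pref, "ln2.g")]], p[[paste0(pref, "ln2.b")]])
  }
  q_out <- x2[((n - 1) * B + 1):(n * B), , drop = FALSE]
  sweep(q_out %*% p[["out.W"]], 2L, p[["out.b"]], "+")
}
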