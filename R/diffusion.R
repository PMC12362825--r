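# Denoising diffusion machinery in embedding space: variance schedule,
# closed-form forward marginal, Gaussian posterior of the reverse process,
# x0-prediction training loss, and ancestral sampling conditioned on a SNP
# embedding.

#' Diffusion variance schedule
#'
#' Builds beta_1..beta_T with derived alpha_t = 1 - beta_t and cumulative
#' products alpha_bar_t. The default is the standard linear schedule from
#' 1e-4 to 0.02 over T = 1000 steps; a cosine option is provided.
#'
#' @param T_steps number of timesteps.
#' @param kind "linear" or "cosine".
#' @param beta_start,beta_end linear schedule endpoints.
#' @return a `diffusion_schedule` list with betas, alphas, alpha_bars.
#' @export
make_schedule <- function(T_steps = 1000L, kind = c("linear", "cosine"),
                          beta_start = 1e-4, beta_end = 0.02) {
  kind <- match.arg(kind)
  if (T_steps < 1L) stop("T must be >= 1")
  if (kind == "linear") {
    betas <- seq(beta_start, beta_end, length.out = T_steps)
  } else {
    s <- 0.008
    f <- function(t) cos((t / T_steps + s) / (1 + s) * pi / 2)^2
    ab <- f(0:T_steps) / f(0)
    betas <- pmin(pmax(1 - ab[-1] / ab[-(T_steps + 1)], 1e-8), 0.999)
  }
  alphas <- 1 - betas
  alpha_bars <- cumprod(alphas)
  sch <- structure(list(T_steps = as.integer(T_steps), betas = betas,
                        alphas = alphas, alpha_bars = alpha_bars, kind = kind),
                   class = "diffusion_schedule")
  stopifnot(all(betas > 0 & betas < 1), all(diff(alpha_bars) < 0))
  sch
}

#' Sample the forward-process marginal q(z_t | z_0)
#'
#' Draws z_t = sqrt(alpha_bar_t) z0 + sqrt(1 - alpha_bar_t) eps with
#' eps ~ N(0, I), the closed-form marginal implied by iterating the
#' stepwise Gaussian corruption. t = 0 returns z0 exactly.
#'
#' @param z0 matrix (B x d) or vector of clean embeddings.
#' @param t integer timestep (scalar or length B), 0 <= t <= T.
#' @param schedule a `diffusion_schedule`.
#' @param seed optional RNG seed.
#' @param noise optional pre-drawn noise of the same shape as z0.
#' @return matrix of noisy embeddings.
#' @export
q_sample <- function(z0, t, schedule, seed = NULL, noise = NULL) {
  if (is.null(dim(z0))) z0 <- matrix(z0, 1)
  if (any(t < 0L | t > schedule$T_steps)) stop("t out of range [0, T]")
  ab <- ifelse(t == 0L, 1, schedule$alpha_bars[pmax(t, 1L)])
  if (is.null(noise)) {
    if (!is.null(seed)) set.seed(seed)
    noise <- matrix(stats::rnorm(length(z0)), nrow(z0))
  }
  sqrt(ab) * z0 + sqrt(1 - ab) * noise
}

#' Gaussian posterior q(z_{t-1} | z_t, z_0)
#'
#' Bayes' rule applied to the linear-Gaussian forward process gives a
#' Gaussian with mean
#' mu = sqrt(alpha_bar_{t-1}) beta_t / (1 - alpha_bar_t) z0 +
#'      sqrt(alpha_t) (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t) z_t
#' and variance beta_tilde_t = (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t) beta_t.
#' t = 1 deterministically returns z0 (variance 0).
#'
#' @param z0 clean (or predicted-clean) embeddings, B x d.
#' @param zt noisy embeddings at step t, B x d.
#' @param t integer timestep, 1 <= t <= T.
#' @param schedule a `diffusion_schedule`.
#' @return list(mean = B x d matrix, var = scalar variance).
#' @export
posterior_params <- function(z0, zt, t, schedule) {
  if (is.null(dim(z0))) z0 <- matrix(z0, 1)
  if (is.null(dim(zt))) zt <- matrix(zt, 1)
  if (t < 1L || t > schedule$T_steps) stop("t out of range [1, T]")
  if (t == 1L) return(list(mean = z0, var = 0))
  ab_t <- schedule$alpha_bars[t]
  ab_prev <- schedule$alpha_bars[t - 1L]
  beta_t <- schedule$betas[t]
  alpha_t <- schedule$alphas[t]
  coef0 <- sqrt(ab_prev) * beta_t / (1 - ab_t)
  coeft <- sqrt(alpha_t) * (1 - ab_prev) / (1 - ab_t)
  list(mean = coef0 * z0 + coeft * zt,
       var = (1 - ab_prev) / (1 - ab_t) * beta_t)
}

#' Diffusion prior training loss (x0 parameterization)
#'
#' Draws t uniformly from 1..T and noise for each row, corrupts z0 to z_t,
#' and returns the mean-squared error between the network's prediction of
#' the clean embedding f(z_t, t, y) and z0.
#'
#' @param net a `prior_net`.
#' @param z0 clean face embeddings, B x latent.
#' @param y conditioning SNP embeddings, B x latent (or NULL).
#' @param schedule a `diffusion_schedule`.
#' @param seed RNG seed for (t, noise).
#' @param covariates optional covariate data.frame aligned with rows.
#' @return scalar loss.
#' @export
prior_loss <- function(net, z0, y, schedule, seed = NULL, covariates = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(z0))) z0 <- matrix(z0, 1)
  B <- nrow(z0)
  t <- sample.int(schedule$T_steps, B, replace = TRUE)
  zt <- q_sample(z0, t, schedule)
  pred <- prior_forward(net, ad_wrap_params(net$params), ad_const(zt), t,
                        if (is.null(y)) NULL else ad_const(y),
                        covariates, training = FALSE)
  mean((ad_value(pred) - z0)^2)
}

#' Ancestral sampling from the conditional diffusion prior
#'
#' Starts from z_T ~ N(0, I) and at each step predicts the clean embedding
#' z0_hat = f(z_t, t, y), then draws z_{t-1} from the Gaussian posterior
#' q(z_{t-1} | z_t, z0_hat). The final step returns z0_hat deterministically.
#' Uses the EMA weights when present (default).
#'
#' @param net a `prior_net`.
#' @param y conditioning SNP embeddings, B x latent (or NULL for the
#'   covariates-only ablation).
#' @param schedule a `diffusion_schedule`.
#' @param seed RNG seed; the chain is deterministic given (y, seed).
#' @param covariates optional covariate data.frame (B rows).
#' @param use_ema sample with the EMA weights if available.
#' @param n optional batch size when y is NULL.
#' @return B x latent matrix of sampled face embeddings.
#' @export
sample_prior <- function(net, y, schedule, seed = 1L, covariates = NULL,
                         use_ema = TRUE, n = NULL) {
  params <- if (use_ema && !is.null(net$ema)) net$ema else net$params
  if (!is.null(y) && is.null(dim(y))) y <- matrix(y, 1)
  B <- if (!is.null(y)) nrow(y) else if (!is.null(covariates)) nrow(covariates)
       else n %||% 1L
  d <- net$spec$latent
  set.seed(seed)
  zt <- matrix(stats::rnorm(B * d), B, d)
  for (t in seq(schedule$T_steps, 1L)) {
    pred <- prior_predict(net, params, zt, rep(t, B), y, covariates)
    if (any(!is.finite(pred))) {
      stop("non-finite prediction in sampling chain at step t = ", t)
    }
    if (t == 1L) {
      zt <- pred
    } else {
      post <- posterior_params(pred, zt, t, schedule)
      zt <- post$mean + sqrt(post$var) * matrix(stats::rnorm(B * d), B, d)
    }
  }
  zt
}
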