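# Small softmax MLP classifier used for latent-feature prediction and as
# the differentiable head for gradient-based SNP attribution.

mlp_init <- function(d_in, n_classes, hidden = 16L, seed = 1L) {
  set.seed(seed)
  list(params = list(W1 = glorot(d_in, hidden), b1 = numeric(hidden),
                     W2 = glorot(hidden, n_classes), b2 = numeric(n_classes)),
       d_in = d_in, n_classes = n_classes, hidden = hidden)
}

mlp_forward <- function(p, x) {
  h <- ad_relu(ad_add_bias(ad_matmul(x, p$W1), p$b1))
  ad_add_bias(ad_matmul(h, p$W2), p$b2)
}

#' Train a softmax MLP classifier
#'
#' One hidden ReLU layer followed by a softmax output, trained with AdamW on
#' cross-entropy. Used to predict categorical facial features from latent
#' embeddings.
#'
#' @param x N x d feature matrix.
#' @param y factor (or integer) class labels.
#' @param hidden hidden width.
#' @param epochs full-batch training epochs.
#' @param lr learning rate.
#' @param seed RNG seed.
#' @return an `mlp_classifier` with the class levels attached.
#' @export
mlp_train <- function(x, y, hidden = 16L, epochs = 300L, lr = 5e-3, seed = 1L) {
  y <- as.factor(y)
  levels_ <- levels(y)
  yi <- as.integer(y)
  model <- mlp_init(ncol(x), length(levels_), hidden, seed)
  p <- model$params
  opt <- adamw_new(p)
  xs <- scale(x)
  ctr <- attr(xs, "scaled:center"); scl <- attr(xs, "scaled:scale")
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  for (e in seq_len(epochs)) {
    nodes <- ad_wrap_params(p)
    loss <- ad_cross_entropy(mlp_forward(nodes, ad_const(xs)), yi)
    ad_backward(loss)
    g <- lapply(nodes, function(nd) nd$grad %||% (nd$value * 0))
    res <- adamw_step(p, g, opt, lr = lr, wd = 1e-4)
    p <- res$params; opt <- res$state
  }
  structure(list(params = p, levels = levels_, center = ctr, scale = scl,
                 hidden = hidden), class = "mlp_classifier")
}

#' @rdname mlp_train
#' @param model an `mlp_classifier`.
#' @param type "class" or "prob".
#' @export
mlp_predict <- function(model, x, type = c("class", "prob")) {
  type <- match.arg(type)
  xs <- sweep(sweep(x, 2L, model$center, "-"), 2L, model$scale, "/")
  logits <- ad_value(mlp_forward(ad_wrap_params(model$params), ad_const(xs)))
  if (type == "prob") {
    ex <- exp(logits - apply(logits, 1, max))
    pr <- ex / rowSums(ex)
    colnames(pr) <- model$levels
    return(pr)
  }
  factor(model$levels[max.col(logits, ties.method = "first")],
         levels = model$levels)
}
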