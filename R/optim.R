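# Adam optimizer with decoupled weight decay, operating on flat named lists
# of arrays. Parameter "groups" (e.g. core vs decoder, each with its own
# learning rate and weight decay) are handled by the caller passing per-group
# lr/wd to adamw_step().

adamw_new <- function(params) {
  st <- list(t = 0L, m = rapply(params, function(p) p * 0, how = "replace"),
             v = rapply(params, function(p) p * 0, how = "replace"))
  st
}

# params/grads: flat named lists of arrays (same names). Returns list(params, state).
adamw_step <- function(params, grads, state, lr, wd = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + wd * params[[nm]])
  }
  list(params = params, state = state)
}

# Global L2 gradient-norm clipping across a flat list of gradient arrays.
clip_grad_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm && total > 0) {
    sc <- max_norm / total
    grads <- rapply(grads, function(g) g * sc, how = "replace")
  }
  attr(grads, "norm") <- total
  grads
}

# Exponential moving average of parameters: ema <- beta*ema + (1-beta)*param.
ema_update <- function(ema, params, beta) {
  for (nm in names(params)) {
    ema[[nm]] <- beta * ema[[nm]] + (1 - beta) * params[[nm]]
  }
  ema
}

# Flatten a nested parameter list to a single-level named list (path names).
flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    if (is.list(x[[nm]])) {
      out <- c(out, flatten_params(x[[nm]], key))
    } else {
      out[[key]] <- x[[nm]]
    }
  }
  out
}

unflatten_params <- function(flat, skeleton) {
  res <- skeleton
  assign_path <- function(lst, path, value) {
    if (length(path) == 1L) {
      lst[[path]] <- value
    } else {
      lst[[path[1L]]] <- assign_path(lst[[path[1L]]], path[-1L], value)
    }
    lst
  }
  for (nm in names(flat)) {
    res <- assign_path(res, strsplit(nm, ".", fixed = TRUE)[[1L]], flat[[nm]])
  }
  res
}
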