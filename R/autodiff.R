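# Minimal reverse-mode automatic differentiation over R arrays.
#
# Every differentiable quantity is an `ad_node`: an environment holding a
# numeric value (matrix or 3-d array), its parents in the computation graph,
# and a backward closure mapping the output gradient to parent gradients.
# Graphs are built dynamically per forward pass; ad_backward() runs a
# topological sweep and accumulates gradients into the nodes, from which the
# optimizer reads them. Values are plain doubles so all heavy lifting is
# delegated to BLAS / Matrix sparse products.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

ad_next_id <- function() {
  .ad_env$counter <- .ad_env$counter + 1L
  .ad_env$counter
}

#' @noRd
ad_node <- function(value, parents = list(), backfn = NULL, requires = NULL) {
  if (length(parents) > 0) {
    parents <- lapply(parents, function(p) {
      if (inherits(p, "ad_node")) p else ad_const(p)
    })
  }
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  e$nid <- ad_next_id()
  if (is.null(requires)) {
    requires <- length(parents) > 0 &&
      any(vapply(parents, function(p) p$requires, logical(1)))
  }
  e$requires <- requires
  class(e) <- "ad_node"
  e
}

ad_is_node <- function(x) inherits(x, "ad_node")

ad_const <- function(x) ad_node(x, requires = FALSE)

ad_param <- function(x) ad_node(x, requires = TRUE)

ad_value <- function(x) if (ad_is_node(x)) x$value else x

# Wrap a (possibly nested) list of arrays as parameter nodes.
ad_wrap_params <- function(params) {
  rapply(params, ad_param, classes = c("matrix", "array", "numeric"),
         how = "replace")
}

# Wrap as constants (frozen weights: no gradients tracked).
ad_wrap_consts <- function(params) {
  rapply(params, ad_const, classes = c("matrix", "array", "numeric"),
         how = "replace")
}

# Collect gradients from a wrapped parameter structure (zeros if unused).
ad_collect_grads <- function(wrapped) {
  rapply(wrapped, function(nd) {
    if (is.null(nd$grad)) array(0, dim = dim(nd$value) %||% length(nd$value)) else nd$grad
  }, classes = "ad_node", how = "replace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- backward pass ---------------------------------------------------------

ad_backward <- function(root, seed_grad = NULL) {
  stopifnot(ad_is_node(root))
  if (is.null(seed_grad)) {
    stopifnot(length(root$value) == 1L)
    seed_grad <- 1
  }
  # iterative topological order (DFS, post-order)
  order <- vector("list", 256L)
  n_ord <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, i = 0L))
  assign(as.character(root$nid), TRUE, envir = visited)
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    node <- top$node
    kids <- node$parents
    if (top$i < length(kids)) {
      stack[[length(stack)]]$i <- top$i + 1L
      child <- kids[[top$i + 1L]]
      key <- as.character(child$nid)
      if (child$requires && !exists(key, envir = visited, inherits = FALSE)) {
        assign(key, TRUE, envir = visited)
        stack[[length(stack) + 1L]] <- list(node = child, i = 0L)
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  root$grad <- seed_grad
  for (k in seq(n_ord, 1L)) {
    node <- order[[k]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    gs <- node$backfn(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$requires || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(root)
}

# ---- elementwise & linear ops ---------------------------------------------

ad_add <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(av + bv, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_node(ad_value(a) - ad_value(b), list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(a, s) {  # s plain scalar
  ad_node(ad_value(a) * s, list(a), function(g) list(g * s))
}

ad_matmul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

# constant sparse matrix G times dense node x
ad_spmm <- function(G, x) {
  xv <- ad_value(x)
  ad_node(as.matrix(G %*% xv), list(x), function(g) {
    list(as.matrix(Matrix::crossprod(G, g)))
  })
}

# add a row-vector bias to every row of a matrix
ad_add_bias <- function(x, b) {
  xv <- ad_value(x); bv <- ad_value(b)
  ad_node(sweep(xv, 2L, as.numeric(bv), "+"), list(x, b), function(g) {
    list(g, colSums(g))
  })
}

ad_relu <- function(x) {
  xv <- ad_value(x)
  mask <- xv > 0
  ad_node(xv * mask, list(x), function(g) list(g * mask))
}

ad_hcat <- function(xs) {
  vals <- lapply(xs, ad_value)
  ncols <- vapply(vals, ncol, integer(1))
  ends <- cumsum(ncols)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(do.call(cbind, vals), xs, function(g) {
    lapply(seq_along(xs), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

ad_vcat <- function(xs) {
  vals <- lapply(xs, ad_value)
  nrows <- vapply(vals, nrow, integer(1))
  ends <- cumsum(nrows)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(do.call(rbind, vals), xs, function(g) {
    lapply(seq_along(xs), function(j) g[starts[j]:ends[j], , drop = FALSE])
  })
}

ad_reshape <- function(x, dims) {
  xv <- ad_value(x)
  old <- dim(xv)
  y <- xv
  dim(y) <- dims
  ad_node(y, list(x), function(g) {
    dim(g) <- old
    list(g)
  })
}

ad_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(if (ad_is_node(x)) x else ad_const(x))
  xv <- ad_value(x)
  mask <- array((stats::runif(length(xv)) >= p) / (1 - p), dim = dim(xv))
  ad_node(xv * mask, list(x), function(g) list(g * mask))
}

# L2-normalize each row of a matrix (used inside the contrastive loss)
ad_l2norm_rows <- function(x, eps = 1e-12) {
  xv <- ad_value(x)
  nrm <- sqrt(rowSums(xv^2)) + eps
  y <- xv / nrm
  ad_node(y, list(x), function(g) {
    dot <- rowSums(g * y)
    list((g - y * dot) / nrm)
  })
}

# layer normalization over the last dimension (rows after flattening)
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ad_value(x)
  dims <- dim(xv)
  d <- dims[length(dims)]
  xm <- xv
  dim(xm) <- c(prod(dims) / d, d)
  mu <- rowMeans(xm)
  xc <- xm - mu
  va <- rowMeans(xc^2)
  sd_ <- sqrt(va + eps)
  xhat <- xc / sd_
  gv <- as.numeric(ad_value(gamma)); bv <- as.numeric(ad_value(beta))
  y <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  dim(y) <- dims
  ad_node(y, list(x, gamma, beta), function(g) {
    gm <- g
    dim(gm) <- c(prod(dims) / d, d)
    g_gamma <- colSums(gm * xhat)
    g_beta <- colSums(gm)
    gxhat <- sweep(gm, 2L, gv, "*")
    gx <- (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat)) / sd_
    dim(gx) <- dims
    list(gx, g_gamma, g_beta)
  })
}

# ---- reductions & losses ---------------------------------------------------

ad_mean <- function(x) {
  xv <- ad_value(x)
  n <- length(xv)
  ad_node(sum(xv) / n, list(x), function(g) {
    list(array(g / n, dim = dim(xv) %||% n))
  })
}

ad_sum <- function(x) {
  xv <- ad_value(x)
  ad_node(sum(xv), list(x), function(g) {
    list(array(g, dim = dim(xv) %||% length(xv)))
  })
}

# mean absolute deviation between prediction node and constant target
ad_l1_loss <- function(pred, target) {
  pv <- ad_value(pred); tv <- ad_value(target)
  diff <- pv - tv
  n <- length(diff)
  ad_node(sum(abs(diff)) / n, list(pred), function(g) {
    list(array(g * sign(diff) / n, dim = dim(pv)))
  })
}

ad_mse_loss <- function(pred, target) {
  pv <- ad_value(pred); tv <- ad_value(target)
  diff <- pv - tv
  n <- length(diff)
  ad_node(sum(diff^2) / n, list(pred), function(g) {
    list(array(g * 2 * diff / n, dim = dim(pv)))
  })
}

# cross-entropy with integer labels (1-based), mean over rows
ad_cross_entropy <- function(logits, labels) {
  lv <- ad_value(logits)
  n <- nrow(lv)
  mx <- apply(lv, 1L, max)
  ex <- exp(lv - mx)
  sm <- ex / rowSums(ex)
  picked <- lv[cbind(seq_len(n), labels)]
  loss <- mean(log(rowSums(ex)) + mx - picked)
  ad_node(loss, list(logits), function(g) {
    gr <- sm
    gr[cbind(seq_len(n), labels)] <- gr[cbind(seq_len(n), labels)] - 1
    list(g * gr / n)
  })
}

ad_softmax_rows <- function(x) {
  xv <- ad_value(x)
  mx <- apply(xv, 1L, max)
  ex <- exp(xv - mx)
  y <- ex / rowSums(ex)
  ad_node(y, list(x), function(g) {
    list((g - rowSums(g * y)) * y)
  })
}

# ---- token-sequence helpers (3-d arrays, dim = B x n x d) ------------------

ad_stack_tokens <- function(xs) {
  # xs: list of n nodes, each B x d  ->  B x n x d
  vals <- lapply(xs, ad_value)
  B <- nrow(vals[[1]]); d <- ncol(vals[[1]]); n <- length(vals)
  y <- array(0, dim = c(B, n, d))
  for (j in seq_len(n)) y[, j, ] <- vals[[j]]
  ad_node(y, xs, function(g) {
    lapply(seq_len(n), function(j) matrix(g[, j, ], B, d))
  })
}

ad_slice_token <- function(x, j) {
  xv <- ad_value(x)
  dims <- dim(xv)
  ad_node(matrix(xv[, j, ], dims[1], dims[3]), list(x), function(g) {
    gx <- array(0, dim = dims)
    gx[, j, ] <- g
    list(gx)
  })
}

# shared linear layer applied to every token: (B,n,d) %*% W (d,m) + b
ad_linear3 <- function(x, W, b = NULL) {
  xv <- ad_value(x)
  dims <- dim(xv)
  Wv <- ad_value(W)
  x2 <- xv; dim(x2) <- c(dims[1] * dims[2], dims[3])
  y2 <- x2 %*% Wv
  if (!is.null(b)) y2 <- sweep(y2, 2L, as.numeric(ad_value(b)), "+")
  y <- y2; dim(y) <- c(dims[1], dims[2], ncol(Wv))
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ad_node(y, parents, function(g) {
    g2 <- g; dim(g2) <- c(dims[1] * dims[2], ncol(Wv))
    gx <- g2 %*% t(Wv); dim(gx) <- dims
    gW <- crossprod(x2, g2)
    if (is.null(b)) list(gx, gW) else list(gx, gW, colSums(g2))
  })
}

# Fused multi-head self-attention block over a token sequence.
# x: (B, n, d); Wq/Wk/Wv/Wo: (d, d); biases length d. Scaled dot-product
# per head with optional attention dropout; hand-written backward.
ad_mha <- function(x, Wq, bq, Wk, bk, Wv, bv_, Wo, bo, n_heads,
                   dropout_p = 0, training = FALSE) {
  xv <- ad_value(x)
  dims <- dim(xv); B <- dims[1]; n <- dims[2]; d <- dims[3]
  stopifnot(d %% n_heads == 0)
  dh <- d %/% n_heads
  scale <- 1 / sqrt(dh)
  x2 <- xv; dim(x2) <- c(B * n, d)
  Wqv <- ad_value(Wq); Wkv <- ad_value(Wk); Wvv <- ad_value(Wv); Wov <- ad_value(Wo)
  Q <- sweep(x2 %*% Wqv, 2L, as.numeric(ad_value(bq)), "+")
  K <- sweep(x2 %*% Wkv, 2L, as.numeric(ad_value(bk)), "+")
  V <- sweep(x2 %*% Wvv, 2L, as.numeric(ad_value(bv_)), "+")
  # per-sample row blocks: rows (b-1)*?? -- layout of dim() collapse is
  # b fastest, so token i of sample b sits at row (i-1)*B + b
  row_of <- function(b) seq(b, B * n, by = B)
  O <- matrix(0, B * n, d)
  A_store <- vector("list", B)
  use_drop <- training && dropout_p > 0
  M_store <- if (use_drop) {
    array((stats::runif(B * n_heads * n * n) >= dropout_p) / (1 - dropout_p),
          dim = c(n, n, n_heads, B))
  } else NULL
  for (b in seq_len(B)) {
    rs <- row_of(b)
    Ah <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cs <- ((h - 1) * dh + 1):(h * dh)
      Qh <- Q[rs, cs, drop = FALSE]; Kh <- K[rs, cs, drop = FALSE]
      S <- tcrossprod(Qh, Kh) * scale
      S <- S - S[cbind(seq_len(n), max.col(S, ties.method = "first"))]
      E <- exp(S)
      A <- E / rowSums(E)
      Ad <- if (use_drop) A * M_store[, , h, b] else A
      O[rs, cs] <- Ad %*% V[rs, cs, drop = FALSE]
      Ah[[h]] <- A
    }
    A_store[[b]] <- Ah
  }
  Y2 <- sweep(O %*% Wov, 2L, as.numeric(ad_value(bo)), "+")
  Y <- Y2; dim(Y) <- dims
  ad_node(Y, list(x, Wq, bq, Wk, bk, Wv, bv_, Wo, bo), function(g) {
    g2 <- g; dim(g2) <- c(B * n, d)
    gWo <- crossprod(O, g2)
    gbo <- colSums(g2)
    gO <- g2 %*% t(Wov)
    gQ <- matrix(0, B * n, d); gK <- matrix(0, B * n, d); gV <- matrix(0, B * n, d)
    for (b in seq_len(B)) {
      rs <- row_of(b)
      for (h in seq_len(n_heads)) {
        cs <- ((h - 1) * dh + 1):(h * dh)
        A <- A_store[[b]][[h]]
        gOh <- gO[rs, cs, drop = FALSE]
        Vh <- V[rs, cs, drop = FALSE]
        Mk <- if (!is.null(M_store)) M_store[, , h, b] else NULL
        gAd <- tcrossprod(gOh, Vh)
        Aeff <- if (!is.null(Mk)) A * Mk else A
        gV[rs, cs] <- crossprod(Aeff, gOh)
        gA <- if (!is.null(Mk)) gAd * Mk else gAd
        gS <- (gA - rowSums(gA * A)) * A * scale
        gQ[rs, cs] <- gS %*% K[rs, cs, drop = FALSE]
        gK[rs, cs] <- crossprod(gS, Q[rs, cs, drop = FALSE])
      }
    }
    gx2 <- gQ %*% t(Wqv) + gK %*% t(Wkv) + gV %*% t(Wvv)
    gx <- gx2; dim(gx) <- dims
    list(gx,
         crossprod(x2, gQ), colSums(gQ),
         crossprod(x2, gK), colSums(gK),
         crossprod(x2, gV), colSums(gV),
         gWo, gbo)
  })
}

ad_transpose <- function(x) {
  ad_node(t(ad_value(x)), list(x), function(g) list(t(g)))
}

# a %*% t(b)
ad_matmul_bt <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(tcrossprod(av, bv), list(a, b), function(g) {
    list(g %*% bv, crossprod(g, av))
  })
}

# select rows of a parameter matrix by integer index (embedding lookup)
ad_gather_rows <- function(W, idx) {
  Wv <- ad_value(W)
  ad_node(Wv[idx, , drop = FALSE], list(W), function(g) {
    gW <- matrix(0, nrow(Wv), ncol(Wv))
    for (r in seq_along(idx)) gW[idx[r], ] <- gW[idx[r], ] + g[r, ]
    list(gW)
  })
}

# Fused spiral gather: select rows of x by idx (slot-major blocks, 0 = pad ->
# zero row) and expose them as a (n_out, l*C) matrix whose column blocks are
# channel-major (an internal weight layout; learned weights absorb it).
ad_gather_concat <- function(x, idx, l) {
  xv <- ad_value(x)
  C <- ncol(xv)
  n_out <- length(idx) %/% l
  xp <- rbind(xv, 0)
  pad <- nrow(xp)
  idx2 <- ifelse(idx == 0L, pad, idx)
  Y <- xp[idx2, , drop = FALSE]
  dim(Y) <- c(n_out, l * C)
  ad_node(Y, list(x), function(g) {
    dim(g) <- c(l * n_out, C)
    rs <- rowsum(g, idx2)
    gx <- matrix(0, nrow(xv), C)
    rid <- as.integer(rownames(rs))
    keep <- rid <= nrow(xv)
    gx[rid[keep], ] <- rs[keep, , drop = FALSE]
    list(gx)
  })
}
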