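# Stage-1 objectives: mesh reconstruction L1, symmetric contrastive
# cross-entropy on cosine similarities, and their weighted sum.

#' Mesh reconstruction L1 loss
#'
#' Mean absolute coordinate deviation, averaged over samples, vertices and
#' coordinates (units: mm), so the value is comparable across mesh sizes.
#'
#' @param pred,true arrays of identical shape (B x V x 3, V x 3, ...).
#' @return scalar loss.
#' @export
mesh_l1_loss <- function(pred, true) {
  if (!identical(dim(pred), dim(true))) stop("shape mismatch in mesh_l1_loss")
  mean(abs(pred - true))
}

#' Symmetric contrastive loss on cosine similarity
#'
#' Embeddings are L2-normalized internally; the similarity logits are
#' Logit1 = alpha * zf zs^T and Logit2 = t(Logit1), and the loss is the mean
#' of the two cross-entropies against the identity pairing (labels 1..N).
#' Equals log(N) when all similarities are identical, and approaches 0 for
#' perfectly aligned, mutually orthogonal pairs as alpha grows.
#'
#' @param z_f,z_s N x d embedding matrices (row i of each is a true pair).
#' @param alpha similarity scale (inverse temperature).
#' @return scalar loss.
#' @export
contrastive_loss <- function(z_f, z_s, alpha = 10) {
  if (!all(dim(z_f) == dim(z_s))) stop("embedding shape mismatch")
  N <- nrow(z_f)
  if (N == 1L) {
    warning("contrastive loss degenerate for a single pair; returning 0")
    return(0)
  }
  zf <- z_f / sqrt(rowSums(z_f^2))
  zs <- z_s / sqrt(rowSums(z_s^2))
  logits <- alpha * tcrossprod(zf, zs)
  ce <- function(L) {
    mx <- apply(L, 1L, max)
    mean(log(rowSums(exp(L - mx))) + mx - diag(L))
  }
  (ce(logits) + ce(t(logits))) / 2
}

#' Total stage-1 loss
#'
#' @param loss_con contrastive component.
#' @param loss_mesh reconstruction component.
#' @param beta1,beta2 component weights.
#' @return beta1 * loss_con + beta2 * loss_mesh.
#' @export
total_loss <- function(loss_con, loss_mesh, beta1 = 1, beta2 = 1) {
  stopifnot(is.finite(loss_con), is.finite(loss_mesh))
  beta1 * loss_con + beta2 * loss_mesh
}

# differentiable version used inside the training loop
ad_contrastive <- function(zf_node, zs_node, alpha) {
  N <- nrow(ad_value(zf_node))
  zf <- ad_l2norm_rows(zf_node)
  zs <- ad_l2norm_rows(zs_node)
  logits <- ad_scale(ad_matmul_bt(zf, zs), alpha)
  l1 <- ad_cross_entropy(logits, seq_len(N))
  l2 <- ad_cross_entropy(ad_transpose(logits), seq_len(N))
  ad_scale(ad_add(l1, l2), 0.5)
}
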