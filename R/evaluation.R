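# Biometric and geometric evaluation: cosine similarity matching, rank-k%
# identification, EER/AUC verification, vertex-wise and chamfer geometry
# errors, determinantal-point-process diversity, and latent feature
# classification on real vs generated faces.

#' Cosine similarity matrix between two embedding sets
#'
#' @param z_query N_query x d matrix (e.g. SNP embeddings).
#' @param z_gallery N_gallery x d matrix (e.g. face embeddings).
#' @return N_query x N_gallery matrix of cosine similarities in [-1, 1].
#' @export
cosine_similarity <- function(z_query, z_gallery) {
  qn <- z_query / sqrt(rowSums(z_query^2))
  gn <- z_gallery / sqrt(rowSums(z_gallery^2))
  tcrossprod(qn, gn)
}

#' Rank-k% identification rates
#'
#' For a square matched similarity matrix (query i's true mate is gallery i),
#' the rank-k% identification rate is the percentage of queries whose true
#' mate ranks within the top ceiling(k/100 * N) gallery entries by score.
#' Ties are broken by stable gallery order.
#'
#' @param sim square similarity matrix.
#' @param rank_percents vector of k values (percent).
#' @return named numeric vector of rates in percent.
#' @export
identification_rates <- function(sim, rank_percents = c(1, 10, 20)) {
  N <- nrow(sim)
  if (N == 0L) stop("empty similarity matrix")
  if (N != ncol(sim)) stop("identification requires a square matched matrix")
  ranks <- vapply(seq_len(N), function(i) {
    ord <- order(-sim[i, ], seq_len(N))
    which(ord == i)
  }, integer(1))
  out <- vapply(rank_percents, function(k) {
    100 * mean(ranks <= ceiling(k / 100 * N))
  }, numeric(1))
  names(out) <- paste0("R", rank_percents)
  out
}

#' Verification metrics: EER and AUC
#'
#' Treats the diagonal of a matched similarity matrix as genuine scores and
#' the off-diagonal as impostor scores, sweeps all thresholds to build the
#' ROC, and reports the area under the curve (trapezoid rule) and the equal
#' error rate (linear interpolation at the FPR = FNR crossing), both in
#' percent. Degenerate score sets (all identical) return AUC 50 / EER 50.
#'
#' @param sim square similarity matrix (or list with `genuine`, `impostor`).
#' @return named vector c(EER, AUC) in percent.
#' @export
verification_metrics <- function(sim) {
  if (is.matrix(sim)) {
    genuine <- diag(sim)
    impostor <- sim[row(sim) != col(sim)]
  } else {
    genuine <- sim$genuine; impostor <- sim$impostor
  }
  scores <- c(genuine, impostor)
  labels <- c(rep(1L, length(genuine)), rep(0L, length(impostor)))
  if (length(unique(scores)) == 1L) {
    return(c(EER = 50, AUC = 50))
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(s) mean(genuine >= s), numeric(1))
  fpr <- vapply(thr, function(s) mean(impostor >= s), numeric(1))
  tpr <- c(0, tpr, 1)
  fpr <- c(0, fpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  # EER: crossing of FPR (increasing) and FNR = 1 - TPR (decreasing)
  fnr <- 1 - tpr
  d <- fpr - fnr
  k <- which(d >= 0)[1]
  eer <- if (is.na(k)) {
    0.5
  } else if (k == 1L || d[k] == 0) {
    (fpr[k] + fnr[k]) / 2
  } else {
    # linear interpolation between ROC points k-1 and k
    w <- d[k - 1] / (d[k - 1] - d[k])
    f1 <- fpr[k - 1] + w * (fpr[k] - fpr[k - 1])
    n1 <- fnr[k - 1] + w * (fnr[k] - fnr[k - 1])
    (f1 + n1) / 2
  }
  c(EER = 100 * eer, AUC = 100 * auc)
}

#' Symmetric chamfer distance between two point sets
#'
#' Mean of the two directed nearest-neighbor mean distances.
#'
#' @param a,b point matrices (n x 3, m x 3).
#' @return scalar distance (mm).
#' @export
chamfer_distance <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  (mean(apply(d, 1L, min)) + mean(apply(d, 2L, min))) / 2
}

#' Geometry errors between predicted and true meshes
#'
#' Vertex-wise Euclidean distances (requires identical topology), their mean
#' and RMSE, the symmetric chamfer distance, and optionally a per-landmark
#' error table.
#'
#' @param pred,true `tri_mesh` objects or V x 3 matrices.
#' @param landmarks optional named vector of vertex indices.
#' @return list with `per_vertex`, `mean`, `rmse`, `chamfer`, `landmark_table`.
#' @export
geometry_errors <- function(pred, true, landmarks = NULL) {
  pv <- if (inherits(pred, "tri_mesh")) pred$vertices else pred
  tv <- if (inherits(true, "tri_mesh")) true$vertices else true
  if (!all(dim(pv) == dim(tv))) {
    stop("topology mismatch: vertex-wise errors need identical vertex sets")
  }
  d <- sqrt(rowSums((pv - tv)^2))
  lm_tab <- NULL
  if (!is.null(landmarks)) {
    lm_tab <- data.frame(landmark = names(landmarks),
                         vertex = as.integer(landmarks),
                         error_mm = d[landmarks], row.names = NULL)
  }
  list(per_vertex = d, mean = mean(d), rmse = sqrt(mean(d^2)),
       chamfer = chamfer_distance(pv, tv), landmark_table = lm_tab)
}

#' Determinantal-point-process diversity score
#'
#' det(K) with K_ij = 1 / (1 + dist(c_i, c_j)), where dist is the mean
#' per-vertex Euclidean distance between meshes (or the Euclidean distance
#' between embedding vectors). A tiny seed-controlled uniform jitter
#' (<= 1e-6) is added to the diagonal for conditioning. Scores lie in [0, 1]:
#' near 1 for diverse sets, near 0 for redundant ones.
#'
#' @param items list of V x 3 matrices / `tri_mesh` objects, or a numeric
#'   matrix whose rows are embedding vectors.
#' @param dist "mesh" or "embedding".
#' @param jitter_seed RNG seed for the diagonal jitter.
#' @param jitter jitter magnitude (0 disables).
#' @return determinant of the kernel matrix.
#' @export
dpp_diversity <- function(items, dist = c("mesh", "embedding"),
                          jitter_seed = 1L, jitter = 1e-6) {
  dist <- match.arg(dist)
  if (is.matrix(items) && dist == "embedding") {
    n <- nrow(items)
    D <- as.matrix(stats::dist(items))
  } else {
    if (is.matrix(items)) items <- list(items)
    items <- lapply(items, function(e) if (inherits(e, "tri_mesh")) e$vertices else e)
    n <- length(items)
    D <- matrix(0, n, n)
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          D[i, j] <- D[j, i] <- mean(sqrt(rowSums((items[[i]] - items[[j]])^2)))
        }
      }
    }
  }
  if (any(!is.finite(D))) stop("non-finite distances in DPP kernel")
  K <- 1 / (1 + D)
  if (jitter > 0) {
    set.seed(jitter_seed)
    diag(K) <- diag(K) + stats::runif(n, 0, jitter)
  }
  det(K)
}

#' Latent feature classification on real vs generated faces
#'
#' For each categorical feature, trains a softmax MLP on training-set
#' latents of real meshes and reports test-set accuracy on (a) latents of
#' real meshes and (b) latents of generated meshes for the same individuals.
#' Single-class features are skipped with a warning.
#'
#' @param train_z training latents (real meshes).
#' @param train_labels data.frame of factor labels (training rows).
#' @param test_z_real,test_z_gen test latents of real / generated meshes.
#' @param test_labels data.frame of factor labels (test rows).
#' @param hidden,epochs classifier size / training epochs.
#' @param seed RNG seed.
#' @return data.frame(feature, n_classes, acc_real, acc_gen).
#' @export
feature_classification <- function(train_z, train_labels, test_z_real,
                                   test_z_gen, test_labels, hidden = 16L,
                                   epochs = 300L, seed = 1L) {
  out <- list()
  for (fn in names(train_labels)) {
    y_tr <- droplevels(as.factor(train_labels[[fn]]))
    if (nlevels(y_tr) < 2L) {
      warning("feature '", fn, "' has a single class; skipped")
      next
    }
    cls <- mlp_train(train_z, y_tr, hidden = hidden, epochs = epochs,
                     seed = seed)
    y_te <- factor(test_labels[[fn]], levels = cls$levels)
    acc_real <- mean(mlp_predict(cls, test_z_real) == y_te)
    acc_gen <- mean(mlp_predict(cls, test_z_gen) == y_te)
    out[[fn]] <- data.frame(feature = fn, n_classes = nlevels(y_tr),
                            acc_real = 100 * acc_real, acc_gen = 100 * acc_gen)
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
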