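# SNP-deletion robustness: subsample the panel at decreasing fractions,
# regenerate faces from the masked genotypes, and tabulate error growth
# overall and per facial region.

#' Subsample the SNP panel
#'
#' Retains floor(fraction * m) SNP columns chosen uniformly at random
#' (seeded); dropped SNPs are set to the panel mean dosage so the input
#' dimension stays fixed for the trained encoder.
#'
#' @param G n x m dosage matrix.
#' @param fraction retained fraction in (0, 1].
#' @param seed RNG seed.
#' @param impute_means optional length-m mean dosages (e.g. training-set
#'   means); defaults to colMeans(G).
#' @return list(G = masked matrix, retained = column indices, count).
#' @export
subsample_panel <- function(G, fraction, seed = 1L, impute_means = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  m <- ncol(G)
  count <- floor(fraction * m)
  set.seed(seed)
  retained <- sort(sample.int(m, count))
  if (is.null(impute_means)) impute_means <- colMeans(G)
  out <- matrix(impute_means, nrow(G), m, byrow = TRUE)
  out[, retained] <- G[, retained]
  dimnames(out) <- dimnames(G)
  list(G = out, retained = retained, count = count)
}

#' SNP-deletion error curve
#'
#' For each retention fraction, masks the test genotypes, regenerates faces
#' through the trained pipeline (SNP encoder -> diffusion prior -> decoder),
#' and computes the mean per-vertex Euclidean error against the true test
#' meshes, overall and per region; several mask seeds are averaged.
#'
#' @param pipeline a `facegen_pipeline` (see [build_pipeline()]).
#' @param dataset the `paired_dataset` the pipeline was trained on.
#' @param fractions retention fractions (default 0.9 down to 0.1).
#' @param seeds mask/sampling seeds to average over.
#' @param include_full prepend the unmasked (fraction 1) row.
#' @param n_subset optional cap on the number of test individuals used
#'   (subsampled deterministically) to bound sampling cost.
#' @return data.frame(fraction, count, region, mean_error_mm, sd_mm).
#' @export
dropout_curve <- function(pipeline, dataset, fractions = seq(0.9, 0.1, by = -0.1),
                          seeds = 1:2, include_full = TRUE, n_subset = NULL) {
  regions <- c(list(whole = seq_len(nrow(dataset$template$mesh$vertices))),
               dataset$template$regions)
  if (any(vapply(regions, length, integer(1)) == 0L)) {
    stop("empty region mask")
  }
  test_idx <- dataset$test_idx
  if (!is.null(n_subset) && n_subset < length(test_idx)) {
    set.seed(derive_seed(seeds[1], "dropout"))
    test_idx <- sort(sample(test_idx, n_subset))
  }
  G_test <- dataset$genotypes$G[test_idx, , drop = FALSE]
  train_means <- colMeans(dataset$genotypes$G[dataset$train_idx, , drop = FALSE])
  covs <- if (is.null(dataset$covariates)) NULL else
    dataset$covariates[test_idx, , drop = FALSE]
  true_shapes <- dataset$shapes[test_idx, , , drop = FALSE]
  fr_list <- if (include_full) c(1, fractions) else fractions
  # stack every (fraction, mask-seed) condition into one generation batch so
  # the whole table costs a single ancestral sampling chain
  combos <- expand.grid(seed = seeds, fraction = fr_list)
  n_te <- length(test_idx)
  G_stack <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    subsample_panel(G_test, combos$fraction[k], seed = combos$seed[k],
                    impute_means = train_means)$G
  }))
  covs_stack <- if (is.null(covs)) NULL else
    covs[rep(seq_len(n_te), nrow(combos)), , drop = FALSE]
  gen <- generate_faces(pipeline, G_stack, covariates = covs_stack,
                        seed = 1000L + seeds[1])
  per_combo <- t(vapply(seq_len(nrow(combos)), function(k) {
    off <- (k - 1L) * n_te
    errs <- vapply(seq_len(n_te), function(i) {
      sqrt(rowSums((gen[off + i, , ] - true_shapes[i, , ])^2))
    }, numeric(dim(gen)[2]))
    vapply(regions, function(rg) mean(errs[rg, ]), numeric(1))
  }, numeric(length(regions))))
  rows <- list()
  for (fr in fr_list) {
    mat <- per_combo[combos$fraction == fr, , drop = FALSE]
    for (rg in names(regions)) {
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = fr, count = floor(fr * ncol(G_test)), region = rg,
        mean_error_mm = mean(mat[, rg]), sd_mm = stats::sd(mat[, rg]))
    }
  }
  do.call(rbind, rows)
}
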