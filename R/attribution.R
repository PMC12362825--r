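# Gradient-based SNP attribution through the frozen SNP encoder and a
# feature classifier (expected-gradients estimator of SHAP values), top-k
# selection with an independent-locus filter, and hypergeometric enrichment
# of selected SNPs against GWAS-significant sets.

#' Expected-gradients SNP attribution
#'
#' Estimates per-SNP attributions of a class score by averaging, over
#' baselines b sampled from the dataset and interpolation points along the
#' straight path from b to x, the input gradient of the score times
#' (x - b). For a linear score w'x this reduces exactly to
#' w_j * (x_j - mean baseline_j). The encoder and classifier are treated as
#' frozen: gradients flow to the inputs only.
#'
#' @param snp_model a `snp_encoder`, or NULL to attribute the classifier
#'   directly on the raw inputs.
#' @param classifier an `mlp_classifier` trained on the encoder's latents
#'   (or on raw inputs when `snp_model` is NULL).
#' @param inputs n x m genotype matrix to explain.
#' @param baselines n_b x m genotype matrix sampled from the dataset.
#' @param target_class integer or factor-level class per input row (defaults
#'   to the classifier's predicted class).
#' @param n_baselines baselines drawn per estimate.
#' @param n_points interpolation points per baseline (midpoint grid).
#' @param seed RNG seed.
#' @return an `attribution_result`: list with `attributions` (n x m),
#'   `mean_abs` (length m), `target_class`, `seed`.
#' @export
gradient_attribution <- function(snp_model, classifier, inputs, baselines,
                                 target_class = NULL, n_baselines = 50L,
                                 n_points = 20L, seed = 1L) {
  if (is.null(baselines) || nrow(baselines) == 0L) {
    stop("at least one baseline sample is required")
  }
  inputs <- as.matrix(inputs)
  n <- nrow(inputs); m <- ncol(inputs)
  score_fn <- function(x_node) {
    feats <- if (is.null(snp_model)) {
      x_node
    } else {
      snp_enc_forward(snp_model, ad_wrap_consts(snp_model$params), x_node,
                      training = FALSE)
    }
    if (!is.null(classifier$center)) {
      feats <- ad_add_bias(feats, -classifier$center)
      feats <- ad_mul(feats, ad_const(matrix(1 / classifier$scale,
                                             nrow(ad_value(feats)),
                                             length(classifier$scale),
                                             byrow = TRUE)))
    }
    mlp_forward(classifier$params, feats)
  }
  if (is.null(target_class)) {
    logits <- ad_value(score_fn(ad_const(inputs)))
    target_class <- max.col(logits, ties.method = "first")
  } else if (is.factor(target_class) || is.character(target_class)) {
    target_class <- match(as.character(target_class), classifier$levels)
  }
  stopifnot(length(target_class) == n)
  set.seed(seed)
  # use every baseline when the budget allows, otherwise subsample
  if (n_baselines >= nrow(baselines)) {
    base_rows <- seq_len(nrow(baselines))
  } else {
    base_rows <- sample.int(nrow(baselines), n_baselines)
  }
  n_baselines <- length(base_rows)
  total <- matrix(0, n, m)
  alphas <- (seq_len(n_points) - 0.5) / n_points
  for (bi in base_rows) {
    b <- baselines[bi, ]
    diff_x <- sweep(inputs, 2L, b, "-")
    grad_acc <- matrix(0, n, m)
    for (a in alphas) {
      x_a <- sweep(diff_x * a, 2L, b, "+")
      x_node <- ad_param(x_a)
      logits <- score_fn(x_node)
      # scalar objective: sum of each sample's target-class logit
      pick <- ad_node(sum(ad_value(logits)[cbind(seq_len(n), target_class)]),
                      list(logits), function(g) {
                        gl <- matrix(0, n, ncol(ad_value(logits)))
                        gl[cbind(seq_len(n), target_class)] <- g
                        list(gl)
                      })
      ad_backward(pick)
      grad_acc <- grad_acc + x_node$grad
    }
    total <- total + diff_x * (grad_acc / n_points)
  }
  attributions <- total / n_baselines
  structure(list(attributions = attributions,
                 mean_abs = colMeans(abs(attributions)),
                 target_class = target_class, n_baselines = n_baselines,
                 n_points = n_points, seed = seed),
            class = "attribution_result")
}

#' Select the top-k SNPs by mean absolute attribution
#'
#' @param attr an `attribution_result` or a numeric score vector.
#' @param k number of SNPs to keep (ties broken by lowest SNP index).
#' @param locus_tags optional per-SNP locus tags; when given, only the
#'   best-scoring SNP per locus is eligible (independent-loci filter).
#' @return integer vector of selected SNP indices.
#' @export
select_top_snps <- function(attr, k, locus_tags = NULL) {
  scores <- if (inherits(attr, "attribution_result")) attr$mean_abs else attr
  if (k <= 0L) stop("k must be positive")
  if (k > length(scores)) stop("k exceeds the panel size")
  eligible <- seq_along(scores)
  if (!is.null(locus_tags)) {
    stopifnot(length(locus_tags) == length(scores))
    keep <- unlist(lapply(split(seq_along(scores), locus_tags), function(idx) {
      idx[order(-scores[idx], idx)[1]]
    }), use.names = FALSE)
    eligible <- sort(keep)
    if (k > length(eligible)) k <- length(eligible)
  }
  ord <- eligible[order(-scores[eligible], eligible)]
  sort(ord[seq_len(k)])
}

#' Hypergeometric enrichment of a SNP set against a GWAS set
#'
#' Upper-tail probability P(X >= overlap) for X ~ Hypergeometric drawing
#' |top_set| SNPs from a panel containing |gwas_set| successes.
#'
#' @param top_set integer indices (or ids) of selected SNPs.
#' @param gwas_set integer indices (or ids) of GWAS-significant SNPs.
#' @param panel_size total number of SNPs in the panel.
#' @return list(overlap, p_value, k_top, n_gwas, panel_size).
#' @export
hypergeometric_enrichment <- function(top_set, gwas_set, panel_size) {
  if (length(top_set) == 0L || length(gwas_set) == 0L) {
    warning("empty SNP set; returning p = 1")
    return(list(overlap = 0L, p_value = 1, k_top = length(top_set),
                n_gwas = length(gwas_set), panel_size = panel_size))
  }
  overlap <- length(intersect(top_set, gwas_set))
  p <- stats::phyper(overlap - 1, length(gwas_set),
                     panel_size - length(gwas_set), length(top_set),
                     lower.tail = FALSE)
  list(overlap = overlap, p_value = p, k_top = length(top_set),
       n_gwas = length(gwas_set), panel_size = panel_size)
}
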