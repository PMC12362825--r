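# End-to-end pipeline orchestration: two-stage training (contrastive
# alignment, then the frozen-encoder diffusion prior), DNA-to-face
# generation, and the full evaluation report.

#' Desk-scale default configuration
#'
#' One bundle of model/training sizes for the synthetic desk-scale study
#' (template level 3: 642 vertices; panel m = 400; latent 32). The
#' cohort-scale reference hyperparameters remain the defaults of the individual
#' config constructors; this bundle overrides sizes and optimizer settings
#' to values that train a desk-scale model from scratch in minutes on one
#' CPU core.
#'
#' @param n,m,level dataset size, panel size, template subdivision level.
#' @param latent shared embedding dimension.
#' @param seed master seed; per-stage seeds are derived via [derive_seed()].
#' @return nested config list.
#' @export
desk_config <- function(n = 600L, m = 400L, level = 3L, latent = 32L,
                        seed = 1L) {
  list(
    data = list(n = n, m = m, level = level, n_causal = 48L, effect_mm = 1.0,
                noise_sd = 0.15, maf_range = c(0.1, 0.5), covariates = TRUE,
                train_frac = 0.8),
    face = face_ae_spec(V = 10L * 4L^level + 2L, channels = c(16L, 16L, 16L, 32L),
                        pool_factors = c(4L, 4L, 4L, 2L), latent = latent),
    snp = snp_encoder_spec(m = m, chunk = 20L, model_dim = 64L, ff_dim = 256L,
                           layers = 2L, heads = 8L, latent = latent),
    align = align_config(alpha = 20, batch_size = 64L, lr_core = 2e-3,
                         wd_core = 1e-4, lr_decoder = 2e-3, wd_decoder = 1e-4,
                         lr_decay = 0.985, epochs = 60L, aug_mask = 0.3,
                         seed = derive_seed(seed, "align")),
    prior = prior_spec(latent = latent, model_dim = 64L, depth = 4L,
                       heads = 4L, ff_mult = 2L, conditions = "snps"),
    prior_train = prior_config(lr = 1e-3, wd = 1e-2, batch_size = 64L,
                               steps = 1700L, cond_noise = 0.3,
                               seed = derive_seed(seed, "prior")),
    # beta_end scaled so alpha_bar_T stays near 0 at the shorter horizon
    schedule = list(T_steps = 300L, kind = "linear", beta_start = 1e-4,
                    beta_end = 0.032),
    seed = as.integer(seed)
  )
}

#' Derive a per-stage seed from the global seed
#'
#' Deterministic fan-out so each pipeline stage is independently
#' reproducible: seed * 1009 + a fixed per-stage offset, reduced modulo
#' 2^31 - 1.
#'
#' @param seed global integer seed.
#' @param stage one of "data", "init", "align", "prior", "sample", "eval",
#'   "attr", "dropout".
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  offsets <- c(data = 1L, init = 2L, align = 3L, prior = 4L, sample = 5L,
               eval = 6L, attr = 7L, dropout = 8L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

#' Bundle trained components into a pipeline
#'
#' @param face a trained `face_ae`.
#' @param snp a trained `snp_encoder`.
#' @param prior a trained `prior_net` (with EMA weights).
#' @param schedule the `diffusion_schedule` used in training.
#' @param z_center,z_scale per-dimension standardization of the face
#'   embeddings used by the diffusion prior (fitted on the training split).
#' @return a `facegen_pipeline`.
#' @export
build_pipeline <- function(face, snp, prior, schedule, z_center = 0,
                           z_scale = 1) {
  structure(list(face = face, snp = snp, prior = prior, schedule = schedule,
                 z_center = z_center, z_scale = z_scale),
            class = "facegen_pipeline")
}

# encode in chunks to bound the size of cached batch operators
chunked <- function(n, size = 120L) split(seq_len(n), ceiling(seq_len(n) / size))

#' Face embeddings for a stack of meshes
#' @param pipeline a `facegen_pipeline`.
#' @param shapes B x V x 3 array.
#' @return B x latent matrix.
#' @export
face_latents <- function(pipeline, shapes) {
  do.call(rbind, lapply(chunked(dim(shapes)[1]), function(idx) {
    face_encode(pipeline$face, shapes[idx, , , drop = FALSE])
  }))
}

#' SNP embeddings for a genotype matrix
#' @param pipeline a `facegen_pipeline`.
#' @param G B x m dosage matrix.
#' @return B x latent matrix.
#' @export
snp_latents <- function(pipeline, G) {
  do.call(rbind, lapply(chunked(nrow(G)), function(idx) {
    snp_encode(pipeline$snp, G[idx, , drop = FALSE])
  }))
}

#' Generate faces from genotypes
#'
#' DNA-to-face path: SNP encoder -> conditional diffusion prior (ancestral
#' sampling with the EMA weights) -> face decoder.
#'
#' @param pipeline a `facegen_pipeline`.
#' @param G B x m genotype dosage matrix.
#' @param covariates optional covariate data.frame (B rows) if the prior
#'   conditions on covariates.
#' @param seed sampling seed (deterministic chain given inputs + seed).
#' @return B x V x 3 array of generated vertex coordinates.
#' @export
generate_faces <- function(pipeline, G, covariates = NULL, seed = 1L) {
  z_s <- if ("snps" %in% pipeline$prior$spec$conditions) {
    snp_latents(pipeline, G)
  } else NULL
  n_row <- if (!is.null(z_s)) nrow(z_s) else nrow(covariates)
  z_std <- sample_prior(pipeline$prior, z_s, pipeline$schedule, seed = seed,
                        covariates = covariates, n = n_row)
  # prior operates on standardized embeddings; map back to encoder scale
  z_f <- sweep(sweep(z_std, 2L, pipeline$z_scale, "*"), 2L,
               pipeline$z_center, "+")
  V <- nrow(pipeline$face$hierarchy$levels[[1]]$vertices)
  out <- array(0, dim = c(nrow(z_f), V, 3))
  for (idx in chunked(nrow(z_f))) {
    dec <- face_decode(pipeline$face, z_f[idx, , drop = FALSE])
    if (length(idx) == 1L) out[idx, , ] <- dec else out[idx, , ] <- dec
  }
  out
}

#' Train the full two-stage pipeline on a paired dataset
#'
#' Stage 1 trains the contrastive alignment (face autoencoder + SNP
#' encoder); stage 2 freezes the encoders, embeds the training split, and
#' trains the conditional diffusion prior on the embeddings.
#'
#' @param dataset a `paired_dataset`.
#' @param cfg from [desk_config()].
#' @param use_covariates condition the prior on age/sex/BMI as well as SNPs.
#' @param verbose print progress.
#' @return list(pipeline, align_history, prior_history).
#' @export
train_pipeline <- function(dataset, cfg = desk_config(), use_covariates = FALSE,
                           verbose = FALSE) {
  face <- face_ae_init(dataset$template$mesh, cfg$face,
                       seed = derive_seed(cfg$seed, "init"))
  snp <- snp_encoder_init(cfg$snp, seed = derive_seed(cfg$seed, "init") + 1L)
  st1 <- train_alignment(dataset, face, snp, cfg$align, verbose = verbose)
  sched <- make_schedule(cfg$schedule$T_steps, cfg$schedule$kind,
                         beta_start = cfg$schedule$beta_start %||% 1e-4,
                         beta_end = cfg$schedule$beta_end %||% 0.02)
  pipe0 <- build_pipeline(st1$face, st1$snp, NULL, sched)
  tr <- dataset$train_idx
  z_f <- face_latents(pipe0, dataset$shapes[tr, , , drop = FALSE])
  z_s <- snp_latents(pipe0, dataset$genotypes$G[tr, , drop = FALSE])
  z_center <- colMeans(z_f)
  z_scale <- apply(z_f, 2L, stats::sd)
  z_scale[z_scale < 1e-8] <- 1
  z_f_std <- sweep(sweep(z_f, 2L, z_center, "-"), 2L, z_scale, "/")
  pspec <- cfg$prior
  covs <- NULL
  if (use_covariates) {
    pspec$conditions <- c("snps", "age", "sex", "bmi")
    covs <- dataset$covariates[tr, , drop = FALSE]
  }
  net <- prior_init(pspec, seed = derive_seed(cfg$seed, "init") + 2L)
  st2 <- train_prior(z_f_std, z_s, net, sched, cfg$prior_train,
                     covariates = covs, verbose = verbose)
  list(pipeline = build_pipeline(st1$face, st1$snp, st2$net, sched,
                                 z_center = z_center, z_scale = z_scale),
       align_history = st1$history, prior_history = st2$history)
}

#' Evaluate a trained pipeline on the held-out split
#'
#' Computes the full evaluation report: cosine-matching identification
#' rates and EER/AUC verification on the test split, generation geometry
#' errors (mean Euclidean, RMSE, chamfer) against the population-mean-face
#' baseline, DPP diversity of real vs generated faces, and latent feature
#' classification accuracy on real vs generated meshes.
#'
#' @param pipeline a `facegen_pipeline`.
#' @param dataset the `paired_dataset`.
#' @param seed evaluation seed (prior sampling, classifiers, DPP jitter).
#' @param rank_percents identification rank percentages.
#' @param n_dpp number of test items entering each DPP kernel.
#' @return an `eval_report` list.
#' @export
evaluate_pipeline <- function(pipeline, dataset, seed = 1L,
                              rank_percents = c(1, 10, 20), n_dpp = 10L) {
  te <- dataset$test_idx
  tr <- dataset$train_idx
  covs_te <- if (!is.null(dataset$covariates) &&
                 any(c("age", "sex", "bmi") %in% pipeline$prior$spec$conditions)) {
    dataset$covariates[te, , drop = FALSE]
  } else NULL
  z_f_te <- face_latents(pipeline, dataset$shapes[te, , , drop = FALSE])
  z_s_te <- snp_latents(pipeline, dataset$genotypes$G[te, , drop = FALSE])
  sim <- cosine_similarity(z_s_te, z_f_te)
  ident <- identification_rates(sim, rank_percents)
  verif <- verification_metrics(sim)
  gen <- generate_faces(pipeline, dataset$genotypes$G[te, , drop = FALSE],
                        covariates = covs_te,
                        seed = derive_seed(seed, "sample"))
  true_te <- dataset$shapes[te, , , drop = FALSE]
  per_sample <- t(vapply(seq_along(te), function(i) {
    ge <- geometry_errors(gen[i, , ], true_te[i, , ])
    c(mean = ge$mean, rmse = ge$rmse, chamfer = ge$chamfer)
  }, numeric(3)))
  mean_face <- apply(dataset$shapes[tr, , , drop = FALSE], c(2, 3), mean)
  baseline <- vapply(seq_along(te), function(i) {
    mean(sqrt(rowSums((mean_face - true_te[i, , ])^2)))
  }, numeric(1))
  set.seed(derive_seed(seed, "eval"))
  dpp_idx <- sample(seq_along(te), min(n_dpp, length(te)))
  dpp_real <- dpp_diversity(lapply(dpp_idx, function(i) true_te[i, , ]),
                            jitter_seed = seed)
  dpp_gen <- dpp_diversity(lapply(dpp_idx, function(i) gen[i, , ]),
                           jitter_seed = seed)
  dpp_mean <- dpp_diversity(lapply(dpp_idx, function(i) mean_face),
                            jitter_seed = seed)
  z_f_tr <- face_latents(pipeline, dataset$shapes[tr, , , drop = FALSE])
  z_gen_te <- face_latents(pipeline, gen)
  fc <- feature_classification(z_f_tr, dataset$labels[tr, , drop = FALSE],
                               z_f_te, z_gen_te,
                               dataset$labels[te, , drop = FALSE],
                               seed = derive_seed(seed, "eval"))
  structure(list(
    identification = ident,
    verification = verif,
    geometry = list(mean_euclidean_mm = mean(per_sample[, "mean"]),
                    rmse_mm = mean(per_sample[, "rmse"]),
                    chamfer_mm = mean(per_sample[, "chamfer"]),
                    baseline_mean_face_mm = mean(baseline)),
    dpp = list(generated = dpp_gen, real = dpp_real, mean_face = dpp_mean),
    feature_classification = fc,
    n_test = length(te), seed = seed
  ), class = "eval_report")
}

#' Attribution + enrichment analysis for one feature
#'
#' Trains a softmax classifier for the feature on SNP-embedding latents of
#' the training split (frozen SNP encoder), computes expected-gradients
#' attributions on test genotypes, selects the top-k SNPs, and tests their
#' hypergeometric enrichment against the feature's GWAS-significant set.
#'
#' @param pipeline a `facegen_pipeline`.
#' @param dataset the `paired_dataset`.
#' @param feature feature name (column of `dataset$labels`).
#' @param k_top number of top SNPs.
#' @param n_explain test samples to attribute (subsampled for speed).
#' @param n_baselines,n_points expected-gradients estimator settings.
#' @param independent_loci apply the best-per-locus filter before selection.
#' @param seed RNG seed.
#' @return list(enrichment, top_snps, attribution, classifier_accuracy).
#' @export
attribute_enrichment <- function(pipeline, dataset, feature, k_top = 50L,
                                 n_explain = 40L, n_baselines = 10L,
                                 n_points = 8L, independent_loci = FALSE,
                                 seed = 1L) {
  tr <- dataset$train_idx; te <- dataset$test_idx
  G <- dataset$genotypes$G
  k_top <- min(k_top, ncol(G))
  z_s_tr <- snp_latents(pipeline, G[tr, , drop = FALSE])
  cls <- mlp_train(z_s_tr, dataset$labels[[feature]][tr],
                   seed = derive_seed(seed, "attr"))
  z_s_te <- snp_latents(pipeline, G[te, , drop = FALSE])
  acc <- mean(mlp_predict(cls, z_s_te) ==
                factor(dataset$labels[[feature]][te], levels = cls$levels))
  set.seed(derive_seed(seed, "attr"))
  expl_idx <- te[sample.int(length(te), min(n_explain, length(te)))]
  attr <- gradient_attribution(pipeline$snp, cls, G[expl_idx, , drop = FALSE],
                               baselines = G[tr, , drop = FALSE],
                               target_class = dataset$labels[[feature]][expl_idx],
                               n_baselines = n_baselines, n_points = n_points,
                               seed = derive_seed(seed, "attr"))
  tags <- if (independent_loci) dataset$genotypes$locus_tags else NULL
  top <- select_top_snps(attr, k_top, locus_tags = tags)
  gwas <- dataset$gwas_sets[[feature]]$snp_index
  enr <- hypergeometric_enrichment(top, gwas, ncol(G))
  list(enrichment = enr, top_snps = top, attribution = attr,
       classifier_accuracy = 100 * acc)
}

#' Pooled attribution enrichment across features
#'
#' Computes expected-gradients attributions for every feature's classifier,
#' combines them per SNP (mean of per-feature attributions normalized to
#' unit total), selects the pooled top-k, and tests enrichment against the
#' union of the per-feature GWAS sets. Pooling raises the power of the
#' enrichment test when individual causal sets are small.
#'
#' @inheritParams attribute_enrichment
#' @param features feature names (default: all features with GWAS sets).
#' @return list(enrichment, top_snps, per_feature_scores).
#' @export
attribute_enrichment_pooled <- function(pipeline, dataset,
                                        features = names(dataset$gwas_sets),
                                        k_top = 200L, n_explain = 40L,
                                        n_baselines = 10L, n_points = 8L,
                                        seed = 1L) {
  G <- dataset$genotypes$G
  k_top <- min(k_top, ncol(G))
  tr <- dataset$train_idx; te <- dataset$test_idx
  z_s_tr <- snp_latents(pipeline, G[tr, , drop = FALSE])
  scores <- matrix(0, ncol(G), length(features),
                   dimnames = list(NULL, features))
  for (fi in seq_along(features)) {
    fn <- features[fi]
    cls <- mlp_train(z_s_tr, dataset$labels[[fn]][tr],
                     seed = derive_seed(seed, "attr") + fi)
    set.seed(derive_seed(seed, "attr") + fi)
    expl_idx <- te[sample.int(length(te), min(n_explain, length(te)))]
    attr <- gradient_attribution(pipeline$snp, cls,
                                 G[expl_idx, , drop = FALSE],
                                 baselines = G[tr, , drop = FALSE],
                                 target_class = dataset$labels[[fn]][expl_idx],
                                 n_baselines = n_baselines,
                                 n_points = n_points,
                                 seed = derive_seed(seed, "attr") + fi)
    s <- attr$mean_abs
    scores[, fi] <- s / sum(s)
  }
  pooled <- rowMeans(scores)
  top <- select_top_snps(pooled, k_top)
  gwas <- sort(unique(unlist(lapply(dataset$gwas_sets[features],
                                    function(g) g$snp_index))))
  enr <- hypergeometric_enrichment(top, gwas, ncol(G))
  list(enrichment = enr, top_snps = top, per_feature_scores = scores)
}
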