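# Stage-1 joint training: contrastive alignment of the SNP and face
# encoders plus L1 mesh reconstruction through the decoder. Two AdamW
# parameter groups (core = both encoders, decoder separate) with a
# multiplicative per-epoch learning-rate decay, as in the reference
# optimization setup.

#' Alignment training configuration
#'
#' Defaults follow the optimization settings of the reference
#' model (tuned for a large cohort); desk-scale runs typically override the
#' learning rates upward and the weight decays downward.
#'
#' @param alpha contrastive similarity scale.
#' @param beta1,beta2 loss weights (contrastive, mesh).
#' @param batch_size contrastive batch size N.
#' @param lr_core,wd_core learning rate / weight decay for both encoders.
#' @param lr_decoder,wd_decoder learning rate / weight decay for the decoder.
#' @param lr_decay multiplicative LR factor applied after each epoch.
#' @param epochs training epochs.
#' @param aug_mask fraction of SNP dosages randomly masked to the
#'   training-mean value in each batch (input-dropout augmentation;
#'   0 disables). Regularizes the SNP encoder and mirrors the panel
#'   incompleteness the deletion experiments probe.
#' @param seed RNG seed (shuffling, dropout).
#' @return config list.
#' @export
align_config <- function(alpha = 10, beta1 = 1, beta2 = 1, batch_size = 64L,
                         lr_core = 7.3e-6, wd_core = 0.30,
                         lr_decoder = 3.2e-5, wd_decoder = 0.001,
                         lr_decay = 0.99, epochs = 30L, aug_mask = 0,
                         seed = 1L) {
  stopifnot(alpha > 0, beta1 >= 0, beta2 >= 0, beta1 + beta2 > 0,
            batch_size >= 1, lr_core > 0, lr_decoder > 0, epochs >= 1,
            aug_mask >= 0, aug_mask < 1)
  list(alpha = alpha, beta1 = beta1, beta2 = beta2,
       batch_size = as.integer(batch_size), lr_core = lr_core,
       wd_core = wd_core, lr_decoder = lr_decoder, wd_decoder = wd_decoder,
       lr_decay = lr_decay, epochs = as.integer(epochs), aug_mask = aug_mask,
       seed = as.integer(seed))
}

#' Train the contrastive alignment stage
#'
#' Jointly trains face encoder, face decoder and SNP encoder on the training
#' split of a paired dataset, minimizing beta1 * contrastive + beta2 * mesh-L1.
#'
#' @param dataset a `paired_dataset`.
#' @param face_model a `face_ae` (template topology must match the dataset).
#' @param snp_model a `snp_encoder`.
#' @param cfg from [align_config()].
#' @param log_path optional JSONL file receiving one record per epoch.
#' @param checkpoint_path optional RDS checkpoint written at the end.
#' @param verbose print per-epoch losses.
#' @return list(face, snp, history) with the trained models and an epoch-wise
#'   loss history data.frame.
#' @export
train_alignment <- function(dataset, face_model, snp_model, cfg = align_config(),
                            log_path = NULL, checkpoint_path = NULL,
                            verbose = FALSE) {
  set.seed(cfg$seed)
  if (is.null(cfg$aug_mask)) cfg$aug_mask <- 0
  train_idx <- dataset$train_idx
  V <- nrow(face_model$hierarchy$levels[[1]]$vertices)
  G_all <- dataset$genotypes$G
  G_means <- colMeans(G_all[train_idx, , drop = FALSE])
  enc_p <- face_model$enc
  dec_p <- face_model$dec
  snp_p <- snp_model$params
  core_flat <- c(stats::setNames(enc_p, paste0("enc.", names(enc_p))),
                 stats::setNames(snp_p, paste0("snp.", names(snp_p))))
  opt_core <- adamw_new(core_flat)
  opt_dec <- adamw_new(dec_p)
  history <- data.frame()
  if (!is.null(log_path)) {
    dir.create(dirname(log_path), recursive = TRUE, showWarnings = FALSE)
    file.create(log_path)
  }
  for (epoch in seq_len(cfg$epochs)) {
    lr_fac <- cfg$lr_decay^(epoch - 1)
    perm <- sample(train_idx)
    n_b <- ceiling(length(perm) / cfg$batch_size)
    ep_con <- 0; ep_mesh <- 0; ep_tot <- 0; n_used <- 0L
    for (bi in seq_len(n_b)) {
      idx <- perm[((bi - 1) * cfg$batch_size + 1):min(bi * cfg$batch_size,
                                                      length(perm))]
      B <- length(idx)
      if (B < 2L) next  # contrastive loss needs at least two pairs
      xb <- aperm(dataset$shapes[idx, , , drop = FALSE], c(2, 1, 3))
      dim(xb) <- c(B * V, 3L)
      enc_nodes <- ad_wrap_params(enc_p)
      dec_nodes <- ad_wrap_params(dec_p)
      snp_nodes <- ad_wrap_params(snp_p)
      zf <- face_enc_forward(face_model, enc_nodes, ad_const(xb), B)
      xhat <- face_dec_forward(face_model, dec_nodes, zf, B)
      G_b <- G_all[idx, , drop = FALSE]
      if (cfg$aug_mask > 0) {
        # anneal the mask fraction from 1.25x to 0.5x of aug_mask over
        # training: aggressive masking early builds robust encodings,
        # lighter masking late sharpens exact matching
        frac <- cfg$aug_mask *
          (1.25 - 0.75 * (epoch - 1) / max(cfg$epochs - 1, 1))
        mask <- matrix(stats::runif(length(G_b)) < frac, nrow(G_b))
        G_b[mask] <- matrix(G_means, nrow(G_b), ncol(G_b), byrow = TRUE)[mask]
      }
      zs <- snp_enc_forward(snp_model, snp_nodes, ad_const(G_b),
                            training = TRUE)
      l_con <- ad_contrastive(zf, zs, cfg$alpha)
      l_mesh <- ad_l1_loss(xhat, xb)
      loss <- ad_add(ad_scale(l_con, cfg$beta1), ad_scale(l_mesh, cfg$beta2))
      if (!is.finite(ad_value(loss))) {
        stop(sprintf(paste0("non-finite loss at epoch %d batch %d ",
                            "(con=%g, mesh=%g; batch mean |x|=%g)"),
                     epoch, bi, ad_value(l_con), ad_value(l_mesh),
                     mean(abs(xb))))
      }
      ad_backward(loss)
      g_core <- c(stats::setNames(lapply(enc_nodes, function(nd) nd$grad %||% (nd$value * 0)),
                                  paste0("enc.", names(enc_nodes))),
                  stats::setNames(lapply(snp_nodes, function(nd) nd$grad %||% (nd$value * 0)),
                                  paste0("snp.", names(snp_nodes))))
      g_dec <- lapply(dec_nodes, function(nd) nd$grad %||% (nd$value * 0))
      core_flat <- c(stats::setNames(enc_p, paste0("enc.", names(enc_p))),
                     stats::setNames(snp_p, paste0("snp.", names(snp_p))))
      res <- adamw_step(core_flat, g_core, opt_core, lr = cfg$lr_core * lr_fac,
                        wd = cfg$wd_core)
      core_flat <- res$params; opt_core <- res$state
      enc_p <- stats::setNames(core_flat[paste0("enc.", names(enc_p))], names(enc_p))
      snp_p <- stats::setNames(core_flat[paste0("snp.", names(snp_p))], names(snp_p))
      res <- adamw_step(dec_p, g_dec, opt_dec, lr = cfg$lr_decoder * lr_fac,
                        wd = cfg$wd_decoder)
      dec_p <- res$params; opt_dec <- res$state
      ep_con <- ep_con + ad_value(l_con) * B
      ep_mesh <- ep_mesh + ad_value(l_mesh) * B
      ep_tot <- ep_tot + ad_value(loss) * B
      n_used <- n_used + B
    }
    rec <- data.frame(epoch = epoch, loss_con = ep_con / n_used,
                      loss_mesh = ep_mesh / n_used, loss_total = ep_tot / n_used,
                      lr_core = cfg$lr_core * lr_fac,
                      lr_decoder = cfg$lr_decoder * lr_fac)
    history <- rbind(history, rec)
    if (!is.null(log_path)) {
      cat(jsonlite::toJSON(as.list(rec), auto_unbox = TRUE, digits = NA),
          "\n", sep = "", file = log_path, append = TRUE)
    }
    if (verbose) {
      message(sprintf("epoch %3d  con %.4f  mesh %.4f  total %.4f",
                      epoch, rec$loss_con, rec$loss_mesh, rec$loss_total))
    }
  }
  face_model$enc <- enc_p
  face_model$dec <- dec_p
  snp_model$params <- snp_p
  out <- list(face = face_model, snp = snp_model, history = history)
  if (!is.null(checkpoint_path)) {
    save_checkpoint(list(face = face_model, snp = snp_model,
                         align_cfg = cfg, history = history), checkpoint_path)
  }
  out
}
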