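# Synthetic paired genotype-face data with planted ground truth.
#
# The simulator emulates the structure of a registered 3D-face cohort:
# Hardy-Weinberg genotype dosages at uniform MAFs, a template mesh deformed
# by per-SNP additive effect fields, covariate (age/sex/BMI) effect fields,
# Gaussian vertex noise, categorical facial-feature labels derived from
# landmark geometry, and planted "GWAS-significant" SNP sets for enrichment
# testing. Effect fields are low-rank (a few spatially smooth basis fields
# with per-SNP loadings) so a small-latent autoencoder can represent them.

#' Simulate a Hardy-Weinberg genotype matrix
#'
#' Per-SNP minor allele frequencies are drawn uniformly from `maf_range` and
#' dosages are Binomial(2, MAF), i.e. Hardy-Weinberg equilibrium.
#'
#' @param n number of samples.
#' @param m number of SNPs.
#' @param maf_range length-2 numeric in (0, 0.5].
#' @param seed RNG seed.
#' @param locus_block SNPs per locus tag (independence groups for the
#'   attribution filter).
#' @return list with `G` (n x m dosage matrix), `maf`, `snp_ids`, `locus_tags`.
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5), seed = 1L,
                               locus_block = 2L) {
  if (n < 1 || m < 1) stop("n and m must be >= 1")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be within (0, 0.5]")
  }
  set.seed(seed)
  maf <- stats::runif(m, maf_range[1], maf_range[2])
  G <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  snp_ids <- sprintf("snp%05d", seq_len(m))
  locus_tags <- sprintf("locus%05d", ceiling(seq_len(m) / locus_block))
  colnames(G) <- snp_ids
  list(G = G, maf = maf, snp_ids = snp_ids, locus_tags = locus_tags)
}

# icosahedron subdivided `level` times, projected to a sphere
icosphere <- function(level, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(level)) {
    mid_cache <- new.env(parent = emptyenv())
    nv <- nrow(v)
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    vlist <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- get0(key, envir = mid_cache)
      if (!is.null(hit)) return(hit)
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      vlist[[length(vlist) + 1L]] <<- matrix(p, 1)
      nv <<- nv + 1L
      assign(key, nv, envir = mid_cache)
      nv
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[(i - 1L) * 4L + 1L, ] <- c(a, ab, ca)
      newf[(i - 1L) * 4L + 2L, ] <- c(b, bc, ab)
      newf[(i - 1L) * 4L + 3L, ] <- c(c_, ca, bc)
      newf[(i - 1L) * 4L + 4L, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  tri_mesh(v * radius, f, validate = FALSE)
}

# named unit directions of the pseudo-landmarks on the template sphere
# (face looks along +z; +y is up)
template_landmark_dirs <- function() {
  d <- rbind(
    pronasale = c(0, 0, 1),
    nasion = c(0, 0.35, 0.94),
    glabella = c(0, 0.52, 0.85),
    subnasale = c(0, -0.22, 0.98),
    alare_left = c(-0.18, -0.06, 0.98),
    alare_right = c(0.18, -0.06, 0.98),
    cheilion_left = c(-0.30, -0.45, 0.84),
    cheilion_right = c(0.30, -0.45, 0.84),
    pogonion = c(0, -0.75, 0.66),
    zygion_left = c(-0.62, 0.22, 0.75),
    zygion_right = c(0.62, 0.22, 0.75),
    forehead = c(0, 0.75, 0.66)
  )
  d / sqrt(rowSums(d^2))
}

#' Synthetic face template with regions and landmarks
#'
#' A subdivided icosphere standing in for a registered facial surface in
#' dense correspondence (level 3 gives 642 vertices / 1280 faces). Named
#' pseudo-landmarks and disjoint nose / eye / rest-of-face region masks are
#' defined by angular caps around fixed directions.
#'
#' @param level subdivision level (vertices = 10 * 4^level + 2).
#' @param radius template radius in mm.
#' @return list with `mesh`, `regions` (named list of vertex index vectors),
#'   `landmarks` (named vertex indices).
#' @export
template_mesh <- function(level = 3L, radius = 80) {
  if (level < 1L) stop("level must be >= 1")
  mesh <- icosphere(level, radius)
  u <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
  ang_to <- function(dir) {
    dir <- dir / sqrt(sum(dir^2))
    acos(pmin(1, pmax(-1, u %*% dir)))
  }
  deg <- pi / 180
  nose <- which(ang_to(c(0, -0.05, 1)) < 22 * deg)
  eye_l <- which(ang_to(c(-0.33, 0.38, 0.86)) < 14 * deg)
  eye_r <- which(ang_to(c(0.33, 0.38, 0.86)) < 14 * deg)
  eyes <- setdiff(union(eye_l, eye_r), nose)
  front <- which(ang_to(c(0, 0, 1)) < 80 * deg)
  face_rest <- setdiff(front, union(nose, eyes))
  dirs <- template_landmark_dirs()
  landmarks <- apply(dirs, 1L, function(d) which.max(u %*% d))
  list(mesh = mesh,
       regions = list(nose = nose, eyes = eyes, face = face_rest),
       landmarks = landmarks)
}

# Smooth radial basis field: Gaussian angular falloff around a center
# direction, displacing along the outward radial direction.
basis_field <- function(template, center_dir, width_deg) {
  v <- template$mesh$vertices
  u <- v / sqrt(rowSums(v^2))
  center_dir <- center_dir / sqrt(sum(center_dir^2))
  ang <- acos(pmin(1, pmax(-1, u %*% center_dir)))
  w <- exp(-ang^2 / (2 * (width_deg * pi / 180)^2))
  u * as.numeric(w)  # V x 3
}

#' Plant per-SNP and covariate effect fields on a template
#'
#' Builds a small set of spatially smooth basis deformation fields centered
#' on facial regions, assigns each causal SNP a loading on one field, and
#' defines covariate effect fields. Also records which feature label each
#' basis field drives and the causal SNP set per feature.
#'
#' @param template from [template_mesh()].
#' @param m panel size.
#' @param n_causal number of causal SNPs (split evenly over basis fields).
#' @param effect_mm typical per-dosage-unit displacement in mm.
#' @param seed RNG seed.
#' @return a `sim_truth` list: basis fields, per-SNP loadings, causal sets
#'   per feature, covariate fields, feature definitions.
#' @export
plant_effects <- function(template, m, n_causal = 40L, effect_mm = 1.0,
                          seed = 1L) {
  set.seed(seed)
  centers <- list(
    nose_tip = c(0, 0, 1),
    nose_bridge = c(0, 0.30, 0.95),
    eye_left = c(-0.33, 0.38, 0.86),
    eye_right = c(0.33, 0.38, 0.86),
    cheek_left = c(-0.5, -0.15, 0.85),
    cheek_right = c(0.5, -0.15, 0.85),
    chin = c(0, -0.7, 0.71),
    forehead = c(0, 0.7, 0.71)
  )
  widths <- c(14, 13, 11, 11, 15, 15, 14, 16)
  K <- length(centers)
  fields <- mapply(function(cd, w) basis_field(template, cd, w),
                   centers, widths, SIMPLIFY = FALSE)
  # features: tertile labels of region statistics, each driven by one or
  # two basis fields (nose vs non-nose categories)
  features <- list(
    nose_protrusion = list(fields = "nose_tip", category = "nose"),
    nasal_root_height = list(fields = "nose_bridge", category = "nose"),
    eye_depth = list(fields = c("eye_left", "eye_right"), category = "other"),
    cheek_width = list(fields = c("cheek_left", "cheek_right"), category = "other"),
    chin_projection = list(fields = "chin", category = "other")
  )
  causal_per_field <- floor(n_causal / K)
  if (causal_per_field < 1L) stop("n_causal too small for the basis fields")
  causal_idx <- sample.int(m, causal_per_field * K)
  field_of_snp <- rep(NA_integer_, m)
  loading <- numeric(m)
  for (k in seq_len(K)) {
    idx <- causal_idx[((k - 1) * causal_per_field + 1):(k * causal_per_field)]
    field_of_snp[idx] <- k
    loading[idx] <- sample(c(-1, 1), length(idx), replace = TRUE) *
      stats::runif(length(idx), 0.8, 1.2) * effect_mm
  }
  causal_sets <- lapply(features, function(ft) {
    ks <- match(ft$fields, names(centers))
    sort(which(field_of_snp %in% ks))
  })
  # covariate fields (per standardized unit): ageing sag of the lower face,
  # sex dimorphism at brow/jaw, BMI cheek fullness
  cov_fields <- list(
    age = -0.6 * basis_field(template, c(0, -0.6, 0.8), 25) +
      0.3 * basis_field(template, c(0, 0.5, 0.87), 20) * -1,
    sex = 0.7 * basis_field(template, c(0, 0.55, 0.84), 18) +
      0.5 * basis_field(template, c(0, -0.72, 0.69), 16),
    bmi = 0.8 * basis_field(template, c(-0.5, -0.15, 0.85), 20) +
      0.8 * basis_field(template, c(0.5, -0.15, 0.85), 20)
  )
  structure(list(field_names = names(centers), fields = fields,
                 field_of_snp = field_of_snp, loading = loading,
                 causal_sets = causal_sets, features = features,
                 cov_fields = cov_fields, n_causal = causal_per_field * K,
                 effect_mm = effect_mm, seed = seed),
            class = "sim_truth")
}

#' Deform the template into per-sample meshes
#'
#' Additive model per sample i with centered dosages g:
#' x_i = template + sum_j (g_ij - mean_j) B_j + age_i B_age + sex_i B_sex +
#' bmi_i B_bmi + eps, eps ~ N(0, sigma^2) per coordinate. Feature labels are
#' tertiles (across the dataset) of region statistics computed from the
#' generated geometry.
#'
#' @param template from [template_mesh()].
#' @param geno from [simulate_genotypes()].
#' @param truth from [plant_effects()].
#' @param covariates data.frame with standardized age, sex (0/1), bmi; NULL
#'   disables covariate effects.
#' @param noise_sd Gaussian vertex noise sd in mm.
#' @param seed RNG seed for the noise.
#' @return list with `shapes` (n x V x 3 array), `labels` (data.frame of
#'   factor labels), `stats` (numeric feature statistics).
#' @export
genotype_to_faces <- function(template, geno, truth, covariates = NULL,
                              noise_sd = 0.15, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  G <- geno$G
  n <- nrow(G); m <- ncol(G)
  V <- nrow(template$mesh$vertices)
  Gc <- sweep(G, 2L, colMeans(G), "-")
  K <- length(truth$fields)
  L <- matrix(0, m, K)
  ok <- !is.na(truth$field_of_snp)
  L[cbind(which(ok), truth$field_of_snp[ok])] <- truth$loading[ok]
  coefs <- Gc %*% L  # n x K
  fields_mat <- t(vapply(truth$fields, function(f) as.numeric(f),
                         numeric(V * 3)))  # K x (V*3)
  defo <- coefs %*% fields_mat  # n x (V*3)
  if (!is.null(covariates)) {
    for (cv in c("age", "sex", "bmi")) {
      if (!is.null(covariates[[cv]])) {
        defo <- defo + outer(as.numeric(covariates[[cv]]),
                             as.numeric(truth$cov_fields[[cv]]))
      }
    }
  }
  set.seed(seed)
  if (noise_sd > 0) {
    defo <- defo + matrix(stats::rnorm(n * V * 3, 0, noise_sd), n)
  }
  shapes_mat <- sweep(defo, 2L, as.numeric(template$mesh$vertices), "+")
  shapes <- array(shapes_mat, dim = c(n, V, 3))
  # feature statistics: mean radial displacement over the driving fields'
  # support (weighted by the field itself)
  u <- template$mesh$vertices / sqrt(rowSums(template$mesh$vertices^2))
  stats_df <- list()
  for (fn in names(truth$features)) {
    ks <- match(truth$features[[fn]]$fields, truth$field_names)
    w <- Reduce(`+`, truth$fields[ks])  # V x 3 weighted radial field
    wvec <- as.numeric(w)
    stats_df[[fn]] <- as.numeric(defo %*% wvec) / sum(rowSums(w * u))
  }
  stats_df <- as.data.frame(stats_df)
  labels <- as.data.frame(lapply(stats_df, function(s) {
    q <- stats::quantile(s, c(1 / 3, 2 / 3))
    if (anyDuplicated(q)) {
      # degenerate statistic (e.g. zero effects): single middle class
      return(factor(rep("mid", length(s)), levels = c("low", "mid", "high")))
    }
    cut(s, breaks = c(-Inf, q, Inf), labels = c("low", "mid", "high"))
  }))
  list(shapes = shapes, labels = labels, stats = stats_df)
}

#' Assemble a paired genotype-face dataset
#'
#' Simulates genotypes, covariates, meshes, labels, planted GWAS sets, and
#' an 80/20 train/test split, all keyed by one seed.
#'
#' @param n samples; @param m SNPs; @param level template subdivision level.
#' @param n_causal causal SNPs; @param effect_mm effect scale (mm);
#' @param noise_sd vertex noise sd (mm); @param maf_range MAF range;
#' @param covariates logical, simulate age/sex/BMI effects;
#' @param train_frac training fraction of the split;
#' @param gwas_decoy_frac decoy fraction of each planted GWAS set;
#' @param seed master seed.
#' @return a `paired_dataset` list.
#' @export
make_paired_dataset <- function(n = 600L, m = 400L, level = 3L,
                                n_causal = 48L, effect_mm = 1.0,
                                noise_sd = 0.15, maf_range = c(0.1, 0.5),
                                covariates = TRUE, train_frac = 0.8,
                                gwas_decoy_frac = 0.25, seed = 1L) {
  template <- template_mesh(level)
  geno <- simulate_genotypes(n, m, maf_range, seed = seed)
  truth <- plant_effects(template, m, n_causal = n_causal,
                         effect_mm = effect_mm, seed = seed + 1L)
  set.seed(seed + 2L)
  covs <- NULL
  if (covariates) {
    covs <- data.frame(
      age = as.numeric(scale(stats::runif(n, 20, 60))),
      sex = stats::rbinom(n, 1L, 0.5),
      bmi = as.numeric(scale(stats::rnorm(n, 23, 3)))
    )
  }
  faces <- genotype_to_faces(template, geno, truth, covariates = covs,
                             noise_sd = noise_sd, seed = seed + 3L)
  set.seed(seed + 4L)
  n_train <- round(train_frac * n)
  train_idx <- sort(sample.int(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)
  # planted GWAS sets: causal SNPs of each feature plus decoys, with
  # synthetic p-values below the genome-wide threshold for causal members
  set.seed(seed + 5L)
  gwas_sets <- lapply(names(truth$causal_sets), function(fn) {
    causal <- truth$causal_sets[[fn]]
    n_decoy <- ceiling(length(causal) * gwas_decoy_frac)
    decoys <- sample(setdiff(seq_len(m), unlist(truth$causal_sets)), n_decoy)
    idx <- c(causal, decoys)
    data.frame(snp_id = geno$snp_ids[idx],
               snp_index = idx,
               p_value = c(stats::runif(length(causal), 1e-12, 1e-8),
                           stats::runif(n_decoy, 1e-4, 0.04)))
  })
  names(gwas_sets) <- names(truth$causal_sets)
  structure(list(template = template, genotypes = geno, truth = truth,
                 covariates = covs, shapes = faces$shapes,
                 labels = faces$labels, feature_stats = faces$stats,
                 train_idx = train_idx, test_idx = test_idx,
                 gwas_sets = gwas_sets, noise_sd = noise_sd, seed = seed),
            class = "paired_dataset")
}

#' Write a paired dataset to disk
#'
#' Writes the genotype TSV (rows = samples, header = SNP ids), one PLY mesh
#' per sample, covariate/label TSVs, per-feature GWAS-set TSVs, the split,
#' and a truth JSON documenting every planted parameter.
#'
#' @param ds a `paired_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(ds$shapes)[1]
  G <- ds$genotypes$G
  utils::write.table(G, file.path(dir, "genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ds$covariates)) {
    utils::write.table(ds$covariates, file.path(dir, "covariates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(ds$labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = seq_len(n),
               split = ifelse(seq_len(n) %in% ds$train_idx, "train", "test")),
    file.path(dir, "split.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  mesh_dir <- file.path(dir, "meshes")
  dir.create(mesh_dir, showWarnings = FALSE)
  tmpl <- ds$template$mesh
  for (i in seq_len(n)) {
    m_i <- tri_mesh(matrix(ds$shapes[i, , ], ncol = 3), tmpl$faces,
                    validate = FALSE)
    write_mesh(m_i, file.path(mesh_dir, sprintf("sample%04d.ply", i)))
  }
  gdir <- file.path(dir, "gwas_sets")
  dir.create(gdir, showWarnings = FALSE)
  for (fn in names(ds$gwas_sets)) {
    utils::write.table(ds$gwas_sets[[fn]][, c("snp_id", "p_value")],
                       file.path(gdir, paste0(fn, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  truth_doc <- list(
    n = n, m = ncol(G), V = nrow(tmpl$vertices),
    noise_sd = ds$noise_sd, seed = ds$seed,
    effect_mm = ds$truth$effect_mm,
    causal_sets = ds$truth$causal_sets,
    loading = ds$truth$loading,
    field_of_snp = ds$truth$field_of_snp
  )
  jsonlite::write_json(truth_doc, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a genotype TSV (samples x SNPs)
#' @param path TSV with a header of SNP ids.
#' @return numeric matrix of dosages.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  as.matrix(df)
}

#' Minimal VCF-to-dosage reader
#'
#' Reads an (uncompressed) VCF and converts GT fields to alternate-allele
#' dosages (0/1/2; missing genotypes become the site mean). Returns samples
#' in rows and variants in columns, matching the genotype-matrix layout.
#'
#' @param path VCF file path.
#' @return numeric dosage matrix with variant IDs as column names.
#' @export
read_vcf_dosages <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("malformed VCF: missing #CHROM header")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  dos <- matrix(NA_real_, length(samples), length(body))
  ids <- character(length(body))
  for (j in seq_along(body)) {
    f <- strsplit(body[j], "\t")[[1]]
    ids[j] <- if (f[3] == ".") paste0(f[1], ":", f[2]) else f[3]
    gt <- sub(":.*$", "", f[-(1:9)])
    d <- vapply(strsplit(gt, "[/|]"), function(a) {
      a <- suppressWarnings(as.integer(a))
      if (anyNA(a)) NA_real_ else sum(a > 0)
    }, numeric(1))
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    dos[, j] <- d
  }
  colnames(dos) <- ids
  rownames(dos) <- samples
  dos
}
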