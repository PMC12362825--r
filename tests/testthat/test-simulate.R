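test_that("genotype simulation obeys Hardy-Weinberg moments and seeding", {
  g <- simulate_genotypes(4000, 6, maf_range = c(0.5, 0.5), seed = 2)
  cm <- colMeans(g$G)
  expect_true(all(abs(cm - 1) < 4 * sqrt(0.5 / 4000) * 2))
  expect_true(all(g$G %in% 0:2))
  g2 <- simulate_genotypes(4000, 6, maf_range = c(0.5, 0.5), seed = 2)
  expect_identical(g$G, g2$G)
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.6)), "maf_range")
  # locus tags group SNPs into independence blocks
  g3 <- simulate_genotypes(5, 6, seed = 1, locus_block = 2L)
  expect_identical(g3$locus_tags,
                   c("locus00001", "locus00001", "locus00002", "locus00002",
                     "locus00003", "locus00003"))
})

test_that("template mesh has the expected subdivision size and structure", {
  tm <- template_mesh(3)
  expect_equal(nrow(tm$mesh$vertices), 642L)   # 10 * 4^3 + 2
  expect_equal(nrow(tm$mesh$faces), 1280L)
  expect_true(consistent_winding(tm$mesh))
  expect_true(all(vapply(tm$regions, length, integer(1)) > 0))
  expect_equal(length(intersect(tm$regions$nose, tm$regions$eyes)), 0L)
  expect_equal(length(intersect(tm$regions$nose, tm$regions$face)), 0L)
  expect_true(all(c("pronasale", "nasion", "glabella") %in% names(tm$landmarks)))
  tm1 <- template_mesh(1)
  expect_equal(nrow(tm1$mesh$vertices), 42L)
})

test_that("zero effects and zero noise reproduce the template exactly", {
  tm <- template_mesh(1)
  g <- simulate_genotypes(5, 12, seed = 1)
  truth <- plant_effects(tm, 12, n_causal = 8L, effect_mm = 0, seed = 1)
  faces <- genotype_to_faces(tm, g, truth, covariates = NULL, noise_sd = 0,
                             seed = 1)
  for (i in 1:5) {
    expect_equal(matrix(faces$shapes[i, , ], ncol = 3), tm$mesh$vertices,
                 ignore_attr = TRUE)
  }
})

test_that("least squares on noise-free faces recovers the planted effect fields", {
  tm <- template_mesh(1)
  n <- 300; m <- 24
  g <- simulate_genotypes(n, m, seed = 5)
  truth <- plant_effects(tm, m, n_causal = 8L, effect_mm = 1, seed = 5)
  faces <- genotype_to_faces(tm, g, truth, covariates = NULL, noise_sd = 0,
                             seed = 1)
  V <- nrow(tm$mesh$vertices)
  defo <- t(vapply(seq_len(n), function(i) {
    as.numeric(matrix(faces$shapes[i, , ], ncol = 3) - tm$mesh$vertices)
  }, numeric(V * 3)))
  Gc <- scale(g$G, scale = FALSE)
  B_hat <- solve(crossprod(Gc), crossprod(Gc, defo))
  for (j in seq_len(m)) {
    want <- if (is.na(truth$field_of_snp[j])) {
      rep(0, V * 3)
    } else {
      truth$loading[j] * as.numeric(truth$fields[[truth$field_of_snp[j]]])
    }
    expect_lt(max(abs(B_hat[j, ] - want)), 1e-8)
  }
})

test_that("tertile feature labels split roughly into thirds", {
  tm <- template_mesh(1)
  g <- simulate_genotypes(3000, 30, seed = 3)
  truth <- plant_effects(tm, 30, n_causal = 8L, seed = 3)
  faces <- genotype_to_faces(tm, g, truth, noise_sd = 0.1, seed = 2)
  tab <- table(faces$labels$nose_protrusion) / 3000
  expect_true(all(abs(tab - 1 / 3) < 0.03))
})

test_that("dataset assembly is reproducible and writes coherent files", {
  ds <- make_paired_dataset(n = 12, m = 16, level = 1, n_causal = 8L, seed = 9)
  expect_equal(length(ds$train_idx), 10L)  # round(0.8 * 12)
  expect_equal(length(ds$test_idx), 2L)
  expect_equal(dim(ds$shapes), c(12, 42, 3))
  # planted GWAS sets contain the causal set plus decoys only
  for (fn in names(ds$gwas_sets)) {
    causal <- ds$truth$causal_sets[[fn]]
    extra <- setdiff(ds$gwas_sets[[fn]]$snp_index, causal)
    expect_true(all(causal %in% ds$gwas_sets[[fn]]$snp_index))
    expect_true(all(!extra %in% unlist(ds$truth$causal_sets)))
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(ds, d1)
  write_dataset(make_paired_dataset(n = 12, m = 16, level = 1, n_causal = 8L,
                                    seed = 9), d2)
  for (f in c("genotypes.tsv", "covariates.tsv", "labels.tsv", "split.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_length(list.files(file.path(d1, "meshes")), 12L)
  m1 <- read_mesh(file.path(d1, "meshes", "sample0001.ply"))
  expect_equal(m1$vertices, matrix(ds$shapes[1, , ], ncol = 3),
               tolerance = 1e-9, ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(truth$n, 12L)
  expect_equal(truth$noise_sd, 0.15)
})

test_that("the minimal VCF reader converts GT fields to dosages", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", ".", "C", "T", ".", "PASS", ".", "GT:DP",
          "0|1:10", "./.:3", "1|1:8", sep = "\t")
  ), p)
  d <- read_vcf_dosages(p)
  expect_equal(dim(d), c(3L, 2L))
  expect_equal(d[, "rs1"], c(s1 = 0, s2 = 1, s3 = 2))
  expect_equal(unname(d["s2", "1:200"]), 1.5)  # site-mean imputation
})
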