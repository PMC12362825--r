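# facegen

Cross-modal generative modeling of 3D facial shape from SNP genotypes, in
pure R.

Forensic DNA phenotyping asks how much of a face can be recovered from a
genome. `facegen` implements a complete pipeline for that question: a
spiral-convolution mesh autoencoder embeds registered 3D facial surfaces
(fixed topology, dense vertex correspondence) into a low-dimensional latent
space; a transformer encoder embeds SNP dosage vectors into the same space;
the two encoders are aligned contrastively; and a conditional denoising
diffusion prior maps SNP embeddings to face embeddings, so that the frozen
decoder can synthesize a 3D face for a genotype it has never seen. The
package targets researchers in facial genetics and forensic phenotyping who
want a fully inspectable, desk-scale implementation of this model family
with planted-truth validation.

## The model

Stage 1 trains the face autoencoder and SNP encoder jointly with

- a reconstruction term `L_mesh = mean |x_hat - x|` (mm, averaged over
  samples, vertices, coordinates), and
- a symmetric contrastive term on L2-normalized embeddings:
  `Logit1 = alpha * z_f z_s^T`, `Logit2 = Logit1^T`,
  `L_con = (CE(Logit1, 0..N-1) + CE(Logit2, 0..N-1)) / 2`,

optimized as `beta1 * L_con + beta2 * L_mesh` by AdamW in two parameter
groups with per-epoch learning-rate decay. Stage 2 freezes everything and
trains a diffusion prior in embedding space: forward corruption
`q(z_t | z_0) = N(sqrt(ab_t) z_0, (1 - ab_t) I)` with a linear variance
schedule, a 4-layer attention network predicting the clean embedding
(x0 parameterization) from `(z_t, t, z_s, covariates)`, mean-squared-error
training with gradient clipping and an EMA of the weights, and exact
ancestral sampling through the Gaussian posterior `q(z_{t-1} | z_t, z_0)`.

Evaluation covers biometric identification (rank-k% rates from cosine
similarities), verification (EER / AUC), geometry (per-vertex Euclidean,
RMSE, chamfer, per-landmark tables, a population-mean-face baseline),
determinantal-point-process diversity, latent feature classification on
real vs generated faces, SNP-deletion robustness curves, and
expected-gradients SNP attribution with hypergeometric enrichment against
GWAS sets.

Since real genome-face cohorts are private, the package includes a
first-class synthetic cohort generator (`make_paired_dataset()`):
Hardy-Weinberg genotypes, a spherical face template with landmarks and
region masks, low-rank spatially smooth per-SNP effect fields, covariate
effects, vertex noise, tertile feature labels, and planted GWAS sets. All
neural components run on a small reverse-mode autodiff engine included in
the package (no external deep-learning framework), verified against finite
differences in the test suite.

## A worked example

```r
library(facegen)

ds  <- make_paired_dataset(n = 120, m = 60, level = 2, seed = 7)  # paired cohort
cfg <- desk_config(n = 120, m = 60, level = 2, latent = 16, seed = 7)
cfg$face <- face_ae_spec(V = 162L, channels = c(8L, 8L, 16L),
                         pool_factors = c(4L, 4L, 2L), latent = 16L,
                         spiral_lengths = c(9L, 9L, 9L),
                         spiral_dilations = c(1L, 1L, 1L))
cfg$snp  <- snp_encoder_spec(m = 60L, chunk = 20L, model_dim = 32L,
                             ff_dim = 64L, layers = 2L, heads = 4L,
                             latent = 16L)

res <- train_pipeline(ds, cfg)            # stage 1 + diffusion prior
rep <- evaluate_pipeline(res$pipeline, ds, seed = 7)

rep$identification
#>       R1      R10      R20
#> 16.66667 29.16667 33.33333
rep$geometry$mean_euclidean_mm       # mean error of generated faces (mm)
#> [1] 0.4152638
rep$geometry$baseline_mean_face_mm   # error of predicting the mean face
#> [1] 0.4230736
```

`rep$identification` gives rank-1/10/20% identification rates on the
held-out 20% (chance for R10 is 10%: the trained model retrieves the right
individual far above chance). The geometry block compares the mean
per-vertex error of DNA-generated faces with the population-mean-face
baseline; the margin between the two is the individual-specific signal
recovered from genotype. Even this small demonstration config (n = 120, 24
test individuals; ~5 minutes on one core) retrieves the right individual
within the top 10% of the gallery three times as often as chance and edges
out the mean-face baseline. The package's reference study is the desk-scale
configuration used by `scripts/acceptance.R` (n = 600, m = 400, 642-vertex
template), where both margins are substantially wider.

Generate faces for new genotypes from the command line:

```sh
Rscript inst/cli/facegen simulate    --out=run --seed=1
Rscript inst/cli/facegen train-align --out=run --seed=1
Rscript inst/cli/facegen train-prior --out=run --seed=1
Rscript inst/cli/facegen generate    --out=run --genotypes=run/dataset/genotypes.tsv
# -> run/generated/generated0001.ply ...
```

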