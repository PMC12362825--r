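---
title: "Reconstructing 3D faces from genotypes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D faces from genotypes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Facial shape is heritable: common variants influence the nose, brow, chin
and overall craniofacial proportions. `facegen` implements a cross-modal
generative pipeline that learns, from paired data, a mapping from a panel of
SNP dosages to a registered 3D facial surface, and can then synthesize a
plausible face for an unseen genotype. The pipeline has three learned
components and a fixed generative bridge:

1. a **face autoencoder** built from spiral convolutions on a fixed mesh
   topology, giving a low-dimensional face embedding $z_f$ and a decoder
   back to vertex coordinates;
2. a **transformer SNP encoder** mapping the dosage vector to an embedding
   $z_s$ in the same space;
3. a **contrastive alignment** objective that pulls matched $(z_s, z_f)$
   pairs together on the cosine-similarity sphere while pushing mismatched
   batch pairs apart;
4. a **conditional diffusion prior** that, given $z_s$ (and optionally
   age/sex/BMI), samples a face embedding $\hat z_f$, which the frozen
   decoder turns into a mesh.

Because cohorts pairing genomes with 3D facial scans are private, the
package ships a synthetic-data module that emulates the structure of such a
cohort with fully known ground truth; every quantitative claim the package
makes is measured on that simulator.

## Mesh machinery

**Spiral neighborhoods.** For a vertex $v$, the 0-ring is $\{v\}$, the
$k$-disk is the union of rings $0..k$, and the $(k{+}1)$-ring is the set of
neighbors of the $k$-ring outside the $k$-disk. A spiral sequence
enumerates rings in order; within each ring we start at the ring vertex
adjacent to the previous ring's first element with the lowest index and
walk counter-clockwise with respect to the face winding (the underlying
reference leaves the convention open; ours is deterministic and
orientation-consistent, which the tests verify against a brute-force BFS
oracle). Spirals shorter than the requested length are padded with a
sentinel treated as a zero feature. A spiral convolution gathers the $l$
spiral features of each vertex, concatenates them, and applies a linear map
— so its receptive field is exactly the spiral support.

**Pooling hierarchy.** Coarser mesh levels come from quadric-error-metric
half-edge collapse: survivors keep their positions, so the down-transition
is a selection matrix, and the up-transition projects each fine vertex
barycentrically onto its nearest coarse triangle. Up-map rows are convex
weights; pooling then unpooling reproduces any coarse-representable field
exactly, a property the tests assert. The cohort-scale architecture pools by
4 four times; on the 642-vertex desk template we use factors (4, 4, 4, 2)
because a fourth factor-4 stage would fall below the 4-vertex floor.

## Architectures

The cohort-scale reference defaults are kept as the documented configuration:
encoder `3 x {Conv(32) -> Pool(4)} -> {Conv(64) -> Pool(4)} -> FC(128)`
with ReLU after each convolution and spiral lengths (9, 9, 9, 9); the
decoder mirrors it with unpooling plus one extra convolution with output
dimension 3. The SNP encoder is a two-layer post-norm transformer (model
dimension 128, feed-forward 512, 8 heads, dropout 0.1, layer-norm epsilon
1e-5). How the dosage vector becomes a token sequence is an open design
point (the reference model only stipulates an MLP dimensionality reduction
before the transformer); we partition the panel into contiguous chunks,
each linearly projected to the model dimension, add learned positional
encodings, and read the embedding from a learned pooling token.

The diffusion prior is a 4-layer attention network over a short token
sequence — conditioning tokens (SNP embedding; optionally age, sex, BMI),
a sinusoidal timestep token, the noisy embedding token, and a learned query
token whose output is the prediction. It predicts the *clean* embedding
(x0 parameterization) without conditional dropout. Covariates enter as
extra tokens: linear embeddings of standardized age and BMI, a two-row
learned table for sex; a condition mask fixed at initialization supports
the ablations (SNPs only; SNPs+sex; SNPs+sex+age+BMI; covariates only).
Where the reference description gives 4 heads of dimension 64 alongside a
hidden dimension of 128, we treat the hidden dimension as authoritative and
derive the head dimension as `model_dim / heads`.

All networks run on a small reverse-mode automatic-differentiation engine
written for this package (dense BLAS matrix ops, sparse pooling operators,
a fused multi-head attention with hand-written backward). Every operator
and each full network is verified against central finite differences in the
test suite.

## Objectives and optimization

Stage 1 minimizes $\beta_1 L_{con} + \beta_2 L_{mesh}$. $L_{mesh}$ is the
mean absolute coordinate deviation; we resolve the reduction ambiguity by
averaging over samples, vertices and coordinates so the value reads in mm
regardless of mesh size. $L_{con}$ builds logits $\alpha\,\hat z_f \hat
z_s^\top$ from L2-normalized embeddings and averages the row-wise and
column-wise cross-entropies against the identity pairing; it equals
$\log N$ at uniform similarity and is symmetric under joint permutation of
pairs. $\alpha$ is a fixed hyperparameter (default 10), and
$\beta_1 = \beta_2 = 1$; none of the three is fixed by the reference model. The
embeddings are normalized *inside* the contrastive loss only — the decoder
consumes the unconstrained $z_f$, which the reconstruction term requires.

Optimization uses Adam with decoupled weight decay in two parameter groups
(encoders vs decoder) and a 0.99-per-epoch multiplicative learning-rate
decay. The reference settings (encoder lr 7.3e-6, weight decay
0.30; decoder lr 3.2e-5, weight decay 0.001; prior lr 0.31e-4, weight decay
0.752) remain the constructor defaults. They were tuned for a ~9,700-person
cohort trained for days on GPUs; at desk scale those learning rates do not
move a freshly initialized model within a few hundred optimizer steps, so
`desk_config()` overrides them (both groups lr 2e-3, weight decay 1e-4;
prior lr 1e-3) — a deliberate package design choice, not a claim about the
reference settings.

Two regularization choices matter at desk scale and are our own additions
to the training loop (the model family, losses and evaluation are
untouched). First, *SNP-dropout augmentation*: during stage 1 a fraction of
each batch's dosages (default 0.3) is masked to the training-mean value.
With only a few hundred training pairs a transformer happily memorizes the
exact dosage vectors, which aligns the training pairs perfectly while
held-out matching stays near chance; input masking forces a distributed,
robust encoding and is the single most effective lever for held-out
identification. The fraction is annealed from 1.25x to 0.5x of its
configured value across training (aggressive early, lighter late). It also
mirrors the panel-incompleteness regime the SNP-deletion experiments
probe. Second, *conditioning-noise augmentation*:
Gaussian noise (sd 0.3) is added to the conditioning embedding during prior
training, which reduces the prior's tendency to memorize the small set of
training embeddings.

Stage 2 freezes the encoders and decoder, embeds the training split, and
trains the prior to predict the clean face embedding from its noised
version, the timestep, and the conditioning, with mean-squared error,
gradient-norm clipping at 0.5, and an EMA of the weights (decay 0.98,
refreshed every 100 steps) used for sampling. Face embeddings are
standardized per dimension before diffusion (the ancestral chain starts
from a standard normal, so the data scale must match); samples are mapped
back before decoding. The reference model does not fix the variance schedule form;
we default to the standard linear schedule 1e-4 to 0.02 (a cosine option is
provided). The cohort-scale default is 1000 timesteps; the desk
configuration uses 300 to keep ancestral sampling for hundreds of test
individuals inside a laptop/CI time budget — the chain is exact in either
case, only the discretization differs. At a shorter horizon the linear
schedule must end higher (the desk config uses beta_end = 0.032) so that
alpha_bar_T stays near zero; otherwise the chain's standard-normal starting
point would not match the forward process's terminal distribution.

## The synthetic cohort

`make_paired_dataset()` is first-class, tested code, not a fixture. Its
defaults define the desk-scale study: n = 600 individuals, m = 400 SNPs,
a 642-vertex spherical face template (radius 80 mm) with named
pseudo-landmarks and disjoint nose/eye/rest-of-face masks, an 80/20
train/test split, and:

* **Genotypes.** Per-SNP minor allele frequencies uniform on (0.1, 0.5),
  dosages Binomial(2, MAF) — Hardy-Weinberg equilibrium. SNPs carry locus
  tags (blocks of 2) standing in for LD-independent loci.
* **Effects.** Eight spatially smooth basis deformation fields (Gaussian
  angular falloff, displacement along the outward normal) centered on
  facial regions; 48 causal SNPs split evenly across fields with per-SNP
  loadings of ±(0.8–1.2) mm per dosage unit. Effects are low-rank and
  smooth by construction so that a small-latent autoencoder can represent
  them — this mirrors the biological premise (regional, additive genetic
  effects) without claiming facial realism.
* **Covariates.** Standardized age, sex (0/1) and BMI with their own
  smooth effect fields (sagging, dimorphism, cheek fullness; 0.5–0.8 mm
  per standard unit).
* **Noise.** Gaussian vertex noise with sd 0.15 mm — "σ small" relative to
  effect sizes, standing in for capture and registration error.
* **Labels.** Tertiles of region statistics (e.g. nose protrusion) computed
  from the generated geometry, so each categorical feature has a known
  causal SNP set; planted "GWAS" tables contain those causal SNPs plus 25%
  decoys with sub-threshold p-values.

What the simulator does **not** emulate: linkage disequilibrium beyond
locus tags, ancestry stratification, non-additive genetics, and the
statistical texture of real facial surfaces. Passing tests therefore
demonstrate that the machinery recovers planted structure under its own
assumptions — they do not certify performance on a real cohort.

## Evaluation

* **Matching.** Cosine similarities between test SNP and face embeddings;
  rank-k% identification (true mate within the top ⌈k/100·N⌉ gallery
  entries, ties broken by stable gallery order) and verification EER/AUC
  from genuine (diagonal) vs impostor (off-diagonal) scores, with a
  declared degenerate-case convention (all-identical scores → 50/50).
* **Geometry.** Per-vertex Euclidean error (valid because all meshes share
  topology), RMSE, symmetric chamfer distance, per-landmark tables, and a
  population-mean-face baseline: the error a method would get by predicting
  the training-mean face for everyone. Beating it means the generation
  carries individual-specific signal.
* **Diversity.** DPP score $\det K$ with $K_{ij} = 1/(1+d_{ij})$, where
  $d$ is the mean per-vertex distance (embedding-space option available),
  with a seeded diagonal jitter ≤ 1e-6 for conditioning.
* **Feature classification.** Softmax MLPs trained on real training-split
  face latents, evaluated on real and generated test latents; the
  real-vs-generated accuracy gap measures whether generated faces preserve
  categorical features.
* **SNP deletion.** Panels masked to fractions 0.9…0.1 (dropped SNPs set to
  the training-mean dosage, keeping the input dimension fixed), faces
  regenerated, and errors tabulated overall and per region. Evaluation-only
  — the encoders are not retrained per fraction.
* **Attribution.** Expected gradients through the frozen SNP encoder and a
  per-feature classifier (average of input gradient × (input − baseline)
  over dataset baselines and path points; exactly $w_j(x_j-\bar b_j)$ for a
  linear score), top-k selection with an optional best-per-locus filter,
  and upper-tail hypergeometric enrichment against the planted GWAS sets.

## Numerical choices and degenerate inputs

Ties in ranking are broken by stable gallery order; equal attribution
scores select the lowest SNP index; a single-pair contrastive batch returns
0 with a warning; empty SNP sets give enrichment p = 1 with a warning; the
t = 1 diffusion step returns the predicted clean state deterministically;
hierarchy construction refuses to pool below 4 vertices; truncated spirals
pad with a zero-feature sentinel. Checkpoints are single RDS archives of
config plus weights; mesh hierarchies are cached to an RDS sidecar keyed by
a mesh fingerprint and the pooling factors.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script run the full pipeline on the
default desk configuration (n = 600, m = 400, V = 642, latent 32; 60
alignment epochs at batch 64 with similarity scale alpha = 20 and mask
fraction 0.3; 1,700 prior steps at batch 64 with covariate conditioning;
300 diffusion steps). The SNP-deletion curve uses a 36-individual test
subset averaged over two mask draws, and attribution uses 40 explained
individuals with 8 baselines × 6 path points per feature, pooled across the
five feature classifiers for the enrichment test. These sizes were chosen so the whole study runs in minutes
on one CPU core while keeping every recovery property measurable; they are
stated here as the package's reference experiment, and all reported numbers
are recomputed at run time by `scripts/acceptance.R` and the test suite.

## Known limitations

The autodiff engine is single-threaded and eager; it is sized for the
desk-scale study, not for the 7,906-vertex, 7,842-SNP cohort-scale model
(the code paths are identical, but expect hours, not minutes). Ancestral
sampling is exact DDPM; no accelerated samplers are provided, and no
classifier-free guidance (the reference model uses none). Identification
rates on the synthetic cohort are bounded away from 100% by design: vertex
noise and covariate-driven variation are not encoded in the SNP embedding,
which mirrors the situation on real cohorts where the same metric is far
from saturated.
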