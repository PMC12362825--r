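# Shared fixtures built in code: small meshes and random mesh generator.

tetra_mesh <- function() {
  tri_mesh(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
           rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
}

# random closed triangulation: an icosphere with jittered vertices
random_small_mesh <- function(seed, level = 1) {
  base <- facegen:::icosphere(level, radius = 1)
  set.seed(seed)
  v <- base$vertices + matrix(stats::rnorm(length(base$vertices), 0, 0.05),
                              ncol = 3)
  tri_mesh(v, base$faces, validate = FALSE)
}

# independent oracle: rings by brute-force BFS edge distance
bfs_rings <- function(mesh, v, k_max) {
  adj <- facegen:::mesh_adjacency(mesh)
  V <- nrow(mesh$vertices)
  dist <- rep(NA_integer_, V)
  dist[v] <- 0L
  frontier <- v
  d <- 0L
  while (length(frontier) > 0 && d < k_max) {
    nxt <- setdiff(unique(unlist(adj[frontier])), which(!is.na(dist)))
    dist[nxt] <- d + 1L
    frontier <- nxt
    d <- d + 1L
  }
  lapply(0:k_max, function(k) sort(which(!is.na(dist) & dist == k)))
}

# a tiny trained-free pipeline for plumbing tests (untrained weights)
tiny_pipeline <- function(seed = 1) {
  ds <- make_paired_dataset(n = 24, m = 30, level = 1, n_causal = 8,
                            noise_sd = 0.05, seed = seed)
  fspec <- face_ae_spec(V = 42L, channels = c(4L, 8L), pool_factors = c(2L, 2L),
                        latent = 8L, spiral_lengths = c(6L, 6L),
                        spiral_dilations = c(1L, 1L))
  face <- face_ae_init(ds$template$mesh, fspec, seed = seed)
  sspec <- snp_encoder_spec(m = 30L, chunk = 10L, model_dim = 16L,
                            ff_dim = 32L, layers = 1L, heads = 2L, latent = 8L)
  snp <- snp_encoder_init(sspec, seed = seed)
  psp <- prior_spec(latent = 8L, model_dim = 16L, depth = 1L, heads = 2L)
  prior <- prior_init(psp, seed = seed)
  prior$ema <- prior$params
  sched <- make_schedule(50L)
  list(ds = ds, pipeline = build_pipeline(face, snp, prior, sched))
}
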