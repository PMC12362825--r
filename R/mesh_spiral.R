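# Spiral neighborhood construction on triangle meshes.
#
# The spiral of a vertex v enumerates its ring neighborhoods in order:
#   0-ring(v)   = {v}
#   k-disk(v)   = union of rings 0..k
#   (k+1)-ring(v) = N(k-ring(v)) \ k-disk(v)
# Within each ring, enumeration starts at the ring vertex adjacent to the
# previous ring's first element with the lowest index and proceeds
# counter-clockwise with respect to the mesh's consistent face winding.
# Truncated spirals (vertices whose disk is too small) are padded with the
# sentinel index 0; convolution layers treat the sentinel as a zero feature.

# adjacency list (list of sorted integer vectors) from faces
mesh_adjacency <- function(mesh) {
  V <- nrow(mesh$vertices)
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
             f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)])
  adj <- vector("list", V)
  sp <- split(e[, 2], e[, 1])
  for (nm in names(sp)) adj[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
  for (i in seq_len(V)) if (is.null(adj[[i]])) adj[[i]] <- integer(0)
  adj
}

#' Ring structure around a vertex
#'
#' Computes the 0-ring through k_max-ring of a vertex: the 0-ring is the
#' vertex itself, and each further ring is the set of neighbors of the
#' previous ring that are not already inside the previous disk. Rings are
#' pairwise disjoint and their union over 0..k equals the k-disk.
#'
#' @param mesh a `tri_mesh`.
#' @param v vertex index (1-based).
#' @param k_max largest ring order to compute.
#' @param adj optional precomputed adjacency list.
#' @return list of integer vectors of length k_max + 1 (0-ring first).
#' @export
ring_structure <- function(mesh, v, k_max, adj = NULL) {
  V <- nrow(mesh$vertices)
  if (v < 1L || v > V) stop("vertex index out of range")
  if (is.null(adj)) adj <- mesh_adjacency(mesh)
  rings <- vector("list", k_max + 1L)
  rings[[1]] <- as.integer(v)
  in_disk <- logical(V)
  in_disk[v] <- TRUE
  for (k in seq_len(k_max)) {
    prev <- rings[[k]]
    cand <- unique(unlist(adj[prev], use.names = FALSE))
    nxt <- sort(cand[!in_disk[cand]])
    rings[[k + 1L]] <- nxt
    in_disk[nxt] <- TRUE
  }
  rings
}

# Cyclic counter-clockwise one-ring order around each vertex, derived from
# the face winding: face (v, a, b) contributes the directed step a -> b in
# v's ring. Returns a list: for vertex v, the successor map as a named
# integer vector, or NULL for isolated vertices.
ring_successors <- function(mesh) {
  V <- nrow(mesh$vertices)
  f <- mesh$faces
  succ <- vector("list", V)
  add <- function(v, a, b) {
    s <- succ[[v]]
    s[as.character(a)] <- b
    succ[[v]] <<- s
  }
  for (i in seq_len(nrow(f))) {
    tri <- f[i, ]
    add(tri[1], tri[2], tri[3])
    add(tri[2], tri[3], tri[1])
    add(tri[3], tri[1], tri[2])
  }
  succ
}

# Order the members of `ring` counter-clockwise when they form v's 1-ring,
# starting from `start`. Falls back to a deterministic greedy chain
# (adjacent-first, lowest index) when the cycle is broken (boundary) or the
# ring is a higher-order ring without full cyclic structure.
order_ring <- function(ring, start, succ_v, adj) {
  if (length(ring) <= 1L) return(ring)
  out <- integer(0)
  remaining <- setdiff(ring, start)
  cur <- start
  out <- c(out, cur)
  # try successor walk first (valid for 1-rings of interior vertices)
  if (!is.null(succ_v)) {
    while (length(remaining) > 0) {
      nxt <- succ_v[as.character(cur)]
      if (is.na(nxt) || !(nxt %in% remaining)) break
      out <- c(out, nxt)
      remaining <- setdiff(remaining, nxt)
      cur <- nxt
    }
  }
  # greedy fallback for whatever is left
  while (length(remaining) > 0) {
    nb <- intersect(adj[[cur]], remaining)
    nxt <- if (length(nb) > 0) min(nb) else min(remaining)
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
    cur <- nxt
  }
  out
}

#' Spiral sequence table
#'
#' Builds, for every vertex, the ordered spiral enumeration of its ring
#' neighborhoods of total length `length * dilation`, then keeps every
#' `dilation`-th element. Row j always starts with vertex j (the 0-ring).
#' Rows are padded with the sentinel 0 when the reachable disk is smaller
#' than the requested spiral.
#'
#' @param mesh a `tri_mesh`.
#' @param length spiral length l (number of kept entries per vertex).
#' @param dilation dilation factor d; the underlying spiral has l*d entries.
#' @return a `spiral_table`: list with `sequences` (V x l integer matrix,
#'   0 = pad), `length`, `dilation`, `pad_index` (0).
#' @export
build_spirals <- function(mesh, length, dilation = 1L) {
  if (length < 1L) stop("length must be >= 1")
  if (dilation < 1L) stop("dilation must be >= 1")
  V <- nrow(mesh$vertices)
  adj <- mesh_adjacency(mesh)
  succ <- ring_successors(mesh)
  total <- length * dilation
  seqs <- matrix(0L, V, length)
  for (v in seq_len(V)) {
    spiral <- as.integer(v)
    prev_first <- v
    prev_ring <- as.integer(v)
    in_disk <- logical(V)
    in_disk[v] <- TRUE
    while (base::length(spiral) < total) {
      cand <- unique(unlist(adj[prev_ring], use.names = FALSE))
      ring <- sort(cand[!in_disk[cand]])
      if (base::length(ring) == 0L) break
      in_disk[ring] <- TRUE
      anchored <- intersect(adj[[prev_first]], ring)
      start <- if (base::length(anchored) > 0) min(anchored) else min(ring)
      # the center's CCW successor map orders the 1-ring; higher rings use
      # the deterministic greedy adjacent-chain inside order_ring
      first_ring <- base::length(prev_ring) == 1L && prev_ring[1] == v
      ordered <- order_ring(ring, start, if (first_ring) succ[[v]] else NULL, adj)
      spiral <- c(spiral, ordered)
      prev_first <- start
      prev_ring <- ring
    }
    if (base::length(spiral) < total) spiral <- c(spiral, rep(0L, total - base::length(spiral)))
    seqs[v, ] <- spiral[seq(1L, by = dilation, length.out = length)]
  }
  structure(list(sequences = seqs, length = as.integer(length),
                 dilation = as.integer(dilation), pad_index = 0L),
            class = "spiral_table")
}
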