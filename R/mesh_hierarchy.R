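# Mesh pooling hierarchy for the autoencoder.
#
# Coarser levels are produced by quadric-error-metric (QEM) half-edge
# collapse: each collapse removes one endpoint of an edge, keeping vertex
# positions of survivors unchanged, so every coarse vertex is a fine vertex.
# The transition maps are:
#   down_map (Vc x Vf): selection of the surviving fine vertices;
#   up_map   (Vf x Vc): barycentric weights of each fine vertex projected
#                       onto its nearest coarse triangle (surviving vertices
#                       get weight 1 on themselves).
# Up-map rows are convex combinations, so pooling then unpooling reproduces
# any coarse-level-representable field exactly.

face_quadric <- function(p1, p2, p3) {
  n <- c(
    (p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
    (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
    (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  )
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) return(matrix(0, 4, 4))
  n <- n / nn
  p <- c(n, -sum(n * p1))
  outer(p, p)
}

quadric_cost <- function(Q, pos) {
  w <- c(pos, 1)
  as.numeric(w %*% Q %*% w)
}

# Closest point on triangle (a,b,c) to p; returns barycentric weights and
# squared distance (Ericson, Real-Time Collision Detection).
closest_point_bary <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(list(bary = c(1, 0, 0), point = a))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(list(bary = c(0, 1, 0), point = b))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(list(bary = c(1 - v, v, 0), point = a + v * ab))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(list(bary = c(0, 0, 1), point = c))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(list(bary = c(1 - w, 0, w), point = a + w * ac))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(list(bary = c(0, 1 - w, w), point = b + w * (c - b)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  list(bary = c(1 - v - w, v, w), point = a + ab * v + ac * w)
}

# One QEM decimation pass to `target` vertices. Returns the coarse mesh plus
# the indices (in the fine mesh) of surviving vertices.
decimate_qem <- function(mesh, target) {
  V <- nrow(mesh$vertices)
  if (target >= V) {
    return(list(mesh = mesh, kept = seq_len(V)))
  }
  if (target < 4L) stop("hierarchy too deep: target below 4 vertices")
  verts <- mesh$vertices
  faces <- mesh$faces
  Q <- array(0, dim = c(4, 4, V))
  for (i in seq_len(nrow(faces))) {
    tri <- faces[i, ]
    K <- face_quadric(verts[tri[1], ], verts[tri[2], ], verts[tri[3], ])
    for (v in tri) Q[, , v] <- Q[, , v] + K
  }
  adj <- mesh_adjacency(mesh)
  e <- unique(t(apply(rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)]),
                      1L, sort)))
  n_e <- nrow(e)
  cost_uv <- numeric(n_e)  # collapse e[,1] -> e[,2] (u dies)
  cost_vu <- numeric(n_e)
  recompute <- function(k) {
    u <- e[k, 1]; v <- e[k, 2]
    Qs <- Q[, , u] + Q[, , v]
    cost_uv[k] <<- quadric_cost(Qs, verts[v, ])
    cost_vu[k] <<- quadric_cost(Qs, verts[u, ])
  }
  for (k in seq_len(n_e)) recompute(k)
  alive <- rep(TRUE, V)
  face_alive <- rep(TRUE, nrow(faces))
  faces_of <- vector("list", V)
  for (i in seq_len(nrow(faces))) {
    for (v in faces[i, ]) faces_of[[v]] <- c(faces_of[[v]], i)
  }
  n_alive <- V
  edge_alive <- rep(TRUE, n_e)
  while (n_alive > target) {
    best <- pmin(cost_uv, cost_vu)
    best[!edge_alive] <- Inf
    k <- which.min(best)
    if (!is.finite(best[k])) stop("decimation stalled before reaching target")
    u <- e[k, 1]; v <- e[k, 2]
    # choose dying endpoint: the cheaper collapse, ties kill the higher index
    if (cost_uv[k] < cost_vu[k] || (cost_uv[k] == cost_vu[k] && u > v)) {
      die <- u; keep <- v
    } else {
      die <- v; keep <- u
    }
    # link condition: shared neighbors must be exactly the edge's two
    # opposite vertices (<= 2), else collapsing pinches the surface
    common <- intersect(adj[[die]], adj[[keep]])
    if (length(common) > 2L) {
      edge_alive[k] <- FALSE
      next
    }
    # collapse
    alive[die] <- FALSE
    n_alive <- n_alive - 1L
    Q[, , keep] <- Q[, , keep] + Q[, , die]
    for (fi in faces_of[[die]]) {
      if (!face_alive[fi]) next
      tri <- faces[fi, ]
      if (keep %in% tri) {
        face_alive[fi] <- FALSE
      } else {
        tri[tri == die] <- keep
        faces[fi, ] <- tri
        faces_of[[keep]] <- c(faces_of[[keep]], fi)
      }
    }
    nb <- setdiff(adj[[die]], keep)
    for (w in nb) {
      adj[[w]] <- sort(unique(c(setdiff(adj[[w]], die), keep)))
    }
    adj[[keep]] <- sort(setdiff(unique(c(adj[[keep]], nb)), c(die, keep)))
    adj[[die]] <- integer(0)
    # remap edges touching the dead vertex onto the survivor, drop dupes
    touch <- which(edge_alive & (e[, 1] == die | e[, 2] == die))
    for (kk in touch) {
      a <- e[kk, 1]; b <- e[kk, 2]
      a2 <- if (a == die) keep else a
      b2 <- if (b == die) keep else b
      if (a2 == b2) { edge_alive[kk] <- FALSE; next }
      e[kk, ] <- sort(c(a2, b2))
    }
    # dedupe and refresh costs around the survivor
    inc <- which(edge_alive & (e[, 1] == keep | e[, 2] == keep))
    if (length(inc) > 1L) {
      key <- paste(e[inc, 1], e[inc, 2])
      edge_alive[inc[duplicated(key)]] <- FALSE
      inc <- inc[!duplicated(key)]
    }
    for (kk in inc) recompute(kk)
  }
  kept <- which(alive)
  remap <- integer(V)
  remap[kept] <- seq_along(kept)
  cf <- faces[face_alive, , drop = FALSE]
  cf <- matrix(remap[cf], ncol = 3L)
  cf <- cf[cf[, 1] != cf[, 2] & cf[, 2] != cf[, 3] & cf[, 1] != cf[, 3], ,
           drop = FALSE]
  key <- apply(cf, 1L, function(r) paste(sort(r), collapse = ":"))
  cf <- cf[!duplicated(key), , drop = FALSE]
  coarse <- tri_mesh(verts[kept, , drop = FALSE], cf, validate = FALSE)
  list(mesh = coarse, kept = kept)
}

transition_maps <- function(fine, coarse, kept) {
  Vf <- nrow(fine$vertices); Vc <- nrow(coarse$vertices)
  down <- Matrix::sparseMatrix(i = seq_len(Vc), j = kept, x = 1,
                               dims = c(Vc, Vf))
  is_kept <- logical(Vf)
  is_kept[kept] <- TRUE
  remap <- integer(Vf)
  remap[kept] <- seq_len(Vc)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  cf <- coarse$faces
  cv <- coarse$vertices
  for (v in seq_len(Vf)) {
    if (is_kept[v]) {
      ii <- c(ii, v); jj <- c(jj, remap[v]); xx <- c(xx, 1)
      next
    }
    p <- fine$vertices[v, ]
    best_d <- Inf; best_bary <- NULL; best_tri <- NULL
    for (t in seq_len(nrow(cf))) {
      tri <- cf[t, ]
      cp <- closest_point_bary(p, cv[tri[1], ], cv[tri[2], ], cv[tri[3], ])
      d <- sum((p - cp$point)^2)
      if (d < best_d) {
        best_d <- d; best_bary <- cp$bary; best_tri <- tri
      }
    }
    nz <- best_bary > 1e-12
    w <- best_bary[nz] / sum(best_bary[nz])
    ii <- c(ii, rep(v, sum(nz))); jj <- c(jj, best_tri[nz]); xx <- c(xx, w)
  }
  up <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(Vf, Vc))
  list(down = down, up = up)
}

#' Build a mesh pooling hierarchy
#'
#' Successively decimates the mesh by the given factors using QEM half-edge
#' collapse and records the sparse down/up transition maps used by pooling
#' and unpooling layers.
#'
#' @param mesh a `tri_mesh` (finest level).
#' @param factors integer vector of per-stage pooling factors (e.g. c(4,4,4,4)).
#' @param cache_dir optional directory; if given, the hierarchy is cached to
#'   an RDS sidecar keyed by a mesh fingerprint and the factors.
#' @return a `mesh_hierarchy`: list with `levels` (fine to coarse),
#'   `down_maps`, `up_maps`, `kept` (surviving fine indices per transition).
#' @export
build_hierarchy <- function(mesh, factors, cache_dir = NULL) {
  if (length(factors) == 0L) stop("factors must be nonempty")
  if (!is.null(cache_dir)) {
    fp <- mesh_fingerprint(mesh, factors)
    cache_file <- file.path(cache_dir, paste0("hierarchy-", fp, ".rds"))
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }
  levels <- list(mesh)
  down_maps <- list(); up_maps <- list(); kept_list <- list()
  cur <- mesh
  for (f in factors) {
    target <- round(nrow(cur$vertices) / f)
    if (target < 4L) stop("hierarchy too deep: level would drop below 4 vertices")
    dec <- decimate_qem(cur, target)
    maps <- transition_maps(cur, dec$mesh, dec$kept)
    levels[[length(levels) + 1L]] <- dec$mesh
    down_maps[[length(down_maps) + 1L]] <- maps$down
    up_maps[[length(up_maps) + 1L]] <- maps$up
    kept_list[[length(kept_list) + 1L]] <- dec$kept
    cur <- dec$mesh
  }
  h <- structure(list(levels = levels, down_maps = down_maps,
                      up_maps = up_maps, kept = kept_list,
                      factors = as.integer(factors)),
                 class = "mesh_hierarchy")
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(h, cache_file)
  }
  h
}

# Cheap content fingerprint for caching (not cryptographic).
mesh_fingerprint <- function(mesh, factors) {
  v <- mesh$vertices
  s1 <- sum(v * rep(c(1.000003, 0.999997, 1.0000011), each = nrow(v)))
  s2 <- sum(as.numeric(mesh$faces) * seq_len(length(mesh$faces)))
  sprintf("%d-%d-%s-%s-%s", nrow(v), nrow(mesh$faces),
          format(s1, digits = 12), format(s2, digits = 12),
          paste(factors, collapse = "x"))
}
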