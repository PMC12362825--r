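#' Triangle mesh in dense vertex correspondence
#'
#' A `tri_mesh` stores vertex coordinates in millimetres and triangular
#' connectivity. All meshes in a dataset are assumed to share one fixed
#' topology (dense correspondence), so vertex-wise comparisons across meshes
#' are meaningful. Face indices are stored 1-based, the R convention; file
#' readers and writers translate from/to the 0-based on-disk convention.
#'
#' @param vertices numeric matrix, V x 3, coordinates in mm.
#' @param faces integer matrix, F x 3, 1-based vertex indices.
#' @param validate check structural invariants (index range, no degenerate
#'   faces, every edge bordering at most two faces).
#' @return an object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an F x 3 matrix")
  m <- structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

validate_mesh <- function(mesh) {
  V <- nrow(mesh$vertices)
  f <- mesh$faces
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > V) stop("face indices out of range [1, V]")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
      stop("degenerate face with repeated vertex index")
    }
    ek <- edge_keys(f)
    tab <- table(ek)
    if (any(tab > 2L)) stop("non-manifold edge borders more than two faces")
  }
  invisible(mesh)
}

# undirected edge keys "a:b" (a<b) for all 3F face edges
edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = ":")
}

#' Check consistent face winding
#'
#' On an orientable manifold mesh with consistent winding, every interior
#' edge appears once in each direction among the faces' directed edges.
#'
#' @param mesh a `tri_mesh`.
#' @return TRUE if no directed edge is repeated.
#' @export
consistent_winding <- function(mesh) {
  f <- mesh$faces
  de <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  keys <- paste(de[, 1], de[, 2], sep = ">")
  !any(duplicated(keys))
}

#' Read a triangle mesh from PLY or OBJ
#'
#' Supports ASCII and binary little-endian PLY, and Wavefront OBJ with
#' triangular faces. Quad or polygon faces raise an unsupported-format error.
#'
#' @param path file path; format inferred from the extension.
#' @return a `tri_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    obj = read_obj(path),
    ply = read_ply(path),
    stop("unsupported mesh format: .", ext)
  )
}

#' Write a triangle mesh to PLY or OBJ
#'
#' @param mesh a `tri_mesh`.
#' @param path output path; format inferred from the extension.
#' @param binary for PLY, write binary little-endian (default) or ASCII.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path, binary = binary),
    stop("unsupported mesh format: .", ext)
  )
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grepl("^v\\s", lines)
  fl <- grepl("^f\\s", lines)
  verts <- NULL
  if (any(vl)) {
    vtok <- strsplit(trimws(sub("^v", "", lines[vl])), "\\s+")
    bad <- which(vapply(vtok, length, integer(1)) < 3L)
    if (length(bad)) {
      stop("malformed OBJ vertex at line ", which(vl)[bad[1]], ": ",
           lines[vl][bad[1]])
    }
    verts <- t(vapply(vtok, function(s) suppressWarnings(as.numeric(s[1:3])),
                      numeric(3)))
    if (anyNA(verts)) {
      r <- which(apply(is.na(verts), 1, any))[1]
      stop("malformed OBJ vertex at line ", which(vl)[r])
    }
  }
  faces <- NULL
  if (any(fl)) {
    ftok <- strsplit(trimws(sub("^f", "", lines[fl])), "\\s+")
    nv <- vapply(ftok, length, integer(1))
    if (any(nv != 3L)) {
      r <- which(nv != 3L)[1]
      stop("unsupported non-triangular face (", nv[r], " vertices) at line ",
           which(fl)[r])
    }
    idx <- function(tok) suppressWarnings(as.integer(sub("/.*$", "", tok)))
    faces <- t(vapply(ftok, function(s) idx(s), integer(3)))
    if (anyNA(faces)) {
      r <- which(apply(is.na(faces), 1, any))[1]
      stop("malformed OBJ face at line ", which(fl)[r])
    }
  }
  tri_mesh(verts, faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
             con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII lines terminated by \n
  read_hline <- function() {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L) stop("malformed PLY: unexpected end of header")
      if (b == as.raw(10L)) break
      chars <- c(chars, b)
    }
    sub("\r$", "", rawToChar(chars))
  }
  magic <- read_hline()
  if (magic != "ply") stop("malformed PLY: missing 'ply' magic at line 1")
  fmt <- NULL; nv <- NA_integer_; nf <- NA_integer_
  elems <- list(); cur <- NULL
  lineno <- 1L
  repeat {
    ln <- read_hline(); lineno <- lineno + 1L
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian")) {
        stop("unsupported PLY format '", fmt, "' at line ", lineno)
      }
    } else if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(count = as.integer(tok[3]), props = list())
      if (cur == "vertex") nv <- as.integer(tok[3])
      if (cur == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("malformed PLY: property before element at line ", lineno)
      elems[[cur]]$props[[length(elems[[cur]]$props) + 1L]] <- tok[-1]
    } else if (tok[1] == "end_header") {
      break
    } else {
      stop("malformed PLY: unrecognized header line ", lineno, ": ", ln)
    }
  }
  if (is.null(fmt)) stop("malformed PLY: no format line")
  if (is.na(nv)) stop("malformed PLY: no vertex element")
  vprops <- elems[["vertex"]]$props
  vnames <- vapply(vprops, function(p) p[length(p)], character(1))
  if (length(vnames) < 3L || !all(c("x", "y", "z") %in% vnames)) {
    stop("malformed PLY: vertex element must carry x, y, z properties")
  }
  ply_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    if (length(rest) < nv) stop("malformed PLY: expected ", nv, " vertex rows")
    vtok <- strsplit(trimws(rest[seq_len(nv)]), "\\s+")
    verts <- matrix(NA_real_, nv, 3L)
    ix <- match(c("x", "y", "z"), vnames)
    for (i in seq_len(nv)) {
      vals <- suppressWarnings(as.numeric(vtok[[i]]))
      if (length(vals) < length(vnames) || anyNA(vals[ix])) {
        stop("malformed PLY vertex at data line ", i)
      }
      verts[i, ] <- vals[ix]
    }
    faces <- NULL
    if (!is.na(nf) && nf > 0) {
      frows <- rest[nv + seq_len(nf)]
      ftok <- lapply(strsplit(trimws(frows), "\\s+"),
                     function(s) suppressWarnings(as.integer(s)))
      cnt <- vapply(ftok, function(s) s[1], integer(1))
      if (any(cnt != 3L)) {
        stop("unsupported non-triangular face (", cnt[which(cnt != 3L)[1]],
             " vertices) at face row ", which(cnt != 3L)[1])
      }
      faces <- t(vapply(ftok, function(s) s[2:4], integer(3))) + 1L
    }
  } else {
    # binary little endian
    vtypes <- vapply(vprops, function(p) p[1], character(1))
    verts <- matrix(NA_real_, nv, 3L)
    ix <- match(c("x", "y", "z"), vnames)
    for (i in seq_len(nv)) {
      row <- numeric(length(vtypes))
      for (j in seq_along(vtypes)) {
        tp <- vtypes[j]
        sz <- ply_size[[tp]]
        if (is.null(sz)) stop("unsupported PLY property type: ", tp)
        if (tp %in% c("float", "float32", "double", "float64")) {
          row[j] <- readBin(con, "double", 1L, size = sz, endian = "little")
        } else {
          row[j] <- readBin(con, "integer", 1L, size = sz, endian = "little",
                            signed = !startsWith(tp, "u"))
        }
      }
      verts[i, ] <- row[ix]
    }
    faces <- NULL
    if (!is.na(nf) && nf > 0) {
      fprops <- elems[["face"]]$props
      lp <- fprops[[1]]
      if (lp[1] != "list") stop("malformed PLY: face property must be a list")
      cnt_sz <- ply_size[[lp[2]]]
      idx_sz <- ply_size[[lp[3]]]
      faces <- matrix(NA_integer_, nf, 3L)
      for (i in seq_len(nf)) {
        cnt <- readBin(con, "integer", 1L, size = cnt_sz, endian = "little",
                       signed = !startsWith(lp[2], "u"))
        if (cnt != 3L) {
          stop("unsupported non-triangular face (", cnt,
               " vertices) at face row ", i)
        }
        faces[i, ] <- readBin(con, "integer", 3L, size = idx_sz,
                              endian = "little") + 1L
      }
    }
  }
  tri_mesh(verts, faces)
}

write_ply <- function(mesh, path, binary = TRUE) {
  V <- nrow(mesh$vertices); F_ <- nrow(mesh$faces)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", V),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", F_),
    "property list uchar int vertex_indices",
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  if (binary) {
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8L, endian = "little")
    if (F_ > 0) {
      f0 <- t(mesh$faces) - 1L
      for (i in seq_len(F_)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f0[, i]), con, size = 4L, endian = "little")
      }
    }
  } else {
    body <- c(
      sprintf("%.17g %.17g %.17g", mesh$vertices[, 1], mesh$vertices[, 2],
              mesh$vertices[, 3]),
      if (F_ > 0) sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                          mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)
    )
    writeBin(charToRaw(paste0(paste(body, collapse = "\n"), "\n")), con)
  }
  invisible(path)
}
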