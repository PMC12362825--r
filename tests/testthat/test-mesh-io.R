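test_that("a minimal OBJ with one triangle parses", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), p)
  m <- read_mesh(p)
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)
  expect_equal(m$faces[1, ], c(1L, 2L, 3L), ignore_attr = TRUE)
})

test_that("write/read round trips preserve geometry and connectivity", {
  mesh <- facegen:::icosphere(3, radius = 80)
  for (ext in c(".obj", ".ply")) {
    p <- withr::local_tempfile(fileext = ext)
    write_mesh(mesh, p)
    back <- read_mesh(p)
    expect_identical(back$faces, mesh$faces)
    expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-6)
  }
  # ascii PLY as well
  p <- withr::local_tempfile(fileext = ".ply")
  write_mesh(mesh, p, binary = FALSE)
  back <- read_mesh(p)
  expect_identical(back$faces, mesh$faces)
  expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-6)
})

test_that("non-triangular faces are rejected with a clear error", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"), p)
  expect_error(read_mesh(p), "non-triangular")
  p2 <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header", "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), p2)
  expect_error(read_mesh(p2), "non-triangular")
})

test_that("malformed files raise parse errors naming the offending line", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 oops 0", "v 0 1 0", "f 1 2 3"), p)
  expect_error(read_mesh(p), "line 2")
  p2 <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("not_ply", "format ascii 1.0"), p2)
  expect_error(read_mesh(p2), "magic")
})

test_that("mesh invariants are validated", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(tri_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(tri_mesh(v, rbind(c(1, 2, 2))), "degenerate")
  expect_true(consistent_winding(tetra_mesh()))
})
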