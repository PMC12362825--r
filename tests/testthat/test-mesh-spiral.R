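test_that("tetrahedron rings: complete adjacency", {
  tet <- tetra_mesh()
  for (v in 1:4) {
    r <- ring_structure(tet, v, 1)
    expect_identical(r[[1]], v)
    expect_identical(r[[2]], sort(setdiff(1:4, v)))
  }
})

test_that("rings match a brute-force BFS edge-distance oracle", {
  for (s in 1:30) {
    mesh <- random_small_mesh(s)
    v <- (s %% nrow(mesh$vertices)) + 1L
    got <- ring_structure(mesh, v, 3)
    want <- bfs_rings(mesh, v, 3)
    for (k in 1:4) expect_identical(sort(got[[k]]), want[[k]])
  }
})

test_that("rings are pairwise disjoint and union to the k-disk", {
  mesh <- random_small_mesh(5, level = 2)
  r <- ring_structure(mesh, 7L, 4)
  all_v <- unlist(r)
  expect_false(any(duplicated(all_v)))
  # k-disk = all vertices within edge distance k
  want <- bfs_rings(mesh, 7L, 4)
  expect_setequal(all_v, unlist(want))
})

test_that("spiral rows start at the center and contain no duplicates", {
  mesh <- random_small_mesh(2, level = 2)
  sp <- build_spirals(mesh, 9L)
  V <- nrow(mesh$vertices)
  expect_equal(dim(sp$sequences), c(V, 9L))
  expect_identical(sp$sequences[, 1], seq_len(V))
  for (v in seq_len(V)) {
    row <- sp$sequences[v, ]
    nonpad <- row[row > 0]
    expect_false(any(duplicated(nonpad)))
    # every non-pad entry lies within the spiral's disk around v
    disk <- unlist(ring_structure(mesh, v, 9))
    expect_true(all(nonpad %in% disk))
  }
})

test_that("length-1 spirals reduce to the 0-ring", {
  mesh <- tetra_mesh()
  sp <- build_spirals(mesh, 1L)
  expect_identical(sp$sequences[, 1], 1:4)
  expect_equal(ncol(sp$sequences), 1L)
})

test_that("tetrahedron spirals follow the start/orientation convention", {
  tet <- tetra_mesh()
  sp <- build_spirals(tet, 4L)
  succ <- facegen:::ring_successors(tet)
  for (v in 1:4) {
    row <- sp$sequences[v, ]
    expect_identical(row[1], v)
    nb <- sort(setdiff(1:4, v))
    # starts at the lowest-index neighbor, then walks the CCW successor cycle
    expect_identical(row[2], min(nb))
    expect_identical(row[3], unname(succ[[v]][as.character(row[2])]))
    expect_identical(row[4], unname(succ[[v]][as.character(row[3])]))
  }
})

test_that("dilation subsamples the dense spiral", {
  mesh <- random_small_mesh(3, level = 2)
  dense <- build_spirals(mesh, 6L, dilation = 1L)
  dil <- build_spirals(mesh, 3L, dilation = 2L)
  expect_identical(dil$sequences, dense$sequences[, c(1L, 3L, 5L)])
})

test_that("spirals are deterministic and pad short disks with the sentinel", {
  tet <- tetra_mesh()
  sp1 <- build_spirals(tet, 9L)
  sp2 <- build_spirals(tet, 9L)
  expect_identical(sp1$sequences, sp2$sequences)
  expect_true(all(sp1$sequences[, 5:9] == 0L))
  expect_identical(sp1$pad_index, 0L)
})
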