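test_that("face enumeration matches the cycle-space dimension", {
  expect_length(enumerate_faces(unit_square()), 1)
  f2 <- enumerate_faces(two_squares())
  expect_length(f2, 2)
  shared <- intersect(f2[[1]]$edges, f2[[2]]$edges)
  expect_length(shared, 1)
  expect_length(enumerate_faces(square_lattice(5, 5)), 16)
  # every generated lattice obeys |faces| = M - N + 1 (checked internally,
  # here via honeycomb and triangular families too)
  expect_length(enumerate_faces(honeycomb_lattice(5, 3)), 15)
  tl <- triangular_lattice(6, 4)
  expect_length(enumerate_faces(tl), n_edges(tl) - n_nodes(tl) + 1)
})

test_that("cycle incidence columns are circulations with face orientation", {
  sq <- unit_square()
  C <- as.matrix(cycle_incidence(sq))
  expect_equal(dim(C), c(4, 1))
  expect_true(all(abs(C) == 1))
  expect_equal(max(abs(t(as.matrix(incidence_matrix(sq))) %*% C)), 0)

  ts <- two_squares()
  C2 <- as.matrix(cycle_incidence(ts))
  shared <- which(rowSums(abs(C2)) == 2)
  expect_length(shared, 1)
  expect_equal(sum(C2[shared, ]), 0)   # opposite signs in adjacent faces

  lat <- random_weighted_lattice(6, 6)
  C6 <- as.matrix(cycle_incidence(lat))
  expect_equal(qr(C6)$rank, n_edges(lat) - n_nodes(lat) + 1)
  expect_equal(max(abs(t(as.matrix(incidence_matrix(lat))) %*% C6)), 0)
})

test_that("reduced dual has inverse weights and lumps shared edges", {
  d <- build_dual(two_squares(w_shared = 4))
  expect_equal(d$n, 2)
  expect_equal(nrow(d$edges), 1)
  expect_equal(d$edges$weight, 1 / 4)
  # inverting the dual weight recovers the primal weight of the single
  # shared edge (weight duality applied twice)
  expect_equal(1 / d$edges$weight, 4)

  # 3x3 lattice: four unit squares -> 4 dual nodes, 4 dual edges, w* = 1
  d2 <- build_dual(square_lattice(3, 3))
  expect_equal(d2$n, 4)
  expect_equal(nrow(d2$edges), 4)
  expect_equal(d2$edges$weight, rep(1, 4))

  # two faces sharing two edges (weights 2 and 4) lump into w* = 3/4
  g <- plane_graph(cbind(c(0, 2, 2, 0, 1), c(0, 0, 2, 2, 1)),
                   data.frame(from = c(1, 2, 3, 4, 1, 5),
                              to   = c(2, 3, 4, 1, 5, 3),
                              weight = c(1, 1, 1, 1, 2, 4)))
  d3 <- build_dual(g)
  expect_equal(d3$n, 2)
  expect_equal(nrow(d3$edges), 1)
  expect_equal(d3$edges$weight, 1 / 2 + 1 / 4)
  expect_length(d3$shared[[1]], 2)
})

test_that("dual Laplacian equals the adjusted C^T W^-1 C construction", {
  ts <- two_squares()
  expect_equal(as.matrix(dual_laplacian(ts)),
               matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)

  lat <- random_weighted_lattice(5, 5, seed = 7)
  Ld <- as.matrix(dual_laplacian(lat))
  expect_equal(max(abs(Ld %*% rep(1, nrow(Ld)))), 0, tolerance = 1e-12)
  expect_true(min(eigen(Ld, symmetric = TRUE, only.values = TRUE)$values) > -1e-10)
  # independent construction: restrict C to edges interior to two faces
  C <- as.matrix(cycle_incidence(lat))
  interior <- rowSums(abs(C)) == 2
  Ct <- C[interior, , drop = FALSE]
  L2 <- t(Ct) %*% ((1 / lat$edges$weight[interior]) * Ct)
  expect_lt(max(abs(Ld - L2)), 1e-12)
})

test_that("cycle-flow (KVL) residual vanishes for solved flows", {
  lat <- random_weighted_lattice(6, 5, seed = 2)
  P <- random_injection(n_nodes(lat), seed = 5)
  fs <- solve_flow(lat, P)
  C <- cycle_incidence(lat)
  kvl <- as.numeric(Matrix::t(C) %*% (fs$flows / lat$edges$weight))
  expect_lt(max(abs(kvl)), 1e-9)
})

test_that("minimum cycle basis dual handles planar and non-planar graphs", {
  # K4: 3 basis cycles, connected dual
  k4 <- k4_plane()
  basis <- minimum_cycle_basis(k4)
  expect_length(basis, 3)
  dk4 <- dual_from_cycle_basis(k4, basis)
  expect_equal(dk4$n, 3)
  expect_true(igraph::is_connected(as_igraph(dk4)))

  # K5 (non-planar): M - N + 1 = 6 basis cycles, dual constructed
  dk5 <- dual_from_cycle_basis(k5_edges(), n = 5)
  expect_equal(dk5$n, 6)
  expect_true(igraph::is_connected(as_igraph(dk5)))
  expect_true(all(vapply(dk5$basis, length, 1L) == 3))  # all triangles

  # on a plane lattice the minimum cycle basis reproduces the face dual
  lat <- square_lattice(4, 3)
  da <- dual_from_cycle_basis(lat)
  db <- build_dual(lat)
  key <- function(d) {
    e <- d$edges[order(d$edges$from, d$edges$to), ]
    sz <- sort(table(c(e$from, e$to)))
    list(n = d$n, m = nrow(e), w = sort(e$weight), deg = as.numeric(sz))
  }
  expect_equal(key(da), key(db))
})

test_that("cycle basis determinism and orientation validity", {
  k4 <- k4_plane()
  expect_identical(minimum_cycle_basis(k4), minimum_cycle_basis(k4))
  # orientation check happens inside: an invalid basis errors
  expect_error(dual_from_cycle_basis(k4, basis = list(c(1, 2, 3), c(1, 2, 4))),
               "closed walk|basis")
})
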