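test_that("incidence matrix follows the fixed edge orientation", {
  e1 <- plane_graph(cbind(c(0, 1), c(0, 0)), data.frame(from = 1, to = 2))
  expect_equal(as.numeric(incidence_matrix(e1)), c(1, -1))

  tri <- plane_graph(cbind(c(0, 1, 0.5), c(0, 0, 1)),
                     data.frame(from = c(1, 2, 3), to = c(2, 3, 1)))
  I <- as.matrix(incidence_matrix(tri))
  expect_true(all(rowSums(I) == 0))             # one +1 and one -1 per row
  expect_true(all(rowSums(abs(I)) == 2))
  expect_true(all(colSums(abs(I)) == 2))        # each node on 2 cycle edges

  lat <- square_lattice(4, 4)
  I4 <- as.matrix(incidence_matrix(lat))
  expect_equal(dim(I4), c(24, 16))
  expect_equal(qr(I4)$rank, 15)                 # N - 1 on a connected graph
})

test_that("constructor enforces the graph invariants", {
  expect_error(plane_graph(cbind(0:1, c(0, 0)),
                           data.frame(from = 1, to = 1)), "self-loop")
  expect_error(plane_graph(cbind(0:1, c(0, 0)),
                           data.frame(from = c(1, 2), to = c(2, 1))), "multi-edge")
  expect_error(plane_graph(cbind(0:1, c(0, 0)),
                           data.frame(from = 1, to = 2, weight = -1)), "positive")
  expect_error(plane_graph(cbind(0:3, rep(0, 4)),
                           data.frame(from = c(1, 3), to = c(2, 4))), "connected")
})

test_that("planarity check accepts lattices and flags crossings", {
  expect_true(check_planarity(square_lattice(5, 4)))
  expect_true(check_planarity(honeycomb_lattice(4, 3)))
  crossed <- plane_graph(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                         data.frame(from = c(1, 2, 3, 4, 1, 2),
                                    to = c(2, 3, 4, 1, 3, 4)))
  expect_error(check_planarity(crossed), "cross")
})

test_that("Laplacian equals I^T W I with the textbook entries", {
  e1 <- plane_graph(cbind(c(0, 1), c(0, 0)),
                    data.frame(from = 1, to = 2, weight = 3.5))
  expect_equal(as.matrix(laplacian_matrix(e1)),
               matrix(c(3.5, -3.5, -3.5, 3.5), 2), ignore_attr = TRUE)

  p <- path3(w = c(2, 3))
  L <- as.matrix(laplacian_matrix(p))
  expect_equal(diag(L), c(2, 5, 3), ignore_attr = TRUE)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), 0, tolerance = 1e-12)
  expect_equal(sum(ev), 10)                    # trace identity

  lat <- random_weighted_lattice(5, 5)
  L5 <- as.matrix(laplacian_matrix(lat))
  expect_equal(max(abs(L5 %*% rep(1, 25))), 0, tolerance = 1e-12)
  expect_true(min(eigen(L5, symmetric = TRUE, only.values = TRUE)$values) > -1e-10)
})

test_that("solve_flow conserves flow and satisfies the energy identity", {
  e1 <- plane_graph(cbind(c(0, 1), c(0, 0)),
                    data.frame(from = 1, to = 2, weight = 2))
  fs <- solve_flow(e1, c(3, -3))
  expect_equal(fs$flows, 3)

  sq <- unit_square()
  fs <- solve_flow(sq, c(1, 0, -1, 0))
  expect_equal(abs(fs$flows), rep(0.5, 4))     # symmetric split

  lat <- square_lattice(5, 5)
  P <- numeric(25); P[1] <- 1; P[25] <- -1
  fs <- solve_flow(lat, P)
  I <- incidence_matrix(lat)
  expect_lt(max(abs(as.numeric(Matrix::t(I) %*% fs$flows) - P)), 1e-10)
  expect_equal(mean(fs$theta), 0, tolerance = 1e-12)
  # energy identity sum F^2/w = theta' L theta
  expect_equal(sum(fs$flows^2 / lat$edges$weight),
               as.numeric(fs$theta %*% laplacian_matrix(lat) %*% fs$theta))

  expect_error(solve_flow(lat, P + 0.01), "not balanced")
})

test_that("flows are invariant under the potential gauge", {
  lat <- random_weighted_lattice(4, 4, seed = 3)
  P <- random_injection(16, seed = 4)
  fs <- solve_flow(lat, P)
  I <- incidence_matrix(lat)
  shifted <- lat$edges$weight * as.numeric(I %*% (fs$theta + 5))
  expect_equal(shifted, fs$flows)
})

test_that("subgraph extraction keeps original ids", {
  lat <- square_lattice(4, 3)
  sub <- subgraph_plane(lat, nodes = c(1, 2, 4, 5))
  expect_equal(attr(sub, "orig_nodes"), c(1, 2, 4, 5))
  expect_equal(n_nodes(sub), 4)
  expect_true(all(lat$edges$weight[attr(sub, "orig_edges")] == sub$edges$weight))
})
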