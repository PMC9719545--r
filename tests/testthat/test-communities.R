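test_that("fiedler pairs match known spectra", {
  # P3 with unit weights: Laplacian spectrum {0, 1, 3}
  expect_equal(fiedler(laplacian_matrix(path3()))$value, 1, tolerance = 1e-12)
  # complete graph K4: lambda_2 = N = 4
  expect_equal(fiedler(laplacian_matrix(k4_plane()))$value, 4, tolerance = 1e-10)
  # sign convention: first non-negligible entry positive, deterministic
  f1 <- fiedler(laplacian_matrix(path3()))
  f2 <- fiedler(laplacian_matrix(path3()))
  expect_identical(f1$vector, f2$vector)
  nz <- which(abs(f1$vector) > 1e-10)[1]
  expect_gt(f1$vector[nz], 0)
})

test_that("weakly bridged cliques obey the cut-set bound tightly", {
  eps <- 1e-6
  bb <- barbell(eps)
  l2 <- fiedler(laplacian_matrix(bb))$value
  expect_lte(l2, (2 / 3) * eps * (1 + 1e-9))   # cut-set bound with N1 = N2 = 3
  bs <- bisect(bb, side = "primal")
  expect_setequal(bs$members1, setdiff(1:6, bs$members2))
  expect_true(setequal(bs$members1, 1:3) || setequal(bs$members1, 4:6))
  expect_equal(bs$mu2, (2 / 3) * eps)
  expect_equal(bs$boundary_edges, 7L)          # the bridge
})

test_that("two-node graph makes the bound exact", {
  e1 <- plane_graph(cbind(c(0, 1), c(0, 0)),
                    data.frame(from = 1, to = 2, weight = 2.5))
  bs <- bisect(e1, side = "primal")
  expect_equal(bs$lambda2, 2 * 2.5)
  expect_equal(bs$mu2, bs$lambda2)
})

test_that("lambda2 <= mu2 for arbitrary balanced partitions", {
  lat <- random_weighted_lattice(5, 4, seed = 11)
  l2 <- fiedler(laplacian_matrix(lat))$value
  set.seed(99)
  for (i in 1:100) {
    m1 <- sample(n_nodes(lat), sample(2:(n_nodes(lat) - 2), 1))
    cs <- cut_set(lat, m1)
    expect_gte(cs$mu2, l2 - 1e-12)
  }
})

test_that("dual bisection extracts the cut-path and its bound", {
  # two faces joined through one edge: 2-node dual, bound exact
  ts <- two_squares(w_shared = 2)
  bs <- bisect(ts, side = "dual")
  expect_equal(bs$lambda2, 2 / 2)      # lambda2* of the 2-node dual
  expect_equal(bs$mu2, bs$lambda2)
  expect_equal(length(bs$boundary_edges), 1)

  # strong central vein: cut-path = the vein, removal disconnects
  pg <- square_lattice(11, 6, mode = "cut_path", contrast = 1e4)
  bs <- bisect(pg, side = "dual")
  expect_setequal(bs$boundary_edges, attr(pg, "boundary"))
  cp <- cut_path(pg, bs$dual, bs$members1)
  expect_true(cp$is_path)
  expect_true(cp$disconnects)
  expect_lt(abs(bs$mu2 - bs$lambda2) / bs$mu2, 0.05)

  # homogeneous lattice: bound still valid for the spectral split
  hom <- square_lattice(7, 5)
  bsh <- suppressWarnings(bisect(hom, side = "dual"))
  expect_lte(bsh$lambda2, bsh$mu2 + 1e-12)
})

test_that("bisection boundary disconnects the graph into its communities", {
  pg <- square_lattice(9, 5, mode = "cut_set", contrast = 0.01)
  bs <- bisect(pg, side = "primal")
  g <- as_igraph(pg)
  g2 <- igraph::subgraph_from_edges(
    g, setdiff(seq_len(n_edges(pg)), bs$boundary_edges),
    delete.vertices = FALSE)
  comp <- igraph::components(g2)$membership
  expect_equal(length(unique(comp)), 2)
  expect_length(unique(comp[bs$members1]), 1)
  expect_length(unique(comp[bs$members2]), 1)
})

test_that("hierarchical decomposition is deterministic with sane leaves", {
  pg <- square_lattice(8, 6, mode = "cut_set", contrast = 0.05)
  t1 <- hierarchical_decompose(pg, 1, side = "primal")
  expect_length(hierarchy_leaves(t1), 2)
  t2 <- hierarchical_decompose(pg, 2, side = "primal")
  expect_identical(hierarchy_leaves(t2),
                   hierarchy_leaves(hierarchical_decompose(pg, 2, side = "primal")))
  # leaves cover all nodes
  expect_setequal(unlist(hierarchy_leaves(t2)), seq_len(n_nodes(pg)))
  # children nest into parents
  expect_true(all(hierarchy_leaves(t2$children[[1]])[[1]] %in% t2$children[[1]]$members))

  vh <- vein_hierarchy_lattice(13, 7, levels = 1)
  td <- hierarchical_decompose(vh$graph, 1, side = "dual")
  expect_length(hierarchy_leaves(td), 2)
  expect_setequal(unlist(hierarchy_leaves(td)), seq_len(n_nodes(vh$graph)))
})

test_that("spectral bound tightens as the boundary weakens (both sides)", {
  gaps_p <- sapply(10^-(1:4), function(eps) {
    pg <- square_lattice(9, 5, mode = "cut_set", contrast = eps)
    bs <- bisect(pg, side = "primal")
    (bs$mu2 - bs$lambda2) / bs$mu2
  })
  expect_true(all(diff(gaps_p) < 0))
  gaps_d <- sapply(10^(1:4), function(c) {
    pg <- square_lattice(9, 5, mode = "cut_path", contrast = c)
    bs <- bisect(pg, side = "dual")
    (bs$mu2 - bs$lambda2) / bs$mu2
  })
  expect_true(all(diff(gaps_d) < 0))
})
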