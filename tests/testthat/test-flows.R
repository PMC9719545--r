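test_that("sensitivity factors match hand-solvable cases", {
  # single edge: all injected flow crosses it
  e1 <- plane_graph(cbind(c(0, 1), c(0, 0)),
                    data.frame(from = 1, to = 2, weight = 3))
  expect_equal(sensitivity_primal(e1, 1, 1), 1)

  # unit square, dipole across edge (1,2): 3/4 stays on the edge and 1/4
  # reroutes over the three-edge path, so the opposite side carries 1/4
  sq <- unit_square()
  H <- sensitivity_matrix(sq)
  opp <- 3   # edge (3,4) is opposite to edge (1,2)
  expect_equal(abs(H[opp, 1]), 0.25)
  expect_equal(H[1, 1], 0.75)    # self-sensitivity of one side of a square
  expect_true(all(diag(H) >= 0 & diag(H) <= 1))
})

test_that("primal and dual sensitivity formulas agree", {
  for (s in 1:2) {
    lat <- random_weighted_lattice(6, 6, seed = s)
    H <- sensitivity_matrix(lat)
    dop <- dual_sensitivity_operator(lat)
    Hd <- -(as.matrix(dop$C) %*% solve(dop$Lcyc, t(as.matrix(dop$C)))) %*%
      diag(1 / lat$edges$weight)
    offdiag <- row(H) != col(H)
    expect_lt(max(abs(H - Hd)[offdiag]), 1e-9)
  }
})

test_that("bridges short-circuit the dual formulation", {
  bb <- barbell()
  eta <- sensitivity_dual(bb, 7, 1)   # bridge edge as trigger
  expect_equal(as.numeric(eta), 0)
  expect_true(isTRUE(attr(eta, "bridge")))
  expect_error(line_outage_flow_change(bb, 7, 1), "bridge")
})

test_that("line outage equals delete-and-resolve", {
  sq <- unit_square()
  P <- c(1, 0, -1, 0)
  fs <- solve_flow(sq, P)
  dF <- line_outage_flow_change(sq, 1, fs$flows)
  rest <- subgraph_plane(sq, edge_ids = 2:4)
  fs2 <- solve_flow(rest, P[attr(rest, "orig_nodes")])
  expect_lt(max(abs((fs$flows + dF)[2:4] - fs2$flows)), 1e-10)
  expect_equal(dF[1], -fs$flows[1])

  # every non-bridge edge of a random weighted lattice
  lat <- random_weighted_lattice(4, 4, seed = 6)
  P <- random_injection(16, seed = 7)
  fs <- solve_flow(lat, P)
  H <- sensitivity_matrix(lat)
  for (e in seq_len(n_edges(lat))) {
    dF <- line_outage_flow_change(lat, e, fs$flows, H = H)
    rest <- subgraph_plane(lat, edge_ids = setdiff(seq_len(n_edges(lat)), e))
    fs2 <- solve_flow(rest, P)
    expect_lt(max(abs((fs$flows + dF)[-e] - fs2$flows)), 1e-9)
  }
})

test_that("rerouting splits by conductance on a symmetric double path", {
  # node 1 to node 2 via two 2-edge paths with conductances 2 and 1;
  # per-path series conductance 1 and 1/2, so flows split 2:1
  g <- plane_graph(cbind(c(0, 2, 1, 1), c(0, 0, 1, -1)),
                   data.frame(from = c(1, 3, 1, 4), to = c(3, 2, 4, 2),
                              weight = c(2, 2, 1, 1)))
  fs <- solve_flow(g, c(3, -3, 0, 0))
  expect_equal(abs(fs$flows[1]), 2)
  expect_equal(abs(fs$flows[3]), 1)
})

test_that("flow ratio collapses when the communities decouple", {
  pg <- square_lattice(9, 4, mode = "cut_set", contrast = 1e-6)
  midx <- (pg$nodes$x[pg$edges$from] + pg$nodes$x[pg$edges$to]) / 2
  ec <- ifelse(midx < attr(pg, "mid_x"), 1L, 2L)
  ec[attr(pg, "boundary")] <- NA_integer_
  fr <- flow_ratio(pg, ec)
  expect_lt(fr$R, 1e-4)
  expect_gt(fr$n_pairs, 0)

  # homogeneous lattice: substantial spill-over into the other community
  pg1 <- square_lattice(9, 4)
  ec1 <- ifelse(midx < attr(pg, "mid_x"), 1L, 2L)
  ec1[attr(pg, "boundary")] <- NA_integer_
  expect_gt(flow_ratio(pg1, ec1)$R, 0.3)
})

test_that("edge communities follow endpoint / face membership", {
  pg <- square_lattice(6, 4, mode = "cut_set", contrast = 0.01)
  bs <- bisect(pg, side = "primal")
  ec <- edge_communities(pg, bs)
  expect_true(all(is.na(ec[bs$boundary_edges])))
  expect_setequal(stats::na.omit(unique(ec)), 1:2)

  pgd <- square_lattice(7, 4, mode = "cut_path", contrast = 100)
  bsd <- bisect(pgd, side = "dual")
  ecd <- edge_communities(pgd, bsd)
  expect_true(all(is.na(ecd[bsd$boundary_edges])))
  expect_setequal(stats::na.omit(unique(ecd)), 1:2)
})
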