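test_that("source model variance follows the Dirichlet closed form", {
  tl <- triangular_lattice(5, 4)
  sm <- source_model(attr(tl, "sources"), attr(tl, "sinks"),
                     K = 500, alpha = 0.01)
  expect_equal(sm$sigma_D2, 500^2 * (2 - 1) / (2^2 * (2 * 0.01 + 1)))
  expect_equal(sm$sigma_D2, 61274.5098, tolerance = 1e-8)
  # alpha -> infinity: Dirichlet concentrates, only sink balancing remains
  sm2 <- source_model(attr(tl, "sources"), attr(tl, "sinks"),
                      K = 500, alpha = 1e12)
  expect_lt(sm2$sigma_D2, 1e-4)
  mom2 <- injection_covariance(sm2, n_nodes(tl))
  s <- attr(tl, "sources")
  nk <- length(attr(tl, "sinks"))
  expect_equal(mom2$cov[s[1], s[1]], nk * sm2$sigma^2 / 4, tolerance = 1e-4)

  expect_error(source_model(1, 2:5), "2 sources")
  expect_error(source_model(1:2, 3:5, alpha = 0), "positive")
  expect_error(source_model(1:2, 2:5), "overlap")
})

test_that("analytic injection moments match Monte-Carlo sampling", {
  tl <- triangular_lattice(5, 4)
  n <- n_nodes(tl)
  sm <- source_model(attr(tl, "sources"), attr(tl, "sinks"), alpha = 0.5)
  mom <- injection_covariance(sm, n)
  expect_lt(max(abs(rowSums(mom$cov))), 1e-8)    # balanced support
  set.seed(10)
  P <- sample_injections(sm, n, 2e4)
  expect_lt(max(abs(rowSums(P))), 1e-10)
  ctr <- sweep(P, 2, mom$mean)
  emp <- crossprod(ctr) / nrow(P)
  # empirical standard error of each covariance entry
  se <- matrix(0, n, n)
  for (i in seq_len(n)) se[i, ] <- apply(ctr * ctr[, i], 2, stats::sd) / sqrt(nrow(P))
  expect_lt(max(abs(emp - mom$cov) / pmax(se, 1e-12)), 5)
  expect_lt(max(abs(colMeans(P) - mom$mean) /
                  pmax(apply(P, 2, stats::sd) / sqrt(nrow(P)), 1e-12)), 5)
})

test_that("mean-square flows propagate moments correctly", {
  sq <- unit_square()
  # deterministic: zero covariance reduces to squared flows
  P <- c(1, 0, -1, 0)
  msf <- mean_square_flows(sq, P, matrix(0, 4, 4))
  expect_equal(msf, rep(0.25, 4))
  # Monte-Carlo oracle with a random balanced-support covariance
  lat <- random_weighted_lattice(4, 3, seed = 9)
  n <- n_nodes(lat)
  set.seed(11)
  B <- matrix(rnorm(n * 3), n, 3); B <- B - rep(colMeans(B), each = n)
  S <- tcrossprod(B)
  mu <- random_injection(n, seed = 12)
  msf <- mean_square_flows(lat, mu, S)
  Z <- matrix(rnorm(3 * 2e4), 2e4, 3)
  Ps <- rep(mu, each = 2e4) + Z %*% t(B)
  I <- as.matrix(incidence_matrix(lat))
  L <- as.matrix(laplacian_matrix(lat))
  A <- (lat$edges$weight * I) %*% (solve(L + 1 / n) - 1 / n)
  Fs <- Ps %*% t(A)
  se <- apply(Fs^2, 2, stats::sd) / sqrt(nrow(Fs))
  expect_lt(max(abs(colMeans(Fs^2) - msf) / pmax(se, 1e-12)), 5)
})

test_that("dissipation optimum satisfies budget, descent and stationarity", {
  tl <- triangular_lattice(6, 4)
  sm <- source_model(attr(tl, "sources"), attr(tl, "sinks"), alpha = 1)
  opt <- optimize_network(tl, sm, gamma = 0.9, n_restarts = 2, seed = 2)
  expect_equal(sum(opt$weights^0.9), 1, tolerance = 1e-9)
  expect_true(all(diff(opt$D_history) <= 1e-9 * opt$D_history[-1] + 1e-12))
  mom <- injection_covariance(sm, n_nodes(tl))
  msf <- mean_square_flows(tl, mom$mean, mom$cov, weights = opt$weights)
  surviving <- opt$weights > 1e-6 * max(opt$weights)
  ratio <- msf[surviving] / opt$weights[surviving]^(1 + 0.9)
  expect_lt((max(ratio) - min(ratio)) / mean(ratio), 0.01)
})

test_that("a single steady source with gamma < 1 yields a loopless optimum", {
  tl <- triangular_lattice(5, 4)
  n <- n_nodes(tl)
  mu <- rep(-1, n); mu[1] <- n - 1
  opt <- optimize_network(tl, model = NULL, gamma = 0.9, n_restarts = 3,
                          seed = 8, moments = list(mean = mu, cov = matrix(0, n, n)))
  keep <- setdiff(seq_len(n_edges(tl)), opt$pruned)
  # a tree spanning all nodes: N - 1 edges, no cycles
  expect_equal(length(keep), n - 1)
  g <- igraph::subgraph_from_edges(as_igraph(tl), keep, delete.vertices = FALSE)
  expect_true(igraph::is_connected(g))
})
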