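#' Fluctuating-source injection model
#'
#' Statistical model of the nodal injections of a supply network with
#' `N_s >= 2` sources and Gaussian sinks. Sink outflows are iid
#' `N(mu, sigma^2)`. The total sink demand is shared equally among the
#' sources, plus a zero-mean fluctuation built from a symmetric Dirichlet
#' vector `X ~ Dir(alpha)` scaled by `K`:
#' `P_source_i = -(1/N_s) * sum(P_sinks) + K * (1/N_s - X_i)`,
#' so every joint sample is exactly balanced. The source fluctuation
#' variance is `sigma_D^2 = K^2 (N_s - 1) / (N_s^2 (N_s alpha + 1))`;
#' small `alpha` means strong fluctuations.
#'
#' @param sources node ids acting as sources (length `N_s >= 2`)
#' @param sinks node ids acting as sinks
#' @param mu,sigma mean and standard deviation of each sink's outflow
#'   (a negative `mu` is an outflow)
#' @param K fluctuation scale
#' @param alpha Dirichlet concentration (`> 0`)
#' @return a `source_model` list; `sigma_D2` holds the closed-form variance
#' @export
source_model <- function(sources, sinks, mu = -1, sigma = 0.1,
                         K = 500, alpha = 1) {
  ns <- length(sources)
  if (ns < 2) stop("need at least 2 sources")
  if (alpha <= 0) stop("alpha must be positive")
  if (length(intersect(sources, sinks))) stop("sources and sinks overlap")
  sigma_D2 <- K^2 * (ns - 1) / (ns^2 * (ns * alpha + 1))
  structure(list(sources = as.integer(sources), sinks = as.integer(sinks),
                 n_sources = ns, mu = mu, sigma = sigma, K = K,
                 alpha = alpha, sigma_D2 = sigma_D2),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("source_model: %d sources, %d sinks, alpha = %g, sigma_D^2 = %.6g\n",
              x$n_sources, length(x$sinks), x$alpha, x$sigma_D2))
  invisible(x)
}

#' Closed-form mean and covariance of the injections
#'
#' First and second moments of the joint injection vector implied by the
#' fluctuating-source model: sinks are iid Gaussian; sources carry the
#' shared sink-balancing term (inducing sink-source and source-source
#' covariances) plus the independent Dirichlet fluctuation with
#' `Var X_i = (N_s - 1) / (N_s^2 (N_s alpha + 1))` and
#' `Cov(X_i, X_j) = -1 / (N_s^2 (N_s alpha + 1))`.
#'
#' @param model a [source_model()]
#' @param n total number of nodes
#' @return list with `mean` (length `n`) and `cov` (`n x n`); the covariance
#'   is supported on the balanced subspace (`rowSums = 0`)
#' @export
injection_covariance <- function(model, n) {
  m <- model
  ns <- m$n_sources; nk <- length(m$sinks)
  if (ns + nk != n) stop("sources + sinks must cover all nodes")
  mean_vec <- numeric(n)
  mean_vec[m$sinks] <- m$mu
  mean_vec[m$sources] <- -nk * m$mu / ns
  cov <- matrix(0, n, n)
  cov[m$sinks, m$sinks] <- diag(m$sigma^2, nk)
  # sources share -(1/ns) * sum of sinks
  cov[m$sources, m$sinks] <- matrix(-m$sigma^2 / ns, ns, nk)
  cov[m$sinks, m$sources] <- t(cov[m$sources, m$sinks])
  varX <- (ns - 1) / (ns^2 * (ns * m$alpha + 1))
  covX <- -1 / (ns^2 * (ns * m$alpha + 1))
  dir_cov <- matrix(m$K^2 * covX, ns, ns)   # Cov of K*(1/ns - X) terms
  diag(dir_cov) <- m$K^2 * varX
  cov[m$sources, m$sources] <- nk * m$sigma^2 / ns^2 + dir_cov
  list(mean = mean_vec, cov = cov)
}

#' Sample balanced injection vectors
#'
#' Monte-Carlo draws from the fluctuating-source model (used as an oracle
#' for [injection_covariance()] and for stochastic experiments). Dirichlet
#' variates are generated as normalized Gamma draws.
#'
#' @param model a [source_model()]
#' @param n total number of nodes
#' @param nsamp number of samples
#' @return `nsamp x n` matrix; every row sums to zero (up to rounding)
#' @export
sample_injections <- function(model, n, nsamp) {
  m <- model
  ns <- m$n_sources; nk <- length(m$sinks)
  P <- matrix(0, nsamp, n)
  sinkdraw <- matrix(stats::rnorm(nsamp * nk, m$mu, m$sigma), nsamp, nk)
  P[, m$sinks] <- sinkdraw
  G <- matrix(stats::rgamma(nsamp * ns, shape = m$alpha), nsamp, ns)
  X <- G / rowSums(G)
  tot <- rowSums(sinkdraw)
  P[, m$sources] <- -tot / ns + m$K * (1 / ns - X)
  P
}

#' Mean-square edge flows under stochastic injections
#'
#' Propagates the injection mean and covariance linearly through the flow
#' solution `F = W I L^+ P`:
#' `<F_l^2> = (A mu)_l^2 + (A Sigma A^T)_{ll}` with `A = W I L^+`.
#'
#' @param graph a `plane_graph`
#' @param mean,cov injection moments (e.g. from [injection_covariance()])
#' @param weights optional edge weights overriding the graph's
#' @return numeric vector of `<F^2>` per edge
#' @export
mean_square_flows <- function(graph, mean, cov, weights = NULL) {
  w <- if (is.null(weights)) graph$edges$weight else weights
  I <- as.matrix(incidence_matrix(graph))
  Lp <- laplacian_pinv(laplacian_matrix(graph, weights = w))
  A <- (w * I) %*% Lp
  mu_F <- as.numeric(A %*% mean)
  var_F <- rowSums((A %*% cov) * A)
  mu_F^2 + var_F
}

#' Optimize a supply network for minimum dissipation
#'
#' Finds edge weights minimizing the expected dissipation
#' `D = sum(<F^2> / w)` under the resource constraint `sum(w^gamma) = 1`,
#' for injections drawn from a fluctuating-source model. Uses the classical
#' fixed-point rescaling for this objective family: at a constrained
#' stationary point `w_l` is proportional to `<F_l^2>^(1/(1+gamma))`, so the
#' iteration alternates between computing `<F^2>` at the current weights and
#' resetting the (renormalized) weights accordingly. The landscape is
#' multi-modal for `gamma < 1`, hence several random restarts are taken and
#' the best final `D` returned. Within each restart `D` is non-increasing;
#' iteration stops when its relative change falls below `tol`. Edges below
#' `prune * max(w)` are reported as pruned (dead) but kept at a tiny weight
#' so the Laplacian stays invertible.
#'
#' @param graph a `plane_graph` (weights used only as size template)
#' @param model a [source_model()], or `NULL` when `moments` is supplied
#' @param moments optional list with `mean` and `cov` of the injections,
#'   overriding the model (e.g. a deterministic single-source layout)
#' @param gamma cost exponent in `(0, 1]`
#' @param n_restarts random restarts
#' @param seed RNG seed
#' @param tol relative convergence tolerance on `D`
#' @param maxit iteration cap per restart
#' @param prune relative pruning floor for reporting dead edges
#' @return list with `weights` (optimal, normalized), `D`, `pruned`
#'   (edge ids), `D_history` of the winning restart, `iterations`
#' @export
optimize_network <- function(graph, model, gamma = 0.9, n_restarts = 5,
                             seed = NULL, tol = 1e-9, maxit = 500,
                             prune = 1e-8, moments = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_nodes(graph); m <- n_edges(graph)
  mom <- if (is.null(moments)) injection_covariance(model, n) else moments
  wmin <- 1e-12
  best <- NULL
  for (r in seq_len(n_restarts)) {
    w <- stats::runif(m, 0.5, 1.5)
    w <- w / sum(w^gamma)^(1 / gamma)
    Dhist <- numeric(0)
    for (it in seq_len(maxit)) {
      msf <- mean_square_flows(graph, mom$mean, mom$cov, weights = w)
      D <- sum(msf / w)
      Dhist <- c(Dhist, D)
      if (it > 1 && abs(Dhist[it - 1] - D) <= tol * D) break
      w_new <- pmax(msf, 0)^(1 / (1 + gamma))
      w_new <- pmax(w_new, wmin * max(w_new))
      w <- w_new / sum(w_new^gamma)^(1 / gamma)
    }
    if (is.null(best) || D < best$D)
      best <- list(weights = w, D = D, D_history = Dhist, iterations = it)
  }
  best$pruned <- which(best$weights < prune * max(best$weights))
  if (!is.null(model)) {
    # an optimum must keep every source connected to the sinks
    keep <- setdiff(seq_len(m), best$pruned)
    g <- igraph::subgraph_from_edges(as_igraph(graph),
                                     keep, delete.vertices = FALSE)
    comp <- igraph::components(g)$membership
    if (length(unique(comp[c(model$sources, model$sinks)])) > 1)
      stop("pruning disconnected a source from the sinks")
  }
  best
}

#' Scan the optimal-network community transition over source fluctuations
#'
#' For each Dirichlet concentration `alpha`, optimizes the network
#' (several restarts) and measures the primal and dual Fiedler values of the
#' *pruned* optimized network (dead edges removed, its own plane dual
#' rebuilt). Increasing fluctuation variance `sigma_D^2` (decreasing
#' `alpha`) drives optimal networks from a primal community structure
#' (`lambda_2` small) to a dual one with a central vein (`lambda_2*`
#' small). Raw Fiedler values of the primal and the dual live on
#' incomparable scales here (the resource constraint pins the primal weight
#' scale, and dual weights are inverse weights), so alongside the raw values
#' the scan reports the Fiedler values of the degree-normalized Laplacians
#' `D^(-1/2) L D^(-1/2)` (`lambda2_norm`, `lambda2_dual_norm`), the standard
#' scale-free connectivity measure; these are dimensionless, directly
#' comparable between primal and dual, and are the transition diagnostic.
#' A disconnected pruned network has `lambda_2 = 0`; a loopless one has no
#' dual and yields `NA`.
#'
#' @param graph lattice from [triangular_lattice()] (attributes `sources`,
#'   `sinks`), or any `plane_graph` plus explicit roles via `model_args`
#' @param alphas Dirichlet concentrations to scan
#' @param gamma cost exponent
#' @param n_restarts restarts per alpha; quantiles are taken across them
#' @param seed RNG seed
#' @param model_args extra arguments for [source_model()] (`mu`, `sigma`, `K`)
#' @return data frame with one row per alpha: `alpha`, `sigma_D2`, medians
#'   and 25/75 quantiles of `lambda2` and `lambda2_dual`, and `D`
#' @export
transition_scan <- function(graph, alphas, gamma = 0.9, n_restarts = 5,
                            seed = 1, model_args = list()) {
  sources <- attr(graph, "sources")
  sinks <- attr(graph, "sinks")
  if (is.null(sources)) stop("graph must carry source/sink roles")
  rows <- lapply(seq_along(alphas), function(k) {
    a <- alphas[k]
    model <- do.call(source_model,
                     c(list(sources = sources, sinks = sinks, alpha = a),
                       model_args))
    l2 <- numeric(n_restarts); l2d <- numeric(n_restarts)
    l2n <- numeric(n_restarts); l2dn <- numeric(n_restarts)
    Ds <- numeric(n_restarts)
    for (r in seq_len(n_restarts)) {
      opt <- optimize_network(graph, model, gamma = gamma, n_restarts = 1,
                              seed = seed + 1000 * k + r)
      keep <- which(opt$weights > 1e-8 * max(opt$weights))
      sub <- subgraph_plane(graph, edge_ids = keep)
      sub$edges$weight <- opt$weights[keep]
      L <- laplacian_matrix(sub)
      l2[r] <- tryCatch(fiedler(L)$value, error = function(e) 0)
      l2n[r] <- tryCatch(fiedler(normalized_laplacian(L))$value,
                         error = function(e) 0)
      dres <- tryCatch({
        d <- build_dual(sub)
        Ld <- dual_laplacian(d)
        c(fiedler(Ld)$value, fiedler(normalized_laplacian(Ld))$value)
      }, error = function(e) c(NA_real_, NA_real_))
      l2d[r] <- dres[1]; l2dn[r] <- dres[2]
      Ds[r] <- opt$D
    }
    data.frame(alpha = a, sigma_D2 = model$sigma_D2,
               lambda2 = stats::median(l2),
               lambda2_q25 = as.numeric(stats::quantile(l2, .25)),
               lambda2_q75 = as.numeric(stats::quantile(l2, .75)),
               lambda2_dual = stats::median(l2d, na.rm = TRUE),
               lambda2_dual_q25 = as.numeric(stats::quantile(l2d, .25, na.rm = TRUE)),
               lambda2_dual_q75 = as.numeric(stats::quantile(l2d, .75, na.rm = TRUE)),
               lambda2_norm = stats::median(l2n),
               lambda2_dual_norm = stats::median(l2dn, na.rm = TRUE),
               D = stats::median(Ds))
  })
  do.call(rbind, rows)
}
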