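#' One synchronous step of the weighted threshold cascade
#'
#' A node flips to state 1 when the weighted average of its neighbours'
#' states exceeds its threshold, `sum(w_ik s_k) / sum(w_ik) > phi_i`; state 1
#' is absorbing. All nodes update simultaneously.
#'
#' @param state 0/1 vector of node states
#' @param A weighted adjacency matrix (dense or sparse), or a `plane_graph`
#' @param phi threshold vector (recycled)
#' @return updated state vector
#' @export
cascade_step <- function(state, A, phi) {
  if (inherits(A, "plane_graph")) A <- adjacency_matrix(A)
  deg <- Matrix::rowSums(A)
  frac <- as.numeric(A %*% state) / deg
  pmax(state, as.numeric(frac > phi))
}

#' Weighted adjacency matrix of a plane graph
#'
#' @param graph a `plane_graph`
#' @return sparse symmetric N x N matrix
#' @export
adjacency_matrix <- function(graph) {
  e <- graph$edges
  n <- n_nodes(graph)
  Matrix::sparseMatrix(i = c(e$from, e$to), j = c(e$to, e$from),
                       x = c(e$weight, e$weight), dims = c(n, n))
}

#' Run a threshold cascade to its fixed point
#'
#' Iterates [cascade_step()] until no state changes. Since states are
#' monotone on a finite graph this takes at most N steps.
#'
#' @inheritParams cascade_step
#' @return list with `state` (final 0/1 vector), `rho_inf` (final infected
#'   fraction) and `steps`
#' @export
run_cascade <- function(state, A, phi) {
  if (inherits(A, "plane_graph")) A <- adjacency_matrix(A)
  steps <- 0L
  repeat {
    s2 <- cascade_step(state, A, phi)
    if (identical(s2, state)) break
    state <- s2
    steps <- steps + 1L
  }
  list(state = state, rho_inf = mean(state), steps = steps)
}

#' Define the boundary-blocking cascade experiment
#'
#' Describes the standard experiment on a square lattice with an
#' inhomogeneous middle strip. The strip consists of all edges incident to
#' `strip_cols` (by default the two node columns immediately right of the
#' lattice midline); a random fraction `p_e` of these edges is reweighted to
#' `w` in each replicate, all other edges keep weight one. The seeded "left
#' part" consists of the columns left of any strip edge; a random fraction
#' `rho0` of its nodes starts infected. All nodes share the uniform
#' threshold `phi`, chosen below the single-neighbour flip point 1/4 of an
#' interior lattice node so that the homogeneous cascade (`w = 1`) is
#' global, while both a weak (`w << 1`) and a strong (`w >> 1`) strip stop
#' it near the midline.
#'
#' @param nx,ny lattice size (defaults 26 x 15)
#' @param w strip edge weight
#' @param p_e fraction of strip edges reweighted per replicate
#' @param rho0 initially infected fraction of the left part
#' @param phi uniform threshold
#' @param strip_cols node columns whose incident edges form the strip
#' @return a `cascade_experiment` list with the lattice, the strip edge ids
#'   and the seedable node set
#' @export
cascade_experiment <- function(nx = 26, ny = 15, w = 1, p_e = 0.8,
                               rho0 = 0.05, phi = 0.18,
                               strip_cols = NULL) {
  if (is.null(strip_cols)) strip_cols <- floor(nx / 2) + c(1L, 2L)
  stopifnot(p_e > 0, p_e <= 1, rho0 > 0, rho0 < 1)
  pg <- square_lattice(nx, ny)
  xs <- pg$nodes$x
  e <- pg$edges
  strip <- which(xs[e$from] %in% strip_cols | xs[e$to] %in% strip_cols)
  touched <- unique(c(e$from[strip], e$to[strip]))
  left <- which(xs < min(xs[touched]))
  structure(list(graph = pg, nx = nx, ny = ny, w = w, p_e = p_e,
                 rho0 = rho0, phi = phi, strip = strip, left = left),
            class = "cascade_experiment")
}

#' Run replicates of the cascade experiment
#'
#' Each replicate draws a fresh random subset of strip edges (fraction
#' `p_e`) to reweight and a fresh random seed set (fraction `rho0` of the
#' left part), then runs the cascade to its fixed point.
#'
#' @param experiment a [cascade_experiment()]
#' @param reps number of replicates
#' @param seed RNG seed (an integer) for reproducibility
#' @return numeric vector of final infected fractions, one per replicate
#' @export
run_cascade_experiment <- function(experiment, reps = 200, seed = NULL) {
  ex <- experiment
  if (!is.null(seed)) set.seed(seed)
  n <- n_nodes(ex$graph)
  nseed <- max(1L, round(ex$rho0 * length(ex$left)))
  vapply(seq_len(reps), function(r) {
    wts <- rep(1, n_edges(ex$graph))
    sel <- ex$strip[stats::runif(length(ex$strip)) < ex$p_e]
    wts[sel] <- ex$w
    e <- ex$graph$edges
    A <- Matrix::sparseMatrix(i = c(e$from, e$to), j = c(e$to, e$from),
                              x = c(wts, wts), dims = c(n, n))
    s0 <- numeric(n)
    s0[sample(ex$left, nseed)] <- 1
    run_cascade(s0, A, ex$phi)$rho_inf
  }, numeric(1))
}

#' Scan the cascade outcome over strip weights
#'
#' For each strip weight, runs the experiment for `reps` replicates and
#' records the median and the 25/75 percent quantiles of the final infected
#' fraction.
#'
#' @param w_values strip weights to scan
#' @param reps replicates per weight
#' @param seed RNG seed
#' @param ... passed to [cascade_experiment()]
#' @return data frame with columns `w`, `median`, `q25`, `q75`
#' @export
cascade_scan <- function(w_values, reps = 200, seed = 1, ...) {
  stopifnot(reps >= 2)
  out <- lapply(seq_along(w_values), function(k) {
    ex <- cascade_experiment(w = w_values[k], ...)
    rho <- run_cascade_experiment(ex, reps = reps, seed = seed + k)
    data.frame(w = w_values[k],
               median = stats::median(rho),
               q25 = as.numeric(stats::quantile(rho, 0.25)),
               q75 = as.numeric(stats::quantile(rho, 0.75)))
  })
  do.call(rbind, out)
}
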