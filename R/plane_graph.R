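#' Construct a plane graph
#'
#' A `plane_graph` is a connected, simple, weighted undirected graph together
#' with a straight-line drawing in the plane: every node carries 2D
#' coordinates, and the combinatorial embedding (the counter-clockwise order of
#' edges around each node) is derived from those coordinates. Each edge is
#' stored with a fixed orientation from its smaller to its larger node id; all
#' sign conventions of incidence and cycle matrices inherit this orientation.
#'
#' @param coords numeric matrix or data frame with columns `x`, `y` (row `i`
#'   is node `i`), or with an additional `id` column holding the integers
#'   `1..N` in any order.
#' @param edges data frame (or 2/3-column matrix) with columns `from`, `to`
#'   and optionally `weight` (default 1). Weights must be strictly positive
#'   and finite.
#' @param validate if `TRUE` (default), check connectivity, simplicity and
#'   weight positivity. The straight-line drawing is *not* checked for edge
#'   crossings here; use [check_planarity()] on demand.
#' @return an object of class `plane_graph` with elements `nodes`
#'   (data frame `id`, `x`, `y`) and `edges` (data frame `from`, `to`,
#'   `weight`, oriented `from < to`).
#' @examples
#' pg <- plane_graph(cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
#'                   data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1)))
#' n_nodes(pg); n_edges(pg)
#' @export
plane_graph <- function(coords, edges, validate = TRUE) {
  coords <- as.data.frame(coords)
  if (!all(c("x", "y") %in% names(coords))) {
    if (ncol(coords) >= 2) names(coords)[1:2] <- c("x", "y")
  }
  n <- nrow(coords)
  if ("id" %in% names(coords)) {
    ord <- order(coords$id)
    coords <- coords[ord, , drop = FALSE]
    if (!identical(as.integer(coords$id), seq_len(n)))
      stop("node ids must be the integers 1..N")
  }
  nodes <- data.frame(id = seq_len(n), x = as.numeric(coords$x),
                      y = as.numeric(coords$y))

  edges <- as.data.frame(edges)
  if (!all(c("from", "to") %in% names(edges)))
    names(edges)[1:2] <- c("from", "to")
  if (!"weight" %in% names(edges)) edges$weight <- 1
  edges <- data.frame(from = as.integer(edges$from), to = as.integer(edges$to),
                      weight = as.numeric(edges$weight))
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp

  pg <- structure(list(nodes = nodes, edges = edges), class = "plane_graph")
  if (validate) validate_plane_graph(pg)
  pg
}

#' @export
print.plane_graph <- function(x, ...) {
  cat(sprintf("plane_graph: %d nodes, %d edges, weights in [%.4g, %.4g]\n",
              n_nodes(x), n_edges(x), min(x$edges$weight), max(x$edges$weight)))
  invisible(x)
}

#' @rdname plane_graph
#' @param graph a `plane_graph`
#' @export
n_nodes <- function(graph) nrow(graph$nodes)

#' @rdname plane_graph
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' @rdname plane_graph
#' @export
edge_weights <- function(graph) graph$edges$weight

#' Validate plane graph invariants
#'
#' Checks that the graph is simple (no self-loops or multi-edges), connected,
#' and that all edge weights are strictly positive and finite. Called by the
#' constructor; exported for use after manual edits of weights.
#'
#' @param graph a `plane_graph`
#' @return invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_plane_graph <- function(graph) {
  e <- graph$edges
  n <- n_nodes(graph)
  if (any(e$from == e$to)) stop("self-loops are not allowed")
  if (any(e$from < 1L) || any(e$to > n)) stop("edge endpoints outside 1..N")
  key <- paste(e$from, e$to)
  if (anyDuplicated(key)) stop("multi-edges are not allowed in the primal graph")
  if (any(!is.finite(e$weight)) || any(e$weight <= 0))
    stop("all edge weights must be strictly positive and finite")
  if (!is.finite(sum(graph$nodes$x) + sum(graph$nodes$y)))
    stop("node coordinates must be finite")
  g <- as_igraph(graph)
  if (!igraph::is_connected(g)) stop("graph must be connected")
  invisible(TRUE)
}

#' Convert to an igraph object
#'
#' @param graph a `plane_graph` or `dual_graph`
#' @return an undirected weighted [igraph::graph] with the same vertex order.
#' @export
as_igraph <- function(graph) {
  UseMethod("as_igraph")
}

#' @export
as_igraph.plane_graph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = graph$nodes)
}

#' Check the straight-line drawing for edge crossings
#'
#' Verifies that no two edges of the drawing given by the node coordinates
#' intersect except at shared endpoints. Quadratic in the number of edges;
#' intended for the desk-scale graphs this package works with.
#'
#' @param graph a `plane_graph`
#' @param tol geometric tolerance for the intersection predicate
#' @return `TRUE` if the drawing is plane, otherwise an error naming one
#'   crossing pair.
#' @export
check_planarity <- function(graph, tol = 1e-12) {
  e <- graph$edges
  x <- graph$nodes$x; y <- graph$nodes$y
  m <- nrow(e)
  p1x <- x[e$from]; p1y <- y[e$from]; p2x <- x[e$to]; p2y <- y[e$to]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(m - 1)) {
    js <- (i + 1):m
    # skip pairs sharing an endpoint
    share <- e$from[js] == e$from[i] | e$from[js] == e$to[i] |
             e$to[js] == e$from[i] | e$to[js] == e$to[i]
    js <- js[!share]
    if (!length(js)) next
    d1 <- cross(p1x[i], p1y[i], p2x[i], p2y[i], p1x[js], p1y[js])
    d2 <- cross(p1x[i], p1y[i], p2x[i], p2y[i], p2x[js], p2y[js])
    d3 <- cross(p1x[js], p1y[js], p2x[js], p2y[js], p1x[i], p1y[i])
    d4 <- cross(p1x[js], p1y[js], p2x[js], p2y[js], p2x[i], p2y[i])
    bad <- (d1 * d2 < -tol) & (d3 * d4 < -tol)
    if (any(bad))
      stop(sprintf("edges %d and %d cross in the drawing", i, js[which(bad)[1]]))
  }
  TRUE
}

#' Edge-node incidence matrix
#'
#' Builds the signed M x N incidence matrix: row `l` has +1 at the node where
#' edge `l` starts and -1 at the node where it ends (edges are oriented from
#' smaller to larger node id at construction). Row order matches the edge
#' order of the weight vector.
#'
#' @param graph a `plane_graph`
#' @return a sparse [Matrix::sparseMatrix] of dimension M x N
#' @export
incidence_matrix <- function(graph) {
  m <- n_edges(graph); n <- n_nodes(graph)
  Matrix::sparseMatrix(
    i = c(seq_len(m), seq_len(m)),
    j = c(graph$edges$from, graph$edges$to),
    x = c(rep(1, m), rep(-1, m)),
    dims = c(m, n))
}

#' Weighted graph Laplacian
#'
#' `L = I^T W I` where `I` is the incidence matrix and `W = diag(w)`:
#' off-diagonal entries are minus the edge weight, the diagonal holds weighted
#' degrees. Symmetric positive semidefinite with `L 1 = 0`; on a connected
#' graph the zero eigenvalue is simple.
#'
#' @param graph a `plane_graph`
#' @param weights optional replacement edge weights (same order as
#'   `graph$edges`)
#' @return sparse symmetric N x N matrix
#' @export
laplacian_matrix <- function(graph, weights = NULL) {
  w <- if (is.null(weights)) graph$edges$weight else weights
  I <- incidence_matrix(graph)
  Matrix::t(I) %*% (w * I)
}

# Pseudoinverse of a graph Laplacian via the rank-one shift
# (L + J/N)^-1 = L^+ + J/N on a connected graph.
laplacian_pinv <- function(L) {
  n <- nrow(L)
  J <- matrix(1 / n, n, n)
  solve(as.matrix(L) + J) - J
}

#' Degree-normalized Laplacian
#'
#' `D^(-1/2) L D^(-1/2)` with `D` the weighted-degree diagonal: the
#' scale-free form whose spectrum is invariant under a global rescaling of
#' the edge weights, making connectivity comparable across graphs with very
#' different weight scales (e.g. a primal graph and its inverse-weight
#' dual).
#'
#' @param L a graph Laplacian (dense or sparse)
#' @return dense symmetric matrix
#' @export
normalized_laplacian <- function(L) {
  L <- as.matrix(L)
  d <- diag(L)
  if (any(d <= 0)) stop("normalized Laplacian needs positive weighted degrees")
  s <- 1 / sqrt(d)
  t(t(L * s) * s)
}

#' Solve the linear flow (discrete Poisson) problem
#'
#' Given balanced nodal injections `P` (sum zero), solves `L theta = P` for
#' the potentials in the mean-zero gauge and returns the edge flows
#' `F = W I theta`. The additive constant of the potential is physically
#' irrelevant; flows are gauge-invariant.
#'
#' @param graph a `plane_graph`
#' @param P numeric injection vector of length N, summing to zero
#' @param tol tolerance for the balance check (relative to `sum(|P|)`)
#' @return a `flow_state`: list with `P`, `theta` (mean-zero), `flows`
#'   (per edge, positive in the stored from -> to direction)
#' @export
solve_flow <- function(graph, P, tol = 1e-8) {
  n <- n_nodes(graph)
  if (length(P) != n) stop("injection vector has wrong length")
  scale <- max(sum(abs(P)), 1)
  if (abs(sum(P)) > tol * scale)
    stop("injections are not balanced: sum(P) = ", format(sum(P)))
  L <- as.matrix(laplacian_matrix(graph))
  theta <- solve(L + 1 / n, P)   # (L + J/N) theta = P, exact for balanced P
  theta <- theta - mean(theta)
  I <- incidence_matrix(graph)
  flows <- graph$edges$weight * as.numeric(I %*% theta)
  res <- max(abs(as.numeric(Matrix::t(I) %*% flows) - P))
  if (res > 1e-6 * scale)
    stop("flow solve failed (is the graph connected?), residual ", format(res))
  structure(list(P = P, theta = theta, flows = flows, residual = res),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("flow_state: %d nodes, max |F| = %.4g, KCL residual %.2e\n",
              length(x$theta), max(abs(x$flows)), x$residual))
  invisible(x)
}

#' Dissipated power of a flow state
#'
#' `sum(F^2 / w)`, which equals `theta^T L theta` for any solved state.
#'
#' @param graph a `plane_graph`
#' @param state a `flow_state` from [solve_flow()]
#' @export
dissipation <- function(graph, state) {
  sum(state$flows^2 / graph$edges$weight)
}

#' Rotation system of the embedding
#'
#' For each node, the incident edges sorted counter-clockwise by the angle of
#' the outgoing direction, as required for face tracing.
#'
#' @param graph a `plane_graph`
#' @return list over nodes; each element is an integer vector of edge ids in
#'   counter-clockwise order.
#' @keywords internal
rotation_system <- function(graph) {
  n <- n_nodes(graph)
  e <- graph$edges
  x <- graph$nodes$x; y <- graph$nodes$y
  rot <- vector("list", n)
  # incident (edge, other endpoint) pairs per node
  inc <- split(seq_len(2 * nrow(e)),
               c(e$from, e$to))
  other <- c(e$to, e$from)
  eid <- rep(seq_len(nrow(e)), 2)
  for (v in seq_len(n)) {
    idx <- inc[[as.character(v)]]
    if (is.null(idx)) stop("isolated node ", v)
    o <- other[idx]
    ang <- atan2(y[o] - y[v], x[o] - x[v])
    rot[[v]] <- eid[idx][order(ang)]
  }
  rot
}

#' Extract an induced subgraph keeping track of original ids
#'
#' Returns the `plane_graph` induced by `nodes` (or by `edge_ids`, in which
#' case nodes are the endpoints of those edges). Node ids are relabelled
#' `1..n'`; the original ids are kept in `attr(, "orig_nodes")` and original
#' edge ids in `attr(, "orig_edges")`.
#'
#' @param graph a `plane_graph`
#' @param nodes original node ids to keep (ignored when `edge_ids` given)
#' @param edge_ids original edge ids to keep
#' @param validate check connectivity of the result (default `FALSE`;
#'   subgraphs are allowed to be disconnected, callers decide)
#' @export
subgraph_plane <- function(graph, nodes = NULL, edge_ids = NULL, validate = FALSE) {
  if (!is.null(edge_ids)) {
    e <- graph$edges[edge_ids, , drop = FALSE]
    nodes <- sort(unique(c(e$from, e$to)))
  } else {
    nodes <- sort(unique(as.integer(nodes)))
    keep <- graph$edges$from %in% nodes & graph$edges$to %in% nodes
    edge_ids <- which(keep)
    e <- graph$edges[keep, , drop = FALSE]
  }
  relabel <- integer(n_nodes(graph))
  relabel[nodes] <- seq_along(nodes)
  out <- plane_graph(graph$nodes[nodes, c("x", "y")],
                     data.frame(from = relabel[e$from], to = relabel[e$to],
                                weight = e$weight),
                     validate = FALSE)
  if (validate) validate_plane_graph(out)
  attr(out, "orig_nodes") <- nodes
  attr(out, "orig_edges") <- edge_ids
  out
}

#' Plot a plane graph
#'
#' Draws the straight-line embedding; line width encodes the edge weight on a
#' log scale.
#'
#' @param x a `plane_graph`
#' @param node_col node colours (recycled), e.g. community labels
#' @param ... passed to [graphics::plot()]
#' @export
plot.plane_graph <- function(x, node_col = "grey30", ...) {
  e <- x$edges
  lw <- log10(e$weight / stats::median(e$weight))
  lw <- 1 + 2 * (lw - min(lw)) / max(1e-9, diff(range(lw)))
  graphics::plot(x$nodes$x, x$nodes$y, type = "n", asp = 1,
                 xlab = "x", ylab = "y", ...)
  graphics::segments(x$nodes$x[e$from], x$nodes$y[e$from],
                     x$nodes$x[e$to], x$nodes$y[e$to], lwd = lw, col = "grey55")
  graphics::points(x$nodes$x, x$nodes$y, pch = 19, cex = 0.7, col = node_col)
  invisible(x)
}
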