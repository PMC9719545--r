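#' Enumerate the interior faces of a plane graph
#'
#' Traces all faces of the straight-line embedding with the standard
#' rotation-system (next-edge) walk on directed edges, identifies the outer
#' face as the one with the most negative signed area, and returns the
#' interior faces, each as a cyclic sequence of edges with orientation signs
#' (+1 when the stored from -> to orientation agrees with the
#' counter-clockwise face traversal). The number of interior faces always
#' equals the cycle-space dimension M - N + 1.
#'
#' @param graph a `plane_graph`
#' @return a `face_set`: list of faces, each a list with `edges` (edge ids),
#'   `signs` (+-1), `nodes` (vertex cycle) and `area` (signed, positive).
#'   Attributes: `outer` (the excluded outer face), `primal`.
#' @examples
#' sq <- plane_graph(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
#'                   data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1)))
#' length(enumerate_faces(sq))  # 1 interior face
#' @export
enumerate_faces <- function(graph) {
  e <- graph$edges
  m <- nrow(e)
  n <- n_nodes(graph)
  rot <- rotation_system(graph)
  # position of each edge within the rotation at each of its endpoints
  pos <- lapply(rot, function(v) {
    p <- integer(m); p[v] <- seq_along(v); p
  })
  x <- graph$nodes$x; y <- graph$nodes$y

  # directed edge k in 1..2m: k <= m is from->to, k > m is to->from
  visited <- logical(2 * m)
  head_of <- c(e$to, e$from)
  tail_of <- c(e$from, e$to)
  faces <- list()
  for (start in seq_len(2 * m)) {
    if (visited[start]) next
    walk_edges <- integer(0); walk_signs <- integer(0); walk_nodes <- integer(0)
    k <- start
    repeat {
      if (visited[k]) {
        if (k == start && length(walk_edges)) break
        stop("embedding inconsistency: face traversal revisited a directed edge")
      }
      visited[k] <- TRUE
      eid <- if (k <= m) k else k - m
      walk_edges <- c(walk_edges, eid)
      walk_signs <- c(walk_signs, if (k <= m) 1L else -1L)
      walk_nodes <- c(walk_nodes, tail_of[k])
      v <- head_of[k]
      rv <- rot[[v]]
      p <- pos[[v]][eid]
      # clockwise-next edge at v after the arrival edge: predecessor in the
      # counter-clockwise rotation; yields counter-clockwise interior faces
      nxt_e <- rv[if (p == 1) length(rv) else p - 1]
      k <- if (e$from[nxt_e] == v) nxt_e else nxt_e + m
      if (k == start) break
    }
    a <- signed_area(x[walk_nodes], y[walk_nodes])
    faces[[length(faces) + 1]] <- list(edges = walk_edges, signs = walk_signs,
                                       nodes = walk_nodes, area = a)
  }
  areas <- vapply(faces, `[[`, numeric(1), "area")
  outer_idx <- which.min(areas)
  if (areas[outer_idx] >= 0)
    stop("embedding inconsistency: no outer face with negative signed area")
  interior <- faces[-outer_idx]
  if (length(interior) != m - n + 1)
    stop(sprintf(paste("face count %d differs from cycle-space dimension",
                       "M - N + 1 = %d; the drawing is not plane"),
                 length(interior), m - n + 1))
  if (any(vapply(interior, `[[`, numeric(1), "area") <= 0))
    stop("embedding inconsistency: interior face with non-positive area")
  structure(interior, class = "face_set",
            outer = faces[[outer_idx]], primal = graph)
}

signed_area <- function(x, y) {
  nx <- c(x[-1], x[1]); ny <- c(y[-1], y[1])
  sum(x * ny - nx * y) / 2
}

#' @export
print.face_set <- function(x, ...) {
  cat(sprintf("face_set: %d interior faces\n", length(x)))
  invisible(x)
}

#' Cycle-edge incidence matrix
#'
#' The M x (M - N + 1) signed matrix `C` whose column `c` is the oriented
#' boundary of interior face `c`: entry +1 if the edge's stored orientation
#' agrees with the counter-clockwise traversal of the face, -1 if reversed,
#' 0 otherwise. Every column is a circulation, i.e. `I^T C = 0` exactly.
#'
#' @param faces a `face_set` from [enumerate_faces()], or a `plane_graph`
#' @return sparse M x (M - N + 1) matrix
#' @export
cycle_incidence <- function(faces) {
  if (inherits(faces, "plane_graph")) faces <- enumerate_faces(faces)
  graph <- attr(faces, "primal")
  m <- n_edges(graph)
  i <- unlist(lapply(faces, `[[`, "edges"))
  j <- rep(seq_along(faces), vapply(faces, function(f) length(f$edges), 1L))
  xx <- unlist(lapply(faces, `[[`, "signs"))
  C <- Matrix::sparseMatrix(i = i, j = j, x = xx,
                            dims = c(m, length(faces)))
  IC <- Matrix::t(incidence_matrix(graph)) %*% C
  if (max(abs(IC)) != 0)
    stop("orientation error: I^T C != 0, face boundaries are not circulations")
  C
}

#' Cycle-space Laplacian (full face basis)
#'
#' `C^T W^-1 C` with the complete face-edge incidence matrix. This is the
#' operator of the cycle-flow Poisson equation; edges on the outer boundary
#' contribute to its diagonal, so it is positive definite (a grounded
#' Laplacian) and invertible. For community detection use [dual_laplacian()]
#' instead, which is the graph Laplacian of the reduced dual graph.
#'
#' @param graph a `plane_graph`
#' @param faces optional pre-computed `face_set`
#' @return dense symmetric positive-definite matrix of size M - N + 1
#' @export
cycle_laplacian <- function(graph, faces = NULL) {
  if (is.null(faces)) faces <- enumerate_faces(graph)
  C <- cycle_incidence(faces)
  as.matrix(Matrix::t(C) %*% ((1 / graph$edges$weight) * C))
}

#' Build the (reduced) weighted dual graph
#'
#' Nodes of the dual are the interior faces of the plane graph; two faces are
#' joined by a dual edge when they share at least one primal edge. The dual
#' weight is the summed inverse primal weight over all shared edges,
#' `w* = sum(1/w_l)`, so parallel dual edges are lumped into one (the reduced
#' dual). Strong primal connections therefore become weak dual ones and vice
#' versa. The map from each dual edge to its shared primal edges is retained.
#'
#' @param graph a `plane_graph` with at least 2 interior faces
#' @param faces optional pre-computed `face_set`
#' @return a `dual_graph`: list with `n` (number of faces), `edges`
#'   (data frame `from`, `to`, `weight`), `shared` (list of primal edge-id
#'   vectors per dual edge), `coords` (face centroids, for plotting only),
#'   `faces`, `primal`.
#' @export
build_dual <- function(graph, faces = NULL) {
  if (is.null(faces)) faces <- enumerate_faces(graph)
  nf <- length(faces)
  if (nf < 2) stop("degenerate dual: fewer than 2 interior faces")
  m <- n_edges(graph)
  # faces containing each edge (at most 2)
  eid <- unlist(lapply(faces, `[[`, "edges"))
  fid <- rep(seq_len(nf), vapply(faces, function(f) length(f$edges), 1L))
  if (any(table(eid) > 2)) stop("an edge appears in more than 2 interior faces")
  byedge <- split(fid, eid)
  shared2 <- byedge[vapply(byedge, length, 1L) == 2]
  pe <- as.integer(names(shared2))
  f1 <- pmin(vapply(shared2, `[`, 1L, 1), vapply(shared2, `[`, 1L, 2))
  f2 <- pmax(vapply(shared2, `[`, 1L, 1), vapply(shared2, `[`, 1L, 2))
  key <- paste(f1, f2)
  winv <- 1 / graph$edges$weight[pe]
  agg <- rowsum(winv, key)
  ord <- match(rownames(agg), key)
  de <- data.frame(from = f1[ord], to = f2[ord], weight = as.numeric(agg))
  shared <- split(pe, key)[rownames(agg)]
  centro <- t(vapply(faces, function(f)
    c(mean(graph$nodes$x[f$nodes]), mean(graph$nodes$y[f$nodes])), numeric(2)))
  dual <- structure(list(n = nf, edges = de, shared = unname(shared),
                         coords = data.frame(x = centro[, 1], y = centro[, 2]),
                         faces = faces, primal = graph),
                    class = "dual_graph")
  g <- as_igraph(dual)
  if (!igraph::is_connected(g))
    stop("dual graph is disconnected: faces do not share chains of edges")
  dual
}

#' @export
print.dual_graph <- function(x, ...) {
  cat(sprintf("dual_graph: %d faces, %d dual edges, w* in [%.4g, %.4g]\n",
              x$n, nrow(x$edges), min(x$edges$weight), max(x$edges$weight)))
  invisible(x)
}

#' @export
as_igraph.dual_graph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(id = seq_len(graph$n)))
}

#' Laplacian of the reduced dual graph
#'
#' The ordinary weighted graph Laplacian of [build_dual()]'s reduced dual:
#' off-diagonals are minus the lumped inverse-weight sums, row sums are zero.
#' Equivalently, `C~^T W^-1 C~` where `C~` is the face-edge incidence matrix
#' restricted to edges shared by two interior faces (the adjustment the
#' reduced dual requires). This is the operator whose Fiedler pair defines
#' dual communities.
#'
#' @param x a `plane_graph` or a `dual_graph`
#' @return sparse symmetric PSD matrix of size M - N + 1
#' @export
dual_laplacian <- function(x) {
  dual <- if (inherits(x, "dual_graph")) x else build_dual(x)
  e <- dual$edges
  i <- c(e$from, e$to, e$from, e$to)
  j <- c(e$to, e$from, e$from, e$to)
  v <- c(-e$weight, -e$weight, e$weight, e$weight)
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(dual$n, dual$n))
}

#' Minimum cycle basis of a weighted graph
#'
#' Horton's algorithm: candidate cycles are formed by closing each edge
#' through shortest paths from every root node; candidates are sorted by
#' total weight and greedily selected when linearly independent over GF(2).
#' Ties are broken by lexicographic edge order so the basis is deterministic.
#' Intended for small graphs (the algebraic dual of non-planar networks).
#'
#' @param edges data frame `from`, `to`, `weight` (or a `plane_graph`)
#' @param n number of nodes (taken from the graph if omitted)
#' @return list of integer vectors of edge ids, each a simple cycle;
#'   `length = M - N + 1`
#' @export
minimum_cycle_basis <- function(edges, n = NULL) {
  if (inherits(edges, "plane_graph")) {
    n <- n_nodes(edges); edges <- edges$edges
  }
  e <- as.data.frame(edges)
  m <- nrow(e)
  if (is.null(n)) n <- max(e$from, e$to)
  dim_cs <- m - n + 1
  if (dim_cs <= 0) return(list())
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = data.frame(id = seq_len(n)))
  # candidate cycles: for each root v and edge (a,b): SP(v,a) + (a,b) + SP(b,v)
  cand <- list()
  for (v in seq_len(n)) {
    sp <- igraph::shortest_paths(g, from = v, to = igraph::V(g),
                                 weights = e$weight, output = "epath")$epath
    for (k in seq_len(m)) {
      pa <- as.integer(sp[[e$from[k]]]); pb <- as.integer(sp[[e$to[k]]])
      cyc <- sort(c(setdiff(union(pa, pb), intersect(pa, pb)), k))
      if (length(cyc) < 3) next
      # keep only simple cycles: every touched node has degree exactly 2
      vs <- c(e$from[cyc], e$to[cyc])
      if (any(table(vs) != 2)) next
      cand[[length(cand) + 1]] <- cyc
    }
  }
  if (!length(cand)) stop("no candidate cycles found")
  key <- vapply(cand, paste, "", collapse = ",")
  cand <- cand[!duplicated(key)]
  wt <- vapply(cand, function(cc) sum(e$weight[cc]), 1)
  lex <- vapply(cand, function(cc) paste(sprintf("%06d", cc), collapse = ""), "")
  cand <- cand[order(wt, lex)]
  # greedy GF(2) independence
  basis <- list(); pivots <- list()
  for (cc in cand) {
    vec <- logical(m); vec[cc] <- TRUE
    for (b in pivots) if (vec[b$pivot]) vec <- xor(vec, b$vec)
    if (any(vec)) {
      pivots[[length(pivots) + 1]] <- list(pivot = which(vec)[1], vec = vec)
      basis[[length(basis) + 1]] <- cc
      if (length(basis) == dim_cs) break
    }
  }
  if (length(basis) != dim_cs)
    stop("could not complete a cycle basis (graph disconnected?)")
  basis
}

#' Algebraic dual from a cycle basis
#'
#' Generalizes [build_dual()] to graphs without a plane embedding: dual nodes
#' are the basis cycles (by default the minimum cycle basis), joined whenever
#' two cycles share an edge, with weight `sum(1/w_l)` over shared edges. On a
#' plane graph with its face basis this reproduces the plane dual. The
#' orientation of each basis cycle is fixed by walking it from its smallest
#' node id; the resulting incidence matrix satisfies `I^T C = 0`.
#'
#' @param edges data frame `from`, `to`, `weight` (or a `plane_graph`)
#' @param basis list of edge-id vectors (simple cycles); computed by
#'   [minimum_cycle_basis()] when omitted
#' @param n number of nodes
#' @return a `dual_graph` (without face geometry; `coords` are `NA`)
#' @export
dual_from_cycle_basis <- function(edges, basis = NULL, n = NULL) {
  pg <- NULL
  if (inherits(edges, "plane_graph")) {
    pg <- edges; n <- n_nodes(pg); edges <- pg$edges
  }
  e <- as.data.frame(edges)
  if (is.null(n)) n <- max(e$from, e$to)
  if (is.null(basis)) basis <- minimum_cycle_basis(e, n)
  nf <- length(basis)
  if (nf < 2) stop("degenerate dual: fewer than 2 basis cycles")
  # orient each cycle and check it is a circulation
  m <- nrow(e)
  Ci <- integer(0); Cj <- integer(0); Cx <- integer(0)
  for (b in seq_len(nf)) {
    cyc <- basis[[b]]
    # walk the cycle: adjacency among its edges
    vs <- sort(unique(c(e$from[cyc], e$to[cyc])))
    cur_v <- vs[1]
    remaining <- cyc
    repeat {
      k <- remaining[e$from[remaining] == cur_v | e$to[remaining] == cur_v][1]
      if (is.na(k)) break
      sgn <- if (e$from[k] == cur_v) 1L else -1L
      Ci <- c(Ci, k); Cj <- c(Cj, b); Cx <- c(Cx, sgn)
      cur_v <- if (sgn == 1L) e$to[k] else e$from[k]
      remaining <- setdiff(remaining, k)
      if (!length(remaining)) break
    }
    if (length(remaining)) stop("basis cycle ", b, " is not a single closed walk")
  }
  C <- Matrix::sparseMatrix(i = Ci, j = Cj, x = Cx, dims = c(m, nf))
  I <- Matrix::sparseMatrix(i = c(seq_len(m), seq_len(m)),
                            j = c(e$from, e$to),
                            x = c(rep(1, m), rep(-1, m)), dims = c(m, n))
  if (max(abs(Matrix::t(I) %*% C)) != 0)
    stop("invalid basis: I^T C != 0")
  # shared edges -> dual edges
  cnt <- tabulate(Ci, m)
  de <- list(); shared <- list()
  pairkeys <- character(0)
  for (k in which(cnt >= 2)) {
    fs <- sort(Cj[Ci == k])
    for (a in seq_len(length(fs) - 1)) for (b2 in (a + 1):length(fs)) {
      key <- paste(fs[a], fs[b2])
      idx <- match(key, pairkeys)
      if (is.na(idx)) {
        pairkeys <- c(pairkeys, key)
        de[[length(de) + 1]] <- c(fs[a], fs[b2], 1 / e$weight[k])
        shared[[length(shared) + 1]] <- k
      } else {
        de[[idx]][3] <- de[[idx]][3] + 1 / e$weight[k]
        shared[[idx]] <- c(shared[[idx]], k)
      }
    }
  }
  dd <- as.data.frame(do.call(rbind, de))
  names(dd) <- c("from", "to", "weight")
  structure(list(n = nf, edges = dd, shared = shared,
                 coords = data.frame(x = rep(NA_real_, nf),
                                     y = rep(NA_real_, nf)),
                 faces = NULL, primal = pg, basis = basis),
            class = "dual_graph")
}
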