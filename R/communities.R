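#' Fiedler value and vector
#'
#' Second-smallest eigenpair of a graph Laplacian, computed with a dense
#' symmetric eigensolver (the networks handled here are desk-scale, so a
#' dense solve is both exact and reproducible). The eigenvector is normalized
#' and its sign fixed so that its first entry of non-negligible magnitude is
#' positive, making repeated runs bit-identical.
#'
#' @param L symmetric PSD matrix (dense or sparse)
#' @param tol relative threshold below which the second eigenvalue is treated
#'   as zero, signalling a disconnected graph
#' @return list with `value` (lambda_2 >= 0) and `vector` (v_2)
#' @export
fiedler <- function(L, tol = 1e-12) {
  L <- as.matrix(L)
  n <- nrow(L)
  if (n < 2) stop("need at least 2 nodes")
  es <- eigen(L, symmetric = TRUE)
  lambda2 <- es$values[n - 1]
  v2 <- es$vectors[, n - 1]
  scale <- mean(diag(L))
  if (lambda2 < tol * max(scale, 1))
    stop("graph appears disconnected: lambda_2 ~ 0")
  nz <- which(abs(v2) > 1e-10)[1]
  if (!is.na(nz) && v2[nz] < 0) v2 <- -v2
  list(value = lambda2, vector = v2)
}

#' Spectral bisection of a primal or dual graph
#'
#' Splits the nodes of the graph (side `"primal"`) or the faces of its dual
#' (side `"dual"`) into two communities by the sign of the Fiedler vector
#' relative to a threshold `h` (default 0, entries equal to `h` go to the
#' positive side). For a primal bisection the boundary is the *cut-set* of
#' edges between the communities and the topological connectivity is
#' `mu_2 = (N1+N2)/(N1 N2) * sum of cut weights`, an upper bound on
#' `lambda_2`. For a dual bisection the boundary is the *cut-path* of primal
#' edges shared by faces of different dual communities and
#' `mu_2* = (N1*+N2*)/(N1* N2*) * sum of inverse cut-path weights >= lambda_2*`.
#'
#' @param graph a `plane_graph`
#' @param side `"primal"` or `"dual"`
#' @param h Fiedler-vector threshold
#' @param dual optional pre-built `dual_graph` (side = "dual")
#' @return a `bisection` object; see Details.
#' @details The returned list contains `side`, `lambda2`, `vector`, `h`,
#'   `members1`/`members2` (node ids, or face indices for the dual side),
#'   `n1`/`n2`, `boundary_edges` (primal edge ids: cut-set or cut-path),
#'   `boundary_nodes` (cut-path terminal nodes, dual side only) and `mu2`.
#' @export
bisect <- function(graph, side = c("primal", "dual"), h = 0, dual = NULL) {
  side <- match.arg(side)
  if (side == "primal") {
    fp <- fiedler(laplacian_matrix(graph))
    grp <- ifelse(fp$vector - h >= 0, 1L, 2L)
    if (length(unique(grp)) < 2) stop("trivial split: one community is empty")
    members1 <- which(grp == 1L); members2 <- which(grp == 2L)
    cs <- cut_set(graph, members1)
    out <- list(side = side, lambda2 = fp$value, vector = fp$vector, h = h,
                members1 = members1, members2 = members2,
                n1 = length(members1), n2 = length(members2),
                boundary_edges = cs$edges, boundary_nodes = integer(0),
                mu2 = cs$mu2, graph = graph, dual = NULL)
  } else {
    if (is.null(dual)) dual <- build_dual(graph)
    fp <- fiedler(dual_laplacian(dual))
    grp <- ifelse(fp$vector - h >= 0, 1L, 2L)
    if (length(unique(grp)) < 2) stop("trivial split: one community is empty")
    members1 <- which(grp == 1L); members2 <- which(grp == 2L)
    cp <- cut_path(graph, dual, members1)
    out <- list(side = side, lambda2 = fp$value, vector = fp$vector, h = h,
                members1 = members1, members2 = members2,
                n1 = length(members1), n2 = length(members2),
                boundary_edges = cp$edges, boundary_nodes = cp$nodes,
                mu2 = cp$mu2, graph = graph, dual = dual)
  }
  class(out) <- "bisection"
  out
}

#' @export
print.bisection <- function(x, ...) {
  star <- if (x$side == "dual") "*" else ""
  cat(sprintf(
    "bisection (%s): |V1| = %d, |V2| = %d, lambda2%s = %.6g <= mu2%s = %.6g (%d boundary edges)\n",
    x$side, x$n1, x$n2, star, x$lambda2, star, x$mu2, length(x$boundary_edges)))
  invisible(x)
}

#' Cut-set of a primal node partition
#'
#' Edges with endpoints in different communities, together with the
#' topological connectivity `mu_2` they define. Removing the cut-set
#' disconnects the two communities.
#'
#' @param graph a `plane_graph`
#' @param members1 node ids of the first community (rest form the second)
#' @return list with `edges` (edge ids), `mu2`, `n1`, `n2`
#' @export
cut_set <- function(graph, members1) {
  n <- n_nodes(graph)
  in1 <- logical(n); in1[members1] <- TRUE
  e <- graph$edges
  cut <- which(in1[e$from] != in1[e$to])
  n1 <- sum(in1); n2 <- n - n1
  if (n1 == 0 || n2 == 0) stop("both communities must be nonempty")
  list(edges = cut, mu2 = (n1 + n2) / (n1 * n2) * sum(e$weight[cut]),
       n1 = n1, n2 = n2)
}

#' Cut-path of a dual face partition
#'
#' Primal edges shared by faces belonging to different dual communities,
#' together with their terminal nodes. Removing the path (its edges and
#' nodes) disconnects the primal graph, which is verified; a warning of class
#' `dualcomm_nonpath` is emitted when the shared edges do not form a single
#' simple path.
#'
#' @param graph a `plane_graph`
#' @param dual its `dual_graph`
#' @param members1 face indices of the first dual community
#' @return list with `edges` (primal edge ids), `nodes` (their endpoints),
#'   `mu2` (the dual topological connectivity `mu_2*`), `n1`, `n2`,
#'   `is_path`, `disconnects`
#' @export
cut_path <- function(graph, dual, members1) {
  in1 <- logical(dual$n); in1[members1] <- TRUE
  crossing <- in1[dual$edges$from] != in1[dual$edges$to]
  pedges <- sort(unique(unlist(dual$shared[crossing])))
  n1 <- sum(in1); n2 <- dual$n - n1
  if (n1 == 0 || n2 == 0) stop("both dual communities must be nonempty")
  mu2 <- (n1 + n2) / (n1 * n2) * sum(1 / graph$edges$weight[pedges])
  nodes <- sort(unique(c(graph$edges$from[pedges], graph$edges$to[pedges])))
  # does the path really cut the primal graph?
  g <- as_igraph(graph)
  keep <- setdiff(seq_len(n_nodes(graph)), nodes)
  disconnects <- length(keep) == 0 ||
    !igraph::is_connected(igraph::induced_subgraph(g, keep))
  deg <- table(factor(c(graph$edges$from[pedges], graph$edges$to[pedges]),
                      levels = nodes))
  is_path <- all(deg <= 2) && sum(deg == 1) == 2 &&
    igraph::is_connected(igraph::subgraph_from_edges(g, pedges,
                                                     delete.vertices = TRUE))
  if (!is_path)
    warning(structure(class = c("dualcomm_nonpath", "warning", "condition"),
                      list(message = "shared boundary edges do not form a single path",
                           call = sys.call())))
  list(edges = pedges, nodes = nodes, mu2 = mu2, n1 = n1, n2 = n2,
       is_path = is_path, disconnects = disconnects)
}

#' Hierarchical decomposition by repeated spectral bisection
#'
#' Repeats [bisect()] up to `m` levels. At each level the boundary edges of
#' the current split are removed and the procedure recurses on the two
#' resulting primal subgraphs. On the primal side a subgraph is the connected
#' piece containing each community. On the dual side each child consists of
#' the edges belonging only to faces of one dual community (boundary edges
#' belong to neither child, nodes on the cut-path belong to both children),
#' and each child's dual is re-derived from its own embedding. A branch stops
#' early when its graph has fewer than 4 nodes or (dual side) fewer than 2
#' interior faces; isolated nodes produced by boundary removal are kept as
#' singleton leaves.
#'
#' @param graph a `plane_graph`
#' @param m maximum depth (`m = 1` gives a single bisection, 2 leaves)
#' @param side `"primal"` or `"dual"`
#' @param h Fiedler threshold passed to [bisect()]
#' @return a `hierarchy` tree: nested list with `members` (original node
#'   ids), `bisection` (or `NULL` at leaves), `children`, `status`.
#' @export
hierarchical_decompose <- function(graph, m, side = c("primal", "dual"), h = 0) {
  side <- match.arg(side)
  stopifnot(m >= 1)
  decompose_rec(graph, seq_len(n_nodes(graph)), m, side, h)
}

decompose_rec <- function(graph, orig_ids, depth, side, h) {
  node <- list(members = orig_ids, bisection = NULL, children = NULL,
               status = "leaf")
  if (n_nodes(graph) < 4) return(node)
  if (side == "dual" && n_edges(graph) - n_nodes(graph) + 1 < 2) {
    node$status <- "no-dual"
    return(node)
  }
  bs <- tryCatch(bisect(graph, side = side, h = h),
                 error = function(e) NULL)
  if (is.null(bs)) { node$status <- "bisect-failed"; return(node) }
  node$bisection <- bs
  parts <- split_children(graph, bs)
  node$status <- "split"
  # nodes stranded by boundary removal (all incident edges on the boundary)
  # are kept as singleton leaves next to the two regular children
  uncovered <- setdiff(seq_len(n_nodes(graph)),
                       unlist(lapply(parts, `[[`, "nodes")))
  node$children <- lapply(parts, function(p) {
    sub <- p$graph
    ids <- orig_ids[p$nodes]
    if (depth - 1 >= 1 && !is.null(sub) && n_nodes(sub) >= 2 &&
        igraph::is_connected(as_igraph(sub))) {
      decompose_rec(sub, ids, depth - 1, side, h)
    } else {
      list(members = ids, bisection = NULL, children = NULL, status = "leaf")
    }
  })
  for (u in uncovered)
    node$children[[length(node$children) + 1]] <-
      list(members = orig_ids[u], bisection = NULL, children = NULL,
           status = "isolated")
  node
}

# children of a bisection as (local node index set, plane_graph or NULL)
split_children <- function(graph, bs) {
  if (bs$side == "primal") {
    keep <- setdiff(seq_len(n_edges(graph)), bs$boundary_edges)
    e <- graph$edges[keep, , drop = FALSE]
    lapply(list(bs$members1, bs$members2), function(mem) {
      inmem <- graph$edges$from %in% mem & graph$edges$to %in% mem
      eids <- intersect(keep, which(inmem))
      if (!length(eids))
        return(list(nodes = mem, graph = NULL))
      sub <- subgraph_plane(graph, nodes = mem)
      list(nodes = mem, graph = sub)
    })
  } else {
    dual <- bs$dual
    nf <- dual$n
    comm <- integer(nf); comm[bs$members1] <- 1L; comm[bs$members2] <- 2L
    # community of each primal edge: faces containing it
    eid <- unlist(lapply(dual$faces, `[[`, "edges"))
    fid <- rep(seq_len(nf), vapply(dual$faces, function(f) length(f$edges), 1L))
    byedge <- split(comm[fid], eid)
    ecomm <- vapply(byedge, function(cs) {
      u <- unique(cs)
      if (length(u) == 1) u else NA_integer_   # boundary edges: both sides
    }, 1L)
    face_edge <- as.integer(names(ecomm))
    eidsets <- lapply(1:2, function(side_i)
      face_edge[!is.na(ecomm) & ecomm == side_i])
    boundary <- face_edge[is.na(ecomm)]
    # bridges (edges in no interior face) join every child their endpoints
    # reach through non-boundary edges, so pendant trees stay attached
    unassigned <- setdiff(seq_len(n_edges(graph)),
                          c(face_edge))
    lapply(eidsets, function(eids) {
      if (!length(eids)) return(list(nodes = integer(0), graph = NULL))
      S <- unique(c(graph$edges$from[eids], graph$edges$to[eids]))
      repeat {
        grow <- unassigned[(graph$edges$from[unassigned] %in% S |
                            graph$edges$to[unassigned] %in% S) &
                           !(unassigned %in% eids)]
        if (!length(grow)) break
        eids <- c(eids, grow)
        S <- unique(c(S, graph$edges$from[grow], graph$edges$to[grow]))
      }
      sub <- subgraph_plane(graph, edge_ids = sort(eids))
      list(nodes = attr(sub, "orig_nodes"), graph = sub)
    })
  }
}

#' Leaf node sets of a hierarchy
#'
#' @param tree result of [hierarchical_decompose()]
#' @return list of integer vectors (original node ids), left-to-right
#' @export
hierarchy_leaves <- function(tree) {
  if (is.null(tree$children)) return(list(tree$members))
  do.call(c, lapply(tree$children, hierarchy_leaves))
}

#' Per-node leaf labels of a hierarchy
#'
#' Assigns each node the index of the first leaf containing it (children of a
#' dual-side split may overlap on cut-path nodes).
#'
#' @param tree result of [hierarchical_decompose()]
#' @param n number of nodes of the root graph
#' @return integer vector of length `n`
#' @export
hierarchy_labels <- function(tree, n = max(tree$members)) {
  lv <- hierarchy_leaves(tree)
  lab <- rep(NA_integer_, n)
  for (i in seq_along(lv)) {
    idx <- lv[[i]]
    lab[idx[is.na(lab[idx])]] <- i
  }
  lab
}
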