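#' Edge-to-edge sensitivity matrix (primal form)
#'
#' The M x M matrix `H = W I L^+ I^T` whose entry `H[l, e]` is the
#' sensitivity factor `eta_{v1,v2,l}`: the flow change on edge `l` per unit
#' of extra inflow injected at the start node of edge `e = (v1, v2)` and
#' withdrawn at its end node. In power-systems terminology these are the
#' power transfer distribution factors. Self-sensitivities `H[e, e]` lie in
#' `[0, 1]`.
#'
#' @param graph a `plane_graph`
#' @return dense M x M matrix
#' @export
sensitivity_matrix <- function(graph) {
  I <- as.matrix(incidence_matrix(graph))
  Lp <- laplacian_pinv(laplacian_matrix(graph))
  H <- (graph$edges$weight * I) %*% Lp %*% t(I)
  dimnames(H) <- NULL
  H
}

#' Sensitivity factor, primal formulation
#'
#' `eta = w_l l_l^T I L^+ I^T l_e`: response of the flow on edge `l` to a
#' unit dipole injection across edge `e`, computed from the pseudoinverse of
#' the primal Laplacian.
#'
#' @param graph a `plane_graph`
#' @param e trigger edge id
#' @param l responding edge id
#' @return scalar sensitivity factor
#' @seealso [sensitivity_dual()] for the equivalent dual-graph formula
#' @export
sensitivity_primal <- function(graph, e, l) {
  I <- as.matrix(incidence_matrix(graph))
  Lp <- laplacian_pinv(laplacian_matrix(graph))
  graph$edges$weight[l] *
    as.numeric(I[l, , drop = FALSE] %*% Lp %*% I[e, ])
}

#' Sensitivity factor, dual formulation
#'
#' For `l != e`, `eta = -(1/w_e) l_l^T C (L*_cyc)^-1 C^T l_e`, where `C` is
#' the full face-edge incidence matrix and `L*_cyc = C^T W^-1 C` the
#' cycle-space Laplacian. Derived by choosing the particular KCL solution
#' `dF_part = dP l_e` and solving the cycle-flow Poisson equation; it agrees
#' with the primal formula exactly. If `e` is a bridge (belongs to no cycle)
#' the sensitivity on every other edge is 0 and the result carries
#' `attr(, "bridge") = TRUE`.
#'
#' @param graph a `plane_graph`
#' @param e trigger edge id
#' @param l responding edge id, `l != e`
#' @param dual_op optional precomputed list from [dual_sensitivity_operator()]
#' @return scalar sensitivity factor
#' @export
sensitivity_dual <- function(graph, e, l, dual_op = NULL) {
  if (l == e) stop("dual formulation applies to l != e")
  if (is.null(dual_op)) dual_op <- dual_sensitivity_operator(graph)
  ce <- dual_op$C[e, , drop = FALSE]
  if (all(ce == 0)) {
    out <- 0
    attr(out, "bridge") <- TRUE
    return(out)
  }
  f <- solve(dual_op$Lcyc, as.numeric(ce))
  -(1 / graph$edges$weight[e]) * sum(dual_op$C[l, ] * f)
}

#' Precompute the operators of the dual sensitivity formula
#'
#' @param graph a `plane_graph`
#' @return list with dense `C` and `Lcyc = C^T W^-1 C`
#' @export
dual_sensitivity_operator <- function(graph) {
  faces <- enumerate_faces(graph)
  C <- as.matrix(cycle_incidence(faces))
  list(C = C, Lcyc = crossprod(C, (1 / graph$edges$weight) * C))
}

#' Flow changes after a line outage
#'
#' Simulates the complete failure of edge `e` carrying pre-failure flow
#' `F_e` with the rerouting identity
#' `dF_l = eta_{e,l} * F_e / (1 - eta_{e,e})` for `l != e` (and
#' `dF_e = -F_e`). Equivalent to deleting the edge and re-solving the flow
#' problem.
#'
#' @param graph a `plane_graph`
#' @param e failing edge id
#' @param flows pre-failure edge flow vector (e.g. `solve_flow(...)$flows`),
#'   or a single number interpreted as the flow on `e`
#' @param H optional precomputed [sensitivity_matrix()]
#' @return numeric vector of flow changes per edge
#' @export
line_outage_flow_change <- function(graph, e, flows, H = NULL) {
  g <- as_igraph(graph)
  if (e %in% igraph::bridges(g))
    stop("edge ", e, " is a bridge: its failure disconnects the network")
  if (is.null(H)) H <- sensitivity_matrix(graph)
  Fe <- if (length(flows) == 1) flows else flows[e]
  eta_ee <- H[e, e]
  dF <- H[, e] * Fe / (1 - eta_ee)
  dF[e] <- -Fe
  dF
}

# hop distance between edges: min over endpoint pairs of unweighted
# shortest-path length (independent of the scanned weights)
edge_distances <- function(graph) {
  g <- as_igraph(graph)
  dn <- igraph::distances(g, weights = NA)
  e <- graph$edges
  pmin(dn[e$from, e$from], dn[e$from, e$to],
       dn[e$to, e$from], dn[e$to, e$to])
}

#' Assign edges to the communities of a bisection
#'
#' An edge belongs to a community when both endpoints (primal bisection) or
#' both adjacent interior faces (dual bisection) lie in it; boundary edges
#' belong to neither and get `NA`. For the dual side an edge bordering the
#' outer face inherits the community of its single interior face.
#'
#' @param graph a `plane_graph`
#' @param bisection a [bisect()] result
#' @return integer vector (1, 2 or `NA`) of length M
#' @export
edge_communities <- function(graph, bisection) {
  m <- n_edges(graph)
  if (bisection$side == "primal") {
    grp <- integer(n_nodes(graph))
    grp[bisection$members1] <- 1L; grp[bisection$members2] <- 2L
    out <- ifelse(grp[graph$edges$from] == grp[graph$edges$to],
                  grp[graph$edges$from], NA_integer_)
  } else {
    dual <- bisection$dual
    comm <- integer(dual$n)
    comm[bisection$members1] <- 1L; comm[bisection$members2] <- 2L
    eid <- unlist(lapply(dual$faces, `[[`, "edges"))
    fid <- rep(seq_len(dual$n),
               vapply(dual$faces, function(f) length(f$edges), 1L))
    out <- rep(NA_integer_, m)
    for (k in seq_len(m)) {
      cs <- unique(comm[fid[eid == k]])
      if (length(cs) == 1) out[k] <- cs
    }
  }
  out
}

#' Mean flow ratio between two communities
#'
#' For every trigger edge `e` inside a community, compares the magnitude of
#' flow changes it induces in the *other* community with those in its *own*
#' community, controlled for hop distance `d`:
#' `R(e, d) = <|eta|>_{other, d} / <|eta|>_{same, d}`, and the mean flow
#' ratio `R` is the average of `R(e, d)` over all trigger edges and
#' distances where both bin averages exist. `R ~ 1` means failures spread
#' unhindered; `R ~ 0` means the boundary insulates the other community.
#'
#' @param graph a `plane_graph`
#' @param edge_comm integer vector from [edge_communities()] (1, 2, `NA`)
#' @param H optional precomputed [sensitivity_matrix()]
#' @return list with `R` (mean flow ratio), `table` (data frame `e`, `d`,
#'   `ratio`) and `n_pairs`
#' @export
flow_ratio <- function(graph, edge_comm, H = NULL) {
  if (is.null(H)) H <- sensitivity_matrix(graph)
  D <- edge_distances(graph)
  m <- n_edges(graph)
  triggers <- which(!is.na(edge_comm))
  res_e <- integer(0); res_d <- integer(0); res_r <- numeric(0)
  for (e in triggers) {
    same <- which(edge_comm == edge_comm[e]); same <- setdiff(same, e)
    other <- which(!is.na(edge_comm) & edge_comm != edge_comm[e])
    if (!length(other) || !length(same)) next
    eta <- abs(H[, e])
    ds <- intersect(unique(D[same, e]), unique(D[other, e]))
    for (d in ds) {
      ms <- mean(eta[same[D[same, e] == d]])
      mo <- mean(eta[other[D[other, e] == d]])
      res_e <- c(res_e, e); res_d <- c(res_d, d)
      res_r <- c(res_r, if (ms > 0) mo / ms else NA_real_)
    }
  }
  tab <- data.frame(e = res_e, d = res_d, ratio = res_r)
  list(R = mean(tab$ratio, na.rm = TRUE), table = tab,
       n_pairs = sum(!is.na(tab$ratio)))
}

#' Scan the mean flow ratio over boundary weights
#'
#' Builds a square lattice whose central boundary is either weakened
#' (`mode = "cut_set"`, primal communities) or strengthened
#' (`mode = "cut_path"`, dual communities) by the factor `w`, and records the
#' mean flow ratio together with the primal and dual Fiedler values.
#'
#' @param nx,ny lattice dimensions
#' @param w_values numeric vector of boundary weights
#' @param mode `"cut_set"` or `"cut_path"`
#' @return data frame with columns `w`, `R`, `lambda2`, `lambda2_dual`
#' @export
flow_ratio_scan <- function(nx = 21, ny = 10, w_values, mode = c("cut_set", "cut_path")) {
  mode <- match.arg(mode)
  out <- lapply(w_values, function(w) {
    pg <- square_lattice(nx, ny, mode = mode, contrast = w)
    # communities fixed by the lattice geometry so that R is comparable
    # across the scan (the spectral split is degenerate at w = 1)
    midx <- (pg$nodes$x[pg$edges$from] + pg$nodes$x[pg$edges$to]) / 2
    ec <- ifelse(midx < attr(pg, "mid_x"), 1L, 2L)
    ec[attr(pg, "boundary")] <- NA_integer_
    fr <- flow_ratio(pg, ec)
    l2 <- fiedler(laplacian_matrix(pg))$value
    l2d <- fiedler(dual_laplacian(pg))$value
    data.frame(w = w, R = fr$R, lambda2 = l2, lambda2_dual = l2d)
  })
  do.call(rbind, out)
}
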