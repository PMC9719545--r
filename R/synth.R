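#' Square lattice with a tunable community boundary
#'
#' Generates an `nx` by `ny` square grid on integer coordinates (node id
#' `(i-1)*ny + j` for column `i`, row `j`). Two boundary modes reproduce the
#' canonical two-community geometries:
#'
#' * `cut_set`: the horizontal edges crossing the vertical midline get weight
#'   `contrast * base_weight`. Weakening them (`contrast < 1`) induces two
#'   primal communities (left/right node sets).
#' * `cut_path`: the vertical edges of the central column get weight
#'   `contrast * base_weight`. Strengthening them (`contrast > 1`) creates a
#'   strong central vein, i.e. two dual communities (left/right face sets).
#'
#' @param nx,ny number of columns and rows (both >= 2)
#' @param base_weight weight of unmodified edges
#' @param mode `"none"`, `"cut_set"` or `"cut_path"`
#' @param contrast multiplicative weight factor of the boundary edges
#' @return a `plane_graph` with attributes `boundary` (edge ids of the
#'   reweighted set), `mid_x` (x position of the boundary) and `node_side`
#'   (-1 left, +1 right, 0 on the boundary line)
#' @export
square_lattice <- function(nx, ny, base_weight = 1,
                           mode = c("none", "cut_set", "cut_path"),
                           contrast = 1) {
  mode <- match.arg(mode)
  if (nx < 2 || ny < 2) stop("need nx >= 2 and ny >= 2")
  nid <- function(i, j) (i - 1L) * ny + j
  ii <- rep(seq_len(nx), each = ny)
  jj <- rep(seq_len(ny), nx)
  coords <- cbind(x = ii, y = jj)
  eh <- cbind(nid(rep(seq_len(nx - 1), each = ny), rep(seq_len(ny), nx - 1)),
              nid(rep(2:nx, each = ny), rep(seq_len(ny), nx - 1)))
  ev <- cbind(nid(rep(seq_len(nx), each = ny - 1), rep(seq_len(ny - 1), nx)),
              nid(rep(seq_len(nx), each = ny - 1), rep(2:ny, nx)))
  edges <- data.frame(from = c(eh[, 1], ev[, 1]), to = c(eh[, 2], ev[, 2]),
                      weight = base_weight)
  horiz <- c(rep(TRUE, nrow(eh)), rep(FALSE, nrow(ev)))
  pg <- plane_graph(coords, edges)

  xs <- coords[, 1]
  boundary <- integer(0)
  if (mode == "cut_set") {
    cutx <- floor(nx / 2) + 0.5                  # between two central columns
    boundary <- which(horiz &
      (xs[pg$edges$from] - cutx) * (xs[pg$edges$to] - cutx) < 0)
    mid_x <- cutx
  } else if (mode == "cut_path") {
    cc <- ceiling((nx + 1) / 2)                  # central column
    boundary <- which(!horiz & xs[pg$edges$from] == cc)
    mid_x <- cc
  } else {
    mid_x <- (nx + 1) / 2
  }
  pg$edges$weight[boundary] <- base_weight * contrast
  attr(pg, "boundary") <- boundary
  attr(pg, "mid_x") <- mid_x
  attr(pg, "node_side") <- sign(xs - mid_x)
  pg
}

#' Triangular lattice with source/sink roles
#'
#' A rectangular patch of the triangular tessellation: row `j` holds `nx`
#' nodes at `x = i + (j mod 2)/2`, `y = j*sqrt(3)/2`, each joined to its
#' horizontal neighbours and to the two nearest nodes of the next row, so
#' every interior face is a triangle. The leftmost and the rightmost node
#' (ties broken towards mid-height, then deterministically) are marked as
#' sources; all other nodes are sinks, as in the fluctuating-source
#' supply-network experiments.
#'
#' @param nx,ny nodes per row and number of rows
#' @param base_weight initial edge weight
#' @return a `plane_graph` with attributes `sources` (two node ids) and
#'   `sinks`
#' @export
triangular_lattice <- function(nx, ny, base_weight = 1) {
  if (nx < 2 || ny < 2) stop("need nx >= 2 and ny >= 2")
  nid <- function(i, j) j * nx + i + 1L     # i, j zero-based
  ij <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))
  off <- (ij$j %% 2) / 2
  coords <- cbind(x = ij$i + off, y = ij$j * sqrt(3) / 2)
  ef <- list()
  for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    if (i + 1 < nx) ef[[length(ef) + 1]] <- c(nid(i, j), nid(i + 1, j))
    if (j + 1 < ny) {
      ef[[length(ef) + 1]] <- c(nid(i, j), nid(i, j + 1))
      io <- if (j %% 2 == 0) i - 1L else i + 1L   # second upper neighbour
      if (io >= 0 && io < nx)
        ef[[length(ef) + 1]] <- c(nid(i, j), nid(io, j + 1))
    }
  }
  em <- do.call(rbind, ef)
  pg <- plane_graph(coords, data.frame(from = em[, 1], to = em[, 2],
                                       weight = base_weight))
  xs <- coords[, 1]; ys <- coords[, 2]
  ymid <- (min(ys) + max(ys)) / 2
  pick <- function(cands) cands[order(abs(ys[cands] - ymid), ys[cands])][1]
  attr(pg, "sources") <- c(pick(which(xs == min(xs))),
                           pick(which(xs == max(xs))))
  attr(pg, "sinks") <- setdiff(seq_len(nrow(coords)), attr(pg, "sources"))
  pg
}

#' Honeycomb lattice with a tunable community boundary
#'
#' Tiles `ncol x nrow` hexagonal cells (pointy-top, unit side) and returns
#' the vertex graph. A central vertical line defines two communities of
#' nodes; the boundary can be reweighted in two ways:
#'
#' * `cut_across`: edges crossing the midline get weight `contrast`
#'   (weak for `contrast < 1`: primal communities),
#' * `cut_along`: the edges of the zig-zag path running just left of the
#'   midline from bottom to top get weight `contrast` (strong for
#'   `contrast > 1`: dual communities).
#'
#' @param ncol,nrow hexagon cells horizontally / vertically
#' @param base_weight default edge weight
#' @param mode `"none"`, `"cut_across"` or `"cut_along"`
#' @param contrast boundary weight factor
#' @return `plane_graph` with attributes `boundary` (edge ids), `mid_x`,
#'   `node_side` (-1/+1 by x position, 0 only in `cut_along` mode for path
#'   nodes)
#' @export
honeycomb_lattice <- function(ncol, nrow, base_weight = 1,
                              mode = c("none", "cut_across", "cut_along"),
                              contrast = 1) {
  mode <- match.arg(mode)
  if (ncol < 2 || nrow < 1) stop("need ncol >= 2 and nrow >= 1")
  sq3 <- sqrt(3)
  hexv <- cbind(x = c(0, sq3 / 2, sq3 / 2, 0, -sq3 / 2, -sq3 / 2),
                y = c(-1, -0.5, 0.5, 1, 0.5, -0.5))
  verts <- list(); edges <- list()
  for (ci in 0:(ncol - 1)) for (cj in 0:(nrow - 1)) {
    cx <- ci * sq3 + (cj %% 2) * sq3 / 2
    cy <- cj * 1.5
    vv <- cbind(hexv[, 1] + cx, hexv[, 2] + cy)
    verts[[length(verts) + 1]] <- vv
    edges[[length(edges) + 1]] <- vv
  }
  allv <- do.call(rbind, verts)
  key <- paste(round(allv[, 1], 6), round(allv[, 2], 6))
  uk <- !duplicated(key)
  nodes <- allv[uk, , drop = FALSE]
  idmap <- match(key, key[uk])
  eset <- list()
  for (h in seq_along(verts)) {
    base <- (h - 1) * 6
    for (s in 1:6) {
      a <- idmap[base + s]; b <- idmap[base + (s %% 6) + 1]
      eset[[length(eset) + 1]] <- c(min(a, b), max(a, b))
    }
  }
  em <- unique(do.call(rbind, eset))
  pg <- plane_graph(cbind(x = nodes[, 1], y = nodes[, 2]),
                    data.frame(from = em[, 1], to = em[, 2],
                               weight = base_weight))
  xs <- pg$nodes$x
  # cut line in the middle of the vertex-column gap nearest the centre, so
  # that crossing edges form a genuine cut (no vertex lies on the line)
  ux <- sort(unique(round(xs, 6)))
  gaps <- which(diff(ux) > 0.5)
  centre <- (min(xs) + max(xs)) / 2
  gi <- gaps[which.min(abs((ux[gaps] + ux[gaps + 1]) / 2 - centre))]
  mid_x <- (ux[gi] + ux[gi + 1]) / 2
  boundary <- integer(0)
  node_side <- sign(round(xs - mid_x, 6))
  if (mode == "cut_across") {
    boundary <- which((xs[pg$edges$from] - mid_x) *
                      (xs[pg$edges$to] - mid_x) < -1e-9)
  } else if (mode == "cut_along") {
    # zig-zag path from the bottom-most to the top-most node near the midline,
    # found as a shortest path penalizing horizontal distance from the line
    g <- as_igraph(pg)
    pen <- abs((xs[pg$edges$from] + xs[pg$edges$to]) / 2 - mid_x) + 0.1
    near <- which(abs(xs - mid_x) < sq3)
    bot <- near[which.min(pg$nodes$y[near])]
    top <- near[which.max(pg$nodes$y[near])]
    sp <- igraph::shortest_paths(g, from = bot, to = top, weights = pen,
                                 output = "epath")$epath[[1]]
    boundary <- as.integer(sp)
    pnodes <- unique(c(pg$edges$from[boundary], pg$edges$to[boundary]))
    node_side[pnodes] <- 0
  }
  pg$edges$weight[boundary] <- base_weight * contrast
  attr(pg, "boundary") <- boundary
  attr(pg, "mid_x") <- mid_x
  attr(pg, "node_side") <- node_side
  pg
}

#' Square lattice with nested strong veins and known hierarchy
#'
#' Builds a lattice whose dual-community hierarchy is known by construction:
#' a strong primary vein (the vertical edges of one column, weight `c1`)
#' splits the network left/right; at `levels >= 2`, weaker secondary veins
#' (horizontal edges of one row within each half, weight `c2`) split each
#' half top/bottom. The veins are deliberately off-centre, the way real
#' venation is: dual bisection still finds them (a strong vein is an
#' arbitrarily weak dual cut wherever it runs), while primal bisection is
#' driven by balance and does not align with them. The ground-truth node
#' sets follow the same convention as the dual side of
#' [hierarchical_decompose()]: vein nodes belong to both adjacent
#' communities.
#'
#' @param nx,ny lattice size
#' @param levels 1 or 2 hierarchy levels
#' @param c1,c2 primary and secondary vein weights (`c1 > c2 > 1`)
#' @param primary_col column of the primary vein
#' @param secondary_rows rows of the secondary veins in the left and right
#'   half
#' @return list with `graph`, `truth` (list of leaf node-id sets),
#'   `labels` (per-node partition of the `levels`-deep leaves, vein nodes
#'   assigned to one side deterministically) and the vein edge ids.
#' @export
vein_hierarchy_lattice <- function(nx = 15, ny = 9, levels = 2,
                                   c1 = 1e3, c2 = 1e2,
                                   primary_col = max(3, round(nx / 3)),
                                   secondary_rows = c(max(2, round(ny / 3)),
                                                      min(ny - 1, round(2 * ny / 3)))) {
  stopifnot(levels %in% 1:2, c1 > c2, c2 > 1)
  pg <- square_lattice(nx, ny)
  xs <- pg$nodes$x; ys <- pg$nodes$y
  e <- pg$edges
  cc <- primary_col
  rl <- secondary_rows[1]; rr <- secondary_rows[2]
  primary <- which(xs[e$from] == cc & xs[e$to] == cc)
  pg$edges$weight[primary] <- c1
  secondary <- integer(0)
  if (levels >= 2) {
    horiz <- which(ys[e$from] == ys[e$to])
    sec_l <- which(ys[e$from] == rl & ys[e$to] == rl & xs[e$to] <= cc)
    sec_r <- which(ys[e$from] == rr & ys[e$to] == rr & xs[e$from] >= cc)
    secondary <- intersect(horiz, c(sec_l, sec_r))
    pg$edges$weight[secondary] <- c2
  }
  left  <- which(xs <= cc); right <- which(xs >= cc)
  if (levels == 1) {
    truth <- list(left, right)
    labels <- ifelse(xs < cc, 1L, 2L); labels[xs == cc] <- 1L
  } else {
    truth <- list(intersect(left, which(ys >= rl)),
                  intersect(left, which(ys <= rl)),
                  intersect(right, which(ys >= rr)),
                  intersect(right, which(ys <= rr)))
    labels <- ifelse(xs <= cc,
                     ifelse(ys > rl, 1L, 2L),
                     ifelse(ys > rr, 3L, 4L))
  }
  list(graph = pg, truth = truth, labels = labels,
       primary = primary, secondary = secondary)
}
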