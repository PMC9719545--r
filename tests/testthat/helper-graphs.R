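# Small fixture graphs built in code.

unit_square <- function(w = 1) {
  plane_graph(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
              data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1), weight = w))
}

# two unit squares sharing the edge (2,3); shared weight settable
two_squares <- function(w_shared = 1) {
  plane_graph(cbind(c(0, 1, 1, 0, 2, 2), c(0, 0, 1, 1, 0, 1)),
              data.frame(from = c(1, 2, 3, 4, 2, 5, 6),
                         to   = c(2, 3, 4, 1, 5, 6, 3),
                         weight = c(1, w_shared, 1, 1, 1, 1, 1)))
}

# two triangles joined by a single bridge of weight eps
barbell <- function(eps = 1e-6) {
  plane_graph(cbind(c(0, 1, 0.5, 2.5, 3.5, 3), c(0, 0, 1, 0, 0, 1)),
              data.frame(from = c(1, 2, 1, 4, 5, 4, 2),
                         to   = c(2, 3, 3, 5, 6, 6, 4),
                         weight = c(1, 1, 1, 1, 1, 1, eps)))
}

path3 <- function(w = c(1, 1)) {
  plane_graph(cbind(0:2, rep(0, 3)),
              data.frame(from = 1:2, to = 2:3, weight = w))
}

# planar drawing of K4 (one node inside the triangle)
k4_plane <- function() {
  plane_graph(cbind(c(0, 2, 1, 1), c(0, 0, 2, 0.7)),
              data.frame(from = c(1, 1, 1, 2, 2, 3), to = c(2, 3, 4, 3, 4, 4)))
}

# K5 as a plain edge list (non-planar; for the cycle-basis dual)
k5_edges <- function() {
  p <- t(utils::combn(5, 2))
  data.frame(from = p[, 1], to = p[, 2], weight = 1)
}

random_weighted_lattice <- function(nx = 6, ny = 6, seed = 1) {
  pg <- square_lattice(nx, ny)
  set.seed(seed)
  pg$edges$weight <- stats::runif(n_edges(pg), 0.5, 2)
  pg
}

# balanced random injection vector
random_injection <- function(n, seed = 1) {
  set.seed(seed)
  P <- stats::rnorm(n)
  P - mean(P)
}
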