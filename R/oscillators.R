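#' Second-order phase-oscillator network
#'
#' System of oscillators `M_i ddtheta + D_i dtheta = omega_i +
#' sum_j w_ij sin(theta_j - theta_i)` on the edges of a plane graph. Only
#' the phase-locked fixed points matter for the analyses here, so inertia
#' and damping are stored but do not enter the steady-state equations.
#' Natural frequencies are re-centred to sum to zero (the co-rotating
#' frame).
#'
#' @param graph a `plane_graph`; couplings are its edge weights
#' @param omega natural frequencies (length N); re-centred to mean zero
#' @param inertia,damping per-node `M_i`, `D_i` (recycled; must be > 0)
#' @return an `oscillator_system`
#' @export
oscillator_system <- function(graph, omega, inertia = 1, damping = 1) {
  n <- n_nodes(graph)
  omega <- rep_len(omega, n)
  if (any(inertia <= 0) || any(damping <= 0))
    stop("inertia and damping must be positive")
  structure(list(graph = graph, omega = omega - mean(omega),
                 inertia = rep_len(inertia, n), damping = rep_len(damping, n)),
            class = "oscillator_system")
}

#' Phase-locked steady state
#'
#' Solves `omega_i + sum_j w_ij sin(theta_j - theta_i) = 0` by a damped
#' Newton iteration in the mean-zero gauge, starting from the linearized
#' (DC) solution `theta = L^+ omega`. The Jacobian is the effective
#' Laplacian with weights `w_ij cos(theta_j - theta_i)`; its singular
#' constant direction is removed by the usual rank-one shift. Convergence
#' failure signals that no stable phase-locked state was found at these
#' parameters.
#'
#' @param system an [oscillator_system()]
#' @param theta0 optional starting phases
#' @param tol residual tolerance (max norm)
#' @param maxit Newton iteration cap
#' @return list with `theta` (mean-zero phases), `residual`, `iterations`
#' @export
steady_state <- function(system, theta0 = NULL, tol = 1e-10, maxit = 100) {
  pg <- system$graph
  n <- n_nodes(pg)
  I <- as.matrix(incidence_matrix(pg))
  w <- pg$edges$weight
  L <- as.matrix(laplacian_matrix(pg))
  mismatch <- function(th) system$omega - as.numeric(t(I) %*% (w * sin(I %*% th)))
  theta <- if (is.null(theta0)) as.numeric(solve(L + 1 / n, system$omega))
           else theta0 - mean(theta0)
  g <- mismatch(theta)
  for (it in seq_len(maxit)) {
    if (max(abs(g)) < tol)
      return(list(theta = theta - mean(theta), residual = max(abs(g)),
                  iterations = it - 1L))
    ceff <- w * cos(as.numeric(I %*% theta))
    Leff <- t(I) %*% (ceff * I)
    step <- tryCatch(as.numeric(solve(Leff + 1 / n, g)),
                     error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      theta_new <- theta + lam * step
      g_new <- mismatch(theta_new)
      if (max(abs(g_new)) < max(abs(g)) || lam < 1e-4) break
      lam <- lam / 2
    }
    if (max(abs(g_new)) >= max(abs(g)) && lam < 1e-4) break
    theta <- theta_new; g <- g_new
  }
  if (max(abs(g)) < tol)
    return(list(theta = theta - mean(theta), residual = max(abs(g)),
                iterations = maxit))
  stop("no convergence to a phase-locked state (residual ",
       format(max(abs(g))), ")")
}

#' Steady-state response to a localized frequency perturbation
#'
#' Adds `domega` to the natural frequency of one node, recomputes the
#' phase-locked state from the unperturbed one, and returns the gauge-fixed
#' phase shifts `dtheta_i` (mean zero). The frequency sum must stay zero
#' for a locked state to exist; the compensation is either *local*
#' (`counter_node` given: `-domega` at that node, a balanced dipole like
#' the dipole injections of the flow-network sensitivity analysis) or
#' *global* (`counter_node = NULL`: `-domega/N` everywhere). Note that
#' global compensation forces a net current `domega * N_C / N` into every
#' other community `C` regardless of the boundary weights, so only the
#' local form can reveal boundary-induced suppression of the response.
#'
#' @param system an [oscillator_system()]
#' @param node perturbed node id
#' @param domega perturbation magnitude (rad/time)
#' @param counter_node optional node receiving `-domega`
#' @param base optional precomputed [steady_state()] of `system`
#' @return list with `dtheta`, `theta_base`, `theta_pert`
#' @export
perturb_response <- function(system, node, domega = 0.1, counter_node = NULL,
                             base = NULL) {
  if (is.null(base)) base <- steady_state(system)
  omega2 <- system$omega
  omega2[node] <- omega2[node] + domega
  if (!is.null(counter_node)) {
    if (counter_node == node) stop("counter_node must differ from node")
    omega2[counter_node] <- omega2[counter_node] - domega
  }
  sys2 <- system
  sys2$omega <- omega2 - mean(omega2)
  pert <- steady_state(sys2, theta0 = base$theta)
  dtheta <- pert$theta - base$theta
  list(dtheta = dtheta - mean(dtheta), theta_base = base$theta,
       theta_pert = pert$theta)
}

#' Response variance within a community
#'
#' Standard (population) variance of the response magnitudes `|dtheta_i|`
#' over the nodes of a community: `mean(a^2) - mean(a)^2`. The literal
#' unnormalized expression `sum(a^2) - sum(a)^2` is attached as
#' `attr(, "unnormalized")` for reference; it is dimensionally inconsistent
#' as a variance, so the normalized form is the primary statistic.
#'
#' @param dtheta phase-shift vector (from [perturb_response()])
#' @param community node ids of the community
#' @return scalar variance with attribute `unnormalized`
#' @export
community_response_variance <- function(dtheta, community) {
  if (!length(community)) stop("community is empty")
  a <- abs(dtheta[community])
  out <- mean(a^2) - mean(a)^2
  attr(out, "unnormalized") <- sum(a^2) - sum(a)^2
  out
}

#' Suppression of oscillator responses across a community boundary
#'
#' Honeycomb-lattice experiment: for each boundary contrast, draws random
#' natural frequencies, perturbs a node adjacent to the community boundary,
#' and records the response variance in the non-perturbed community. With a
#' primal boundary (`type = "primal"`, weak edges across the midline) the
#' contrast ladder weakens the crossing edges; with a dual boundary
#' (`type = "dual"`, strong edges along the midline) it strengthens the
#' boundary path. Medians over frequency draws quantify the suppression.
#'
#' The frequency disorder and the perturbation must stay below the sine
#' capacity of the weakest boundary (at contrast `c` the crossing edges can
#' carry at most `c` times their count), otherwise no phase-locked state
#' exists; the defaults keep the weakest rung of a `10^-2` primal ladder
#' lockable for almost all draws. Draws without a locked state are skipped
#' and counted in the `failed` column.
#'
#' @param type `"primal"` or `"dual"`
#' @param contrasts boundary weight factors (primal: `<= 1`; dual: `>= 1`)
#' @param reps random frequency draws per contrast
#' @param ncol,nrow honeycomb size
#' @param omega_scale frequencies are iid uniform on
#'   `[-omega_scale, omega_scale]`, re-centred
#' @param domega perturbation size
#' @param seed RNG seed
#' @return data frame: `contrast`, `lambda2`, `lambda2_dual`,
#'   `var_other_median`, `var_other_q25`, `var_other_q75`,
#'   `var_same_median`, `failed`
#' @export
oscillator_suppression_scan <- function(type = c("primal", "dual"), contrasts,
                                        reps = 50, ncol = 6, nrow = 4,
                                        omega_scale = 0.005, domega = 0.01,
                                        seed = 1) {
  type <- match.arg(type)
  mode <- if (type == "primal") "cut_across" else "cut_along"
  rows <- lapply(seq_along(contrasts), function(k) {
    pg <- honeycomb_lattice(ncol, nrow, mode = mode, contrast = contrasts[k])
    side <- attr(pg, "node_side")
    left <- which(side < 0); right <- which(side > 0)
    # perturb a dipole near the boundary, inside the left community:
    # +domega at the left node closest to the boundary, -domega at its
    # left-community neighbour farthest from the boundary (deterministic)
    cand <- left[order(-pg$nodes$x[left], pg$nodes$y[left])]
    pnode <- cand[1]
    nb <- unique(c(pg$edges$to[pg$edges$from == pnode],
                   pg$edges$from[pg$edges$to == pnode]))
    nb <- nb[nb %in% left]
    cnode <- nb[order(pg$nodes$x[nb], pg$nodes$y[nb])][1]
    n <- n_nodes(pg)
    set.seed(seed + 101 * k)
    vo <- rep(NA_real_, reps); vs <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      omega <- stats::runif(n, -omega_scale, omega_scale)
      sys <- oscillator_system(pg, omega)
      resp <- tryCatch(perturb_response(sys, pnode, domega = domega,
                                        counter_node = cnode),
                       error = function(e) NULL)
      if (is.null(resp)) next   # no phase-locked state for this draw
      vo[r] <- as.numeric(community_response_variance(resp$dtheta, right))
      vs[r] <- as.numeric(community_response_variance(resp$dtheta, left))
    }
    failed <- sum(is.na(vo))
    vo <- vo[!is.na(vo)]; vs <- vs[!is.na(vs)]
    data.frame(failed = failed, contrast = contrasts[k],
               lambda2 = fiedler(laplacian_matrix(pg))$value,
               lambda2_dual = fiedler(dual_laplacian(pg))$value,
               var_other_median = stats::median(vo),
               var_other_q25 = as.numeric(stats::quantile(vo, .25)),
               var_other_q75 = as.numeric(stats::quantile(vo, .75)),
               var_same_median = stats::median(vs))
  })
  do.call(rbind, rows)
}
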