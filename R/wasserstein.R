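# Exact 1-Wasserstein (earth mover) distance between two vertex measures,
# solved as a minimum-cost transportation problem by successive shortest
# augmenting paths on the bipartite support graph.  When the measures' common
# denominator D is moderate the marginals are scaled to integer units of 1/D
# and every intermediate quantity is integral, so the optimum is exact; for
# very large D the same algorithm runs on double weights with a small
# tolerance.

# successive-shortest-path min-cost transport.
# supply, demand: positive vectors with equal sums; cost: finite matrix.
# Returns the flow matrix.  tol = 0 for integral inputs.
.transport_ssp <- function(supply, demand, cost, tol = 0) {
  na <- length(supply); nb <- length(demand)
  flow <- matrix(0, na, nb)
  sup <- supply; dem <- demand
  while (any(sup > tol)) {
    # Bellman-Ford over the residual network: forward arcs A->B with cost
    # C[i,j], backward arcs B->A with cost -C[i,j] where flow[i,j] > 0.
    dA <- ifelse(sup > tol, 0, Inf)
    dB <- rep(Inf, nb)
    predB <- integer(nb)            # A-node feeding each B label
    predA <- integer(na)            # B-node feeding each A label (0 = source)
    for (round in seq_len(na + nb + 1L)) {
      changed <- FALSE
      for (j in seq_len(nb)) {
        cand <- dA + cost[, j]
        i <- which.min(cand)
        if (length(i) && cand[i] < dB[j]) {
          dB[j] <- cand[i]; predB[j] <- i; changed <- TRUE
        }
      }
      for (i in seq_len(na)) {
        back <- which(flow[i, ] > tol)
        if (length(back)) {
          cand <- dB[back] - cost[i, back]
          k <- which.min(cand)
          if (cand[k] < dA[i]) {
            dA[i] <- cand[k]; predA[i] <- back[k]; changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    open <- which(dem > tol)
    j <- open[which.min(dB[open])]
    if (!is.finite(dB[j])) stop("transport problem infeasible")
    # trace the augmenting path back to a supply node, find the bottleneck
    path_f <- list(); path_b <- list()
    jj <- j
    repeat {
      i <- predB[jj]
      path_f[[length(path_f) + 1L]] <- c(i, jj)
      if (predA[i] == 0L) { i_start <- i; break }
      jj <- predA[i]
      path_b[[length(path_b) + 1L]] <- c(i, jj)
    }
    b <- min(dem[j], sup[i_start],
             if (length(path_b)) {
               min(vapply(path_b, function(e) flow[e[1], e[2]], numeric(1)))
             } else Inf)
    for (e in path_f) flow[e[1], e[2]] <- flow[e[1], e[2]] + b
    for (e in path_b) flow[e[1], e[2]] <- flow[e[1], e[2]] - b
    sup[i_start] <- sup[i_start] - b
    dem[j] <- dem[j] - b
  }
  flow
}

#' Exact 1-Wasserstein distance between two vertex measures
#'
#' Minimises the total mass-times-distance cost of moving `mu_a` onto `mu_b`
#' over the transportation polytope (all plans whose marginals reproduce the
#' two measures).  Distances must lie in 0:3, the attainable range between
#' the two sides of a (hyper)edge; the optimal plan's mass is decomposed by
#' distance into the vector (m0, m1, m2, m3), so that the transport cost is
#' m1 + 2 m2 + 3 m3 and the Ollivier-Ricci curvature is m0 - m2 - 2 m3.
#'
#' The optimal plan need not be unique; one optimal plan is returned, and
#' only the cost (hence the curvature), not the m-vector, is canonical.
#'
#' @param mu_a,mu_b `vertex_measure`s summing to exactly 1.
#' @param dist numeric matrix of pairwise distances with row names covering
#'   the support of `mu_a` and column names the support of `mu_b`; entries
#'   must be in `0:3`.
#' @return an object of class `transport_plan`: list with components `from`,
#'   `to` (support vertices), `flow` (matrix of moved mass), `cost`,
#'   `m` (numeric m-vector), `exact` (logical; whether the rational path was
#'   used), and when exact, `cost_rat` and `m_rat` (numerator/denominator
#'   pairs).
#' @examples
#' h <- fixture("fig3")
#' p <- wasserstein1(hyper_in_measure(h, "e"), hyper_out_measure(h, "e"),
#'                   hyper_distances_for(h, "e"))
#' p$cost  # 1.25
#' @export
wasserstein1 <- function(mu_a, mu_b, dist) {
  stopifnot(inherits(mu_a, "vertex_measure"), inherits(mu_b, "vertex_measure"))
  if (is.null(rownames(dist)) || is.null(colnames(dist))) {
    stop("dist must have row and column names")
  }
  if (!all(mu_a$vertex %in% rownames(dist)) ||
      !all(mu_b$vertex %in% colnames(dist))) {
    stop("dist must cover the supports of both measures")
  }
  C <- dist[mu_a$vertex, mu_b$vertex, drop = FALSE]
  if (any(!is.finite(C)) || any(C < 0) || any(C != round(C)) || any(C > 3)) {
    stop("distances must be integers in 0:3")
  }
  D <- lcm_all(c(mu_a$den, mu_b$den))
  exact <- D <= 2^45
  if (exact) {
    sup <- mu_a$num * (D / mu_a$den)
    dem <- mu_b$num * (D / mu_b$den)
    if (sum(sup) != D || sum(dem) != D) {
      stop("measure marginals do not both sum to 1 at denominator ", D)
    }
    units <- .transport_ssp(sup, dem, C, tol = 0)
    flow <- units / D
    cost_units <- sum(units * C)
    cost_rat <- rat(cost_units, D)
    m_units <- vapply(0:3, function(d) sum(units[C == d]), numeric(1))
    m_rat <- vapply(0:3, function(d) rat(m_units[d + 1], D), numeric(2))
    m <- m_units / D
    cost <- cost_units / D
  } else {
    sup <- mu_a$num / mu_a$den
    dem <- mu_b$num / mu_b$den
    flow <- .transport_ssp(sup, dem, C, tol = 1e-12)
    cost <- sum(flow * C)
    m <- vapply(0:3, function(d) sum(flow[C == d]), numeric(1))
    cost_rat <- NULL
    m_rat <- NULL
  }
  dimnames(flow) <- list(mu_a$vertex, mu_b$vertex)
  structure(list(from = mu_a$vertex, to = mu_b$vertex, flow = flow,
                 cost = cost, cost_rat = cost_rat,
                 m = stats::setNames(m, paste0("m", 0:3)), m_rat = m_rat,
                 exact = exact, dist = C),
            class = "transport_plan")
}

#' @export
print.transport_plan <- function(x, ...) {
  cat("transport plan: W1 =",
      if (x$exact) rat_fmt(x$cost_rat) else format(x$cost),
      "\n  m-vector:", paste(format(x$m), collapse = " "), "\n")
  invisible(x)
}

#' Mass-to-hole distance matrix for a hyperedge
#'
#' Convenience wrapper assembling the pairwise directed distances between the
#' support of the in-measure and the support of the out-measure of a
#' hyperedge, as needed by [wasserstein1()].
#'
#' @param H a `directed_hypergraph`.
#' @param e a hyperedge id.
#' @return integer matrix with the in-support as rows and out-support as
#'   columns.
#' @export
hyper_distances_for <- function(H, e) {
  mu_in <- hyper_in_measure(H, e)
  mu_out <- hyper_out_measure(H, e)
  m <- .hyper_dist_matrix(H, mu_in$vertex, mu_out$vertex)
  if (any(!is.finite(m))) {
    stop("mass/hole pair at distance > 3 for hyperedge '", e,
         "'; hypergraph structure is inconsistent")
  }
  m
}
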