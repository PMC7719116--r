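#' Ollivier-Ricci curvature of an edge or hyperedge
#'
#' O(e) = 1 - W1(mu_a, mu_b), where W1 is the 1-Wasserstein distance between
#' the two probability measures attached to the edge and the curvature always
#' lies in \[-2, 1\].  Equivalently, with m_i the mass moved at distance i in
#' an optimal plan, O(e) = m0 - m2 - 2 m3.
#'
#' For an undirected edge e = (v, w) the measures are the uniform
#' neighbourhood measures of [undirected_measures()] and distances are
#' unrestricted shortest paths in the graph (they may traverse e).  For a
#' directed hyperedge the measures are the splitting-procedure measures of
#' [hyper_in_measure()] / [hyper_out_measure()] and the distance is the
#' directed hyperpath distance of [hyper_distance()].  A directed graph is
#' computed through its hypergraph embedding ([digraph_to_hypergraph()]),
#' which reproduces the directed edge-measure formulation exactly.
#'
#' The value 1 is attained when every mass coincides with a hole of the same
#' size (m0 = 1, e.g. inside directed triangles); the value -2 when every
#' mass must be moved through e itself (m3 = 1, no shortcuts).
#'
#' @param structure an `undirected_graph`, `directed_graph` or
#'   `directed_hypergraph`.
#' @param e an edge `c(v, w)` or a hyperedge id.
#' @return an object of class `ollivier_curvature`: list with components
#'   `value`, `value_rat` (numerator/denominator pair, `NULL` if the float
#'   path was used), `m` (m-vector of the returned optimal plan, which is not
#'   canonical), and `plan` (a `transport_plan`).
#' @examples
#' d <- fixture("directed_path")
#' ollivier(d, c("v", "w"))$value   # -2
#' @export
ollivier <- function(structure, e) {
  UseMethod("ollivier")
}

.ollivier_result <- function(plan) {
  if (plan$exact) {
    value_rat <- rat_sub(c(1, 1), plan$cost_rat)
    value <- rat_num(value_rat)
  } else {
    value_rat <- NULL
    value <- 1 - plan$cost
  }
  structure(list(value = value, value_rat = value_rat, m = plan$m,
                 plan = plan),
            class = "ollivier_curvature")
}

#' @export
ollivier.undirected_graph <- function(structure, e) {
  mm <- undirected_measures(structure, e)
  ig <- .as_igraph(structure)
  d <- igraph::distances(ig, v = mm$mu_v$vertex, to = mm$mu_w$vertex)
  if (any(!is.finite(d))) {
    stop("disconnected supports for edge (", e[1], ", ", e[2], ")")
  }
  .ollivier_result(wasserstein1(mm$mu_v, mm$mu_w, d))
}

#' @export
ollivier.directed_graph <- function(structure, e) {
  i <- .edge_pos(structure, e)
  H <- digraph_to_hypergraph(structure)
  ollivier(H, paste0(structure$edges[i, 1], "->", structure$edges[i, 2]))
}

#' @export
ollivier.directed_hypergraph <- function(structure, e) {
  mu_in <- hyper_in_measure(structure, e)
  mu_out <- hyper_out_measure(structure, e)
  d <- .hyper_dist_matrix(structure, mu_in$vertex, mu_out$vertex)
  if (any(!is.finite(d))) {
    stop("mass/hole pair at distance > 3 for hyperedge '", e,
         "'; hypergraph structure is inconsistent")
  }
  .ollivier_result(wasserstein1(mu_in, mu_out, d))
}

#' @export
print.ollivier_curvature <- function(x, ...) {
  cat("Ollivier-Ricci curvature:",
      if (!is.null(x$value_rat)) rat_fmt(x$value_rat) else format(x$value),
      "\n  m-vector:", paste(format(x$m), collapse = " "),
      "(one optimal plan; not canonical)\n")
  invisible(x)
}
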