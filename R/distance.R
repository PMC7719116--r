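# Directed hypergraph distances.  One step moves from any tail vertex of a
# hyperedge to any of its head vertices.  Between a mass and a hole of the
# same hyperedge the distance is at most 3 (the route through the focal
# hyperedge itself), so the search is truncated at depth 3.

# distances from u to every vertex, truncated at depth `max_depth`
.hyper_bfs <- function(H, u, max_depth = 3L) {
  dist <- stats::setNames(rep(Inf, length(H$vertices)), H$vertices)
  dist[u] <- 0L
  frontier <- u
  d <- 0L
  while (length(frontier) > 0 && d < max_depth) {
    d <- d + 1L
    nxt <- character(0)
    for (v in frontier) {
      for (id in H$out_index[[v]]) {
        nxt <- c(nxt, H$head[[.he_pos(H, id)]])
      }
    }
    nxt <- unique(nxt)
    nxt <- nxt[!is.finite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Directed distance between two vertices of a hypergraph
#'
#' The minimal number of directed hyperedges that must be traversed to get
#' from `u` to `v`, where traversing a hyperedge moves from any of its tail
#' vertices to any of its head vertices.  Between a mass and a hole of the
#' same hyperedge this distance is at most 3, attained when the only route is
#' through the focal hyperedge; the search is therefore truncated at depth 3
#' and a pair further apart raises an error.
#'
#' @param H a `directed_hypergraph`.
#' @param u,v vertex labels.
#' @return integer in 0:3; 0 if and only if `u == v`.
#' @export
hyper_distance <- function(H, u, v) {
  stopifnot(inherits(H, "directed_hypergraph"))
  .check_vertex(H, u)
  .check_vertex(H, v)
  d <- .hyper_bfs(H, u)[v]
  if (!is.finite(d)) {
    stop("no directed hyperpath of length <= 3 from '", u, "' to '", v, "'")
  }
  as.integer(d)
}

# pairwise distance matrix between two vertex sets (rows: from, cols: to)
.hyper_dist_matrix <- function(H, from, to) {
  m <- matrix(Inf, length(from), length(to), dimnames = list(from, to))
  for (i in seq_along(from)) m[i, ] <- .hyper_bfs(H, from[i])[to]
  m
}
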