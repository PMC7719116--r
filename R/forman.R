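#' Forman-Ricci curvature of an undirected edge
#'
#' The degree of an edge e is the number of its neighbours, i.e. of edges
#' sharing a vertex with e (e itself is not its own neighbour); the
#' Forman-Ricci curvature is F(e) = 2 - deg(e).  Equivalently, with
#' deg_v(e) the number of edges other than e incident to endpoint v,
#' F(e) = 2 - deg_v(e) - deg_w(e).  Very negative values mark edges whose
#' two endpoints are both highly connected.
#'
#' @param G an `undirected_graph`.
#' @param e an edge, given as a character vector `c(v, w)`.
#' @return integer curvature value.
#' @examples
#' g <- undirected_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d")))
#' forman_undirected(g, c("b", "c"))  # interior path edge: 0
#' @export
forman_undirected <- function(G, e) {
  stopifnot(inherits(G, "undirected_graph"))
  i <- .edge_pos(G, e)
  v <- G$edges[i, 1]; w <- G$edges[i, 2]
  deg_v <- nrow(edges_at(G, v)) - 1L  # exclude e itself
  deg_w <- nrow(edges_at(G, w)) - 1L
  as.integer(2L - deg_v - deg_w)
}

#' Forman-Ricci curvature of a directed edge
#'
#' For a directed edge e = (v, w) with tail v and head w, the inputs of e are
#' the edges with head v and the outputs are the edges with tail w;
#' F(e) = 2 - deg_in(e) - deg_out(e).  The reverse edge (w, v), when present,
#' counts as an input: the definition is purely incidence-based.
#'
#' @param D a `directed_graph`.
#' @param e an edge `c(tail, head)`.
#' @return integer curvature value.
#' @export
forman_directed <- function(D, e) {
  stopifnot(inherits(D, "directed_graph"))
  i <- .edge_pos(D, e)
  v <- D$edges[i, 1]; w <- D$edges[i, 2]
  deg_in <- sum(D$edges[, 2] == v)   # e has head w != v, so e never counts
  deg_out <- sum(D$edges[, 1] == w)
  as.integer(2L - deg_in - deg_out)
}

# in/out hyperedge degree of a hyperedge, with multiplicity: a hyperedge
# incoming at k tail vertices of e counts k times
.hyper_degrees <- function(H, i) {
  id <- H$ids[i]
  deg_in <- 0L
  for (v in H$tail[[i]]) {
    deg_in <- deg_in + length(in_hyperedges_at(H, v, exclude = id))
  }
  deg_out <- 0L
  for (v in H$head[[i]]) {
    deg_out <- deg_out + length(out_hyperedges_at(H, v, exclude = id))
  }
  c(deg_in, deg_out)
}

#' Forman-Ricci curvature of a directed hyperedge
#'
#' For a hyperedge e = (e1, e2), F(e) = |e1| + |e2| - deg_in(e) - deg_out(e),
#' where deg_in(e) counts, over the tail vertices of e, the hyperedges coming
#' in at each of them, and deg_out(e) counts, over the head vertices, the
#' hyperedges going out.  A hyperedge touching several tail vertices of e is
#' counted once per vertex (multiplicity counting); e itself is excluded.
#' A catalyst vertex (in both tail and head) contributes to both sides.
#'
#' @param H a `directed_hypergraph`.
#' @param e a hyperedge id.
#' @return integer curvature value.
#' @export
forman_hypergraph <- function(H, e) {
  stopifnot(inherits(H, "directed_hypergraph"))
  i <- .he_pos(H, e)
  d <- .hyper_degrees(H, i)
  as.integer(length(H$tail[[i]]) + length(H$head[[i]]) - d[1] - d[2])
}

#' Degree difference of an edge or hyperedge
#'
#' For an undirected edge e = (v, w) this is |deg_v(e) - deg_w(e)|, the
#' absolute difference of the two endpoint edge-degrees (e excluded from
#' both counts): a local indicator of (dis)assortativity.  For a directed
#' edge or hyperedge it is the signed difference deg_out(e) - deg_in(e),
#' with the same incidence counting as the directed Forman curvature:
#' positive for productive edges (more output than input), negative for
#' receptive ones.
#'
#' @param structure an `undirected_graph`, `directed_graph` or
#'   `directed_hypergraph`.
#' @param e an edge `c(v, w)` or a hyperedge id.
#' @return integer; non-negative in the undirected case, signed otherwise.
#' @export
degree_difference <- function(structure, e) {
  UseMethod("degree_difference")
}

#' @export
degree_difference.undirected_graph <- function(structure, e) {
  i <- .edge_pos(structure, e)
  v <- structure$edges[i, 1]; w <- structure$edges[i, 2]
  deg_v <- nrow(edges_at(structure, v)) - 1L
  deg_w <- nrow(edges_at(structure, w)) - 1L
  as.integer(abs(deg_v - deg_w))
}

#' @export
degree_difference.directed_graph <- function(structure, e) {
  i <- .edge_pos(structure, e)
  v <- structure$edges[i, 1]; w <- structure$edges[i, 2]
  deg_in <- sum(structure$edges[, 2] == v)
  deg_out <- sum(structure$edges[, 1] == w)
  as.integer(deg_out - deg_in)
}

#' @export
degree_difference.directed_hypergraph <- function(structure, e) {
  i <- .he_pos(structure, e)
  d <- .hyper_degrees(structure, i)
  as.integer(d[2] - d[1])
}
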