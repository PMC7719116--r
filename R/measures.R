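#' Construct a vertex measure
#'
#' A probability distribution over vertices with exact rational weights
#' `num/den`, the object an edge's Ollivier-Ricci curvature transports
#' between.  Weights must be positive and sum to exactly 1.
#'
#' @param vertex character vector of support vertices.
#' @param num,den parallel numerator/denominator vectors (integers).
#' @param side label recording which side of the edge the measure describes.
#' @return an object of class `vertex_measure`.
#' @examples
#' vertex_measure(c("a", "b"), c(1, 1), c(2, 2))
#' @export
vertex_measure <- function(vertex, num, den, side = "undirected") {
  o <- order(vertex)
  m <- structure(list(vertex = vertex[o], num = num[o], den = den[o],
                      side = side),
                 class = "vertex_measure")
  s <- rat_vsum(m$num, m$den)
  if (!rat_eq(s, c(1, 1))) {
    stop("measure weights must sum to exactly 1 (got ", rat_fmt(s), ")")
  }
  if (any(m$num <= 0)) stop("measure weights must be positive")
  m
}

#' @export
print.vertex_measure <- function(x, ...) {
  cat("vertex measure (", x$side, "):\n", sep = "")
  for (i in seq_along(x$vertex)) {
    cat("  ", x$vertex[i], ": ", rat_fmt(c(x$num[i], x$den[i])), "\n", sep = "")
  }
  invisible(x)
}

#' Numeric weights of a vertex measure
#'
#' @param m a `vertex_measure`.
#' @return named numeric vector of weights (exact rationals converted to
#'   double), named by vertex.
#' @export
measure_weights <- function(m) {
  stopifnot(inherits(m, "vertex_measure"))
  stats::setNames(m$num / m$den, m$vertex)
}

# accumulate weight num/den onto vertex v in environment acc
.acc_add <- function(acc, v, num, den) {
  cur <- acc[[v]]
  if (is.null(cur)) acc[[v]] <- rat(num, den)
  else acc[[v]] <- rat_add(cur, rat(num, den))
  invisible(NULL)
}

.acc_measure <- function(acc, side) {
  vs <- ls(acc)
  num <- vapply(vs, function(v) acc[[v]][1], numeric(1))
  den <- vapply(vs, function(v) acc[[v]][2], numeric(1))
  vertex_measure(vs, unname(num), unname(den), side = side)
}

#' Neighbourhood measures of an undirected edge
#'
#' For e = (v, w), each edge incident to v receives weight 1/|E_v|, where
#' E_v is the set of edges at v (including e itself); mapping each incident
#' edge to its far endpoint makes this the uniform measure on the neighbour
#' set of v, which includes w.  The pair (mu_v, mu_w) is what the
#' 1-Wasserstein distance in the Ollivier-Ricci curvature compares.
#'
#' @param G an `undirected_graph`.
#' @param e an edge `c(v, w)`.
#' @return list with components `mu_v` and `mu_w`, both `vertex_measure`s.
#' @export
undirected_measures <- function(G, e) {
  stopifnot(inherits(G, "undirected_graph"))
  i <- .edge_pos(G, e)
  v <- G$edges[i, 1]; w <- G$edges[i, 2]
  one_side <- function(a) {
    inc <- edges_at(G, a)
    far <- ifelse(inc[, 1] == a, inc[, 2], inc[, 1])
    vertex_measure(far, rep(1, length(far)), rep(length(far), length(far)),
                   side = paste0("undirected-", a))
  }
  list(mu_v = one_side(v), mu_w = one_side(w))
}

# shared engine for the in/out measure of a hyperedge: the splitting
# procedure.  own = tail (in) or head (out) vertex set of the focal e;
# step1(v) = hyperedges incoming (resp. outgoing) at v, excluding e;
# step2(f) = tail (resp. head) vertex set of hyperedge f.
.split_measure <- function(own, step1, step2, side) {
  eta <- length(own)
  acc <- new.env(parent = emptyenv())
  free <- character(0)  # sources resp. sinks: keep their share in place
  for (v in own) {
    nb <- step1(v)
    if (length(nb) == 0) {
      .acc_add(acc, v, 1, eta)
      free <- c(free, v)
    } else {
      k <- length(nb)
      for (f in nb) {
        share <- step2(f)
        if (length(share) == 0) {
          # a neighbouring hyperedge with an empty far side cannot receive
          # mass; its share stays on v itself
          .acc_add(acc, v, 1, eta * k)
        } else {
          for (u in share) .acc_add(acc, u, 1, eta * k * length(share))
        }
      }
    }
  }
  m <- .acc_measure(acc, side)
  attr(m, "free") <- sort(free)
  m
}

#' In- and out-measures of a directed hyperedge
#'
#' The total measure 1 is split evenly among the eta_in tail vertices of the
#' focal hyperedge e.  A source (a tail vertex with no incoming hyperedges,
#' e excluded) keeps its share 1/eta_in on itself.  At any other tail vertex
#' the share is divided evenly among the hyperedges coming in there, and each
#' such hyperedge's portion is divided evenly among its tail vertices; shares
#' landing on the same vertex accumulate.  All arithmetic is exact rational.
#' `hyper_out_measure` is the mirror image: sinks, outgoing hyperedges at
#' head vertices, portions divided among their head vertices (the holes).
#'
#' The attribute `"free"` of the result lists the sources (resp. sinks),
#' which retain their share in place; see [mass_set()] for the mass/hole sets,
#' which by definition exclude them.
#'
#' @param H a `directed_hypergraph`.
#' @param e a hyperedge id.
#' @return a `vertex_measure`.
#' @examples
#' h <- fixture("fig3")
#' hyper_in_measure(h, "e")   # src: 1/2, tm: 1/2
#' hyper_out_measure(h, "e")  # snk: 1/2, tm: 1/4, tr1: 1/8, tr2: 1/8
#' @export
hyper_in_measure <- function(H, e) {
  stopifnot(inherits(H, "directed_hypergraph"))
  i <- .he_pos(H, e)
  if (length(H$tail[[i]]) == 0) {
    stop("head-only hyperedge '", H$ids[i], "': in-measure undefined")
  }
  .split_measure(H$tail[[i]],
                 function(v) in_hyperedges_at(H, v, exclude = H$ids[i]),
                 function(f) H$tail[[.he_pos(H, f)]],
                 side = "in")
}

#' @rdname hyper_in_measure
#' @export
hyper_out_measure <- function(H, e) {
  stopifnot(inherits(H, "directed_hypergraph"))
  i <- .he_pos(H, e)
  if (length(H$head[[i]]) == 0) {
    stop("tail-only hyperedge '", H$ids[i], "': out-measure undefined")
  }
  .split_measure(H$head[[i]],
                 function(v) out_hyperedges_at(H, v, exclude = H$ids[i]),
                 function(f) H$head[[.he_pos(H, f)]],
                 side = "out")
}

#' Mass and hole sets of a hyperedge
#'
#' The mass set M of a hyperedge e is the union of the tails of the
#' hyperedges that come in at a tail vertex of e (e itself excluded); its
#' members are the precursors of e's inputs.  The hole set H is the union of
#' the heads of the hyperedges going out at a head vertex of e: the derived
#' vertices.  Sources and sinks retain measure but are, by definition, not
#' members of these sets; they are reported by the `"free"` attribute of
#' [hyper_in_measure()] / [hyper_out_measure()].
#'
#' @param H a `directed_hypergraph`.
#' @param e a hyperedge id.
#' @return character vector of vertices.
#' @export
mass_set <- function(H, e) {
  stopifnot(inherits(H, "directed_hypergraph"))
  i <- .he_pos(H, e)
  res <- character(0)
  for (v in H$tail[[i]]) {
    for (f in in_hyperedges_at(H, v, exclude = H$ids[i])) {
      res <- c(res, H$tail[[.he_pos(H, f)]])
    }
  }
  sort(unique(res))
}

#' @rdname mass_set
#' @export
hole_set <- function(H, e) {
  stopifnot(inherits(H, "directed_hypergraph"))
  i <- .he_pos(H, e)
  res <- character(0)
  for (v in H$head[[i]]) {
    for (f in out_hyperedges_at(H, v, exclude = H$ids[i])) {
      res <- c(res, H$head[[.he_pos(H, f)]])
    }
  }
  sort(unique(res))
}
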