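#' Construct an undirected graph
#'
#' A simple undirected, unweighted graph: a finite set of vertex labels and a
#' set of unordered vertex pairs.  Vertex labels are opaque strings compared by
#' exact equality.  Self-loops and duplicate edges are rejected.
#'
#' @param edges two-column character matrix (or data frame), one edge per row.
#' @param vertices optional character vector of vertex labels; endpoints of
#'   `edges` are added automatically, so this is only needed to declare
#'   isolated vertices.
#' @return an object of class `undirected_graph` with components `vertices`
#'   (character) and `edges` (two-column character matrix).
#' @examples
#' g <- undirected_graph(rbind(c("a", "b"), c("b", "c")))
#' edges_at(g, "b")
#' @export
undirected_graph <- function(edges = NULL, vertices = NULL) {
  edges <- .as_edge_matrix(edges)
  if (any(edges[, 1] == edges[, 2])) {
    bad <- edges[edges[, 1] == edges[, 2], 1][1]
    stop("self-loop at vertex '", bad, "' not allowed in a simple graph")
  }
  # canonical order within each pair so (a,b) and (b,a) are the same edge
  swap <- edges[, 1] > edges[, 2]
  edges[swap, ] <- edges[swap, 2:1, drop = FALSE]
  key <- paste(edges[, 1], edges[, 2], sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate undirected edge: ",
         sub("\r", " -- ", key[duplicated(key)][1]))
  }
  vertices <- sort(unique(c(as.character(vertices), as.vector(edges))))
  structure(list(vertices = vertices, edges = edges),
            class = "undirected_graph")
}

#' Construct a directed graph
#'
#' A simple directed, unweighted graph: ordered vertex pairs (tail, head).
#' The pairs (a,b) and (b,a) are distinct edges and may coexist; self-loops
#' and repeated ordered pairs are rejected.
#'
#' @param edges two-column character matrix (or data frame); column 1 is the
#'   tail, column 2 the head of each edge.
#' @param vertices optional character vector of extra (isolated) vertices.
#' @return an object of class `directed_graph`.
#' @examples
#' d <- directed_graph(rbind(c("u", "v"), c("v", "w"), c("w", "z")))
#' @export
directed_graph <- function(edges = NULL, vertices = NULL) {
  edges <- .as_edge_matrix(edges)
  if (any(edges[, 1] == edges[, 2])) {
    bad <- edges[edges[, 1] == edges[, 2], 1][1]
    stop("self-loop at vertex '", bad, "' not allowed")
  }
  key <- paste(edges[, 1], edges[, 2], sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate directed edge: ",
         sub("\r", " -> ", key[duplicated(key)][1]))
  }
  vertices <- sort(unique(c(as.character(vertices), as.vector(edges))))
  structure(list(vertices = vertices, edges = edges),
            class = "directed_graph")
}

.as_edge_matrix <- function(edges) {
  if (is.null(edges)) return(matrix(character(0), ncol = 2))
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.character(edges) && is.null(dim(edges)) && length(edges) == 2) {
    edges <- matrix(edges, ncol = 2)
  }
  if (!is.matrix(edges) || ncol(edges) != 2) {
    stop("edges must be a two-column matrix or data frame")
  }
  storage.mode(edges) <- "character"
  dimnames(edges) <- NULL
  edges
}

#' Construct a directed hypergraph
#'
#' A directed hypergraph is a vertex set together with hyperedges, each an
#' ordered pair of vertex subsets: a tail (inputs, e.g. the reactants of a
#' chemical reaction) and a head (outputs, the products).  Tail and head may
#' overlap (catalysts); at most one of them may be empty.  Hyperedges with
#' identical tail and head are permitted provided their ids differ
#' (parallel hyperedges).
#'
#' @param hyperedges a list; each element is a list with components `id`
#'   (label), `tail` and `head` (character vectors of vertex labels).
#' @param vertices optional character vector of extra (isolated) vertices.
#' @return an object of class `directed_hypergraph` with components
#'   `vertices`, `ids`, `tail` (list), `head` (list) and per-vertex incidence
#'   indices.
#' @examples
#' h <- directed_hypergraph(list(
#'   list(id = "r1", tail = c("a", "b"), head = "c"),
#'   list(id = "r2", tail = "c", head = c("d", "e"))
#' ))
#' @export
directed_hypergraph <- function(hyperedges = list(), vertices = NULL) {
  ids <- vapply(hyperedges, function(e) as.character(e$id), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate hyperedge id: ", ids[duplicated(ids)][1])
  }
  tails <- lapply(hyperedges, function(e) {
    t <- unique(as.character(e$tail))
    t[nzchar(t)]
  })
  heads <- lapply(hyperedges, function(e) {
    h <- unique(as.character(e$head))
    h[nzchar(h)]
  })
  for (i in seq_along(ids)) {
    if (length(tails[[i]]) == 0 && length(heads[[i]]) == 0) {
      stop("hyperedge '", ids[i], "': tail and head must not both be empty")
    }
  }
  vertices <- sort(unique(c(as.character(vertices),
                            unlist(tails), unlist(heads))))
  h <- structure(list(vertices = vertices, ids = ids,
                      tail = tails, head = heads),
                 class = "directed_hypergraph")
  h$in_index <- .build_index(vertices, heads, ids)   # v -> ids with v in head
  h$out_index <- .build_index(vertices, tails, ids)  # v -> ids with v in tail
  h
}

.build_index <- function(vertices, memberships, ids) {
  idx <- stats::setNames(vector("list", length(vertices)), vertices)
  for (i in seq_along(ids)) {
    for (v in memberships[[i]]) idx[[v]] <- c(idx[[v]], ids[i])
  }
  idx
}

.check_vertex <- function(x, v) {
  if (length(v) != 1 || !v %in% x$vertices) {
    stop("unknown vertex '", paste(v, collapse = ","), "'")
  }
}

.he_pos <- function(h, id) {
  i <- match(id, h$ids)
  if (is.na(i)) stop("no hyperedge with id '", id, "'")
  i
}

#' Edges incident to a vertex
#'
#' Returns the set of edges of an undirected graph that have `v` as an
#' endpoint.  For an edge e = (v, w) the returned set contains e itself; its
#' cardinality is the vertex degree of `v`.
#'
#' @param graph an `undirected_graph`.
#' @param v a vertex label.
#' @return two-column character matrix of incident edges (zero rows for an
#'   isolated vertex).
#' @export
edges_at <- function(graph, v) {
  stopifnot(inherits(graph, "undirected_graph"))
  .check_vertex(graph, v)
  graph$edges[graph$edges[, 1] == v | graph$edges[, 2] == v, , drop = FALSE]
}

#' Hyperedges coming in at / going out of a vertex
#'
#' `in_hyperedges_at` lists the hyperedges whose head contains `v` (the
#' hyperedges that come in at `v`); `out_hyperedges_at` lists those whose tail
#' contains `v`.  During curvature computation the focal hyperedge is always
#' passed as `exclude`, so that a hyperedge never counts as its own input or
#' output, even when its tail and head overlap.
#'
#' @param H a `directed_hypergraph`.
#' @param v a vertex label.
#' @param exclude optional hyperedge id to omit from the result.
#' @return character vector of hyperedge ids.
#' @export
in_hyperedges_at <- function(H, v, exclude = NULL) {
  stopifnot(inherits(H, "directed_hypergraph"))
  .check_vertex(H, v)
  ids <- H$in_index[[v]]
  if (!is.null(exclude)) ids <- ids[ids != exclude]
  if (is.null(ids)) character(0) else ids
}

#' @rdname in_hyperedges_at
#' @export
out_hyperedges_at <- function(H, v, exclude = NULL) {
  stopifnot(inherits(H, "directed_hypergraph"))
  .check_vertex(H, v)
  ids <- H$out_index[[v]]
  if (!is.null(exclude)) ids <- ids[ids != exclude]
  if (is.null(ids)) character(0) else ids
}

#' Embed a directed graph as a directed hypergraph
#'
#' A directed edge is a directed hyperedge with singleton tail and singleton
#' head.  The embedding is a bijection on edges and preserves the vertex set;
#' all curvature measures computed on the image agree with the directed-graph
#' code paths.  Hyperedge ids are `"tail->head"`.
#'
#' @param D a `directed_graph`.
#' @return a `directed_hypergraph` with one singleton hyperedge per edge.
#' @export
digraph_to_hypergraph <- function(D) {
  stopifnot(inherits(D, "directed_graph"))
  hes <- lapply(seq_len(nrow(D$edges)), function(i) {
    list(id = paste0(D$edges[i, 1], "->", D$edges[i, 2]),
         tail = D$edges[i, 1], head = D$edges[i, 2])
  })
  directed_hypergraph(hes, vertices = D$vertices)
}

# locate an undirected/directed edge given as c(v, w); returns its row index
.edge_pos <- function(x, e) {
  e <- as.character(e)
  if (length(e) != 2) stop("an edge is a pair of vertex labels")
  if (inherits(x, "undirected_graph")) {
    hit <- which((x$edges[, 1] == e[1] & x$edges[, 2] == e[2]) |
                 (x$edges[, 1] == e[2] & x$edges[, 2] == e[1]))
  } else {
    hit <- which(x$edges[, 1] == e[1] & x$edges[, 2] == e[2])
  }
  if (length(hit) == 0) {
    stop("edge (", e[1], ", ", e[2], ") is not in the graph")
  }
  hit[1]
}

#' @export
print.undirected_graph <- function(x, ...) {
  cat("undirected graph:", length(x$vertices), "vertices,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' @export
print.directed_graph <- function(x, ...) {
  cat("directed graph:", length(x$vertices), "vertices,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' @export
print.directed_hypergraph <- function(x, ...) {
  cat("directed hypergraph:", length(x$vertices), "vertices,",
      length(x$ids), "hyperedges\n")
  invisible(x)
}

# igraph view of an undirected graph (isolated vertices kept)
.as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    data.frame(from = g$edges[, 1], to = g$edges[, 2],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = g$vertices, stringsAsFactors = FALSE))
}
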