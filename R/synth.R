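# Seeded synthetic generators and small exact fixtures, so every measure is
# testable without external data.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Seeded random graphs, digraphs and directed hypergraphs
#'
#' Erdos-Renyi graphs and digraphs (each possible edge present independently
#' with probability `p`) and random directed hypergraphs (`m` hyperedges
#' whose tail and head sizes are drawn uniformly from the given ranges, with
#' memberships sampled without replacement).  By default tails and heads are
#' disjoint; set `allow_catalysts = TRUE` to allow overlap.  Identical
#' arguments and seed always yield the identical structure.
#'
#' @param kind one of `"er-graph"`, `"er-digraph"`, `"random-hypergraph"`.
#' @param n vertex count.
#' @param p edge probability (graph kinds).
#' @param m hyperedge count (hypergraph kind).
#' @param tail_size,head_size integer ranges `c(lo, hi)` for tail/head sizes.
#' @param allow_catalysts allow a vertex in both tail and head of the same
#'   hyperedge.
#' @param seed integer seed; the caller's random-number state is preserved.
#' @return an `undirected_graph`, `directed_graph` or `directed_hypergraph`.
#' @examples
#' g <- generate_network("er-graph", n = 8, p = 0.4, seed = 1)
#' h <- generate_network("random-hypergraph", n = 8, m = 5, seed = 2)
#' @export
generate_network <- function(kind = c("er-graph", "er-digraph",
                                      "random-hypergraph"),
                             n, p = 0.3, m = n,
                             tail_size = c(1, 3), head_size = c(1, 3),
                             allow_catalysts = FALSE, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  verts <- paste0("v", seq_len(n))
  .with_seed(seed, {
    switch(kind,
      "er-graph" = {
        pairs <- t(utils::combn(verts, 2))
        keep <- stats::runif(nrow(pairs)) < p
        undirected_graph(pairs[keep, , drop = FALSE], vertices = verts)
      },
      "er-digraph" = {
        pairs <- expand.grid(from = verts, to = verts,
                             stringsAsFactors = FALSE)
        pairs <- as.matrix(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
        keep <- stats::runif(nrow(pairs)) < p
        directed_graph(pairs[keep, , drop = FALSE], vertices = verts)
      },
      "random-hypergraph" = {
        if (!allow_catalysts && tail_size[2] + head_size[2] > n) {
          stop("tail_size and head_size ranges together exceed n; ",
               "disjoint tails and heads are impossible")
        }
        if (allow_catalysts && max(tail_size[2], head_size[2]) > n) {
          stop("tail_size or head_size range exceeds n")
        }
        hes <- lapply(seq_len(m), function(i) {
          ts <- sample(tail_size[1]:tail_size[2], 1)
          hs <- sample(head_size[1]:head_size[2], 1)
          tl <- sample(verts, ts)
          hd <- if (allow_catalysts) {
            sample(verts, hs)
          } else {
            sample(setdiff(verts, tl), hs)
          }
          list(id = paste0("e", i), tail = tl, head = hd)
        })
        directed_hypergraph(hes, vertices = verts)
      })
  })
}

#' Named exact fixtures
#'
#' Small hand-built structures whose curvature values are known in closed
#' form, used throughout the test suite and documentation:
#'
#' * `"fig3"`: a 7-vertex, 4-hyperedge directed hypergraph whose red focal
#'   hyperedge `e = ({src, t2}, {h2, snk})` has in-measure
#'   \{src: 1/2, tm: 1/2\}, out-measure
#'   \{snk: 1/2, tm: 1/4, tr1: 1/8, tr2: 1/8\}, W1 = 5/4 and
#'   Ollivier curvature -1/4.
#' * `"directed_path"`: u -> v -> w -> z; the middle edge attains the lower
#'   bound O = -2.
#' * `"directed_3cycle"`: u -> v -> w -> u; every edge attains the upper
#'   bound O = 1 (mass and hole coincide).
#' * `"isolated_hyperedge"`: the single hyperedge ({a1, a2}, {b1, b2, b3});
#'   O = 0 and F = |e1| + |e2| = 5.
#' * `"fig4_triangle"`, `"fig4_quadrangle"`, `"fig4_pentagon"`: a focal
#'   singleton hyperedge `e = ({v}, {w})` plus one incoming and one outgoing
#'   hyperedge, arranged so the single mass-to-hole distance is 0, 1 or 2,
#'   contributing to m0, m1 or m2 respectively (O = 1, 0, -1).
#'
#' @param name fixture name.
#' @return a `directed_graph` or `directed_hypergraph`.
#' @examples
#' ollivier(fixture("fig3"), "e")$value  # -0.25
#' @export
fixture <- function(name) {
  known <- c("fig3", "directed_path", "directed_3cycle",
             "isolated_hyperedge", "fig4_triangle", "fig4_quadrangle",
             "fig4_pentagon")
  if (!is.character(name) || length(name) != 1 || !name %in% known) {
    stop("unknown fixture; available: ", paste(known, collapse = ", "))
  }
  switch(name,
    fig3 = directed_hypergraph(list(
      list(id = "e", tail = c("src", "t2"), head = c("h2", "snk")),
      list(id = "f", tail = "tm", head = "t2"),
      list(id = "g1", tail = "h2", head = "tm"),
      list(id = "g2", tail = "h2", head = c("tr1", "tr2"))
    )),
    directed_path = directed_graph(rbind(c("u", "v"), c("v", "w"),
                                         c("w", "z"))),
    directed_3cycle = directed_graph(rbind(c("u", "v"), c("v", "w"),
                                           c("w", "u"))),
    isolated_hyperedge = directed_hypergraph(list(
      list(id = "e", tail = c("a1", "a2"), head = c("b1", "b2", "b3"))
    )),
    fig4_triangle = directed_hypergraph(list(
      list(id = "e", tail = "v", head = "w"),
      list(id = "in", tail = "u", head = "v"),
      list(id = "out", tail = "w", head = "u")
    )),
    fig4_quadrangle = directed_hypergraph(list(
      list(id = "e", tail = "v", head = "w"),
      list(id = "in", tail = "u1", head = "v"),
      list(id = "out", tail = "w", head = "u2"),
      list(id = "chord", tail = "u1", head = "u2")
    )),
    fig4_pentagon = directed_hypergraph(list(
      list(id = "e", tail = "v", head = "w"),
      list(id = "in", tail = "u1", head = "v"),
      list(id = "out", tail = "w", head = "u2"),
      list(id = "hop1", tail = "u1", head = "x"),
      list(id = "hop2", tail = "x", head = "u2")
    )))
}
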