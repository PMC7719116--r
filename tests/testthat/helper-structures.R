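# small builders shared across tests

path_graph <- function(labels) {
  n <- length(labels)
  undirected_graph(cbind(labels[-n], labels[-1]))
}

star_graph <- function(center, leaves) {
  undirected_graph(cbind(center, leaves))
}

# native directed Ollivier computation straight from the edge-measure
# formulation, used as an independent check of the hypergraph code path:
# mass 1/n1 at the tail of each incoming edge (or kept at v if v is a
# source), holes 1/n2 at the head of each outgoing edge (or kept at w),
# distance = shortest directed path, W1 by brute-force atom assignment.
directed_ollivier_reference <- function(D, e) {
  v <- e[1]; w <- e[2]
  inc <- D$edges[D$edges[, 2] == v, , drop = FALSE]
  out <- D$edges[D$edges[, 1] == w, , drop = FALSE]
  mu_in <- if (nrow(inc) == 0) {
    stats::setNames(1, v)
  } else {
    tapply(rep(1 / nrow(inc), nrow(inc)), inc[, 1], sum)
  }
  mu_out <- if (nrow(out) == 0) {
    stats::setNames(1, w)
  } else {
    tapply(rep(1 / nrow(out), nrow(out)), out[, 2], sum)
  }
  ig <- igraph::graph_from_data_frame(
    data.frame(from = D$edges[, 1], to = D$edges[, 2]),
    directed = TRUE,
    vertices = data.frame(name = D$vertices))
  dmat <- igraph::distances(ig, v = names(mu_in), to = names(mu_out),
                            mode = "out")
  to_rat <- function(x) {
    den <- round(1 / min(x))
    vertex_measure(names(x), round(as.numeric(x) * den), rep(den, length(x)))
  }
  bf <- brute_force_w1(to_rat(mu_in), to_rat(mu_out), dmat)
  1 - bf$cost
}
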