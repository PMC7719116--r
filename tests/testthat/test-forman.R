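test_that("undirected Forman curvature matches hand counts", {
  expect_identical(forman_undirected(undirected_graph(rbind(c("a", "b"))),
                                     c("a", "b")), 2L)
  p4 <- path_graph(c("a", "b", "c", "d"))
  expect_identical(forman_undirected(p4, c("b", "c")), 0L)
  k14 <- star_graph("c", paste0("l", 1:4))
  expect_identical(forman_undirected(k14, c("c", "l1")), -1L)
  expect_error(forman_undirected(p4, c("a", "d")), "not in the graph")
})

test_that("edge-degree and endpoint-degree forms of Forman agree", {
  for (s in 1:8) {
    g <- generate_network("er-graph", n = 8, p = 0.45, seed = 20 + s)
    ig <- igraph::graph_from_data_frame(
      data.frame(from = g$edges[, 1], to = g$edges[, 2]), directed = FALSE,
      vertices = data.frame(name = g$vertices))
    degs <- igraph::degree(ig)
    for (i in seq_len(nrow(g$edges))) {
      e <- g$edges[i, ]
      expect_identical(forman_undirected(g, e),
                       as.integer(2 - (degs[[e[1]]] - 1) - (degs[[e[2]]] - 1)))
    }
  }
})

test_that("directed Forman curvature counts inputs at tail, outputs at head", {
  expect_identical(forman_directed(directed_graph(rbind(c("a", "b"))),
                                   c("a", "b")), 2L)
  d <- fixture("directed_path")
  expect_identical(forman_directed(d, c("v", "w")), 0L)
  instar <- directed_graph(rbind(c("a", "v"), c("b", "v"), c("c", "v"),
                                 c("v", "w"), c("w", "x"), c("w", "y")))
  expect_identical(forman_directed(instar, c("v", "w")), -3L)
  # the reverse edge counts as an input (pure incidence counting)
  rev2 <- directed_graph(rbind(c("a", "b"), c("b", "a")))
  expect_identical(forman_directed(rev2, c("a", "b")), 2L - 1L - 1L)
})

test_that("hypergraph Forman uses sizes and multiplicity counting", {
  expect_identical(forman_hypergraph(fixture("isolated_hyperedge"), "e"), 5L)
  expect_identical(forman_hypergraph(fixture("fig3"), "e"), 1L)
  # a hyperedge entering two tail vertices of e is counted twice
  h <- directed_hypergraph(list(
    list(id = "e", tail = c("a", "b"), head = "c"),
    list(id = "f", tail = "x", head = c("a", "b"))
  ))
  expect_identical(forman_hypergraph(h, "e"), 3L - 2L - 0L)
})

test_that("each added incoming hyperedge lowers hypergraph Forman by one", {
  for (s in 1:6) {
    h <- generate_network("random-hypergraph", n = 8, m = 4,
                          tail_size = c(1, 3), head_size = c(1, 3),
                          seed = 40 + s)
    f0 <- forman_hypergraph(h, "e1")
    t1 <- h$tail[[1]][1]
    hes <- lapply(seq_along(h$ids), function(i) {
      list(id = h$ids[i], tail = h$tail[[i]], head = h$head[[i]])
    })
    # n = 8 with sides of size <= 3 guarantees an unused vertex
    extra <- setdiff(h$vertices, c(h$tail[[1]], h$head[[1]]))[1]
    hes[[length(hes) + 1]] <- list(id = "plus", tail = extra, head = t1)
    h2 <- directed_hypergraph(hes, vertices = h$vertices)
    expect_identical(forman_hypergraph(h2, "e1"), f0 - 1L)
  }
})

test_that("degree difference is |deg_v - deg_w| undirected, signed directed", {
  p4 <- path_graph(c("a", "b", "c", "d"))
  expect_identical(degree_difference(p4, c("b", "c")), 0L)
  k14 <- star_graph("c", paste0("l", 1:4))
  expect_identical(degree_difference(k14, c("c", "l1")), 3L)
  # undirected: invariant under endpoint order
  expect_identical(degree_difference(k14, c("l1", "c")), 3L)
  instar <- directed_graph(rbind(c("a", "v"), c("b", "v"), c("c", "v"),
                                 c("v", "w"), c("w", "x"), c("w", "y")))
  expect_identical(degree_difference(instar, c("v", "w")), -1L)
  expect_error(degree_difference(p4, c("x", "y")), "not in the graph")
})
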