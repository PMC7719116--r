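test_that("graph constructors enforce simplicity", {
  expect_error(undirected_graph(rbind(c("a", "a"))), "self-loop")
  expect_error(undirected_graph(rbind(c("a", "b"), c("b", "a"))), "duplicate")
  expect_error(directed_graph(rbind(c("a", "a"))), "self-loop")
  expect_error(directed_graph(rbind(c("a", "b"), c("a", "b"))), "duplicate")
  # reverse directed edge is a distinct edge
  d <- directed_graph(rbind(c("a", "b"), c("b", "a")))
  expect_equal(nrow(d$edges), 2L)
})

test_that("hypergraph constructor validates hyperedges", {
  expect_error(directed_hypergraph(list(
    list(id = "e", tail = character(0), head = character(0))
  )), "not both be empty")
  expect_error(directed_hypergraph(list(
    list(id = "e", tail = "a", head = "b"),
    list(id = "e", tail = "c", head = "d")
  )), "duplicate hyperedge id")
  # parallel hyperedges with distinct ids are allowed
  h <- directed_hypergraph(list(
    list(id = "e1", tail = "a", head = "b"),
    list(id = "e2", tail = "a", head = "b")
  ))
  expect_equal(length(h$ids), 2L)
  # catalysts: tail and head may overlap
  h2 <- directed_hypergraph(list(list(id = "r", tail = c("a", "h"),
                                      head = c("b", "h"))))
  expect_setequal(h2$tail[[1]], c("a", "h"))
  expect_setequal(h2$head[[1]], c("b", "h"))
})

test_that("edges_at returns exactly the incident edges", {
  g <- undirected_graph(rbind(c("a", "b"), c("a", "c"), c("b", "c")),
                        vertices = "iso")
  expect_equal(nrow(edges_at(g, "iso")), 0L)
  ea <- edges_at(g, "a")
  expect_equal(nrow(ea), 2L)
  expect_setequal(as.vector(ea), c("a", "b", "a", "c"))
  p4 <- path_graph(c("a", "b", "c", "d"))
  eb <- edges_at(p4, "b")
  expect_setequal(paste(eb[, 1], eb[, 2]), c("a b", "b c"))
  expect_error(edges_at(g, "nope"), "unknown vertex 'nope'")
})

test_that("edges_at over all vertices counts every edge twice", {
  for (s in 1:5) {
    g <- generate_network("er-graph", n = 8, p = 0.4, seed = s)
    total <- sum(vapply(g$vertices, function(v) nrow(edges_at(g, v)),
                        numeric(1)))
    expect_identical(total, 2 * nrow(g$edges))
  }
})

test_that("incoming/outgoing hyperedge queries honour exclusion", {
  h <- fixture("fig3")
  expect_identical(in_hyperedges_at(h, "t2", exclude = "e"), "f")
  expect_identical(in_hyperedges_at(h, "src", exclude = "e"), character(0))
  expect_setequal(out_hyperedges_at(h, "h2", exclude = "e"), c("g1", "g2"))
  # without exclusion the focal hyperedge itself appears
  expect_identical(out_hyperedges_at(h, "src"), "e")
  expect_identical(out_hyperedges_at(h, "src", exclude = "e"), character(0))
  expect_error(in_hyperedges_at(h, "ghost"), "unknown vertex")
  # a hyperedge with a catalyst is excluded from its own inputs
  hc <- directed_hypergraph(list(list(id = "r", tail = "c", head = "c"),
                                 list(id = "s", tail = "x", head = "c")))
  expect_identical(in_hyperedges_at(hc, "c", exclude = "r"), "s")
})

test_that("digraph embedding preserves edges and vertices", {
  expect_equal(length(digraph_to_hypergraph(directed_graph())$ids), 0L)
  d <- fixture("directed_path")
  h <- digraph_to_hypergraph(d)
  expect_equal(length(h$ids), 3L)
  expect_true(all(lengths(h$tail) == 1L), all(lengths(h$head) == 1L))
  expect_identical(h$vertices, d$vertices)
})

test_that("all curvatures agree between digraphs and their hypergraph image", {
  for (s in 1:12) {
    d <- generate_network("er-digraph", n = sample(4:8, 1), p = 0.35,
                          seed = 100 + s)
    if (nrow(d$edges) == 0) next
    h <- digraph_to_hypergraph(d)
    for (i in seq_len(nrow(d$edges))) {
      e <- d$edges[i, ]
      id <- paste0(e[1], "->", e[2])
      expect_identical(forman_directed(d, e), forman_hypergraph(h, id))
      expect_identical(degree_difference(d, e), degree_difference(h, id))
      o1 <- ollivier(d, e)
      o2 <- ollivier(h, id)
      expect_identical(o1$value_rat, o2$value_rat)
    }
  }
})
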