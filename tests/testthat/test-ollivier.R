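weights_of <- function(m) measure_weights(m)

test_that("undirected neighbourhood measures are uniform on neighbours", {
  iso <- undirected_graph(rbind(c("v", "w")))
  mm <- undirected_measures(iso, c("v", "w"))
  expect_equal(weights_of(mm$mu_v), c(w = 1))
  expect_equal(weights_of(mm$mu_w), c(v = 1))
  k3 <- undirected_graph(rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_equal(weights_of(undirected_measures(k3, c("a", "b"))$mu_v),
               c(b = 0.5, c = 0.5))
  p4 <- path_graph(c("a", "b", "c", "d"))
  expect_equal(weights_of(undirected_measures(p4, c("b", "c"))$mu_v),
               c(a = 0.5, c = 0.5))
})

test_that("hyperedge measures follow the even-splitting procedure", {
  h <- fixture("fig3")
  mi <- hyper_in_measure(h, "e")
  expect_identical(mi$vertex, c("src", "tm"))
  expect_identical(mi$num, c(1, 1))
  expect_identical(mi$den, c(2, 2))
  expect_identical(attr(mi, "free"), "src")  # the source keeps its share
  mo <- hyper_out_measure(h, "e")
  expect_identical(mo$vertex, c("snk", "tm", "tr1", "tr2"))
  expect_identical(mo$num, c(1, 1, 1, 1))
  expect_identical(mo$den, c(2, 4, 8, 8))
  expect_identical(attr(mo, "free"), "snk")
  # isolated hyperedge: every tail vertex is a source
  iso <- fixture("isolated_hyperedge")
  expect_equal(weights_of(hyper_in_measure(iso, "e")), c(a1 = 0.5, a2 = 0.5))
  expect_error(hyper_in_measure(directed_hypergraph(list(
    list(id = "x", tail = character(0), head = "a")
  )), "x"), "in-measure undefined")
})

test_that("mass and hole sets exclude sources and sinks", {
  h <- fixture("fig3")
  expect_identical(mass_set(h, "e"), "tm")
  expect_setequal(hole_set(h, "e"), c("tm", "tr1", "tr2"))
  iso <- fixture("isolated_hyperedge")
  expect_identical(mass_set(iso, "e"), character(0))
})

test_that("hypergraph distance is the directed hyperpath length, at most 3", {
  h <- fixture("fig3")
  expect_identical(hyper_distance(h, "tm", "tm"), 0L)
  expect_identical(hyper_distance(h, "src", "snk"), 1L)
  expect_identical(hyper_distance(h, "tm", "tr1"), 3L)
  expect_identical(hyper_distance(h, "src", "tm"), 2L)
  expect_error(hyper_distance(h, "snk", "src"), "no directed hyperpath")
})

test_that("wasserstein1 solves small transport problems exactly", {
  m <- vertex_measure(c("a", "b"), c(1, 1), c(2, 2))
  d0 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- wasserstein1(m, m, d0)
  expect_identical(p$cost, 0)
  expect_identical(unname(p$m), c(1, 0, 0, 0))
  pu <- vertex_measure("u", 1, 1)
  pv <- vertex_measure("v", 1, 1)
  d3 <- matrix(3, 1, 1, dimnames = list("u", "v"))
  p2 <- wasserstein1(pu, pv, d3)
  expect_identical(p2$cost, 3)
  expect_identical(unname(p2$m), c(0, 0, 0, 1))
  h <- fixture("fig3")
  p3 <- wasserstein1(hyper_in_measure(h, "e"), hyper_out_measure(h, "e"),
                     hyper_distances_for(h, "e"))
  expect_identical(p3$cost_rat, c(5, 4))
})

test_that("Ollivier values and m-vector identities hold on random structures", {
  n_checked <- 0
  for (s in 1:10) {
    h <- generate_network("random-hypergraph", n = sample(4:8, 1),
                          m = sample(2:6, 1), tail_size = c(1, 2),
                          head_size = c(1, 2), seed = 300 + s)
    for (id in h$ids) {
      o <- ollivier(h, id)
      p <- o$plan
      expect_true(p$exact)
      # value = 1 - W1 = m0 - m2 - 2 m3, exactly (in units of 1/D)
      expect_identical(o$value_rat,
                       hypercurv:::rat_sub(hypercurv:::rat_sub(p$m_rat[, 1], p$m_rat[, 3]),
                               hypercurv:::rat_add(p$m_rat[, 4], p$m_rat[, 4])))
      expect_true(o$value >= -2 && o$value <= 1)
      # m-vector is a partition of the unit mass
      expect_identical(hypercurv:::rat_vsum(p$m_rat[1, ], p$m_rat[2, ]), c(1, 1))
      # marginals of the plan reproduce the measures
      mu_in <- hyper_in_measure(h, id)
      mu_out <- hyper_out_measure(h, id)
      expect_equal(unname(rowSums(p$flow)), mu_in$num / mu_in$den)
      expect_equal(unname(colSums(p$flow)), mu_out$num / mu_out$den)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 20)
})

test_that("directed Ollivier matches an independent edge-measure computation", {
  for (s in 1:8) {
    d <- generate_network("er-digraph", n = sample(4:7, 1), p = 0.35,
                          seed = 500 + s)
    if (nrow(d$edges) == 0) next
    for (i in seq_len(nrow(d$edges))) {
      e <- d$edges[i, ]
      expect_equal(ollivier(d, e)$value, directed_ollivier_reference(d, e))
    }
  }
})

test_that("undirected Ollivier is constant on vertex-transitive graphs", {
  cyc <- undirected_graph(cbind(paste0("c", 1:6),
                                paste0("c", c(2:6, 1))))
  vals <- apply(cyc$edges, 1, function(e) ollivier(cyc, e)$value)
  expect_equal(length(unique(vals)), 1L)
  k4 <- undirected_graph(t(utils::combn(paste0("k", 1:4), 2)))
  vals4 <- apply(k4$edges, 1, function(e) ollivier(k4, e)$value)
  expect_equal(length(unique(vals4)), 1L)
  k3 <- undirected_graph(rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_identical(ollivier(k3, c("a", "b"))$value_rat, c(1, 2))
})

test_that("source and sink fallbacks keep the measure in place", {
  # e = u -> v with nothing upstream and one edge downstream
  d <- directed_graph(rbind(c("u", "v"), c("v", "w")))
  o <- ollivier(d, c("u", "v"))
  # single mass retained at u, single hole at w, distance 2 through e
  expect_identical(o$value_rat, c(-1, 1))
})
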