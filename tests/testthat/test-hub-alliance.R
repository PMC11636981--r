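wmat <- function(edges, nodes) {
  # edges: data.frame(from, to, w)
  m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    m[edges$from[i], edges$to[i]] <- edges$w[i]
    m[edges$to[i], edges$from[i]] <- edges$w[i]
  }
  diag(m) <- 1
  m
}

test_that("network thresholding filters edges and prunes low-degree nodes", {
  nodes <- letters[1:4]
  # all weights below threshold: empty graph with a warning
  low <- wmat(data.frame(from = "a", to = "b", w = 0.01), nodes)
  expect_warning(g0 <- threshold_network(low), "empty")
  expect_equal(igraph::vcount(g0), 0)
  # a bare triangle dies under the strict iterative degree filter
  tri <- wmat(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
                         w = 0.9), nodes[1:3])
  expect_warning(gt <- threshold_network(tri), "empty")
  expect_equal(igraph::vcount(gt), 0)
  # K4 survives (all degrees 3 > 2)
  k4 <- matrix(0.9, 4, 4, dimnames = list(nodes, nodes)); diag(k4) <- 1
  g4 <- threshold_network(k4)
  expect_equal(igraph::vcount(g4), 4)
  expect_equal(igraph::ecount(g4), 6)
  # raising min_weight never increases the edge count
  res <- default_run()
  counts <- sapply(c(0.02, 0.05, 0.1, 0.2), function(w) {
    igraph::ecount(suppressWarnings(
      threshold_network(res$tom, min_weight = w)))
  })
  expect_true(all(diff(counts) <= 0))
  # provenance is recorded
  expect_equal(res$graph$weight_source, "tom")
  expect_equal(res$graph$min_weight, 0.05)
})

test_that("top-k filter drops edges outside both endpoints' strongest k", {
  # a-b and c-d are each endpoint's strongest edge; a-c is in neither
  # endpoint's top-1 and is dropped, while a star keeps all edges because
  # every leaf retains its only edge
  nodes <- letters[1:4]
  ed <- data.frame(from = c("a", "c", "a"), to = c("b", "d", "c"),
                   w = c(0.9, 0.9, 0.5))
  g <- suppressWarnings(threshold_network(wmat(ed, nodes), min_weight = 0.05,
                                          min_degree = 0, top_k = 1))
  expect_equal(igraph::ecount(g), 2)
  expect_false(igraph::are_adjacent(g, "a", "c"))

  star <- data.frame(from = "h", to = letters[1:5],
                     w = c(0.9, 0.8, 0.3, 0.2, 0.1))
  gs <- suppressWarnings(threshold_network(wmat(star, c("h", letters[1:5])),
                                           min_weight = 0.05,
                                           min_degree = 0, top_k = 2))
  expect_equal(igraph::ecount(gs), 5)
})

test_that("MCC matches exhaustive enumeration and the known closed forms", {
  # triangle: one maximal 3-clique, every node scores (3-1)! = 2
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  expect_equal(unname(mcc_scores(tri)), rep(2, 3))
  # star: edgeless neighborhood at the center gives MCC = degree
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("c", "l1", "l2", "l3")
  sc <- mcc_scores(star)
  expect_equal(unname(sc["c"]), 3)
  expect_equal(unname(sc[c("l1", "l2", "l3")]), rep(1, 3))
  # isolated node scores zero
  iso <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(iso)$name <- c("x", "y")
  expect_equal(unname(mcc_scores(iso)), c(0, 0))
  # exhaustive oracle on seeded random graphs
  for (seed in 1:20) {
    rg <- random_graph(n = sample(5:12, 1), p = runif(1, 0.2, 0.7),
                       seed = seed)
    expect_equal(mcc_scores(rg$graph), mcc_oracle(rg$adj))
  }
})

test_that("hub ranking is deterministic with documented tie-breaks", {
  # two disjoint triangles: all MCC equal, ties resolved lexicographically
  g <- igraph::graph_from_literal(a - b, b - c, c - a, d - e, e - f, f - d)
  hubs <- rank_hubs(g, top_n = 6)
  expect_equal(hubs$gene, sort(igraph::V(g)$name))
  expect_equal(hubs$mcc, rep(2, 6))
  expect_warning(rank_hubs(g, top_n = 10), "top_n")
  # a dense clique member outranks sparse nodes
  res <- default_run()
  hubs2 <- rank_hubs(res$graph, top_n = 5)
  expect_true(all(diff(hubs2$mcc) <= 0))
})

test_that("first neighbors are the union of direct neighbors minus the seeds", {
  g <- igraph::graph_from_literal(a - b, b - c)
  expect_equal(first_neighbors(g, "b"), c("a", "c"))
  expect_warning(nb <- first_neighbors(g, c("b", "zz")), "absent")
  expect_equal(nb, c("a", "c"))
  expect_warning(nb0 <- first_neighbors(g, "zz"), "absent")
  expect_equal(nb0, character())
})

test_that("planted pathway neighborhoods are recovered and disjoint", {
  res <- default_run()
  for (s in names(res$neighbors)) {
    truth <- res$truth$true_neighbors[[s]]
    found <- res$neighbors[[s]]
    recall <- length(intersect(found, truth)) / length(truth)
    precision <- length(intersect(found, truth)) / length(found)
    expect_gte(recall, 0.9)
    expect_gte(precision, 0.9)
  }
  expect_lte(length(intersect(res$neighbors$CBB, res$neighbors$rTCA)), 1)
})

test_that("alliance matrices enumerate intersections exactly", {
  sets <- list(A = c("a", "b"), B = c("b", "c"), C = "c")
  al <- alliance_matrix(sets)
  expect_equal(dim(al$membership), c(3L, 3L))
  expect_equal(al$shared["A", "B"], 1L)
  expect_equal(al$shared["A", "C"], 0L)
  expect_equal(al$jaccard["A", "B"], 1 / 3)
  expect_equal(al$jaccard["B", "C"], 1 / 2)
  # exclusive patterns: a in A only, b in A&B, c in B&C
  pat <- setNames(al$intersections$count, al$intersections$sets)
  expect_equal(unname(pat["A"]), 1L)
  expect_equal(unname(pat["A&B"]), 1L)
  expect_equal(unname(pat["B&C"]), 1L)
  # disjoint and identical set limits
  d <- alliance_matrix(list(X = "p", Y = "q"))
  expect_equal(d$shared["X", "Y"], 0L)
  expect_equal(d$jaccard["X", "Y"], 0)
  i <- alliance_matrix(list(X = c("p", "q"), Y = c("p", "q")))
  expect_equal(i$jaccard["X", "Y"], 1)
  # permutation invariance to gene ordering
  al2 <- alliance_matrix(lapply(sets, rev))
  expect_equal(al2$shared, al$shared)
  expect_equal(al2$intersections, al$intersections)
  # category map: unknown genes counted, shared counts per category
  cm <- data.frame(gene = c("a", "b", "zz"),
                   category = c("sulfur", "sulfur", "unknown"))
  al3 <- alliance_matrix(sets, cm)
  expect_equal(al3$n_unknown_category_genes, 1L)
  expect_equal(al3$category_counts["sulfur", "A"], 2L)
  expect_equal(al3$category_counts["sulfur", "B"], 1L)
})
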