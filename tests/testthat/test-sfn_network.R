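test_that("contingency matrix counts isoforms per (TU, FL) cell", {
  ds <- build_catalogue(organism_dataset(
    paste0("p", 1:5), c("t1", "t1", "t1", "t2", "t2"),
    list("A", "A", "B", "C", "C"), "o"), "x")
  cm <- build_contingency(ds)
  dense <- as_contingency_matrix(cm)
  fl_a <- ds$proteins$fl_id[1L]; fl_b <- ds$proteins$fl_id[3L]
  expect_equal(dense["t1", fl_a], 2L)
  expect_equal(dense["t1", fl_b], 1L)
  # monoform TU with several SVs: one cell holding the SV count
  expect_equal(sum(dense["t2", ] > 0), 1L)
  expect_equal(max(dense["t2", ]), 2L)
  # row sums count annotated proteins
  expect_equal(unname(rowSums(dense)), c(3, 2))
  empty <- build_contingency(build_catalogue(
    organism_dataset(character(0), character(0), list(), "e"), "x"))
  expect_equal(nrow(empty$cells), 0L)
})

test_that("SFN edges accumulate one unit per polyform TU sharing an FL pair", {
  two <- build_catalogue(organism_dataset(
    paste0("p", 1:4), c("t1", "t1", "t2", "t2"),
    list("A", "B", "A", "B"), "o"), "x")
  g <- build_sfn(two)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 2L)

  tri <- build_catalogue(organism_dataset(
    paste0("p", 1:3), rep("t1", 3), list("A", "B", "C"), "o"), "x")
  gt <- build_sfn(tri)
  expect_equal(igraph::ecount(gt), 3L)
  expect_equal(igraph::E(gt)$weight, rep(1L, 3))

  mono <- build_catalogue(organism_dataset(
    paste0("p", 1:2), c("t1", "t2"), list("A", "B"), "o"), "x")
  expect_equal(igraph::ecount(build_sfn(mono)), 0L)
  # isolated FLs appear only on request
  expect_equal(igraph::vcount(build_sfn(mono)), 0L)
  expect_equal(igraph::vcount(build_sfn(mono, include_isolated = TRUE)), 2L)
})

test_that("network statistics match hand-computed degree summaries", {
  tri <- igraph::make_ring(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  st <- network_stats(tri)
  expect_equal(st$n_nodes, 3L); expect_equal(st$n_edges, 3L)
  expect_equal(st$avg_neighbors, 2)
  expect_equal(st$heterogeneity, 0)

  star <- igraph::make_star(4, mode = "undirected")
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
  sst <- network_stats(star)
  expect_equal(sst$avg_neighbors, 1.5)
  expect_equal(sst$heterogeneity, sqrt(0.75) / 1.5)

  two_edges <- igraph::make_graph(c("a", "b", "c", "d"), directed = FALSE)
  cst <- network_stats(two_edges)
  expect_equal(cst$n_components, 2L)
  expect_equal(cst$component_sizes, c(2L, 2L))
  expect_error(network_stats(igraph::make_empty_graph(0)), "empty")
})

test_that("hub ranking uses distinct-neighbor degree with id tie-breaks", {
  star <- igraph::make_star(4, mode = "undirected")
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
  hubs <- rank_hubs(star, 2L)
  expect_equal(hubs$fl_id[1L], "hub")
  expect_equal(hubs$degree[1L], 3L)
  expect_equal(hubs$fl_id[2L], "l1")  # tie among leaves -> lexicographic
  tri <- igraph::make_ring(3); igraph::V(tri)$name <- c("x", "y", "z")
  expect_equal(nrow(rank_hubs(tri, 5L)), 3L)
})

test_that("edge weights equal brute-force enumeration on random small datasets", {
  set.seed(2026)
  for (i in 1:20) {
    ds <- random_small_dataset(sample(2:6, 1L))
    g <- build_sfn(ds)
    expect_equal(sfn_edge_weights(g), sfn_oracle_weights(ds))
    # total edge weight identity: sum over polyform TUs of C(|fls|, 2)
    nfl <- lengths(ds$tus$fls[ds$tus$class == "polyform"])
    expect_equal(sum(unlist(sfn_edge_weights(g))), sum(choose(nfl, 2)))
    # nodes are FLs of polyform TUs only
    poly_fls <- unique(unlist(ds$tus$fls[ds$tus$class == "polyform"]))
    expect_true(all(igraph::V(g)$name %in% poly_fls))
  }
})

test_that("edge set is invariant to TU and protein input order", {
  set.seed(31)
  ds <- random_small_dataset(6L)
  p <- ds$proteins
  perm <- sample(nrow(p))
  ds2 <- build_catalogue(organism_dataset(
    p$protein_id[perm], p$tu_id[perm], p$keywords[perm], "rand"), "r")
  expect_equal(sfn_edge_weights(build_sfn(ds2)),
               sfn_edge_weights(build_sfn(ds)))
})
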