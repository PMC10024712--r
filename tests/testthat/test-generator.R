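test_that("built-in motif templates have the documented shape", {
  house <- make_motif("house")
  expect_length(house$node_ids, 5)
  expect_identical(nrow(house$edge_set), 6L)
  tri <- make_motif("triangle")
  expect_length(tri$node_ids, 3)
  expect_identical(nrow(tri$edge_set), 3L)
  expect_identical(make_motif(tri), tri)   # custom template passthrough
  expect_error(make_motif("pentagon"), "unknown motif shape")
})

test_that("grow_subgraph honors size and edge-count accounting", {
  house <- make_motif("house")
  set.seed(1)
  # n_s equal to the motif size: Poisson(0) == 0, bare motif back
  bare <- grow_subgraph(house, 5)
  expect_identical(bare$num_nodes, 5L)
  expect_identical(nrow(bare$edges), 6L)

  # with m = 1, every grown node adds exactly one undirected edge
  for (i in 1:20) {
    sg <- grow_subgraph(house, 11, m = 1)
    expect_identical(nrow(sg$edges), 6L + (sg$num_nodes - 5L))
  }

  # expected size: mean node count over many draws approximately n_s
  sizes <- replicate(300, grow_subgraph(house, 11, m = 1)$num_nodes)
  expect_lt(abs(mean(sizes) - 11), 3 * sqrt(6) / sqrt(300))

  # every grown node has a motif node in its 1-hop neighborhood
  sg <- grow_subgraph(house, 14, m = 2)
  for (v in setdiff(seq_len(sg$num_nodes), 1:5)) {
    nb <- c(sg$edges[sg$edges[, 1] == v, 2], sg$edges[sg$edges[, 2] == v, 1])
    expect_true(any(nb %in% 1:5))
  }
})

test_that("wiring grants second motifs pairwise and respects the cap", {
  set.seed(5)
  subs <- replicate(2, grow_subgraph(make_motif("house"), 8), simplify = FALSE)
  g <- connect_subgraphs(subs, p = 1, K = 2)
  counts <- vapply(seq_len(g$num_nodes), function(v) motif_count(g, v),
                   integer(1))
  expect_identical(sum(counts == 2L), 2L)  # one granted node per side
  expect_true(all(counts >= 1L & counts <= 2L))

  # p = 0: no inter-subgraph edges, every label 0
  set.seed(6)
  subs <- replicate(3, grow_subgraph(make_motif("house"), 8), simplify = FALSE)
  g0 <- connect_subgraphs(subs, p = 0, K = 2)
  expect_true(all(assign_labels(g0, 2) == 0L))
})

test_that("labels equal motif count minus one, clipped to the class range", {
  hw <- house_with_tail()
  # node 7 has no motif in its closed neighborhood: the contract is violated
  expect_error(assign_labels(hw, 2), "at least one motif")

  ds <- small_dataset(seed = 4, n_sub = 20)
  g <- ds$graph
  K <- ds$config$num_classes
  for (v in seq_len(g$num_nodes)) {
    expected <- min(brute_motif_count(g, v) - 1L, K - 1L)
    expect_identical(g$labels[v], expected)
  }
})

test_that("generation is deterministic given the seed", {
  a <- generate_dataset(shapeggen_config(num_subgraphs = 15, seed = 11))
  b <- generate_dataset(shapeggen_config(num_subgraphs = 15, seed = 11))
  expect_identical(a$graph, b$graph)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$split, b$split)
  c <- generate_dataset(shapeggen_config(num_subgraphs = 15, seed = 12))
  expect_false(identical(a$graph$edges, c$graph$edges))
})

test_that("presets carry the reference parameter values", {
  base <- shapeggen_preset("SG-Base")
  expect_identical(base$motif_shape, "house")
  expect_identical(base$num_subgraphs, 1200L)
  expect_equal(base$connection_prob, 0.006)
  expect_identical(base$subgraph_size, 11L)
  expect_identical(base$num_classes, 2L)
  expect_identical(base$num_features, 11L)
  expect_identical(base$num_informative, 4L)
  expect_equal(base$class_sep, 0.6)
  expect_identical(base$clusters_per_class, 2L)
  expect_equal(base$protected_noise, 0.5)
  expect_equal(base$homophily, 1)
  expect_identical(base$gnn_layers, 3L)

  expect_equal(shapeggen_preset("SG-Unfair")$protected_noise, 0.75)
  expect_equal(shapeggen_preset("SG-Heterophilic")$homophily, -1)
  more <- shapeggen_preset("SG-MoreInform")
  expect_identical(c(more$num_informative, more$num_features), c(8L, 11L))
  less <- shapeggen_preset("SG-LessInform")
  expect_identical(c(less$num_informative, less$num_features), c(4L, 21L))
  small <- shapeggen_preset("SG-SmallEx")
  expect_identical(small$motif_shape, "triangle")
  expect_identical(length(small$motif$node_ids), 3L)
  expect_identical(small$num_subgraphs, 1300L)
  expect_identical(small$subgraph_size, 12L)
  expect_equal(small$class_sep, 0.5)
  expect_error(shapeggen_preset("SG-Nope"), "SG-Base")
})

test_that("ba_shapes builds houses on a preferential-attachment base", {
  ds <- ba_shapes(30, num_houses = 4, perturb_edges = 3, seed = 2)
  g <- ds$graph
  expect_identical(g$num_nodes, 30L + 20L)
  for (m in g$motifs) expect_true(all(g$labels[m$node_ids] == 1L))
  expect_identical(sum(g$labels == 1L), 20L)

  ds0 <- ba_shapes(20, num_houses = 0, seed = 3)
  expect_true(all(ds0$graph$labels == 0L))
  # masks of a motif-free graph are all zero
  expect_true(all(vapply(ds0$ground_truth, function(gt)
    all(gt$masks[[1]]$node_scores == 0), logical(1))))
})

test_that("stratified split matches the requested fractions", {
  labels <- rep(c(0L, 1L), c(4382, 8768))
  sp <- split_dataset(labels, c(0.7, 0.05, 0.25), seed = 1)
  expect_equal(sum(sp == "test"), round(0.25 * 4382) + round(0.25 * 8768),
               tolerance = 2)
  expect_equal(as.vector(table(sp[labels == 1])) / 8768,
               c(0.7, 0.05, 0.25), tolerance = 0.001)
  expect_identical(split_dataset(labels, c(0.7, 0.05, 0.25), seed = 1), sp)
  expect_true(all(split_dataset(labels, c(1, 0, 0), seed = 1) == "train"))
  expect_error(split_dataset(c(0L, 0L, 1L), c(0.7, 0.05, 0.25), seed = 1),
               "fewer members")
})
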