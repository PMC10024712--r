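test_that("predictor configuration rejects degenerate settings", {
  expect_error(predictor_config(epochs = 0), "epochs")
  expect_error(predictor_config(layers = 0), "layers")
})

test_that("softmax outputs are normalized on every node", {
  pred <- tiny_predictor()
  ds <- small_dataset(seed = 3, n_sub = 40, p = 0.05, class_sep = 3)
  for (v in sample(ds$graph$num_nodes, 10)) {
    sg <- enclosing_subgraph(ds$graph, v, 3)
    p <- predict_node(pred, sg)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
    expect_length(embed_node(pred, sg), pred$hidden_dim)
  }
})

test_that("training is reproducible and learns a separable task", {
  # strongly separated features, sparse wiring: high absolute accuracy
  ds <- generate_dataset(shapeggen_config(num_subgraphs = 50,
                                          class_sep = 5, seed = 31))
  cfg <- predictor_config(epochs = 300, seed = 7)
  p1 <- train_gnn(ds, cfg)
  p2 <- train_gnn(ds, cfg)
  expect_identical(p1$params, p2$params)

  acc_on <- function(ds, p) {
    test_rows <- which(ds$split == "test")
    mean(vapply(test_rows, function(v) {
      sg <- enclosing_subgraph(ds$graph, v, ds$config$gnn_layers)
      predict_node(p, sg, type = "class")
    }, integer(1)) == ds$graph$labels[test_rows])
  }
  expect_gte(acc_on(ds, p1), 0.9)

  # denser wiring gives a balanced task: accuracy must beat the
  # majority-class baseline computed from the generated labels
  ds2 <- generate_dataset(shapeggen_config(num_subgraphs = 50,
                                           connection_prob = 0.05,
                                           class_sep = 5, seed = 31))
  p3 <- train_gnn(ds2, predictor_config(epochs = 400, seed = 7))
  test_rows <- which(ds2$split == "test")
  majority <- max(table(ds2$graph$labels[test_rows])) / length(test_rows)
  expect_gt(acc_on(ds2, p3), majority)
})

test_that("analytic input gradients match finite differences", {
  pred <- tiny_predictor()
  ds <- small_dataset(seed = 3, n_sub = 40, p = 0.05, class_sep = 3)
  sg <- enclosing_subgraph(ds$graph, which(ds$split == "test")[1], 2)
  for (cls in 1:2) {
    g_an <- graphxgen:::input_gradient(pred, sg, cls)
    g_fd <- graphxgen:::numeric_input_gradient(pred, sg, cls)
    denom <- max(abs(g_fd), 1e-8)
    expect_lt(max(abs(g_an - g_fd)) / denom, 1e-4)
  }
})

test_that("gradient explainer concentrates on what drives the logit", {
  # single-feature linear predictor: saliency lives on that feature
  pred <- tiny_predictor()
  params <- pred$params
  eye <- function(m) {
    m[] <- 0
    k <- min(dim(m))
    m[cbind(seq_len(k), seq_len(k))] <- 1
    m
  }
  for (l in seq_along(params$layers)) {
    params$layers[[l]]$w1 <- eye(params$layers[[l]]$w1)
    params$layers[[l]]$w2 <- eye(params$layers[[l]]$w2)
    params$layers[[l]]$b1[] <- 0
    params$layers[[l]]$b2[] <- 0
    params$layers[[l]]$eps <- 0
  }
  params$w_out[] <- 0
  params$w_out[1, 1] <- 1   # class-1 logit reads hidden unit 1 = feature 1
  params$b_out[] <- c(1, 0) # make class 1 the argmax
  lin <- pred
  lin$params <- params
  ds <- small_dataset(seed = 3, n_sub = 40, p = 0.05, class_sep = 3)
  sg <- enclosing_subgraph(ds$graph, 3, 2)
  sg$features <- abs(sg$features) + 1   # keep every ReLU active
  m <- gradient_explainer(lin, sg)
  expect_gt(m$feature_scores[1], 0)
  expect_true(all(m$feature_scores[-1] == 0))

  # constant predictor: all-zero saliency
  const <- pred
  for (l in seq_along(const$params$layers)) {
    const$params$layers[[l]]$w1[] <- 0
    const$params$layers[[l]]$w2[] <- 0
  }
  const$params$w_out[] <- 0
  mc <- gradient_explainer(const, sg)
  expect_true(all(mc$node_scores == 0))
})

test_that("random explainer draws the documented distributions", {
  ds <- small_dataset(seed = 3, n_sub = 40, p = 0.05, class_sep = 3)
  sg <- enclosing_subgraph(ds$graph, 8, 3)
  set.seed(1)
  m1 <- random_explainer(sg)
  expect_length(m1$node_scores, length(sg$node_ids))
  expect_length(m1$feature_scores, ncol(sg$features))
  expect_length(m1$edge_scores, nrow(sg$edges))
  set.seed(2)
  m2 <- random_explainer(sg)
  expect_false(identical(m1$node_scores, m2$node_scores))

  # scores are exchangeable across node positions: relabeling the subgraph
  # leaves the score distribution unchanged
  set.seed(3)
  a <- replicate(300, random_explainer(sg)$node_scores[1])
  b <- replicate(300, random_explainer(sg)$node_scores[length(sg$node_ids)])
  expect_gt(suppressWarnings(ks.test(a, b))$p.value, 0.01)
})

test_that("predictor serialization round-trips predictions", {
  pred <- tiny_predictor()
  path <- withr::local_tempfile(fileext = ".json")
  save_predictor(pred, path)
  back <- load_predictor(path)
  ds <- small_dataset(seed = 3, n_sub = 40, p = 0.05, class_sep = 3)
  sg <- enclosing_subgraph(ds$graph, 11, 3)
  expect_equal(predict_node(back, sg), predict_node(pred, sg),
               tolerance = 1e-12)
  expect_identical(back$arch, pred$arch)
})

test_that("gcn-like aggregation trains and predicts too", {
  ds <- generate_dataset(shapeggen_config(num_subgraphs = 40,
                                          connection_prob = 0.05,
                                          class_sep = 3, seed = 33))
  p <- train_gnn(ds, predictor_config(arch = "gcn_like", epochs = 60,
                                      seed = 2))
  sg <- enclosing_subgraph(ds$graph, 4, 3)
  expect_equal(sum(predict_node(p, sg)), 1, tolerance = 1e-6)
})
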