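test_that("top-k binarization keeps the highest scores, ties to low index", {
  expect_identical(binarize_topk(c(0.9, 0.5, 0.1, 0.2), 0.25),
                   c(1L, 0L, 0L, 0L))
  expect_identical(binarize_topk(rep(0.5, 4), 0.5), c(1L, 1L, 0L, 0L))
  expect_identical(binarize_topk(c(0.1, 0.3), 1), c(1L, 1L))
  expect_identical(sum(binarize_topk(runif(43), 0.25)), 11L)  # ceil(0.25*43)
  expect_error(binarize_topk(numeric(0), 0.5), "nonempty")
})

test_that("jaccard equals exhaustive confusion counts on all 4-bit masks", {
  grid <- as.matrix(expand.grid(rep(list(0:1), 4)))
  for (i in seq_len(16)) for (j in seq_len(16)) {
    gt <- grid[i, ]; pr <- grid[j, ]
    tp <- 0; fp <- 0; fn <- 0
    for (b in 1:4) {
      if (gt[b] == 1 && pr[b] == 1) tp <- tp + 1
      if (gt[b] == 0 && pr[b] == 1) fp <- fp + 1
      if (gt[b] == 1 && pr[b] == 0) fn <- fn + 1
    }
    oracle <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
    expect_identical(jaccard(gt, pr), oracle)
  }
  expect_identical(jaccard(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_error(jaccard(c(1, 0), c(1, 0, 0)), "lengths differ")
})

test_that("explanation accuracy takes the best ground-truth match", {
  nodes <- 1:4
  gts <- ground_truth_set(
    list(explanation_mask(c(1, 1, 0, 0), kind = "ground_truth"),
         explanation_mask(c(0, 0, 1, 1), kind = "ground_truth")),
    nodes, matrix(integer(0), ncol = 2))
  pred <- explanation_mask(node_scores = c(0.9, 0.8, 0.1, 0.2))
  # top-50% keeps nodes 1,2: J = 1 against the first mask, 0 against second
  expect_identical(gea(gts, pred, "node", 0.5), 1)
  # |zeta| = 1 reduces to plain jaccard after binarization
  one <- ground_truth_set(list(gts$masks[[2]]), nodes,
                          matrix(integer(0), ncol = 2))
  expect_identical(gea(one, pred, "node", 0.5),
                   jaccard(c(0, 0, 1, 1), binarize_topk(pred$node_scores, 0.5)))
  # prediction equal to a member, binarized at its own support size,
  # scores exactly 1; at k = 1 everything is kept and the score drops
  exact <- explanation_mask(node_scores = c(0, 0, 1, 1))
  expect_identical(gea(gts, exact, "node", 0.5), 1)
  expect_identical(gea(gts, exact, "node", 1), 0.5)
})

test_that("unfaithfulness is 0 for identity masks and ~0.5 for ln(2) KL", {
  pred <- tiny_predictor()
  ds <- small_dataset(seed = 3, n_sub = 40, p = 0.05, class_sep = 3)
  v <- which(ds$split == "test")[1]
  sg <- enclosing_subgraph(ds$graph, v, 3)
  idm <- explanation_mask(rep(1, length(sg$node_ids)),
                          rep(1, ncol(sg$features)),
                          rep(1, nrow(sg$edges)))
  for (ch in c("node", "feature", "edge")) {
    val <- gef(pred, sg, idm, ch, metric_config(k_fraction = 1))
    expect_lt(abs(val), 1e-6)
  }
  # point mass against uniform: KL = ln 2, GEF = 1 - exp(-ln 2) = 1/2
  kl <- graphxgen:::kl_divergence(c(1, 0), c(0.5, 0.5), 1e-12)
  expect_equal(1 - exp(-kl), 0.5, tolerance = 1e-9)
  # any finite KL keeps GEF strictly below 1
  rnd <- explanation_mask(runif(length(sg$node_ids)))
  g <- gef(pred, sg, rnd, "node", metric_config())
  expect_true(g >= 0 && g < 1)
})

test_that("perturbation ball respects the behavior tolerance", {
  pred <- tiny_predictor()
  ds <- small_dataset(seed = 3, n_sub = 40, p = 0.05, class_sep = 3)
  sg <- enclosing_subgraph(ds$graph, which(ds$split == "test")[2], 3)

  # no noise at all: every copy is identical and accepted
  cfg0 <- metric_config(stability_samples = 5, feature_noise_scale = 0,
                        edge_perturb_prob = 0, delta = 0)
  ball <- perturb_neighborhood(sg, cfg0, pred)
  expect_length(ball, 5)
  expect_identical(ball[[1]]$features, sg$features)

  set.seed(1)
  cfg_inf <- metric_config(stability_samples = 8, feature_noise_scale = 0.05,
                           delta = Inf)
  expect_length(perturb_neighborhood(sg, cfg_inf, pred), 8)

  set.seed(1)
  cfg_zero <- metric_config(stability_samples = 8, feature_noise_scale = 0.05,
                            delta = 0)
  expect_length(perturb_neighborhood(sg, cfg_zero, pred), 0)
})

test_that("instability is zero for a constant explainer", {
  pred <- tiny_predictor()
  ds <- small_dataset(seed = 3, n_sub = 40, p = 0.05, class_sep = 3)
  sg <- enclosing_subgraph(ds$graph, which(ds$split == "test")[3], 3)
  const <- function(p, s) explanation_mask(rep(1, length(s$node_ids)),
                                           rep(1, ncol(s$features)),
                                           rep(1, nrow(s$edges)))
  set.seed(2)
  expect_identical(ges(const, pred, sg, "node",
                       metric_config(stability_samples = 5, delta = Inf)), 0)
  # hand-computed cosine distances
  expect_equal(graphxgen:::cosine_distance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2))
  expect_identical(graphxgen:::cosine_distance(c(1, 0), c(0, 1)), 1)
})

test_that("counterfactual mismatch is scale-invariant cosine distance", {
  m1 <- explanation_mask(node_scores = c(2, 0))
  m2 <- explanation_mask(node_scores = c(1, 0))
  expect_equal(gecf(m1, m2, "node"), 0, tolerance = 1e-12)
  m3 <- explanation_mask(node_scores = c(0, 1))
  expect_identical(gecf(m1, m3, "node"), 1)
  expect_identical(gecf(m1, m1, "node"), 0)
  expect_message(
    expect_identical(gecf(m1, explanation_mask(node_scores = c(0, 0)),
                          "node"), 1),
    "zero-norm")
})

test_that("counterfactual subgraph flips only the protected column", {
  ds <- small_dataset(seed = 3, n_sub = 40, p = 0.05, class_sep = 3)
  sg <- enclosing_subgraph(ds$graph, 5, 2)
  p <- ds$graph$protected_idx
  cf <- counterfactual_subgraph(sg, p)
  expect_identical(cf$features[, p], 1 - sg$features[, p])
  expect_identical(cf$features[, -p], sg$features[, -p])
  expect_identical(cf$edges, sg$edges)
})

test_that("statistical parity and group-fairness mismatch", {
  expect_identical(statistical_parity(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_identical(statistical_parity(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0)
  # rates 0.75 vs 0.25 over 4 + 4 nodes
  expect_identical(
    statistical_parity(c(1, 1, 1, 0, 1, 0, 0, 0), rep(c(1, 0), each = 4)),
    0.5)
  expect_error(statistical_parity(c(1, 0), c(1, 1)), "nonempty")

  preds <- c(1, 1, 0, 0, 1, 0)
  prot <- c(1, 1, 1, 0, 0, 0)
  expect_identical(gegf(preds, preds, prot), 0)
  # SP 0.5 vs 0.2 -> 0.3 (hand-built vectors)
  a <- c(rep(1, 5), rep(0, 5), rep(1, 0), rep(0, 10))   # SP = 0.5
  pr <- rep(c(1, 0), each = 10)
  b <- c(rep(1, 5), rep(0, 5), rep(1, 3), rep(0, 7))    # SP = 0.2
  expect_equal(gegf(a, b, pr), 0.3, tolerance = 1e-12)
})
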