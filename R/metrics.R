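# Evaluation metrics for predicted explanations: accuracy against the
# ground-truth masks (best-of-set Jaccard at top-k), unfaithfulness
# (1 - exp(-KL) between predictions on the full and the masked subgraph),
# instability under small perturbations, counterfactual-fairness mismatch,
# and group-fairness mismatch of masked predictions.

#' Metric configuration
#'
#' @param k_fraction top-k fraction used to binarize soft masks (default
#'   0.25, i.e. the top quarter of nodes/features/edges).
#' @param stability_samples number of perturbed copies drawn for the
#'   stability metric.
#' @param feature_noise_scale Gaussian feature noise, as a multiple of each
#'   column's standard deviation.
#' @param edge_perturb_prob per-edge rewiring probability.
#' @param delta model-behavior tolerance of the stability ball; `NULL`
#'   calibrates it as the 95th percentile of the observed behavior
#'   distances of the drawn sample.
#' @param norm_order p of the norm used for the behavior-distance check.
#' @param behavior_source `"logits"` or `"embeddings"`.
#' @param kl_epsilon floor applied to predicted probabilities before the
#'   KL divergence (guards point-mass predictions).
#' @return an object of class `metric_config`.
#' @export
metric_config <- function(k_fraction = 0.25,
                          stability_samples = 25L,
                          feature_noise_scale = 0.01,
                          edge_perturb_prob = 0.001,
                          delta = NULL,
                          norm_order = 2,
                          behavior_source = c("logits", "embeddings"),
                          kl_epsilon = 1e-12) {
  if (k_fraction <= 0 || k_fraction > 1) stop("k_fraction must be in (0, 1]")
  if (kl_epsilon <= 0) stop("kl_epsilon must be > 0")
  structure(list(k_fraction = k_fraction,
                 stability_samples = as.integer(stability_samples),
                 feature_noise_scale = feature_noise_scale,
                 edge_perturb_prob = edge_perturb_prob,
                 delta = delta,
                 norm_order = norm_order,
                 behavior_source = match.arg(behavior_source),
                 kl_epsilon = kl_epsilon),
            class = "metric_config")
}

#' Binarize scores at a top-k fraction
#'
#' Keeps the `ceiling(k_fraction * length(scores))` highest scores as 1 and
#' sets the rest to 0. Ties are broken deterministically in favor of the
#' lowest index.
#'
#' @param scores nonempty numeric vector.
#' @param k_fraction fraction in (0, 1] to keep.
#' @return binary integer vector of the same length.
#' @export
binarize_topk <- function(scores, k_fraction) {
  n <- length(scores)
  if (n == 0L) stop("scores must be nonempty")
  if (k_fraction <= 0 || k_fraction > 1) stop("k_fraction must be in (0, 1]")
  k <- ceiling(k_fraction * n)
  out <- integer(n)
  out[order(-scores, seq_len(n))[seq_len(k)]] <- 1L
  out
}

#' Jaccard index between binary masks
#'
#' `TP / (TP + FP + FN)`. Two all-zero masks agree vacuously and score 1.
#'
#' @param gt,pred binary vectors of equal length.
#' @return value in [0, 1].
#' @export
jaccard <- function(gt, pred) {
  if (length(gt) != length(pred)) stop("mask lengths differ")
  tp <- sum(gt == 1 & pred == 1)
  fp <- sum(gt == 0 & pred == 1)
  fn <- sum(gt == 1 & pred == 0)
  if (tp + fp + fn == 0L) return(1)
  tp / (tp + fp + fn)
}

mask_channel <- function(mask, channel) {
  switch(channel,
         node = mask$node_scores,
         feature = mask$feature_scores,
         edge = mask$edge_scores,
         stop("unknown channel '", channel, "'"))
}

#' Graph explanation accuracy
#'
#' Binarizes the predicted scores of the requested channel at top-k and
#' returns the maximum Jaccard index over all equally valid ground-truth
#' masks.
#'
#' @param gts a [ground_truth_set()].
#' @param pred a predicted [explanation_mask()].
#' @param channel `"node"`, `"feature"` or `"edge"`.
#' @param k_fraction top-k fraction.
#' @return accuracy in [0, 1]; higher is better.
#' @export
gea <- function(gts, pred, channel = c("node", "feature", "edge"),
                k_fraction = 0.25) {
  channel <- match.arg(channel)
  if (length(gts$masks) == 0L) stop("empty ground-truth set")
  scores <- mask_channel(pred, channel)
  if (length(scores) == 0L) stop("predicted mask has no ", channel, " scores")
  bin <- binarize_topk(scores, k_fraction)
  max(vapply(gts$masks, function(m)
    jaccard(mask_channel(m, channel), bin), numeric(1L)))
}

kl_divergence <- function(p, q, eps) {
  p <- pmax(p, eps); p <- p / sum(p)
  q <- pmax(q, eps); q <- q / sum(q)
  sum(p * log(p / q))
}

#' Graph explanation unfaithfulness
#'
#' Masks the enclosing subgraph with the explanation's top-k entries of the
#' requested channel, re-predicts the center node, and returns
#' `1 - exp(-KL(f(S) || f(S')))`. Zero means the masked subgraph preserves
#' the prediction exactly; higher values mean a less faithful explanation.
#'
#' @param predictor a trained predictor (see [train_gnn()]).
#' @param subgraph an [enclosing_subgraph()].
#' @param pred a predicted [explanation_mask()].
#' @param channel channel to mask.
#' @param config a [metric_config()].
#' @return unfaithfulness in [0, 1).
#' @export
gef <- function(predictor, subgraph, pred,
                channel = c("node", "feature", "edge"),
                config = metric_config()) {
  channel <- match.arg(channel)
  p_full <- predict_node(predictor, subgraph)
  masked <- apply_mask(subgraph, pred, channel, config$k_fraction)
  p_mask <- predict_node(predictor, masked)
  if (!all(is.finite(p_full)) || !all(is.finite(p_mask)))
    stop("predictor returned non-finite probabilities")
  1 - exp(-kl_divergence(p_full, p_mask, config$kl_epsilon))
}

#' Sample behavior-preserving perturbations of a subgraph
#'
#' Draws `stability_samples` copies, each with zero-mean Gaussian noise on
#' the node features (scaled per column by `feature_noise_scale` times the
#' column standard deviation) and independent rewiring of each undirected
#' edge with probability `edge_perturb_prob` (the edge is deleted, or an
#' absent intra-subgraph edge is added instead). When a predictor is given,
#' only copies whose behavior distance
#' `||L(S) - L(S')||_p` stays within `delta` are returned.
#'
#' @param subgraph an [enclosing_subgraph()].
#' @param config a [metric_config()].
#' @param predictor optional predictor used for the behavior check.
#' @return list of perturbed subgraphs (possibly empty).
#' @export
perturb_neighborhood <- function(subgraph, config = metric_config(),
                                 predictor = NULL) {
  if (config$stability_samples < 1L) stop("stability_samples must be >= 1")
  col_sd <- apply(subgraph$features, 2L, stats::sd)
  col_sd[!is.finite(col_sd)] <- 0
  n <- length(subgraph$node_ids)
  draws <- lapply(seq_len(config$stability_samples), function(s) {
    out <- subgraph
    if (config$feature_noise_scale > 0) {
      noise <- matrix(stats::rnorm(n * ncol(out$features)), n) *
        rep(config$feature_noise_scale * col_sd, each = n)
      out$features <- out$features + noise
    }
    if (config$edge_perturb_prob > 0 && nrow(out$edges) > 0L) {
      touch <- stats::runif(nrow(out$edges)) < config$edge_perturb_prob
      if (any(touch)) {
        add <- stats::runif(sum(touch)) < 0.5
        keep <- out$edges[!touch, , drop = FALSE]
        for (a in which(touch)[add]) {
          # rewire: the touched edge is replaced by an absent pair
          cand <- absent_edge(out)
          if (!is.null(cand)) keep <- rbind(keep, cand)
        }
        out$edges <- keep[order(keep[, 1L], keep[, 2L]), , drop = FALSE]
      }
    }
    out
  })
  if (is.null(predictor)) return(draws)
  d0 <- behavior_vector(predictor, subgraph, config$behavior_source)
  dist <- vapply(draws, function(sg) {
    dv <- behavior_vector(predictor, sg, config$behavior_source)
    pnorm_dist(d0 - dv, config$norm_order)
  }, numeric(1L))
  delta <- config$delta
  if (is.null(delta)) delta <- stats::quantile(dist, 0.95, names = FALSE)
  draws[dist <= delta]
}

pnorm_dist <- function(x, p) {
  if (is.infinite(p)) max(abs(x)) else sum(abs(x)^p)^(1 / p)
}

behavior_vector <- function(predictor, subgraph, source) {
  if (source == "logits") predict_node(predictor, subgraph, type = "logits")
  else embed_node(predictor, subgraph)
}

# one absent intra-subgraph edge (parent ids), or NULL if the subgraph is
# complete
absent_edge <- function(sg) {
  ids <- sg$node_ids
  n <- length(ids)
  if (n < 2L) return(NULL)
  present <- paste(sg$edges[, 1L], sg$edges[, 2L])
  for (try in seq_len(20L)) {
    pair <- sort(ids[sample.int(n, 2L)])
    if (!paste(pair[1L], pair[2L]) %in% present)
      return(matrix(pair, ncol = 2L))
  }
  NULL
}

cosine_distance <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    message("zero-norm explanation mask: cosine distance set to 1")
    return(1)
  }
  max(0, 1 - sum(a * b) / (na * nb))
}

#' Graph explanation instability
#'
#' Maximum cosine distance between the explanation of the original
#' subgraph and the explanations of its behavior-preserving perturbations.
#' Returns 0 (with a message) when no perturbation passes the behavior
#' check.
#'
#' @param explainer function `(predictor, subgraph) -> explanation_mask`.
#' @param predictor trained predictor.
#' @param subgraph an [enclosing_subgraph()].
#' @param channel score channel compared across perturbations.
#' @param config a [metric_config()].
#' @return instability, non-negative; higher is worse.
#' @export
ges <- function(explainer, predictor, subgraph,
                channel = c("node", "feature", "edge"),
                config = metric_config()) {
  channel <- match.arg(channel)
  base <- mask_channel(explainer(predictor, subgraph), channel)
  ball <- perturb_neighborhood(subgraph, config, predictor)
  if (length(ball) == 0L) {
    message("no perturbation within the behavior ball; instability = 0")
    return(0)
  }
  max(vapply(ball, function(sg) {
    m <- mask_channel(explainer(predictor, sg), channel)
    if (channel == "edge") {
      # align over the original edge set; edges absent after rewiring get 0
      key0 <- paste(subgraph$edges[, 1L], subgraph$edges[, 2L])
      keyp <- paste(sg$edges[, 1L], sg$edges[, 2L])
      m <- ifelse(key0 %in% keyp, m[match(key0, keyp)], 0)
      m[is.na(m)] <- 0
    }
    cosine_distance(base, m)
  }, numeric(1L)))
}

#' Counterfactual-fairness mismatch
#'
#' Cosine distance between the explanation of a subgraph and the
#' explanation of its counterfactual counterpart (protected feature flipped
#' on every node, all else identical). Low values mean the explanation is
#' insensitive to the protected attribute.
#'
#' @param pred predicted [explanation_mask()] of the original subgraph.
#' @param pred_cf predicted mask of the counterfactual subgraph.
#' @param channel channel compared.
#' @return mismatch in [0, 2] (in practice [0, 1] for non-negative scores).
#' @export
gecf <- function(pred, pred_cf, channel = c("node", "feature", "edge")) {
  channel <- match.arg(channel)
  a <- mask_channel(pred, channel)
  b <- mask_channel(pred_cf, channel)
  if (length(a) != length(b)) stop("masks are not aligned")
  cosine_distance(a, b)
}

#' Counterfactual counterpart of a subgraph
#'
#' Flips the binary protected feature column on every node of the
#' subgraph; structure and all other features are untouched.
#'
#' @param subgraph an [enclosing_subgraph()].
#' @param protected_idx protected feature column index.
#' @return a new `enclosing_subgraph`.
#' @export
counterfactual_subgraph <- function(subgraph, protected_idx) {
  if (length(protected_idx) != 1L) stop("protected_idx must be one column")
  subgraph$features[, protected_idx] <- 1 - subgraph$features[, protected_idx]
  subgraph
}

#' Statistical parity of binary predictions
#'
#' Absolute difference of positive-prediction rates between the two
#' protected groups.
#'
#' @param preds binary predictions (1 = positive class).
#' @param protected binary protected-group indicator.
#' @return value in [0, 1].
#' @export
statistical_parity <- function(preds, protected) {
  if (length(preds) != length(protected)) stop("lengths differ")
  g1 <- protected == 1
  if (!any(g1) || !any(!g1)) stop("both protected groups must be nonempty")
  abs(mean(preds[g1] == 1) - mean(preds[!g1] == 1))
}

#' Group-fairness mismatch
#'
#' Absolute difference between the statistical parity of the original
#' predictions and of the predictions obtained from explanation-masked
#' inputs, over the same node set.
#'
#' @param preds_original,preds_masked binary predictions over the same
#'   nodes.
#' @param protected binary protected-group indicator.
#' @return value in [0, 1]; higher means the explanations do not preserve
#'   group fairness.
#' @export
gegf <- function(preds_original, preds_masked, protected) {
  abs(statistical_parity(preds_original, protected) -
      statistical_parity(preds_masked, protected))
}
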