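# Minimal trainable message-passing node classifier. A GIN-like layer
# aggregates each node's own representation plus the sum over neighbors
# before a linear transform and ReLU; a GCN-like layer uses the
# symmetrically normalized mean instead. Training is full-batch Adam on
# cross-entropy with manually derived gradients, so the forward pass is
# also differentiable with respect to the input features (used by the
# gradient explainer).

#' Predictor configuration
#'
#' Defaults follow the study protocol: three convolution layers with
#' hidden width 16, Adam with learning rate 1e-2 and weight decay 1e-5,
#' 1000 epochs, no early stopping.
#'
#' @param layers number of message-passing layers `L`.
#' @param hidden_dim hidden width.
#' @param arch `"gin_like"` (sum aggregation with self term) or
#'   `"gcn_like"` (symmetric-normalized aggregation).
#' @param learning_rate,weight_decay,epochs Adam settings.
#' @param seed RNG seed for initialization.
#' @return an object of class `predictor_config`.
#' @export
predictor_config <- function(layers = 3L, hidden_dim = 16L,
                             arch = c("gin_like", "gcn_like"),
                             learning_rate = 1e-2, weight_decay = 1e-5,
                             epochs = 1000L, seed = 1L) {
  if (layers < 1L) stop("layers must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(layers = as.integer(layers),
                 hidden_dim = as.integer(hidden_dim),
                 arch = match.arg(arch),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "predictor_config")
}

# aggregation operator for an edge set (both orientations, local ids):
# the gin-like path keeps the plain neighbor-sum matrix (the self term is
# added in the forward pass, scaled by the layer's learnable epsilon);
# the gcn-like path uses the symmetric-normalized matrix with self-loops
aggregation_operator <- function(edges_local, n, arch) {
  if (arch == "gin_like") {
    mat <- Matrix::sparseMatrix(i = edges_local[, 1L], j = edges_local[, 2L],
                                x = 1, dims = c(n, n))
  } else {
    s <- Matrix::sparseMatrix(i = c(edges_local[, 1L], seq_len(n)),
                              j = c(edges_local[, 2L], seq_len(n)),
                              x = 1, dims = c(n, n))
    dinv <- 1 / sqrt(Matrix::rowSums(s))
    mat <- Matrix::Diagonal(x = dinv) %*% s %*% Matrix::Diagonal(x = dinv)
  }
  list(mat = mat, arch = arch)
}

aggregate_step <- function(op, h, eps) {
  z <- as.matrix(op$mat %*% h)
  if (op$arch == "gin_like") z <- z + (1 + eps) * h
  z
}

# each convolution: aggregate ((1 + eps) * self + neighbor sum, or the
# normalized variant), then a two-layer MLP with ReLU activations
gnn_forward <- function(params, op, x) {
  nl <- length(params$layers)
  hs <- vector("list", nl + 1L)
  m1 <- vector("list", nl)   # pre-activation of the MLP's first linear
  a1 <- vector("list", nl)   # its ReLU output
  m2 <- vector("list", nl)   # pre-activation of the second linear
  hs[[1L]] <- x
  for (l in seq_len(nl)) {
    lp <- params$layers[[l]]
    z <- aggregate_step(op, hs[[l]], lp$eps)
    m1[[l]] <- sweep(z %*% lp$w1, 2L, lp$b1, "+")
    a1[[l]] <- pmax(m1[[l]], 0)
    m2[[l]] <- sweep(a1[[l]] %*% lp$w2, 2L, lp$b2, "+")
    hs[[l + 1L]] <- pmax(m2[[l]], 0)
  }
  logits <- sweep(hs[[nl + 1L]] %*% params$w_out, 2L, params$b_out, "+")
  list(hs = hs, m1 = m1, a1 = a1, m2 = m2, logits = logits)
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

# gradient of mean cross-entropy over `rows` w.r.t. all parameters
gnn_backward <- function(params, op, fwd, y_onehot, rows) {
  n <- nrow(fwd$logits)
  p <- softmax_rows(fwd$logits)
  dlogits <- matrix(0, n, ncol(p))
  dlogits[rows, ] <- (p[rows, , drop = FALSE] -
                        y_onehot[rows, , drop = FALSE]) / length(rows)
  nl <- length(params$layers)
  h_top <- fwd$hs[[nl + 1L]]
  grads <- list(layers = vector("list", nl))
  grads$w_out <- crossprod(h_top, dlogits)
  grads$b_out <- colSums(dlogits)
  dh <- dlogits %*% t(params$w_out)
  for (l in rev(seq_len(nl))) {
    lp <- params$layers[[l]]
    dm2 <- dh * (fwd$m2[[l]] > 0)
    gw2 <- crossprod(fwd$a1[[l]], dm2)
    gb2 <- colSums(dm2)
    da1 <- dm2 %*% t(lp$w2)
    dm1 <- da1 * (fwd$m1[[l]] > 0)
    z <- aggregate_step(op, fwd$hs[[l]], lp$eps)
    gw1 <- crossprod(z, dm1)
    gb1 <- colSums(dm1)
    dz <- dm1 %*% t(lp$w1)
    geps <- if (op$arch == "gin_like") sum(dz * fwd$hs[[l]]) else 0
    grads$layers[[l]] <- list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2,
                              eps = geps)
    dh <- as.matrix(op$mat %*% dz)               # the operator is symmetric
    if (op$arch == "gin_like") dh <- dh + (1 + lp$eps) * dz
  }
  grads
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Train the message-passing classifier
#'
#' Full-batch Adam on cross-entropy over the training split. Training is
#' seeded and reproducible; validation accuracy is stored on the returned
#' predictor.
#'
#' @param dataset a `shapeggen_dataset` (must carry a train/val/test
#'   split).
#' @param config a [predictor_config()].
#' @return an object of class `gnn_predictor`.
#' @export
train_gnn <- function(dataset, config = predictor_config()) {
  g <- dataset$graph
  if (is.null(dataset$split)) stop("dataset has no split")
  set.seed(config$seed)
  n <- g$num_nodes
  d <- ncol(g$features)
  classes <- sort(unique(g$labels))
  c_out <- max(g$labels) + 1L
  s <- aggregation_operator(g$edges, n, config$arch)
  x <- g$features
  y <- g$labels + 1L
  y_onehot <- matrix(0, n, c_out)
  y_onehot[cbind(seq_len(n), y)] <- 1
  train_rows <- which(dataset$split == "train")
  val_rows <- which(dataset$split == "val")

  dims <- c(d, rep(config$hidden_dim, config$layers))
  params <- list(
    layers = lapply(seq_len(config$layers), function(l)
      list(w1 = glorot(dims[l], dims[l + 1L]),
           b1 = numeric(dims[l + 1L]),
           w2 = glorot(dims[l + 1L], dims[l + 1L]),
           b2 = numeric(dims[l + 1L]),
           eps = 0)),
    w_out = glorot(config$hidden_dim, c_out),
    b_out = numeric(c_out))

  opt <- adam_state(params)
  for (epoch in seq_len(config$epochs)) {
    fwd <- gnn_forward(params, s, x)
    p <- softmax_rows(fwd$logits)
    loss <- -mean(log(pmax(p[cbind(train_rows, y[train_rows])], 1e-30)))
    if (!is.finite(loss))
      stop(sprintf("non-finite training loss at epoch %d", epoch))
    grads <- gnn_backward(params, s, fwd, y_onehot, train_rows)
    upd <- adam_step(params, grads, opt, config$learning_rate,
                     config$weight_decay, epoch)
    params <- upd$params
    opt <- upd$opt
  }
  fwd <- gnn_forward(params, s, x)
  pred <- max.col(fwd$logits, ties.method = "first") - 1L
  val_acc <- if (length(val_rows)) mean(pred[val_rows] == g$labels[val_rows])
             else NA_real_
  structure(list(params = params, arch = config$arch,
                 layers = config$layers, hidden_dim = config$hidden_dim,
                 input_dim = d, num_classes = c_out, config = config,
                 val_accuracy = val_acc),
            class = "gnn_predictor")
}

#' @export
print.gnn_predictor <- function(x, ...) {
  cat(sprintf("gnn_predictor: %s, %d layers, hidden %d, %d classes (val acc %.3f)\n",
              x$arch, x$layers, x$hidden_dim, x$num_classes, x$val_accuracy))
  invisible(x)
}

# flatten/step helpers for Adam
adam_state <- function(params) {
  zero <- rapply(params, function(p) p * 0, how = "replace")
  list(m = zero, v = zero)
}

adam_step <- function(params, grads, opt, lr, wd, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    g <- g + wd * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out_p <- params; out_m <- opt$m; out_v <- opt$v
  for (l in seq_along(params$layers)) {
    for (nm in c("w1", "b1", "w2", "b2", "eps")) {
      r <- walk(params$layers[[l]][[nm]], grads$layers[[l]][[nm]],
                opt$m$layers[[l]][[nm]], opt$v$layers[[l]][[nm]])
      out_p$layers[[l]][[nm]] <- r$p
      out_m$layers[[l]][[nm]] <- r$m
      out_v$layers[[l]][[nm]] <- r$v
    }
  }
  r <- walk(params$w_out, grads$w_out, opt$m$w_out, opt$v$w_out)
  out_p$w_out <- r$p; out_m$w_out <- r$m; out_v$w_out <- r$v
  r <- walk(params$b_out, grads$b_out, opt$m$b_out, opt$v$b_out)
  out_p$b_out <- r$p; out_m$b_out <- r$m; out_v$b_out <- r$v
  list(params = out_p, opt = list(m = out_m, v = out_v))
}

subgraph_operator <- function(predictor, subgraph) {
  n <- length(subgraph$node_ids)
  aggregation_operator(subgraph_edges_local(subgraph), n, predictor$arch)
}

#' Predict the center node of an enclosing subgraph
#'
#' @param predictor a trained [train_gnn()] model.
#' @param subgraph an [enclosing_subgraph()].
#' @param type `"prob"` for the softmax vector, `"logits"` for raw logits,
#'   `"class"` for the 0-based argmax class.
#' @return numeric vector over classes, or a class id.
#' @export
predict_node <- function(predictor, subgraph, type = c("prob", "logits", "class")) {
  type <- match.arg(type)
  op <- subgraph_operator(predictor, subgraph)
  fwd <- gnn_forward(predictor$params, op, subgraph$features)
  logit <- fwd$logits[subgraph$center_local, ]
  switch(type,
         prob = {
           e <- exp(logit - max(logit)); e / sum(e)
         },
         logits = logit,
         class = which.max(logit) - 1L)
}

#' Embedding of the center node
#'
#' Final-layer representation `z_u` of the subgraph's center node.
#'
#' @inheritParams predict_node
#' @return numeric vector of length `hidden_dim`.
#' @export
embed_node <- function(predictor, subgraph) {
  op <- subgraph_operator(predictor, subgraph)
  fwd <- gnn_forward(predictor$params, op, subgraph$features)
  fwd$hs[[length(fwd$hs)]][subgraph$center_local, ]
}

# gradient of the center node's class-`cls` logit w.r.t. input features
input_gradient <- function(predictor, subgraph, cls) {
  op <- subgraph_operator(predictor, subgraph)
  x <- subgraph$features
  fwd <- gnn_forward(predictor$params, op, x)
  n <- nrow(x)
  dh <- matrix(0, n, predictor$hidden_dim)
  dh[subgraph$center_local, ] <- predictor$params$w_out[, cls]
  for (l in rev(seq_len(predictor$layers))) {
    lp <- predictor$params$layers[[l]]
    dm2 <- dh * (fwd$m2[[l]] > 0)
    dm1 <- (dm2 %*% t(lp$w2)) * (fwd$m1[[l]] > 0)
    dz <- dm1 %*% t(lp$w1)
    dh <- as.matrix(op$mat %*% dz)
    if (op$arch == "gin_like") dh <- dh + (1 + lp$eps) * dz
  }
  dh
}

# finite-difference oracle for input_gradient (central differences)
numeric_input_gradient <- function(predictor, subgraph, cls, h = 1e-5) {
  f <- function(x) {
    sg <- subgraph
    sg$features <- x
    predict_node(predictor, sg, type = "logits")[cls]
  }
  x0 <- subgraph$features
  g <- x0 * 0
  for (i in seq_len(nrow(x0))) for (j in seq_len(ncol(x0))) {
    xp <- x0; xp[i, j] <- xp[i, j] + h
    xm <- x0; xm[i, j] <- xm[i, j] - h
    g[i, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

#' Uniform-random baseline explainer
#'
#' Node and edge scores are uniform(0, 1); the feature channel is a
#' standard-Gaussian vector over the feature dimensions.
#'
#' @param subgraph an [enclosing_subgraph()].
#' @param channel channel(s) to populate; `"all"` fills every channel.
#' @return a predicted [explanation_mask()].
#' @export
random_explainer <- function(subgraph, channel = c("all", "node", "feature", "edge")) {
  channel <- match.arg(channel)
  n <- length(subgraph$node_ids)
  node <- if (channel %in% c("all", "node")) stats::runif(n) else numeric(0)
  feat <- if (channel %in% c("all", "feature"))
    stats::rnorm(ncol(subgraph$features)) else numeric(0)
  edge <- if (channel %in% c("all", "edge"))
    stats::runif(nrow(subgraph$edges)) else numeric(0)
  explanation_mask(node, feat, edge, kind = "predicted")
}

#' Vanilla gradient (saliency) explainer
#'
#' Absolute gradient of the predicted-class logit with respect to the
#' input features: entry-wise saliency gives the feature scores at the
#' center node, row sums give the node scores, and each edge scores the
#' mean of its endpoints' node scores. Deterministic given the predictor.
#'
#' @param predictor a trained [train_gnn()] model.
#' @param subgraph an [enclosing_subgraph()].
#' @return a predicted [explanation_mask()].
#' @export
gradient_explainer <- function(predictor, subgraph) {
  cls <- predict_node(predictor, subgraph, type = "class") + 1L
  g <- abs(input_gradient(predictor, subgraph, cls))
  node <- rowSums(g)
  feat <- g[subgraph$center_local, ]
  loc <- if (nrow(subgraph$edges) > 0L)
    matrix(subgraph$local_index_map[subgraph$edges], ncol = 2L)
  else matrix(integer(0), ncol = 2L)
  edge <- if (nrow(loc) > 0L) (node[loc[, 1L]] + node[loc[, 2L]]) / 2
          else numeric(0)
  explanation_mask(node, feat, edge, kind = "predicted")
}

#' Stratified train/validation/test split
#'
#' Seeded, stratified by class; split sizes match the fractions within
#' rounding per class.
#'
#' @param labels integer class labels.
#' @param fractions length-3 nonnegative vector summing to 1
#'   (train, validation, test).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return factor with levels `train`, `val`, `test`.
#' @export
split_dataset <- function(labels, fractions = c(0.7, 0.05, 0.25),
                          seed = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  out <- character(n)
  n_parts <- sum(fractions > 0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < n_parts)
      stop("class ", cl, " has fewer members than the number of split parts")
    idx <- idx[sample.int(length(idx))]
    n_tr <- round(fractions[1L] * length(idx))
    n_va <- round(fractions[2L] * length(idx))
    n_tr <- min(n_tr, length(idx))
    n_va <- min(n_va, length(idx) - n_tr)
    out[idx[seq_len(n_tr)]] <- "train"
    if (n_va > 0L) out[idx[n_tr + seq_len(n_va)]] <- "val"
    rest <- idx[-seq_len(n_tr + n_va)]
    out[rest] <- "test"
  }
  factor(out, levels = c("train", "val", "test"))
}

#' Serialize a trained predictor to a JSON parameter file
#'
#' @param predictor a `gnn_predictor`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_predictor <- function(predictor, path) {
  obj <- list(
    header = list(arch = predictor$arch, layers = predictor$layers,
                  hidden_dim = predictor$hidden_dim,
                  input_dim = predictor$input_dim,
                  num_classes = predictor$num_classes,
                  seed = predictor$config$seed),
    layers = lapply(predictor$params$layers, function(lp)
      lapply(lp, as.numeric)),
    w_out = as.numeric(predictor$params$w_out),
    b_out = predictor$params$b_out,
    val_accuracy = predictor$val_accuracy)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a predictor saved by [save_predictor()]
#'
#' @param path JSON parameter file.
#' @return a `gnn_predictor`.
#' @export
load_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  h <- lapply(obj$header, unlist)
  num <- function(x) as.numeric(unlist(x))
  dims <- c(h$input_dim, rep(h$hidden_dim, h$layers))
  layers <- lapply(seq_len(h$layers), function(l)
    list(w1 = matrix(num(obj$layers[[l]]$w1), dims[l], dims[l + 1L]),
         b1 = num(obj$layers[[l]]$b1),
         w2 = matrix(num(obj$layers[[l]]$w2), dims[l + 1L], dims[l + 1L]),
         b2 = num(obj$layers[[l]]$b2),
         eps = num(obj$layers[[l]]$eps)))
  params <- list(layers = layers,
                 w_out = matrix(num(obj$w_out), h$hidden_dim, h$num_classes),
                 b_out = num(obj$b_out))
  structure(list(params = params, arch = h$arch, layers = h$layers,
                 hidden_dim = h$hidden_dim, input_dim = h$input_dim,
                 num_classes = h$num_classes,
                 config = predictor_config(layers = h$layers,
                                           hidden_dim = h$hidden_dim,
                                           arch = h$arch, seed = h$seed),
                 val_accuracy = as.numeric(unlist(obj$val_accuracy))),
            class = "gnn_predictor")
}
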