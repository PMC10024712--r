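# Node feature generation: a hypercube latent-cluster model for the
# informative block, Gaussian noise for the redundant block, a label-linked
# protected feature, and a homophily/heterophily adjustment of the
# redundant block.

#' Draw informative features from a hypercube cluster model
#'
#' Places `K * c_f` centroids at distinct vertices of the
#' `{-s_f, +s_f}^{n_i}` hypercube, assigns `c_f` centroids to each class,
#' and draws every node's informative block as its (uniformly chosen)
#' class centroid plus standard-normal noise. Larger `s_f` separates the
#' classes more strongly in feature space.
#'
#' @param labels integer class labels in `0..K-1`.
#' @param n_i number of informative features (`K * c_f <= 2^n_i` required).
#' @param s_f class separation factor.
#' @param c_f clusters (centroids) per class.
#' @param K number of classes.
#' @return list with `features` (n x n_i matrix), `centroids`
#'   (`K * c_f` x `n_i`), `centroid_of` (centroid index per node).
#' @export
generate_informative_features <- function(labels, n_i, s_f, c_f, K) {
  if (n_i < 1L) stop("n_i must be >= 1")
  n_cent <- K * c_f
  if (n_cent > 2^n_i)
    stop("K * c_f exceeds the number of hypercube vertices 2^n_i")
  vert <- sample.int(2^n_i, n_cent) - 1L           # distinct vertex codes
  centroids <- t(vapply(vert, function(v) {
    bits <- as.integer(intToBits(v))[seq_len(n_i)]
    ifelse(bits == 1L, s_f, -s_f)
  }, numeric(n_i)))
  centroids <- matrix(centroids, nrow = n_cent, ncol = n_i)
  class_of_centroid <- rep(0:(K - 1L), each = c_f)
  n <- length(labels)
  centroid_of <- integer(n)
  for (cl in 0:(K - 1L)) {
    idx <- which(labels == cl)
    pool <- which(class_of_centroid == cl)
    centroid_of[idx] <- pool[sample.int(c_f, length(idx), replace = TRUE)]
  }
  feats <- centroids[centroid_of, , drop = FALSE] +
    matrix(stats::rnorm(n * n_i), n, n_i)
  list(features = feats, centroids = centroids, centroid_of = centroid_of)
}

#' Append redundant noise features and a protected feature
#'
#' Fills `n_f - n_i - 1` redundant columns with standard-normal noise and
#' one protected column with the binarized label (label > 0) XOR a
#' Bernoulli(`phi`) flip, so the protected/label correlation is
#' `1 - 2 * phi`. Column layout: informative first, then redundant, the
#' protected column last. The protected column is excluded from the
#' ground-truth feature mask.
#'
#' @param informative n x `n_i` matrix from
#'   [generate_informative_features()].
#' @param labels integer class labels.
#' @param n_f total number of feature columns (`>= n_i + 1`).
#' @param n_i number of informative columns.
#' @param phi protected-feature flip probability in [0, 1].
#' @return list with `features` (n x n_f), `informative_idx`,
#'   `protected_idx`, `redundant_idx`.
#' @export
add_redundant_and_protected <- function(informative, labels, n_f, n_i, phi) {
  if (n_f < n_i + 1L) stop("n_f must be at least n_i + 1")
  n <- length(labels)
  n_red <- n_f - n_i - 1L
  red <- matrix(stats::rnorm(n * n_red), n, n_red)
  bin_label <- as.integer(labels > 0L)
  flip <- stats::rbinom(n, 1L, phi)
  protected <- as.numeric(xor(bin_label, flip))
  feats <- cbind(informative, red, protected)
  dimnames(feats) <- NULL
  list(features = feats,
       informative_idx = seq_len(n_i),
       redundant_idx = as.integer(n_i) + seq_len(n_red),
       protected_idx = as.integer(n_f))
}

#' Apply the homophily/heterophily adjustment
#'
#' One synchronous pass over nodes: the redundant feature block of each
#' node is replaced by the unit-normalized sum of its own block and `eta`
#' times the mean block of its neighbors. Positive `eta` pulls connected
#' nodes' features together (homophily), negative `eta` pushes them apart
#' (heterophily). Informative and protected columns are untouched; isolated
#' nodes keep their block unchanged.
#'
#' @param graph a [synthetic_graph()] (only the edges are used).
#' @param features full feature matrix.
#' @param eta homophily coefficient.
#' @param redundant_idx indices of the redundant columns to adjust.
#' @return adjusted feature matrix.
#' @export
apply_homophily <- function(graph, features, eta, redundant_idx) {
  if (length(redundant_idx) == 0L) return(features)
  xr <- features[, redundant_idx, drop = FALSE]
  n <- nrow(xr)
  deg <- tabulate(graph$edges[, 1L], nbins = n)
  a <- Matrix::sparseMatrix(i = graph$edges[, 1L], j = graph$edges[, 2L],
                            x = 1, dims = c(n, n))
  nb_mean <- as.matrix(a %*% xr)
  has_nb <- deg > 0L
  nb_mean[has_nb, ] <- nb_mean[has_nb, , drop = FALSE] / deg[has_nb]
  upd <- xr + eta * nb_mean
  nrm <- sqrt(rowSums(upd^2))
  ok <- has_nb & nrm > 0
  xr[ok, ] <- upd[ok, , drop = FALSE] / nrm[ok]
  features[, redundant_idx] <- xr
  features
}
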