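# Core in-memory containers: undirected graphs with planted motifs,
# enclosing subgraphs, and explanation masks.

#' Construct a synthetic graph container
#'
#' An undirected graph stored as directed edge pairs (every edge appears in
#' both orientations), together with a node-feature matrix, integer class
#' labels and a registry of planted motifs.
#'
#' @param edges two-column integer matrix of node-id pairs. Each undirected
#'   edge must be present in both orientations; self-loops and duplicate
#'   pairs are rejected.
#' @param num_nodes number of nodes; node ids are `1..num_nodes`.
#' @param features numeric matrix with `num_nodes` rows (one per node).
#' @param labels integer vector of class ids in `0..K-1`, length `num_nodes`.
#' @param motifs list of [motif_instance()] objects registered in the graph.
#' @param informative_idx integer indices of feature columns that carry
#'   label signal (the ground-truth feature explanation).
#' @param protected_idx index of the protected (sensitive) feature column,
#'   or `integer(0)` if the graph has none.
#' @param redundant_idx indices of pure-noise feature columns.
#' @return an object of class `synthetic_graph`.
#' @export
synthetic_graph <- function(edges, num_nodes, features, labels,
                            motifs = list(),
                            informative_idx = integer(0),
                            protected_idx = integer(0),
                            redundant_idx = integer(0)) {
  edges <- as_edge_matrix(edges)
  if (nrow(edges) > 0L) {
    if (max(edges) > num_nodes || min(edges) < 1L)
      stop("edge endpoints must be node ids in 1..num_nodes")
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed")
    key <- paste(edges[, 1L], edges[, 2L])
    if (anyDuplicated(key))
      stop("duplicate edge pairs are not allowed")
    rkey <- paste(edges[, 2L], edges[, 1L])
    if (!all(rkey %in% key))
      stop("edge list must be symmetric: every edge stored in both orientations")
  }
  features <- as.matrix(features)
  if (nrow(features) != num_nodes)
    stop("feature matrix must have one row per node")
  labels <- as.integer(labels)
  if (length(labels) != num_nodes)
    stop("labels must have one entry per node")
  if (length(intersect(informative_idx, protected_idx)) > 0L)
    stop("informative and protected feature indices must be disjoint")
  g <- structure(list(
    num_nodes = as.integer(num_nodes),
    edges = edges,
    features = features,
    labels = labels,
    motifs = motifs,
    informative_idx = as.integer(informative_idx),
    protected_idx = as.integer(protected_idx),
    redundant_idx = as.integer(redundant_idx)
  ), class = "synthetic_graph")
  g
}

as_edge_matrix <- function(edges) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) return(matrix(integer(0), ncol = 2L))
  if (ncol(edges) != 2L) stop("edges must be a two-column matrix")
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL
  edges
}

#' @export
print.synthetic_graph <- function(x, ...) {
  cat(sprintf("synthetic_graph: %d nodes, %d directed edges, %d motifs, %d features\n",
              x$num_nodes, nrow(x$edges), length(x$motifs), ncol(x$features)))
  invisible(x)
}

#' Construct a motif instance
#'
#' Records a planted template subgraph: the structural ground-truth
#' explanation unit.
#'
#' @param shape_name token naming the shape (`"house"`, `"triangle"`, or a
#'   custom name).
#' @param node_ids ordered vector of distinct node ids forming the motif.
#' @param edge_set two-column matrix of undirected edges internal to the
#'   motif (one row per undirected edge).
#' @return an object of class `motif_instance`.
#' @export
motif_instance <- function(shape_name, node_ids, edge_set) {
  node_ids <- as.integer(node_ids)
  if (anyDuplicated(node_ids)) stop("motif node ids must be distinct")
  edge_set <- as_edge_matrix(edge_set)
  if (nrow(edge_set) > 0L && !all(edge_set %in% node_ids))
    stop("motif edges must join motif nodes")
  structure(list(shape_name = shape_name,
                 node_ids = node_ids,
                 edge_set = edge_set),
            class = "motif_instance")
}

# adjacency list: integer vectors of neighbors per node (empty for isolated)
adjacency_list <- function(graph) {
  adj <- vector("list", graph$num_nodes)
  if (nrow(graph$edges) > 0L) {
    spl <- split(graph$edges[, 2L], graph$edges[, 1L])
    adj[as.integer(names(spl))] <- lapply(spl, as.integer)
  }
  empty <- vapply(adj, is.null, logical(1L))
  adj[empty] <- list(integer(0))
  adj
}

# per-node list of motif ids whose node set contains the node
node_motif_ids <- function(graph) {
  out <- vector("list", graph$num_nodes)
  out[] <- list(integer(0))
  for (i in seq_along(graph$motifs)) {
    for (v in graph$motifs[[i]]$node_ids) out[[v]] <- c(out[[v]], i)
  }
  out
}

#' Extract the L-hop enclosing subgraph around a node
#'
#' Returns the induced subgraph on all nodes at shortest-path distance at
#' most `hops` from `center` -- the receptive field of a `hops`-layer
#' message-passing model. Local indices are assigned in ascending parent
#' node id, so mask vectors over the subgraph are reproducible.
#'
#' @param graph a [synthetic_graph()].
#' @param center node id of the center node.
#' @param hops non-negative hop count.
#' @return an object of class `enclosing_subgraph` with fields `center`,
#'   `hops`, `node_ids` (sorted parent ids), `edges` (unique undirected
#'   pairs, lexicographic parent-id order), `features` (local rows),
#'   `center_local` and `local_index_map`.
#' @export
enclosing_subgraph <- function(graph, center, hops) {
  center <- as.integer(center)
  if (length(center) != 1L || is.na(center) || center < 1L ||
      center > graph$num_nodes)
    stop("unknown node id: ", center)
  if (hops < 0L) stop("hops must be >= 0")
  adj <- adjacency_list(graph)
  ball <- bfs_ball(adj, center, hops)
  subgraph_from_nodes(graph, ball, center, hops)
}

bfs_ball <- function(adj, center, hops) {
  seen <- center
  frontier <- center
  h <- 0L
  while (h < hops && length(frontier) > 0L) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
    h <- h + 1L
  }
  sort(seen)
}

# build an enclosing_subgraph from a sorted node-id set
subgraph_from_nodes <- function(graph, node_ids, center, hops) {
  node_ids <- sort(as.integer(node_ids))
  keep <- graph$edges[, 1L] %in% node_ids & graph$edges[, 2L] %in% node_ids
  e <- graph$edges[keep, , drop = FALSE]
  und <- e[e[, 1L] < e[, 2L], , drop = FALSE]
  if (nrow(und) > 0L)
    und <- und[order(und[, 1L], und[, 2L]), , drop = FALSE]
  lim <- integer(max(c(node_ids, 1L)))
  lim[node_ids] <- seq_along(node_ids)
  structure(list(
    center = center,
    hops = as.integer(hops),
    node_ids = node_ids,
    edges = und,
    features = graph$features[node_ids, , drop = FALSE],
    center_local = match(center, node_ids),
    local_index_map = lim
  ), class = "enclosing_subgraph")
}

#' @export
print.enclosing_subgraph <- function(x, ...) {
  cat(sprintf("enclosing_subgraph: center %d, %d hops, %d nodes, %d undirected edges\n",
              x$center, x$hops, length(x$node_ids), nrow(x$edges)))
  invisible(x)
}

#' Construct an explanation mask
#'
#' Importance scores over the nodes, features and edges of an enclosing
#' subgraph. Ground-truth masks are binary; predicted masks are soft scores
#' that get binarized at a top-k fraction before accuracy evaluation.
#'
#' @param node_scores numeric vector over the subgraph's nodes (local order).
#' @param feature_scores numeric vector of length equal to the number of
#'   feature columns.
#' @param edge_scores numeric vector over the subgraph's undirected edges
#'   (lexicographic parent-id order).
#' @param kind `"ground_truth"` (binary scores enforced) or `"predicted"`.
#' @return an object of class `explanation_mask`.
#' @export
explanation_mask <- function(node_scores = numeric(0),
                             feature_scores = numeric(0),
                             edge_scores = numeric(0),
                             kind = c("predicted", "ground_truth")) {
  kind <- match.arg(kind)
  if (kind == "ground_truth") {
    for (s in list(node_scores, feature_scores, edge_scores))
      if (length(s) && !all(s %in% c(0, 1)))
        stop("ground-truth masks must be binary")
  }
  structure(list(node_scores = as.numeric(node_scores),
                 feature_scores = as.numeric(feature_scores),
                 edge_scores = as.numeric(edge_scores),
                 kind = kind),
            class = "explanation_mask")
}

#' Construct a set of equally valid ground-truth explanations
#'
#' A prediction may have several equally valid rationales (one per motif in
#' the receptive field); accuracy is scored against the best-matching one.
#'
#' @param masks nonempty list of ground-truth [explanation_mask()] objects.
#' @param node_ids sorted parent node ids of the enclosing subgraph the
#'   masks refer to.
#' @param edges undirected edge pairs of the enclosing subgraph.
#' @param motif_ids integer ids of the motifs each mask corresponds to.
#' @param center center node id.
#' @return an object of class `ground_truth_set`.
#' @export
ground_truth_set <- function(masks, node_ids, edges, motif_ids = integer(0),
                             center = NA_integer_) {
  if (length(masks) < 1L) stop("a ground-truth set must contain at least one mask")
  structure(list(masks = masks,
                 node_ids = as.integer(node_ids),
                 edges = as_edge_matrix(edges),
                 motif_ids = as.integer(motif_ids),
                 center = as.integer(center)),
            class = "ground_truth_set")
}

#' Count motifs in a node's closed 1-hop neighborhood
#'
#' Number of registered motifs whose node set intersects the closed
#' neighborhood \eqn{N_v \cup \{v\}}. A motif member therefore always counts
#' its own motif, which keeps the induced label non-negative.
#'
#' @param graph a [synthetic_graph()].
#' @param v node id.
#' @return integer motif count.
#' @export
motif_count <- function(graph, v) {
  v <- as.integer(v)
  if (length(v) != 1L || is.na(v) || v < 1L || v > graph$num_nodes)
    stop("unknown node id: ", v)
  adj <- adjacency_list(graph)
  nm <- node_motif_ids(graph)
  closed <- c(v, adj[[v]])
  length(unique(unlist(nm[closed], use.names = FALSE)))
}

# vectorized motif counts for all nodes (shared by label assignment)
motif_counts_all <- function(graph) {
  adj <- adjacency_list(graph)
  nm <- node_motif_ids(graph)
  vapply(seq_len(graph$num_nodes), function(v) {
    closed <- c(v, adj[[v]])
    length(unique(unlist(nm[closed], use.names = FALSE)))
  }, integer(1L))
}

#' Mask an enclosing subgraph at a top-k fraction
#'
#' Binarizes the requested score channel at the top-k fraction (see
#' [binarize_topk()]) and applies it: `"feature"` zeroes feature columns
#' outside the kept set, `"node"` zeroes the full feature rows of non-kept
#' nodes (structure retained), `"edge"` removes non-kept edges. The input
#' object is not modified.
#'
#' @param subgraph an [enclosing_subgraph()].
#' @param mask an [explanation_mask()] whose vectors match the subgraph.
#' @param mode `"node"`, `"feature"` or `"edge"`.
#' @param k_fraction fraction in (0, 1] of entries to keep.
#' @return a new `enclosing_subgraph` with masked features or edges.
#' @export
apply_mask <- function(subgraph, mask, mode = c("node", "feature", "edge"),
                       k_fraction = 0.25) {
  mode <- match.arg(mode)
  if (k_fraction <= 0 || k_fraction > 1)
    stop("k_fraction must be in (0, 1]")
  out <- subgraph
  if (mode == "node") {
    s <- mask$node_scores
    if (length(s) != length(subgraph$node_ids))
      stop("node score length does not match subgraph")
    keep <- binarize_topk(s, k_fraction) == 1
    out$features[!keep, ] <- 0
  } else if (mode == "feature") {
    s <- mask$feature_scores
    if (length(s) != ncol(subgraph$features))
      stop("feature score length does not match subgraph")
    keep <- binarize_topk(s, k_fraction) == 1
    out$features[, !keep] <- 0
  } else {
    s <- mask$edge_scores
    if (length(s) != nrow(subgraph$edges))
      stop("edge score length does not match subgraph")
    keep <- binarize_topk(s, k_fraction) == 1
    out$edges <- subgraph$edges[keep, , drop = FALSE]
  }
  out
}

# both-orientation directed edge matrix of a subgraph, in local indices
subgraph_edges_local <- function(sg) {
  e <- sg$edges
  if (nrow(e) == 0L) return(matrix(integer(0), ncol = 2L))
  loc <- matrix(sg$local_index_map[e], ncol = 2L)
  rbind(loc, loc[, 2:1, drop = FALSE])
}
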