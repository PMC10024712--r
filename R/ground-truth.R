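# Ground-truth explanation masks over L-hop enclosing subgraphs.
# Each motif intersecting a node's receptive field is an equally valid
# rationale for its label, so the ground-truth set holds one mask per such
# motif: node mask = that motif's nodes, feature mask = informative
# columns, edge mask = edges whose endpoints both lie in the motif or are
# the center node itself.

#' Build ground-truth explanations for every node
#'
#' For each node `v`, extracts the `L`-hop enclosing subgraph and emits one
#' binary ground-truth mask per motif whose node set intersects it. The
#' feature mask marks the informative columns (the protected and redundant
#' columns are 0) and is shared by all masks of a node.
#'
#' @param graph a [synthetic_graph()] with registered motifs.
#' @param L hop count of the enclosing subgraphs (receptive-field depth).
#' @param informative_idx informative feature column indices.
#' @return list of [ground_truth_set()] objects, one per node.
#' @export
build_ground_truth <- function(graph, L, informative_idx) {
  n <- graph$num_nodes
  n_f <- ncol(graph$features)
  feature_mask <- as.numeric(seq_len(n_f) %in% informative_idx)
  balls <- lhop_balls(graph, L)
  adj <- adjacency_list(graph)
  motif_of <- integer(n)                      # single-membership fast path
  for (i in seq_along(graph$motifs)) motif_of[graph$motifs[[i]]$node_ids] <- i
  motif_nodes <- lapply(graph$motifs, `[[`, "node_ids")

  out <- vector("list", n)
  for (v in seq_len(n)) {
    ball <- balls[[v]]
    mids <- unique(motif_of[ball])
    mids <- sort(mids[mids != 0L])
    und <- ball_edges(adj, ball)
    masks <- vector("list", length(mids))
    for (k in seq_along(mids)) {
      mn <- motif_nodes[[mids[k]]]
      node_mask <- as.numeric(ball %in% mn)
      allowed <- c(mn, v)
      edge_mask <- if (nrow(und) > 0L)
        as.numeric(und[, 1L] %in% allowed & und[, 2L] %in% allowed)
      else numeric(0)
      masks[[k]] <- explanation_mask(node_mask, feature_mask, edge_mask,
                                     kind = "ground_truth")
    }
    if (length(masks) == 0L)    # node with no motif in range (e.g. BA base)
      masks <- list(explanation_mask(numeric(length(ball)), feature_mask,
                                     numeric(nrow(und)),
                                     kind = "ground_truth"))
    out[[v]] <- ground_truth_set(masks, ball, und, motif_ids = mids,
                                 center = v)
  }
  out
}

# sorted node-id vectors of all <=L-hop balls, via sparse boolean powers
lhop_balls <- function(graph, L) {
  n <- graph$num_nodes
  if (nrow(graph$edges) == 0L || L == 0L)
    return(lapply(seq_len(n), function(v) v))
  s <- Matrix::sparseMatrix(i = c(graph$edges[, 1L], seq_len(n)),
                            j = c(graph$edges[, 2L], seq_len(n)),
                            x = 1, dims = c(n, n))
  p <- s
  for (h in seq_len(L - 1L)) {
    p <- p %*% s
    p@x[] <- 1   # keep path counts from growing; only the pattern matters
  }
  p <- Matrix::drop0(p)
  # symmetric pattern: column j holds the ball of node j, already sorted
  ptr <- p@p
  idx <- p@i + 1L
  lapply(seq_len(n), function(v) idx[(ptr[v] + 1L):ptr[v + 1L]])
}

# undirected edges (sorted pairs, lexicographic) induced on a sorted ball
ball_edges <- function(adj, ball) {
  nb <- adj[ball]
  len <- lengths(nb)
  if (sum(len) == 0L) return(matrix(integer(0), ncol = 2L))
  from <- rep.int(ball, len)
  to <- unlist(nb, use.names = FALSE)
  keep <- from < to & (to %in% ball)
  und <- cbind(from[keep], to[keep])
  if (nrow(und) > 1L) und <- und[order(und[, 1L], und[, 2L]), , drop = FALSE]
  storage.mode(und) <- "integer"
  und
}

#' Ground-truth explanation for a single node, computed directly
#'
#' Brute-force construction by explicit breadth-first search and set
#' intersection; useful for cross-checking [build_ground_truth()].
#'
#' @param graph a [synthetic_graph()].
#' @param v node id.
#' @param L hop count.
#' @param informative_idx informative feature columns.
#' @return a [ground_truth_set()].
#' @export
ground_truth_for_node <- function(graph, v, L, informative_idx) {
  sg <- enclosing_subgraph(graph, v, L)
  n_f <- ncol(graph$features)
  feature_mask <- as.numeric(seq_len(n_f) %in% informative_idx)
  mids <- which(vapply(graph$motifs, function(m)
    length(intersect(m$node_ids, sg$node_ids)) > 0L, logical(1L)))
  masks <- lapply(mids, function(mi) {
    mn <- graph$motifs[[mi]]$node_ids
    allowed <- c(mn, v)
    explanation_mask(
      as.numeric(sg$node_ids %in% mn),
      feature_mask,
      if (nrow(sg$edges) > 0L)
        as.numeric(sg$edges[, 1L] %in% allowed & sg$edges[, 2L] %in% allowed)
      else numeric(0),
      kind = "ground_truth")
  })
  if (length(masks) == 0L)
    masks <- list(explanation_mask(numeric(length(sg$node_ids)),
                                   feature_mask * 0,
                                   numeric(nrow(sg$edges)),
                                   kind = "ground_truth"))
  ground_truth_set(masks, sg$node_ids, sg$edges, motif_ids = mids, center = v)
}
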