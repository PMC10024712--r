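# Classic house-motif benchmark: a Barabasi-Albert base graph with
# five-node house motifs attached, binary in-house labels.

#' Generate a BA-Shapes dataset
#'
#' Grows a preferential-attachment base graph on `num_nodes` nodes (one
#' edge per new node), attaches `num_houses` five-node house motifs, each
#' by a single edge to a uniformly chosen base node, and perturbs the
#' result with `perturb_edges` random extra edges. Labels are binary:
#' whether the node is in a house (1) or not (0). Ground-truth masks are
#' built over `hops`-hop enclosing subgraphs as for the main generator.
#'
#' @param num_nodes number of base-graph nodes (>= 5).
#' @param num_houses number of house motifs attached.
#' @param perturb_edges number of random extra edges.
#' @param hops receptive-field depth of the ground-truth subgraphs.
#' @param seed RNG seed.
#' @return a `shapeggen_dataset`.
#' @export
ba_shapes <- function(num_nodes, num_houses = 0L, perturb_edges = 0L,
                      hops = 3L, seed = 1L) {
  if (num_nodes < 5L) stop("num_nodes must be >= 5")
  set.seed(seed)
  base <- igraph::sample_pa(num_nodes, m = 1, directed = FALSE)
  und <- igraph::as_edgelist(base, names = FALSE)
  house <- make_motif("house")
  motifs <- vector("list", num_houses)
  total <- num_nodes
  for (i in seq_len(num_houses)) {
    ids <- total + 1:5
    und <- rbind(und, matrix(ids[house$edge_set], ncol = 2L))
    anchor <- sample.int(num_nodes, 1L)
    und <- rbind(und, c(anchor, ids[sample.int(5L, 1L)]))
    motifs[[i]] <- motif_instance("house", ids,
                                  matrix(ids[house$edge_set], ncol = 2L))
    total <- total + 5L
  }
  key <- paste(pmin(und[, 1L], und[, 2L]), pmax(und[, 1L], und[, 2L]))
  added <- 0L
  guard <- 0L
  while (added < perturb_edges && guard < 100L * max(1L, perturb_edges)) {
    guard <- guard + 1L
    pair <- sample.int(total, 2L)
    k <- paste(min(pair), max(pair))
    if (!k %in% key) {
      und <- rbind(und, pair)
      key <- c(key, k)
      added <- added + 1L
    }
  }
  edges <- rbind(und, und[, 2:1, drop = FALSE])
  storage.mode(edges) <- "integer"
  labels <- integer(total)
  for (m in motifs) labels[m$node_ids] <- 1L
  graph <- synthetic_graph(edges, total,
                           features = matrix(1, total, 1L),
                           labels = labels, motifs = motifs)
  gt <- build_ground_truth(graph, hops, integer(0))
  split <- split_dataset(labels, c(0.7, 0.05, 0.25))
  structure(list(graph = graph, ground_truth = gt,
                 config = list(generator = "ba_shapes",
                               num_nodes = num_nodes,
                               num_houses = num_houses,
                               perturb_edges = perturb_edges,
                               hops = hops, seed = seed,
                               num_classes = 2L),
                 split = split),
            class = "shapeggen_dataset")
}
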