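# Shared fixtures, memoised so expensive generations run once per session.

.gx_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .gx_cache)) assign(key, expr, envir = .gx_cache)
  get(key, envir = .gx_cache)
}

# full-size baseline dataset (used by the acceptance suite)
sg_base <- function(seed, ground_truth = TRUE) {
  key <- paste0("base_", seed, "_", ground_truth)
  cached(key, generate_dataset(shapeggen_preset("SG-Base", seed = seed),
                               ground_truth = ground_truth))
}

# small generated dataset for module-level checks
small_dataset <- function(seed = 1, n_sub = 30, p = 0.05, ...) {
  key <- paste0("small_", seed, "_", n_sub, "_", p, "_",
                paste(unlist(list(...)), collapse = "_"))
  cached(key, generate_dataset(shapeggen_config(num_subgraphs = n_sub,
                                                connection_prob = p,
                                                seed = seed, ...)))
}

# small trained predictor on an easily separable task
tiny_predictor <- function() {
  cached("tiny_pred", {
    ds <- small_dataset(seed = 3, n_sub = 40, p = 0.05, class_sep = 3)
    train_gnn(ds, predictor_config(epochs = 150, seed = 1))
  })
}

# hand-built graph: a house motif (nodes 1-5), a pendant node 6 on node 1,
# and a chain 6-7 so node 7 has no motif in its 1-hop neighborhood
house_with_tail <- function() {
  house <- make_motif("house")
  und <- rbind(house$edge_set, c(1L, 6L), c(6L, 7L))
  edges <- rbind(und, und[, 2:1])
  synthetic_graph(edges, 7L, features = matrix(0, 7, 2),
                  labels = integer(7),
                  motifs = list(motif_instance("house", 1:5, house$edge_set)))
}

# path graph a-b-c-... as a synthetic_graph
path_graph <- function(n) {
  und <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  edges <- rbind(und, und[, 2:1])
  synthetic_graph(edges, n, features = matrix(seq_len(n)), labels = integer(n))
}

# independent brute-force motif count (set intersections on the edge matrix)
brute_motif_count <- function(graph, v) {
  nb <- graph$edges[graph$edges[, 1L] == v, 2L]
  closed <- c(v, nb)
  sum(vapply(graph$motifs, function(m)
    length(intersect(m$node_ids, closed)) > 0L, logical(1L)))
}
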