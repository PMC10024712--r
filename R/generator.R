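# Motif-planting graph generator: per-subgraph preferential-attachment
# growth around a motif, sparse inter-subgraph wiring that gives selected
# nodes a second motif in their 1-hop neighborhood, and labels equal to
# (number of motifs in the closed 1-hop neighborhood) - 1.

#' Built-in motif templates
#'
#' `"house"` is the five-node shape used in classic GNN-explainability
#' benchmarks: a 4-cycle base with a roof apex joined to two adjacent base
#' nodes (6 undirected edges). `"triangle"` is the complete graph on three
#' nodes. A `motif_instance` passed instead of a token is returned
#' unchanged, allowing custom templates.
#'
#' @param shape `"house"`, `"triangle"`, or a [motif_instance()] template.
#' @return a `motif_instance` with local node ids `1..n`.
#' @export
make_motif <- function(shape) {
  if (inherits(shape, "motif_instance")) return(shape)
  switch(shape,
    house = motif_instance("house", 1:5,
      rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L), c(3L, 5L), c(4L, 5L))),
    triangle = motif_instance("triangle", 1:3,
      rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L))),
    stop("unknown motif shape '", shape,
         "'; built-in shapes are 'house' and 'triangle'")
  )
}

#' Generator configuration
#'
#' Bundles the generation parameters with the seed. Defaults follow the
#' baseline configuration of the generator (see [shapeggen_preset()]).
#'
#' @param motif_shape motif token or [motif_instance()] template.
#' @param num_subgraphs number of locally grown subgraphs `N_s`.
#' @param connection_prob probability `p` that a given pair of subgraphs is
#'   connected.
#' @param subgraph_size expected subgraph node count `n_s` (motif included).
#' @param num_classes number of classes `K` of the induced node-level task.
#' @param num_features total feature dimension `n_f`.
#' @param num_informative number of label-correlated feature columns `n_i`.
#' @param class_sep class separation factor `s_f`: half-side of the
#'   hypercube on which class centroids sit; larger values make the
#'   feature-only classification task easier.
#' @param clusters_per_class number of centroids per class `c_f`.
#' @param protected_noise flip probability `phi` of the protected feature
#'   with respect to the binarized label; the protected/label correlation is
#'   `1 - 2 * phi`.
#' @param homophily homophily coefficient `eta`; positive values pull the
#'   redundant feature block of neighbors together, negative values push
#'   them apart.
#' @param gnn_layers receptive-field depth `L` used for the enclosing
#'   subgraphs of the ground-truth explanations.
#' @param attach_edges expected number of attachment edges per grown node
#'   (`m`). Non-integer values mix `floor(m)` and `floor(m) + 1` per node.
#'   The default is calibrated so the baseline preset reproduces the
#'   reference average node degree (see the package vignette).
#' @param connection_rounds expected granting rounds per selected subgraph
#'   pair; non-integer values mix one and two rounds. Like `attach_edges`,
#'   a reconstruction knob of the wiring step (see the package vignette).
#' @param attach_power preferential-attachment kernel exponent of the
#'   subgraph growth step; the default produces the heavy-tailed degree
#'   distribution characteristic of scale-free graphs.
#' @param seed integer RNG seed; generation is fully deterministic given
#'   the seed.
#' @return an object of class `shapeggen_config`.
#' @export
shapeggen_config <- function(motif_shape = "house",
                             num_subgraphs = 1200L,
                             connection_prob = 0.006,
                             subgraph_size = 11L,
                             num_classes = 2L,
                             num_features = 11L,
                             num_informative = 4L,
                             class_sep = 0.6,
                             clusters_per_class = 2L,
                             protected_noise = 0.5,
                             homophily = 1,
                             gnn_layers = 3L,
                             attach_edges = 1.14,
                             connection_rounds = 1.10,
                             attach_power = 2,
                             seed = 1L) {
  motif <- make_motif(motif_shape)
  if (num_informative >= num_features)
    stop("num_informative must be < num_features (room for the protected feature)")
  if (length(motif$node_ids) > subgraph_size)
    stop("motif node count must not exceed subgraph_size")
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (connection_prob < 0 || connection_prob > 1)
    stop("connection_prob must be in [0, 1]")
  if (protected_noise < 0 || protected_noise > 1)
    stop("protected_noise must be in [0, 1]")
  if (attach_edges < 1) stop("attach_edges must be >= 1")
  structure(list(
    motif_shape = if (inherits(motif_shape, "motif_instance")) "custom" else motif_shape,
    motif = motif,
    num_subgraphs = as.integer(num_subgraphs),
    connection_prob = connection_prob,
    subgraph_size = as.integer(subgraph_size),
    num_classes = as.integer(num_classes),
    num_features = as.integer(num_features),
    num_informative = as.integer(num_informative),
    class_sep = class_sep,
    clusters_per_class = as.integer(clusters_per_class),
    protected_noise = protected_noise,
    homophily = homophily,
    gnn_layers = as.integer(gnn_layers),
    attach_edges = attach_edges,
    connection_rounds = connection_rounds,
    attach_power = attach_power,
    seed = as.integer(seed)
  ), class = "shapeggen_config")
}

#' Named generator presets
#'
#' Reference parameter sets for the six study configurations: the homophilic
#' baseline, its heterophilic twin, a small-explanation (triangle) variant,
#' a strongly unfair variant with biased protected feature, and variants
#' with a higher / lower proportion of informative features.
#'
#' @param name one of `"SG-Base"`, `"SG-Heterophilic"`, `"SG-SmallEx"`,
#'   `"SG-Unfair"`, `"SG-MoreInform"`, `"SG-LessInform"`.
#' @param seed RNG seed stored in the returned configuration.
#' @return a [shapeggen_config()].
#' @export
shapeggen_preset <- function(name, seed = 1L) {
  presets <- list(
    "SG-Base"        = list(),
    "SG-Heterophilic" = list(homophily = -1),
    "SG-SmallEx"     = list(motif_shape = "triangle", num_subgraphs = 1300L,
                            subgraph_size = 12L, class_sep = 0.5),
    "SG-Unfair"      = list(protected_noise = 0.75),
    "SG-MoreInform"  = list(num_informative = 8L),
    "SG-LessInform"  = list(num_features = 21L)
  )
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(presets), collapse = ", "))
  do.call(shapeggen_config, c(presets[[name]], list(seed = seed)))
}

#' Grow a preferential-attachment subgraph around a motif
#'
#' Draws `n' ~ Poisson(n_s - |motif|)` additional nodes and attaches each
#' sequentially to the existing local structure. Every grown node places
#' its first edge on a motif node (degree-proportional among motif nodes),
#' which guarantees a motif inside its 1-hop neighborhood; any further
#' attachment edges choose among all existing local nodes with probability
#' proportional to current degree, without replacement.
#'
#' @param template a [motif_instance()] with local ids `1..n`.
#' @param n_s expected subgraph size (must be at least the motif size).
#' @param m expected attachment edges per grown node; non-integer values
#'   mix `floor(m)` and `floor(m) + 1`.
#' @param pow preferential-attachment kernel exponent (attachment
#'   probability proportional to degree^`pow`); superlinear values
#'   concentrate attachments on hubs, giving the heavy-tailed degree
#'   distributions seen in real networks.
#' @return list with `num_nodes`, `edges` (undirected pairs, one row each),
#'   `motif_nodes`.
#' @export
grow_subgraph <- function(template, n_s, m = 1, pow = 1) {
  nm <- length(template$node_ids)
  if (n_s < nm) stop("n_s must be at least the motif size")
  edges <- template$edge_set
  n_new <- stats::rpois(1L, max(0, n_s - nm))
  n <- nm
  deg <- tabulate(c(edges), nbins = nm + n_new)
  if (n_new > 0L) {
    m_lo <- floor(m)
    p_hi <- m - m_lo
    new_edges <- vector("list", n_new)
    for (i in seq_len(n_new)) {
      v <- n + 1L
      mi <- m_lo + (stats::runif(1L) < p_hi)
      mi <- min(mi, n)
      first <- sample_weighted(template$node_ids, deg[template$node_ids], pow)
      targets <- first
      while (length(targets) < mi) {
        cand <- setdiff(seq_len(n), targets)
        targets <- c(targets, sample_weighted(cand, deg[cand], pow))
      }
      new_edges[[i]] <- cbind(targets, rep.int(v, length(targets)))
      deg[targets] <- deg[targets] + 1L
      deg[v] <- length(targets)
      n <- v
    }
    edges <- rbind(edges, do.call(rbind, new_edges))
  }
  storage.mode(edges) <- "integer"
  list(num_nodes = n, edges = edges, motif_nodes = template$node_ids)
}

# degree-proportional sampling of one element (degree 0 treated as 1);
# `pow` is the preferential-attachment kernel exponent
sample_weighted <- function(ids, w, pow = 1) {
  if (length(ids) == 1L) return(ids)
  w <- pmax(w, 1)^pow
  ids[sample.int(length(ids), 1L, prob = w)]
}

#' Assemble subgraphs into one graph with sparse inter-subgraph wiring
#'
#' Local subgraphs are relabeled into a global id space. Each unordered
#' subgraph pair is selected with probability `p`; a selected pair is wired
#' so that exactly one node on each side gains a second motif in its 1-hop
#' neighborhood: a peripheral (non-motif) node with spare motif capacity is
#' linked to a motif node of the partner; when a side's periphery is
#' exhausted, a free motif node substitutes, in which case a single
#' motif-to-motif edge serves both sides. Candidate edges that would push
#' any node beyond `K` motifs are rejected, so every node ends with between
#' 1 and `K` motifs in its closed neighborhood (verified by a final sweep).
#'
#' @param subgraphs list of grown subgraphs from [grow_subgraph()].
#' @param p connection probability per unordered subgraph pair.
#' @param K maximum number of motifs in a closed 1-hop neighborhood.
#' @param shape_name motif shape token recorded in the motif registry.
#' @param rounds expected granting rounds per selected pair (non-integer
#'   values mix one and two rounds).
#' @return a [synthetic_graph()] with empty features/labels (filled in by
#'   the caller) and the motif registry populated.
#' @export
connect_subgraphs <- function(subgraphs, p, K, shape_name = "motif",
                              rounds = 1) {
  ns <- length(subgraphs)
  if (ns < 2L) stop("need at least two subgraphs")
  sizes <- vapply(subgraphs, `[[`, integer(1L), "num_nodes")
  offsets <- c(0L, cumsum(sizes))[seq_len(ns)]
  total <- sum(sizes)

  edge_blocks <- vector("list", ns)
  motifs <- vector("list", ns)
  motif_of_sub <- vector("list", ns)   # global motif node ids per subgraph
  periph_of_sub <- vector("list", ns)
  for (i in seq_len(ns)) {
    sg <- subgraphs[[i]]
    ge <- sg$edges + offsets[i]
    edge_blocks[[i]] <- ge
    mnodes <- sg$motif_nodes + offsets[i]
    medges <- sg$edges[sg$edges[, 1L] %in% sg$motif_nodes &
                       sg$edges[, 2L] %in% sg$motif_nodes, , drop = FALSE] +
      offsets[i]
    motifs[[i]] <- motif_instance(shape_name, mnodes, medges)
    motif_of_sub[[i]] <- mnodes
    periph_of_sub[[i]] <- setdiff(seq_len(sg$num_nodes) + offsets[i], mnodes)
  }
  und <- do.call(rbind, edge_blocks)
  deg <- tabulate(c(und), nbins = total)

  # number of external motifs already granted to each node (own motif not counted)
  extra <- integer(total)
  cap <- K - 1L

  npairs <- ns * (ns - 1L) / 2L
  hit <- which(stats::runif(npairs) < p)
  inter <- vector("list", 2L * length(hit))
  n_inter <- 0L
  if (length(hit) > 0L) {
    # map linear index over unordered pairs (column-major upper triangle)
    j <- ceiling((sqrt(8 * hit + 1) + 1) / 2)
    i <- hit - (j - 1L) * (j - 2L) / 2L
    pick1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]
    for (k in seq_along(hit)) {
      a <- i[k]; b <- j[k]
      n_rounds <- 1L + (stats::runif(1L) < (rounds - 1))
      for (round in seq_len(n_rounds)) {
      pa <- periph_of_sub[[a]][extra[periph_of_sub[[a]]] < cap]
      pb <- periph_of_sub[[b]][extra[periph_of_sub[[b]]] < cap]
      ma_free <- motif_of_sub[[a]][extra[motif_of_sub[[a]]] < cap]
      mb_free <- motif_of_sub[[b]][extra[motif_of_sub[[b]]] < cap]
      new_e <- NULL
      if (length(pa) > 0L && length(pb) > 0L) {
        # one peripheral node per side linked to a motif node of the partner
        # (the motif target itself gains nothing: the source is non-motif)
        xa <- pick1(pa); xb <- pick1(pb)
        ta <- sample_weighted(motif_of_sub[[b]], deg[motif_of_sub[[b]]])
        tb <- sample_weighted(motif_of_sub[[a]], deg[motif_of_sub[[a]]])
        new_e <- rbind(c(xa, ta), c(xb, tb))
        extra[c(xa, xb)] <- extra[c(xa, xb)] + 1L
      } else if (length(ma_free) > 0L && length(mb_free) > 0L) {
        # periphery exhausted on a side: a single motif-to-motif edge grants
        # one motif to each endpoint and serves both sides at once
        xa <- sample_weighted(ma_free, deg[ma_free])
        xb <- sample_weighted(mb_free, deg[mb_free])
        new_e <- rbind(c(xa, xb))
        extra[c(xa, xb)] <- extra[c(xa, xb)] + 1L
      } else if (length(pa) > 0L) {
        # partner saturated: grant this side only
        xa <- pick1(pa)
        ta <- sample_weighted(motif_of_sub[[b]], deg[motif_of_sub[[b]]])
        new_e <- rbind(c(xa, ta))
        extra[xa] <- extra[xa] + 1L
      } else if (length(pb) > 0L) {
        xb <- pick1(pb)
        tb <- sample_weighted(motif_of_sub[[a]], deg[motif_of_sub[[a]]])
        new_e <- rbind(c(xb, tb))
        extra[xb] <- extra[xb] + 1L
      }
      if (!is.null(new_e)) {
        n_inter <- n_inter + 1L
        inter[[n_inter]] <- new_e
        deg[c(new_e)] <- deg[c(new_e)] + 1L
      }
      }
    }
  }
  und <- rbind(und, do.call(rbind, inter[seq_len(n_inter)]))
  # drop accidental duplicates (two events picking the same node pair)
  key <- paste(pmin(und[, 1L], und[, 2L]), pmax(und[, 1L], und[, 2L]))
  und <- und[!duplicated(key), , drop = FALSE]
  edges <- rbind(und, und[, 2:1, drop = FALSE])
  storage.mode(edges) <- "integer"

  g <- synthetic_graph(edges, total,
                       features = matrix(0, total, 0L),
                       labels = integer(total),
                       motifs = motifs)
  enforce_motif_cap(g, K)
}

# final sweep: remove inter-motif edges whose endpoints exceed K motifs
enforce_motif_cap <- function(graph, K) {
  counts <- motif_counts_all(graph)
  if (any(counts == 0L))
    stop("internal consistency error: node without a motif in its neighborhood")
  over <- which(counts > K)
  if (length(over) == 0L) return(graph)
  # remove, for each offending node, external edges to motif nodes until
  # the count falls back to K
  nm <- node_motif_ids(graph)
  own <- vapply(nm, function(x) if (length(x)) x[1L] else 0L, integer(1L))
  e <- graph$edges
  drop <- rep(FALSE, nrow(e))
  for (v in over) {
    excess <- counts[v] - K
    cand <- which(e[, 1L] == v & own[e[, 2L]] != 0L & own[e[, 2L]] != own[v])
    cand <- cand[seq_len(min(excess, length(cand)))]
    for (ci in cand) {
      u <- e[ci, 2L]
      drop[ci] <- TRUE
      drop[e[, 1L] == u & e[, 2L] == v] <- TRUE
    }
  }
  graph$edges <- e[!drop, , drop = FALSE]
  graph
}

#' Assign labels from motif counts
#'
#' The node label is the number of motifs in the closed 1-hop neighborhood
#' minus one, clipped to `0..K-1`. Deterministic given the graph.
#'
#' @param graph a [synthetic_graph()] with registered motifs.
#' @param K number of classes.
#' @return integer label vector.
#' @export
assign_labels <- function(graph, K) {
  counts <- motif_counts_all(graph)
  if (any(counts == 0L))
    stop("every node must have at least one motif in its closed neighborhood")
  pmin(counts - 1L, K - 1L)
}

#' Generate a full synthetic dataset
#'
#' Runs the whole pipeline: grow `N_s` motif-seeded subgraphs, wire them,
#' assign labels, draw informative/redundant/protected features, apply the
#' homophily adjustment, build per-node ground-truth explanations over the
#' `L`-hop enclosing subgraphs, and draw a stratified 70/5/25
#' train/validation/test split. Fully deterministic given `config$seed`.
#'
#' @param config a [shapeggen_config()].
#' @param ground_truth build the per-node ground-truth explanation registry
#'   (default `TRUE`; structure-only studies can skip it).
#' @return an object of class `shapeggen_dataset` with fields `graph`,
#'   `ground_truth` (list over nodes, or `NULL`), `config`, `split`.
#' @export
generate_dataset <- function(config, ground_truth = TRUE) {
  set.seed(config$seed)
  subgraphs <- lapply(seq_len(config$num_subgraphs), function(i)
    grow_subgraph(config$motif, config$subgraph_size, config$attach_edges,
                  config$attach_power))
  graph <- connect_subgraphs(subgraphs, config$connection_prob,
                             config$num_classes,
                             shape_name = config$motif$shape_name,
                             rounds = config$connection_rounds)
  graph$labels <- assign_labels(graph, config$num_classes)
  inform <- generate_informative_features(graph$labels,
                                          config$num_informative,
                                          config$class_sep,
                                          config$clusters_per_class,
                                          config$num_classes)
  feat <- add_redundant_and_protected(inform$features, graph$labels,
                                      config$num_features,
                                      config$num_informative,
                                      config$protected_noise)
  graph$features <- feat$features
  graph$informative_idx <- feat$informative_idx
  graph$protected_idx <- feat$protected_idx
  graph$redundant_idx <- feat$redundant_idx
  graph$features <- apply_homophily(graph, graph$features,
                                    config$homophily, feat$redundant_idx)
  gt <- NULL
  if (ground_truth)
    gt <- build_ground_truth(graph, config$gnn_layers, feat$informative_idx)
  split <- split_dataset(graph$labels, c(0.7, 0.05, 0.25))
  structure(list(graph = graph, ground_truth = gt, config = config,
                 split = split),
            class = "shapeggen_dataset")
}

#' @export
print.shapeggen_dataset <- function(x, ...) {
  g <- x$graph
  cat(sprintf(paste0("shapeggen_dataset: %d nodes, %d directed edges, ",
                     "%d classes, %d features (%d informative)\n"),
              g$num_nodes, nrow(g$edges), x$config$num_classes,
              ncol(g$features), length(g$informative_idx)))
  invisible(x)
}

#' Summary statistics of a generated dataset
#'
#' Node and directed-edge counts, average node degree (directed edges per
#' node) and per-class node counts.
#'
#' @param dataset a `shapeggen_dataset`.
#' @return a named list of statistics.
#' @export
dataset_stats <- function(dataset) {
  g <- dataset$graph
  cls <- table(factor(g$labels, levels = 0:(dataset$config$num_classes - 1L)))
  list(nodes = g$num_nodes,
       directed_edges = nrow(g$edges),
       average_degree = nrow(g$edges) / g$num_nodes,
       class_counts = as.integer(cls),
       num_features = ncol(g$features))
}
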