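# Dataset serialization. A bundle directory holds: edges.tsv (directed
# pairs, both orientations), graph.graphml, features.csv, labels.csv,
# split.csv, masks.json and config.json. Node ids are 0-based contiguous
# integers in every file (and converted to R's 1-based ids in memory).

bundle_files <- c(edges = "edges.tsv", graphml = "graph.graphml",
                  features = "features.csv", labels = "labels.csv",
                  split = "split.csv", masks = "masks.json",
                  config = "config.json")

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a dataset bundle to a directory
#'
#' Emits the edge list (TSV, one row per orientation), a GraphML file with
#' labels and feature vectors as node attributes, the feature matrix
#' (CSV with informative/protected/redundant flags in the header row),
#' labels, the train/val/test split, the ground-truth masks (JSON) and the
#' generator configuration (JSON). Numeric values are written with enough
#' digits to round-trip exactly.
#'
#' @param dataset a `shapeggen_dataset`.
#' @param out_dir output directory (created if missing).
#' @return named vector of written file paths, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- dataset$graph
  paths <- file.path(out_dir, bundle_files)
  names(paths) <- names(bundle_files)

  utils::write.table(data.frame(source = g$edges[, 1L] - 1L,
                                target = g$edges[, 2L] - 1L),
                     paths[["edges"]], sep = "\t", row.names = FALSE,
                     quote = FALSE)

  ig <- igraph::graph_from_edgelist(unique_undirected(g$edges),
                                    directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, g$num_nodes - igraph::vcount(ig)))
  igraph::V(ig)$label <- g$labels
  for (j in seq_len(ncol(g$features)))
    ig <- igraph::set_vertex_attr(ig, paste0("x", j - 1L),
                                  value = g$features[, j])
  igraph::write_graph(ig, paths[["graphml"]], format = "graphml")

  flags <- rep("redundant", ncol(g$features))
  flags[g$informative_idx] <- "informative"
  flags[g$protected_idx] <- "protected"
  feat_chr <- apply(g$features, 2L, fmt_num)
  feat_chr <- matrix(feat_chr, nrow = g$num_nodes)
  colnames(feat_chr) <- paste0("x", seq_len(ncol(g$features)) - 1L, ":", flags)
  utils::write.csv(feat_chr, paths[["features"]], row.names = FALSE,
                   quote = FALSE)

  utils::write.csv(data.frame(node = seq_len(g$num_nodes) - 1L,
                              label = g$labels),
                   paths[["labels"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(node = seq_len(g$num_nodes) - 1L,
                              split = as.character(dataset$split)),
                   paths[["split"]], row.names = FALSE, quote = FALSE)

  masks <- structure(list(), names = character(0))
  if (!is.null(dataset$ground_truth)) {
    masks <- lapply(dataset$ground_truth, function(gt) {
      list(nodes = gt$node_ids - 1L,
           edges = if (nrow(gt$edges)) unname(gt$edges - 1L) else list(),
           motif_ids = gt$motif_ids,
           node_masks = lapply(gt$masks, function(m) m$node_scores),
           feature_mask = gt$masks[[1L]]$feature_scores,
           edge_masks = lapply(gt$masks, function(m) m$edge_scores))
    })
    names(masks) <- as.character(seq_along(masks) - 1L)
  }
  jsonlite::write_json(masks, paths[["masks"]], digits = NA, null = "null")

  cfg <- dataset$config
  cfg_out <- if (inherits(cfg, "shapeggen_config"))
    list(S = cfg$motif_shape, N_s = cfg$num_subgraphs,
         p = cfg$connection_prob, n_s = cfg$subgraph_size,
         K = cfg$num_classes, n_f = cfg$num_features,
         n_i = cfg$num_informative, s_f = cfg$class_sep,
         c_f = cfg$clusters_per_class, phi = cfg$protected_noise,
         eta = cfg$homophily, L = cfg$gnn_layers,
         m = cfg$attach_edges, seed = cfg$seed)
  else cfg
  jsonlite::write_json(cfg_out, paths[["config"]], digits = NA,
                       auto_unbox = TRUE)
  invisible(paths)
}

unique_undirected <- function(edges) {
  und <- edges[edges[, 1L] < edges[, 2L], , drop = FALSE]
  und[order(und[, 1L], und[, 2L]), , drop = FALSE]
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' Reconstructs the dataset and validates the structural invariants
#' (symmetric edge list, matching lengths), failing with an error that
#' names the offending file.
#'
#' @param in_dir bundle directory.
#' @return a `shapeggen_dataset`.
#' @export
read_dataset <- function(in_dir) {
  paths <- file.path(in_dir, bundle_files)
  names(paths) <- names(bundle_files)
  for (nm in setdiff(names(paths), "graphml"))
    if (!file.exists(paths[[nm]]))
      stop("missing bundle file: ", paths[[nm]])

  ed <- utils::read.table(paths[["edges"]], sep = "\t", header = TRUE)
  if (!identical(names(ed), c("source", "target")))
    stop("schema mismatch in ", paths[["edges"]],
         ": expected columns source, target")
  edges <- as.matrix(ed) + 1L

  fe <- utils::read.csv(paths[["features"]], check.names = FALSE)
  flags <- sub("^x[0-9]+:", "", names(fe))
  features <- as.matrix(fe)
  dimnames(features) <- NULL
  n <- nrow(features)

  la <- utils::read.csv(paths[["labels"]])
  if (nrow(la) != n)
    stop("schema mismatch: ", paths[["labels"]],
         " row count differs from features.csv")
  labels <- la$label[order(la$node)]

  sp <- utils::read.csv(paths[["split"]])
  split <- factor(sp$split[order(sp$node)], levels = c("train", "val", "test"))

  key <- paste(edges[, 1L], edges[, 2L])
  if (!all(paste(edges[, 2L], edges[, 1L]) %in% key))
    stop("validation error in ", paths[["edges"]],
         ": edge list is not symmetric")

  cfg <- jsonlite::read_json(paths[["config"]], simplifyVector = TRUE)
  config <- if (all(c("S", "N_s", "n_s") %in% names(cfg)))
    shapeggen_config(motif_shape = cfg$S, num_subgraphs = cfg$N_s,
                     connection_prob = cfg$p, subgraph_size = cfg$n_s,
                     num_classes = cfg$K, num_features = cfg$n_f,
                     num_informative = cfg$n_i, class_sep = cfg$s_f,
                     clusters_per_class = cfg$c_f, protected_noise = cfg$phi,
                     homophily = cfg$eta, gnn_layers = cfg$L,
                     attach_edges = cfg$m, seed = cfg$seed)
  else cfg

  mj <- jsonlite::read_json(paths[["masks"]], simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  gt <- NULL
  motifs <- list()
  if (length(mj) > 0L) {
    gt <- lapply(mj, function(e) {
      node_ids <- unlist(e$nodes) + 1L
      edm <- if (length(e$edges))
        matrix(unlist(e$edges), ncol = 2L, byrow = TRUE) + 1L
      else matrix(integer(0), ncol = 2L)
      fmask <- as.numeric(unlist(e$feature_mask))
      masks <- lapply(seq_along(e$node_masks), function(k)
        explanation_mask(as.numeric(unlist(e$node_masks[[k]])), fmask,
                         as.numeric(unlist(e$edge_masks[[k]])),
                         kind = "ground_truth"))
      ground_truth_set(masks, node_ids, edm,
                       motif_ids = as.integer(unlist(e$motif_ids)))
    })
    # rebuild the motif registry from the masks
    mid_max <- max(c(0L, unlist(lapply(gt, `[[`, "motif_ids"))))
    if (mid_max > 0L) {
      motifs <- vector("list", mid_max)
      for (v in seq_along(gt)) {
        e <- gt[[v]]
        for (k in seq_along(e$motif_ids)) {
          mi <- e$motif_ids[k]
          mem <- e$node_ids[e$masks[[k]]$node_scores == 1]
          motifs[[mi]] <- unique(c(motifs[[mi]], mem))
        }
      }
      edge_key <- paste(edges[, 1L], edges[, 2L])
      motifs <- lapply(motifs, function(mem) {
        mem <- sort(mem)
        prs <- expand.grid(a = mem, b = mem)
        prs <- prs[prs$a < prs$b, , drop = FALSE]
        keep <- paste(prs$a, prs$b) %in% edge_key
        motif_instance("motif", mem,
                       as.matrix(prs[keep, c("a", "b"), drop = FALSE]))
      })
    }
  }

  inform_idx <- which(flags == "informative")
  prot_idx <- which(flags == "protected")
  red_idx <- which(flags == "redundant")
  graph <- synthetic_graph(edges, n, features, labels, motifs = motifs,
                           informative_idx = inform_idx,
                           protected_idx = prot_idx,
                           redundant_idx = red_idx)
  structure(list(graph = graph, ground_truth = gt, config = config,
                 split = split),
            class = "shapeggen_dataset")
}

#' Write a metric result table
#'
#' Flat TSV with columns `node_id`, `metric`, `value` (node ids 0-based).
#'
#' @param results data.frame with those columns (1-based node ids).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(results, path) {
  out <- data.frame(node_id = results$node_id - 1L,
                    metric = results$metric,
                    value = fmt_num(results$value))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
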