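# Inter-process relations: cross-set interaction counts contrasted against a
# null of two random node sets of matching sizes, and the pathway-landscape
# relation graph (shared genes + cross-boundary interactions).

#' Count interactions between two disjoint gene sets
#'
#' @param network `igraph` network.
#' @param set_a,set_b disjoint subsets of the network's nodes.
#' @return integer number of edges with one endpoint in each set.
#' @export
cross_edge_count <- function(network, set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (length(intersect(set_a, set_b)) > 0L) {
    stop_contract("set_a and set_b must be disjoint")
  }
  nodes <- igraph::V(network)$name
  if (!all(set_a %in% nodes) || !all(set_b %in% nodes)) {
    stop_contract("both sets must be subsets of the network nodes")
  }
  el <- igraph::as_edgelist(network, names = TRUE)
  if (nrow(el) == 0L) return(0L)
  in_a1 <- el[, 1L] %in% set_a
  in_b1 <- el[, 1L] %in% set_b
  in_a2 <- el[, 2L] %in% set_a
  in_b2 <- el[, 2L] %in% set_b
  sum((in_a1 & in_b2) | (in_b1 & in_a2))
}

# fast path used in permutation loops: integer-indexed sparse adjacency
cross_count_adj <- function(adj, ia, ib) {
  as.integer(sum(adj[ia, ib, drop = FALSE]))
}

#' Permutation significance of an inter-set interaction count
#'
#' The observed number of interactions between the two sets is contrasted
#' against the counts between two disjoint random node sets of matching
#' sizes, sampled uniformly without replacement from `universe`. The
#' empirical p-value uses the add-one correction
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)` and can never be 0.
#'
#' @param network `igraph` network.
#' @param set_a,set_b disjoint gene sets (subsets of the network nodes).
#' @param universe nodes to sample null sets from; defaults to all network
#'   nodes. Must hold at least `|set_a| + |set_b|` nodes.
#' @param n_perm number of null draws.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return a one-row data.frame (`relation_stat`): `observed`, `null_mean`,
#'   `null_sd`, `z` (NA when `null_sd` is 0), `p_empirical`, `n_perm`,
#'   `seed`.
#' @export
relation_significance <- function(network, set_a, set_b,
                                  universe = igraph::V(network)$name,
                                  n_perm = 999L, seed = 1L) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  if (length(universe) < length(set_a) + length(set_b)) {
    stop_contract("universe (%d) smaller than |set_a| + |set_b| (%d)",
                  length(universe), length(set_a) + length(set_b))
  }
  observed <- cross_edge_count(network, set_a, set_b)
  adj <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  uni_idx <- match(universe, igraph::V(network)$name)
  if (anyNA(uni_idx)) stop_contract("universe must be a subset of network nodes")
  na <- length(set_a)
  nb <- length(set_b)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      draw <- sample(uni_idx, na + nb, replace = FALSE)
      cross_count_adj(adj, draw[seq_len(na)], draw[na + seq_len(nb)])
    }, 0L)
  })
  null_sd <- stats::sd(null_counts)
  data.frame(
    observed = observed,
    null_mean = mean(null_counts),
    null_sd = null_sd,
    z = if (is.na(null_sd) || null_sd == 0) NA_real_ else
      (observed - mean(null_counts)) / null_sd,
    p_empirical = (1 + sum(null_counts >= observed)) / (n_perm + 1),
    n_perm = as.integer(n_perm),
    seed = as.integer(seed)
  )
}

#' Score all inter-segment relations of a process model
#'
#' Every unordered segment pair receives a permutation relation statistic;
#' p-values are Benjamini-Hochberg adjusted across the pairs and relations
#' with `q <= alpha` are flagged significant. Edge weights for rendering are
#' the observed cross-interaction counts.
#'
#' @param model a [process_model()].
#' @param network network to count and sample in; defaults to the model
#'   substrate.
#' @param universe_mode `"substrate"` (nodes of the isolate-free induced
#'   subgraph) or `"full_network"`.
#' @param n_perm,seed,alpha permutation and decision settings.
#' @return the model with `relations` filled: data.frame with `id_a`, `id_b`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `p_empirical`, `q`,
#'   `significant`.
#' @export
score_model_relations <- function(model, network = NULL,
                                  universe_mode = c("substrate", "full_network"),
                                  n_perm = 999L, seed = 1L, alpha = 0.05) {
  stopifnot(inherits(model, "process_model"))
  universe_mode <- match.arg(universe_mode)
  g <- network %||% model$substrate
  universe <- if (universe_mode == "substrate") {
    igraph::V(model$substrate)$name
  } else {
    igraph::V(g)$name
  }
  segs <- model$segments
  if (length(segs) < 2L) {
    model$relations <- data.frame(
      id_a = integer(), id_b = integer(), observed = integer(),
      null_mean = numeric(), null_sd = numeric(), z = numeric(),
      p_empirical = numeric(), q = numeric(), significant = logical()
    )
    return(model)
  }
  pairs <- utils::combn(seq_along(segs), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]
    j <- pairs[2L, k]
    st <- relation_significance(
      g, segs[[i]]$genes, segs[[j]]$genes, universe = universe,
      n_perm = n_perm, seed = derive_seed(seed, sprintf("pair_%d_%d", i, j))
    )
    cbind(data.frame(id_a = segs[[i]]$segment_id,
                     id_b = segs[[j]]$segment_id), st)
  })
  rel <- do.call(rbind, rows)
  rel$q <- stats::p.adjust(rel$p_empirical, method = "BH")
  rel$significant <- rel$q <= alpha
  model$relations <- rel
  model
}

#' Pathway landscape relation graph
#'
#' For every pathway pair, counts the shared genes and the interactions
#' spanning the pathway boundary. Shared genes are excluded from both sides
#' before counting cross-boundary edges, so the two criteria stay separate.
#' A relation is emitted when `shared_genes >= min_shared` or
#' `cross_edges >= min_cross`.
#'
#' @param pathways named list of pathway annotations (see [read_gmt()]).
#' @param network `igraph` network used for cross-boundary interactions.
#' @param min_shared,min_cross emission thresholds.
#' @return data.frame with `id_a`, `id_b`, `shared_genes`, `cross_edges`.
#' @export
pathway_landscape <- function(pathways, network, min_shared = 1L,
                              min_cross = 1L) {
  ids <- names(pathways)
  nodes <- igraph::V(network)$name
  sets <- lapply(pathways, function(p) intersect(p$genes, nodes))
  out <- list()
  if (length(ids) >= 2L) {
    pairs <- utils::combn(seq_along(ids), 2L)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]
      j <- pairs[2L, k]
      shared_all <- length(intersect(pathways[[i]]$genes, pathways[[j]]$genes))
      a <- setdiff(sets[[i]], sets[[j]])
      b <- setdiff(sets[[j]], sets[[i]])
      cross <- cross_edge_count(network, a, b)
      if (shared_all >= min_shared || cross >= min_cross) {
        out[[length(out) + 1L]] <- data.frame(
          id_a = ids[[i]], id_b = ids[[j]],
          shared_genes = shared_all, cross_edges = cross,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      shared_genes = integer(), cross_edges = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write model relations as TSV
#' @param model a scored [process_model()].
#' @param path output path.
#' @param header provenance comment lines.
#' @return the path, invisibly.
#' @export
write_relations_tsv <- function(model, path, header = character()) {
  rel <- model$relations
  if (is.null(rel)) stop_contract("model relations have not been scored")
  write_tsv_report(rel, path, header)
}
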