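# MCODE-style segmentation of a signature-induced subgraph into molecular
# process segments.
#
# Scoring follows the k-core vertex-weighting scheme: each vertex is weighted
# by k * density of the highest k-core of the graph induced on its closed
# neighbourhood. Segments are grown greedily from the highest-weighted unused
# seed, admitting neighbours whose weight is within the vertex weight
# percentage (VWP) of the seed weight and whose own highest-core set is
# already reached by the segment (see the methods vignette for why this core
# reachability condition is part of the growth rule).

#' MCODE segmentation parameters
#'
#' Canonical defaults of the k-core vertex-weighting segmentation: loops
#' excluded, degree cutoff 2, node score cutoff (VWP) 0.2, k-core filter 2,
#' maximum growth depth 100, haircut on, fluff off (fluff density 0.1).
#'
#' @param include_loops ignored for scoring (networks are loop-free by
#'   construction); kept for interface completeness.
#' @param degree_cutoff vertices of lower degree score 0 (integer >= 1).
#' @param node_score_cutoff VWP growth tolerance, fraction in `[0, 1)`:
#'   a neighbour may join when its score is at least
#'   `seed_score * (1 - node_score_cutoff)`.
#' @param k_core_filter discard grown segments containing no k-core of this
#'   order.
#' @param max_depth breadth-first growth depth limit.
#' @param haircut reduce each kept segment to its 2-core.
#' @param fluff add unassigned neighbours whose closed-neighbourhood density
#'   exceeds `fluff_density`.
#' @param fluff_density density threshold for fluff.
#' @return a `mcode_params` list.
#' @export
mcode_params <- function(include_loops = FALSE, degree_cutoff = 2L,
                         node_score_cutoff = 0.2, k_core_filter = 2L,
                         max_depth = 100L, haircut = TRUE, fluff = FALSE,
                         fluff_density = 0.1) {
  if (degree_cutoff < 1L) stop_contract("degree_cutoff must be >= 1")
  if (node_score_cutoff < 0 || node_score_cutoff >= 1) {
    stop_contract("node_score_cutoff must be in [0, 1)")
  }
  structure(list(include_loops = isTRUE(include_loops),
                 degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core_filter = as.integer(k_core_filter),
                 max_depth = as.integer(max_depth),
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_density = fluff_density),
            class = "mcode_params")
}

#' Signature-induced subgraph extraction
#'
#' Restricts a network to the signature genes present in it and (optionally)
#' removes degree-zero nodes, i.e. signature genes with no interaction to any
#' other signature gene.
#'
#' @param network `igraph` network.
#' @param genes character vector of signature genes (or a
#'   [gene_signature()]).
#' @param drop_isolates remove degree-zero nodes from the subgraph.
#' @return the induced `igraph` with attribute `subgraph_report`: `signature`,
#'   `mapped` (genes found in the network), `isolates_removed`, `retained`.
#' @export
induced_signature_subgraph <- function(network, genes, drop_isolates = TRUE) {
  if (inherits(genes, "gene_signature")) genes <- genes$genes
  genes <- unique(as.character(genes))
  present <- intersect(genes, igraph::V(network)$name)
  sub <- igraph::induced_subgraph(network, present)
  n_iso <- 0L
  if (drop_isolates) {
    iso <- igraph::V(sub)$name[igraph::degree(sub) == 0L]
    n_iso <- length(iso)
    sub <- igraph::delete_vertices(sub, iso)
  }
  sub <- igraph::set_graph_attr(sub, "namespace", net_namespace(network))
  sub <- igraph::set_graph_attr(sub, "subgraph_report", list(
    signature = length(genes), mapped = length(present),
    isolates_removed = n_iso, retained = igraph::vcount(sub)
  ))
  sub
}

# Highest k-core of the graph induced on the closed neighbourhood of each
# vertex: returns per-vertex score, core order k and the core's vertex set.
mcode_core_info <- function(network, params) {
  verts <- igraph::V(network)$name
  deg <- igraph::degree(network)
  adj <- igraph::adjacent_vertices(network, igraph::V(network))
  adj <- lapply(adj, function(v) v$name)
  names(adj) <- verts
  info <- vector("list", length(verts))
  names(info) <- verts
  for (v in verts) {
    if (deg[[v]] < params$degree_cutoff) {
      info[[v]] <- list(score = 0, k = 0L, core = character())
      next
    }
    nb <- c(v, adj[[v]])
    sub <- igraph::induced_subgraph(network, nb)
    cores <- igraph::coreness(sub)
    k <- max(cores)
    core_v <- names(cores)[cores == k]
    ksub <- igraph::induced_subgraph(sub, core_v)
    n <- igraph::vcount(ksub)
    dens <- if (n > 1L) 2 * igraph::ecount(ksub) / (n * (n - 1)) else 0
    info[[v]] <- list(score = k * dens, k = k, core = core_v)
  }
  info
}

#' MCODE vertex scores
#'
#' Vertices below the degree cutoff score 0; every other vertex scores
#' `k * density` of the highest k-core of the graph induced on its closed
#' neighbourhood (density `2|E| / (|V| (|V|-1))`, loops excluded).
#'
#' @param network simple undirected `igraph`.
#' @param params [mcode_params()].
#' @return named numeric vector of scores.
#' @export
mcode_score_vertices <- function(network, params = mcode_params()) {
  info <- mcode_core_info(network, params)
  vapply(info, `[[`, 0, "score")
}

#' Grow MCODE process segments from vertex scores
#'
#' Greedy seeding on the highest-scoring unassigned vertex (ties broken
#' lexicographically). Breadth-first growth up to `max_depth` adds an
#' unassigned, not-yet-checked neighbour `u` when
#' `score(u) >= seed_score * (1 - node_score_cutoff)` and the growing segment
#' already contains a vertex of `u`'s own highest-core set (core
#' reachability, which keeps growth from leaking across sparse bridges
#' between dense regions). Post-processing discards segments without a
#' `k_core_filter`-core, optionally trims each segment to its 2-core
#' (haircut) and optionally adds dense unassigned neighbours (fluff).
#' Segments are ordered by size (descending), then by seed identifier.
#'
#' @param network simple undirected `igraph`.
#' @param params [mcode_params()].
#' @param scores optional precomputed vertex scores covering all vertices
#'   (recomputed when missing).
#' @return list of segments, each a list with `segment_id`, `genes` (sorted),
#'   `seed` and `seed_score`.
#' @export
mcode_segments <- function(network, params = mcode_params(), scores = NULL) {
  n <- igraph::vcount(network)
  if (n == 0L || igraph::ecount(network) == 0L) return(list())
  info <- mcode_core_info(network, params)
  sc <- vapply(info, `[[`, 0, "score")
  if (!is.null(scores)) {
    if (!all(igraph::V(network)$name %in% names(scores))) {
      stop_contract("scores must cover all vertices")
    }
    sc <- scores[names(sc)]
  }
  verts <- igraph::V(network)$name
  adj <- igraph::adjacent_vertices(network, igraph::V(network))
  adj <- lapply(adj, function(v) sort(v$name))
  names(adj) <- verts
  assigned <- stats::setNames(rep(FALSE, length(verts)), verts)
  order_idx <- order(-sc[verts], verts)
  raw_segments <- list()
  for (seed in verts[order_idx]) {
    if (assigned[[seed]]) next
    seed_score <- sc[[seed]]
    threshold <- seed_score * (1 - params$node_score_cutoff)
    members <- seed
    assigned[[seed]] <- TRUE
    checked <- stats::setNames(rep(FALSE, length(verts)), verts)
    checked[[seed]] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) > 0L && depth < params$max_depth) {
      nxt <- character()
      for (x in frontier) {
        for (u in adj[[x]]) {
          if (checked[[u]] || assigned[[u]]) next
          checked[[u]] <- TRUE
          if (sc[[u]] < threshold) next
          core_u <- setdiff(info[[u]]$core, u)
          if (length(intersect(core_u, members)) == 0L) next
          members <- c(members, u)
          assigned[[u]] <- TRUE
          nxt <- c(nxt, u)
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    raw_segments[[length(raw_segments) + 1L]] <-
      list(seed = seed, seed_score = seed_score, members = members)
  }
  # post-processing: k-core filter, haircut, fluff
  segments <- list()
  for (seg in raw_segments) {
    sub <- igraph::induced_subgraph(network, seg$members)
    cores <- igraph::coreness(sub)
    if (max(c(cores, 0L)) < params$k_core_filter) {
      for (m in seg$members) assigned[[m]] <- FALSE
      next
    }
    members <- seg$members
    if (params$haircut) {
      two_core <- names(cores)[cores >= 2L]
      dropped <- setdiff(members, two_core)
      for (m in dropped) assigned[[m]] <- FALSE
      members <- two_core
    }
    segments[[length(segments) + 1L]] <-
      list(seed = seg$seed, seed_score = seg$seed_score, members = members)
  }
  if (params$fluff) {
    nb_density <- vapply(verts, function(v) {
      nb <- c(v, adj[[v]])
      m <- length(nb)
      if (m < 2L) return(0)
      2 * igraph::ecount(igraph::induced_subgraph(network, nb)) / (m * (m - 1))
    }, 0)
    for (i in seq_along(segments)) {
      cand <- setdiff(unique(unlist(adj[segments[[i]]$members])),
                      segments[[i]]$members)
      cand <- cand[!assigned[cand] & nb_density[cand] > params$fluff_density]
      segments[[i]]$members <- c(segments[[i]]$members, sort(cand))
    }
  }
  sizes <- vapply(segments, function(s) length(s$members), 0L)
  seeds <- vapply(segments, `[[`, "", "seed")
  ord <- order(-sizes, seeds)
  segments <- segments[ord]
  lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    list(segment_id = i, genes = sort(s$members), seed = s$seed,
         seed_score = s$seed_score)
  })
}

#' Build a molecular process model
#'
#' Composes the three modelling steps: (i) mapping of a feature signature on
#' the interaction network followed by induced subgraph extraction with
#' removal of degree-zero nodes, (ii) MCODE-style segmentation into molecular
#' process segments, and (iii, separately via [score_model_relations()])
#' permutation scoring of inter-segment relations.
#'
#' @param network consolidated `igraph` interaction network.
#' @param signature gene set (character vector, [gene_signature()] or
#'   `consolidated_signature`).
#' @param params [mcode_params()].
#' @param name model label.
#' @return a `process_model`: list with `segments`, `substrate` (isolate-free
#'   induced subgraph), `relations` (`NULL` until scored), `params`, `name`
#'   and `report` (mapping and segmentation bookkeeping).
#' @export
process_model <- function(network, signature, params = mcode_params(),
                          name = "model") {
  if (inherits(signature, "consolidated_signature")) signature <- signature$genes
  if (inherits(signature, "gene_signature")) signature <- signature$genes
  substrate <- induced_signature_subgraph(network, signature,
                                          drop_isolates = TRUE)
  segments <- mcode_segments(substrate, params)
  rep0 <- igraph::graph_attr(substrate, "subgraph_report")
  in_segments <- sum(vapply(segments, function(s) length(s$genes), 0L))
  structure(list(
    name = name,
    segments = segments,
    substrate = substrate,
    relations = NULL,
    params = params,
    report = c(rep0, list(n_segments = length(segments),
                          genes_in_segments = in_segments))
  ), class = "process_model")
}

segment_sizes <- function(model) {
  vapply(model$segments, function(s) length(s$genes), 0L)
}

#' @export
print.process_model <- function(x, ...) {
  cat(sprintf("Molecular process model '%s'\n", x$name))
  cat(sprintf("  substrate: %d genes, %d interactions\n",
              igraph::vcount(x$substrate), igraph::ecount(x$substrate)))
  cat(sprintf("  segments: %d (genes in segments: %d)\n",
              length(x$segments), x$report$genes_in_segments))
  if (!is.null(x$relations)) {
    cat(sprintf("  relations: %d pairs scored, %d significant\n",
                nrow(x$relations), sum(x$relations$significant)))
  }
  invisible(x)
}

#' Summarise a process model
#'
#' @param object a `process_model`.
#' @param ... unused.
#' @return a `summary.process_model` with mapping counts, segment count,
#'   genes in segments, and the segment size median/min/max.
#' @export
summary.process_model <- function(object, ...) {
  sizes <- segment_sizes(object)
  out <- list(
    name = object$name,
    signature = object$report$signature,
    mapped = object$report$mapped,
    isolates_removed = object$report$isolates_removed,
    retained = object$report$retained,
    n_segments = length(object$segments),
    genes_in_segments = object$report$genes_in_segments,
    size_median = if (length(sizes)) stats::median(sizes) else NA_real_,
    size_min = if (length(sizes)) min(sizes) else NA_integer_,
    size_max = if (length(sizes)) max(sizes) else NA_integer_
  )
  class(out) <- "summary.process_model"
  out
}

#' @export
print.summary.process_model <- function(x, ...) {
  cat(sprintf("Molecular process model '%s'\n", x$name))
  cat(sprintf("  signature genes: %d, mapped: %d, isolates removed: %d, retained: %d\n",
              x$signature, x$mapped, x$isolates_removed, x$retained))
  cat(sprintf("  segments: %d; genes in segments: %d\n",
              x$n_segments, x$genes_in_segments))
  if (x$n_segments > 0L) {
    cat(sprintf("  segment sizes: median %.1f, min %d, max %d\n",
                x$size_median, x$size_min, x$size_max))
  }
  invisible(x)
}

# named vector gene -> segment_id for the substrate vertices (NA = none)
segment_membership <- function(model) {
  v <- igraph::V(model$substrate)$name
  out <- stats::setNames(rep(NA_integer_, length(v)), v)
  for (s in model$segments) out[s$genes] <- s$segment_id
  out
}

#' Plot a process model
#'
#' Draws the substrate with vertices coloured by segment membership
#' (unassigned vertices in grey).
#'
#' @param x a `process_model`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.process_model <- function(x, ...) {
  mem <- segment_membership(x)
  g <- x$substrate
  pal <- grDevices::hcl.colors(max(1L, length(x$segments)), "Dark 3")
  col <- ifelse(is.na(mem), "grey80", pal[mem])
  igraph::plot.igraph(g, vertex.color = col, vertex.size = 6,
                      vertex.label = NA, ...)
  invisible(x)
}

#' Write a process model as a TSV segment table (plus optional GraphML)
#'
#' The segment table holds one row per segment gene (segment_id, gene, seed
#' flag, seed score); the GraphML output is the substrate with a `segment`
#' vertex attribute.
#'
#' @param model a `process_model`.
#' @param path TSV output path.
#' @param graphml_path optional GraphML output path.
#' @param header provenance comment lines for the TSV.
#' @return the TSV path, invisibly.
#' @export
write_process_model <- function(model, path, graphml_path = NULL,
                                header = character()) {
  rows <- do.call(rbind, lapply(model$segments, function(s) {
    data.frame(segment_id = s$segment_id, gene = s$genes,
               is_seed = as.integer(s$genes == s$seed),
               seed_score = round(s$seed_score, 6), stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(segment_id = integer(), gene = character(),
                       is_seed = integer(), seed_score = numeric())
  }
  write_tsv_report(rows, path, header)
  if (!is.null(graphml_path)) {
    mem <- segment_membership(model)
    mem[is.na(mem)] <- 0L
    write_network_graphml(model$substrate, graphml_path,
                          vertex_attrs = list(segment = mem))
  }
  invisible(path)
}
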