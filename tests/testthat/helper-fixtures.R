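# Shared fixtures and independent oracles, built in code at test time.

# complete graph on the given vertex names
make_clique <- function(genes) {
  t(utils::combn(genes, 2L))
}

net_from_edges <- function(..., nodes = NULL, namespace = "synthetic") {
  interaction_network(rbind(...), nodes = nodes, namespace = namespace)
}

sig <- function(label, genes, provenance = "omics") {
  gene_signature(label, genes, provenance = provenance,
                 namespace = "synthetic", allow_empty = TRUE)
}

# Independent MCODE scoring oracle: exhaustive enumeration of all vertex
# subsets of the closed neighbourhood. The highest core order is the maximum
# over subsets of the induced minimum degree; the core itself is the union of
# all subsets attaining it (the maximal subgraph of that minimum degree).
oracle_mcode_scores <- function(g, degree_cutoff = 2L) {
  vs <- igraph::V(g)$name
  out <- stats::setNames(numeric(length(vs)), vs)
  for (v in vs) {
    if (igraph::degree(g, v) < degree_cutoff) next
    nb <- c(v, igraph::neighbors(g, v)$name)
    sub <- igraph::induced_subgraph(g, nb)
    sv <- igraph::V(sub)$name
    n <- length(sv)
    subsets <- unlist(lapply(2:n, function(m) {
      utils::combn(n, m, simplify = FALSE)
    }), recursive = FALSE)
    mindeg <- vapply(subsets, function(ix) {
      min(igraph::degree(igraph::induced_subgraph(sub, sv[ix])))
    }, 0)
    best_k <- max(mindeg)
    if (best_k == 0) next
    members <- unique(unlist(lapply(subsets[mindeg >= best_k],
                                    function(ix) sv[ix])))
    ks <- igraph::induced_subgraph(sub, members)
    nv <- igraph::vcount(ks)
    out[[v]] <- best_k * 2 * igraph::ecount(ks) / (nv * (nv - 1))
  }
  out
}

# segment membership vector over all network vertices, unassigned vertices
# as unique singleton labels (used for recovery scoring)
segment_labels <- function(segments, vertex_names) {
  mem <- stats::setNames(rep(NA_integer_, length(vertex_names)), vertex_names)
  for (s in segments) mem[s$genes] <- s$segment_id
  un <- is.na(mem)
  mem[un] <- 10000L + seq_len(sum(un))
  mem
}
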