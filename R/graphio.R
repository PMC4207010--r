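# Reading, identifier-mapping, merging and writing of interaction networks,
# pathway collections and mapping tables.
#
# Networks are undirected simple igraph objects whose vertex names are gene
# identifiers in a single namespace. The namespace travels as the graph
# attribute "namespace"; it is metadata, not validated against any registry.

#' Construct an interaction network from an edge table
#'
#' Builds an undirected simple graph: self-loops are dropped, duplicate and
#' reversed edges are collapsed. The simplification counts are attached as the
#' graph attribute `parse_report`.
#'
#' @param edges two-column character matrix or data.frame of interactor pairs.
#' @param nodes optional character vector of vertices to include even when
#'   isolated.
#' @param name network label.
#' @param namespace identifier namespace label (metadata only).
#' @return an undirected simple `igraph` with attributes `name`, `namespace`
#'   and `parse_report` (rows read, loops dropped, duplicates collapsed).
#' @export
interaction_network <- function(edges, nodes = NULL, name = "network",
                                namespace = "ensembl_gene") {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  storage.mode(edges) <- "character"
  if (ncol(edges) < 2L) stop_contract("edge table needs at least 2 columns")
  a <- check_gene_ids(edges[, 1L], "interactor identifiers")
  b <- check_gene_ids(edges[, 2L], "interactor identifiers")
  n_rows <- length(a)
  loop <- a == b
  a2 <- a[!loop]
  b2 <- b[!loop]
  lo <- pmin(a2, b2)
  hi <- pmax(a2, b2)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  lo <- lo[!dup]
  hi <- hi[!dup]
  verts <- sort(unique(c(lo, hi, as.character(nodes %||% character()))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = if (length(verts)) verts else NULL
  )
  g <- igraph::set_graph_attr(g, "name", name)
  g <- igraph::set_graph_attr(g, "namespace", namespace)
  g <- igraph::set_graph_attr(g, "parse_report", list(
    rows = n_rows, loops_dropped = sum(loop), duplicates_collapsed = sum(dup)
  ))
  g
}

net_namespace <- function(g) {
  igraph::graph_attr(g, "namespace") %||% "unknown"
}

#' Read an interaction table into a network
#'
#' Supports two dialects: `two_column` (TSV, first two columns are interactor
#' identifiers) and `psimitab` (PSI-MI-TAB-like TSV, interactors in columns
#' 1-2 with any `prefix:` before the identifier stripped). Lines starting with
#' `#` are ignored in both dialects.
#'
#' @param path file path.
#' @param format `"two_column"` or `"psimitab"`.
#' @inheritParams interaction_network
#' @return an undirected simple `igraph`; see [interaction_network()] for the
#'   attached parse report.
#' @export
read_interaction_table <- function(path, format = c("two_column", "psimitab"),
                                   name = basename(path),
                                   namespace = "ensembl_gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_contract("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(interaction_network(matrix(character(), ncol = 2L),
                               name = name, namespace = namespace))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 2L)) {
    bad <- line_no[which(n_fields < 2L)[1L]]
    stop_contract("line %d: fewer than 2 tab-separated columns", bad)
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  if (format == "psimitab") {
    # strip a namespace prefix such as "uniprotkb:" before the identifier
    a <- sub("^[^:\t]*:", "", a)
    b <- sub("^[^:\t]*:", "", b)
  }
  empty <- !nzchar(trimws(a)) | !nzchar(trimws(b))
  if (any(empty)) {
    stop_contract("line %d: empty interactor identifier", line_no[which(empty)[1L]])
  }
  interaction_network(cbind(trimws(a), trimws(b)),
                      name = name, namespace = namespace)
}

#' Read a GMT pathway collection
#'
#' Each line is `pathway_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Duplicate genes within a line are collapsed; duplicate pathway ids across
#' lines are an error.
#'
#' @param path file path.
#' @param namespace identifier namespace label.
#' @return named list of pathway annotations, each a list with `pathway_id`,
#'   `name` (description) and `genes` (character vector).
#' @export
read_gmt <- function(path, namespace = "ensembl_gene") {
  if (!file.exists(path)) stop_contract("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop_contract("line %d: GMT line needs id, description and >=1 gene",
                    line_no[[i]])
    }
    id <- f[[1L]]
    if (id %in% names(out)) {
      stop_contract("duplicate pathway id: %s", id)
    }
    genes <- unique(check_gene_ids(f[-(1:2)], sprintf("genes of %s", id)))
    out[[id]] <- list(pathway_id = id, name = f[[2L]], genes = genes,
                      namespace = namespace)
  }
  out
}

#' Write a pathway collection (or list of gene sets) as GMT
#' @param pathways named list as returned by [read_gmt()], or a named list of
#'   character vectors.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(seq_along(pathways), function(i) {
    p <- pathways[[i]]
    if (is.character(p)) {
      p <- list(pathway_id = names(pathways)[[i]], name = "", genes = p)
    }
    paste(c(p$pathway_id, if (nzchar(p$name %||% "")) p$name else "-",
            p$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column identifier mapping table
#'
#' @param path TSV with source identifiers in column 1 and target identifiers
#'   in column 2; `#` lines ignored. The relation may be many-to-many.
#' @param source_namespace,target_namespace namespace labels.
#' @return an `id_mapping` object.
#' @export
read_mapping_table <- function(path, source_namespace = "source",
                               target_namespace = "target") {
  if (!file.exists(path)) stop_contract("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(id_mapping(character(), character(), source_namespace,
                      target_namespace))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop_contract("mapping table rows need 2 columns")
  }
  id_mapping(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L),
             source_namespace, target_namespace)
}

#' Construct an identifier mapping
#' @param source,target parallel character vectors (many-to-many allowed).
#' @param source_namespace,target_namespace namespace labels.
#' @return an `id_mapping`: list with `pairs` (data.frame) and the namespaces.
#' @export
id_mapping <- function(source, target, source_namespace = "source",
                       target_namespace = "target") {
  source <- check_gene_ids(source, "source identifiers")
  target <- check_gene_ids(target, "target identifiers")
  stopifnot(length(source) == length(target))
  pairs <- unique(data.frame(source = source, target = target,
                             stringsAsFactors = FALSE))
  structure(list(pairs = pairs, source_namespace = source_namespace,
                 target_namespace = target_namespace),
            class = "id_mapping")
}

# target sets per source id, as a named list
mapping_targets <- function(mapping, ids) {
  p <- mapping$pairs
  p <- p[p$source %in% ids, , drop = FALSE]
  split(p$target, factor(p$source, levels = ids))
}

#' Translate a network or gene set into another identifier namespace
#'
#' Under `policy = "expand"` every source identifier is replaced by all of its
#' targets; network edges are re-wired to all target combinations and the
#' result re-simplified (an edge whose endpoints map to one common target
#' collapses to a dropped self-loop). Under `policy = "drop_ambiguous"` source
#' identifiers with anything other than exactly one target are removed.
#' Unmapped identifiers are removed under both policies.
#'
#' @param x an `igraph` network (vertex names = identifiers) or a character
#'   vector gene set.
#' @param mapping an [id_mapping()].
#' @param policy `"expand"` or `"drop_ambiguous"`.
#' @param namespace namespace of `x`, checked against
#'   `mapping$source_namespace`; defaults to the network's own attribute.
#' @return object of the same kind in the target namespace, with a
#'   `mapping_report` attribute (`mapped`, `dropped`, `expanded`).
#' @export
map_ids <- function(x, mapping, policy = c("expand", "drop_ambiguous"),
                    namespace = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(mapping, "id_mapping"))
  if (igraph::is_igraph(x)) {
    ns <- namespace %||% net_namespace(x)
    if (!identical(ns, mapping$source_namespace)) {
      stop_contract("namespace mismatch: object is '%s', mapping expects '%s'",
                    ns, mapping$source_namespace)
    }
    ids <- igraph::V(x)$name
    tgt <- mapping_targets(mapping, ids)
    keep <- if (policy == "expand") lengths(tgt) >= 1L else lengths(tgt) == 1L
    report <- list(mapped = sum(keep), dropped = sum(!keep),
                   expanded = sum(lengths(tgt) > 1L & keep))
    el <- igraph::as_edgelist(x, names = TRUE)
    new_edges <- if (nrow(el)) {
      chunks <- lapply(seq_len(nrow(el)), function(i) {
        ta <- tgt[[el[i, 1L]]]
        tb <- tgt[[el[i, 2L]]]
        if (!keep[[el[i, 1L]]] || !keep[[el[i, 2L]]] ||
            length(ta) == 0L || length(tb) == 0L) {
          return(NULL)
        }
        cbind(rep(ta, each = length(tb)), rep(tb, times = length(ta)))
      })
      do.call(rbind, chunks)
    } else {
      NULL
    }
    new_nodes <- unique(unlist(tgt[keep], use.names = FALSE))
    g <- interaction_network(new_edges %||% matrix(character(), ncol = 2L),
                             nodes = new_nodes,
                             name = igraph::graph_attr(x, "name") %||% "network",
                             namespace = mapping$target_namespace)
    attr(g, "mapping_report") <- report
    g
  } else {
    ids <- unique(check_gene_ids(x, "gene set"))
    if (!is.null(namespace) && !identical(namespace, mapping$source_namespace)) {
      stop_contract("namespace mismatch: object is '%s', mapping expects '%s'",
                    namespace, mapping$source_namespace)
    }
    tgt <- mapping_targets(mapping, ids)
    keep <- if (policy == "expand") lengths(tgt) >= 1L else lengths(tgt) == 1L
    out <- sort(unique(unlist(tgt[keep], use.names = FALSE)))
    attr(out, "mapping_report") <- list(mapped = sum(keep),
                                        dropped = sum(!keep),
                                        expanded = sum(lengths(tgt) > 1L & keep))
    out
  }
}

#' Merge interaction networks by node and edge union
#'
#' @param networks list of `igraph` networks sharing one namespace.
#' @param name label for the merged network.
#' @return the union network (simple, undirected). Merging an empty list
#'   yields an empty network.
#' @export
merge_networks <- function(networks, name = "merged") {
  if (length(networks) == 0L) {
    return(interaction_network(matrix(character(), ncol = 2L), name = name))
  }
  stopifnot(all(vapply(networks, igraph::is_igraph, TRUE)))
  ns <- unique(vapply(networks, net_namespace, ""))
  if (length(ns) != 1L) {
    stop_contract("cannot merge networks with mixed namespaces: %s",
                  paste(ns, collapse = ", "))
  }
  edges <- do.call(rbind, lapply(networks, igraph::as_edgelist, names = TRUE))
  nodes <- unique(unlist(lapply(networks, function(g) igraph::V(g)$name)))
  interaction_network(edges %||% matrix(character(), ncol = 2L), nodes = nodes,
                      name = name, namespace = ns)
}

#' Test two networks for graph equality (same nodes, same edge set)
#' @param a,b `igraph` networks.
#' @return logical.
#' @export
graph_equal <- function(a, b) {
  na <- sort(igraph::V(a)$name)
  nb <- sort(igraph::V(b)$name)
  if (!identical(na, nb)) return(FALSE)
  ek <- function(g) {
    el <- igraph::as_edgelist(g, names = TRUE)
    sort(paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "\r"))
  }
  identical(ek(a), ek(b))
}

#' Write a network as a two-column TSV edge list
#'
#' Isolated vertices are written as trailing `node <TAB> -` comment lines so
#' the TSV round-trips through [read_interaction_table()] plus the `nodes`
#' argument of [interaction_network()]; by default only edges are emitted.
#'
#' @param g network.
#' @param path output path.
#' @param header extra provenance lines to prepend as `#` comments.
#' @return the path, invisibly.
#' @export
write_network_tsv <- function(g, path, header = character()) {
  el <- igraph::as_edgelist(g, names = TRUE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste0("# network=", igraph::graph_attr(g, "name") %||% "",
                    " namespace=", net_namespace(g)), con)
  if (nrow(el)) {
    writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
  }
  iso <- igraph::V(g)$name[igraph::degree(g) == 0L]
  if (length(iso)) writeLines(paste0("#ISOLATE\t", iso), con)
  invisible(path)
}

#' Read a network written by [write_network_tsv()]
#' @inheritParams read_interaction_table
#' @return an `igraph` network including any isolated vertices recorded in
#'   the file.
#' @export
read_network_tsv <- function(path, namespace = "ensembl_gene",
                             name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  iso <- sub("^#ISOLATE\t", "", lines[grepl("^#ISOLATE\t", lines)])
  g <- read_interaction_table(path, "two_column", name = name,
                              namespace = namespace)
  if (length(iso)) {
    g2 <- interaction_network(igraph::as_edgelist(g, names = TRUE),
                              nodes = unique(c(igraph::V(g)$name, iso)),
                              name = name, namespace = namespace)
    return(g2)
  }
  g
}

#' Write a network as GraphML
#'
#' Optional vertex attributes (for example the segment membership of a
#' process model substrate) are attached before writing.
#'
#' @param g network.
#' @param path output path.
#' @param vertex_attrs named list of vertex attribute vectors, each named by
#'   vertex.
#' @return the path, invisibly.
#' @export
write_network_graphml <- function(g, path, vertex_attrs = list()) {
  for (nm in names(vertex_attrs)) {
    vals <- vertex_attrs[[nm]][igraph::V(g)$name]
    g <- igraph::set_vertex_attr(g, nm, value = vals)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
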