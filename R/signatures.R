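# Gene signatures with provenance, multi-study consolidation and k-of-m
# consensus building.

#' Construct a gene signature
#'
#' @param label signature label (token).
#' @param genes character vector of gene identifiers (deduplicated).
#' @param provenance `"omics"`, `"literature"` or `"drug:<name>"`.
#' @param namespace identifier namespace label.
#' @param allow_empty permit an empty gene set.
#' @return a `gene_signature` object.
#' @export
gene_signature <- function(label, genes, provenance = "omics",
                           namespace = "ensembl_gene", allow_empty = FALSE) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  genes <- unique(check_gene_ids(as.character(genes),
                                 sprintf("genes of signature '%s'", label)))
  if (!allow_empty && length(genes) == 0L) {
    stop_contract("signature '%s' is empty", label)
  }
  ok <- provenance == "omics" || provenance == "literature" ||
    grepl("^drug:.+", provenance)
  if (!ok) stop_contract("provenance must be omics, literature or drug:<name>")
  structure(list(label = label, genes = sort(genes), provenance = provenance,
                 namespace = namespace),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("Gene signature '%s' (%s, %s): %d genes\n",
              x$label, x$provenance, x$namespace, length(x$genes)))
  invisible(x)
}

check_signature_list <- function(signatures) {
  stopifnot(length(signatures) >= 1L)
  if (!all(vapply(signatures, inherits, TRUE, "gene_signature"))) {
    stop_contract("expected a list of gene_signature objects")
  }
  ns <- unique(vapply(signatures, `[[`, "", "namespace"))
  if (length(ns) != 1L) {
    stop_contract("signatures use mixed namespaces: %s",
                  paste(ns, collapse = ", "))
  }
  invisible(ns)
}

#' Consolidate multi-study gene signatures
#'
#' Union of the member gene sets, retaining for every gene the labels of all
#' contributing signatures so downstream reports can colour features by
#' source (omics, literature, or both).
#'
#' @param signatures list of [gene_signature()] objects in one namespace.
#' @return a `consolidated_signature`: list with `genes` (sorted union),
#'   `sources` (named list: gene -> contributing labels), `members`
#'   (per-signature sizes) and `namespace`.
#' @export
consolidate <- function(signatures) {
  ns <- check_signature_list(signatures)
  labels <- vapply(signatures, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop_contract("duplicate signature labels: %s",
                  paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  gene_label <- data.frame(
    gene = unlist(lapply(signatures, `[[`, "genes"), use.names = FALSE),
    label = rep(labels, times = vapply(signatures, function(s)
      length(s$genes), 0L)),
    stringsAsFactors = FALSE
  )
  genes <- sort(unique(gene_label$gene))
  sources <- split(gene_label$label, factor(gene_label$gene, levels = genes))
  structure(list(
    genes = genes,
    sources = lapply(sources, sort),
    members = stats::setNames(vapply(signatures, function(s)
      length(s$genes), 0L), labels),
    provenance = stats::setNames(vapply(signatures, `[[`, "", "provenance"),
                                 labels),
    namespace = ns
  ), class = "consolidated_signature")
}

#' @export
print.consolidated_signature <- function(x, ...) {
  cat(sprintf("Consolidated signature: %d unique genes from %d sets\n",
              length(x$genes), length(x$members)))
  invisible(x)
}

#' @describeIn consolidate summary with per-signature sizes, pairwise overlap
#'   matrix, support distribution and union size.
#' @param object a `consolidated_signature`.
#' @param ... unused.
#' @export
summary.consolidated_signature <- function(object, ...) {
  labels <- names(object$members)
  ov <- matrix(0L, length(labels), length(labels),
               dimnames = list(labels, labels))
  sets <- lapply(labels, function(l) {
    names(object$sources)[vapply(object$sources, function(s)
      l %in% s, TRUE)]
  })
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      ov[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  support <- table(lengths(object$sources))
  out <- list(sizes = object$members, overlap = ov,
              union_size = length(object$genes), support = support)
  class(out) <- "summary.consolidated_signature"
  out
}

#' @export
print.summary.consolidated_signature <- function(x, ...) {
  cat(sprintf("Union of %d signatures: %d unique genes\n",
              length(x$sizes), x$union_size))
  cat("Per-signature sizes:\n")
  print(x$sizes)
  cat("Pairwise overlaps:\n")
  print(x$overlap)
  invisible(x)
}

#' k-of-m consensus signature
#'
#' Genes present in at least `min_support` of the member signatures. With the
#' default `min_support = 2` this is the consensus used for a family of drug
#' signatures of one drug class (features seen in at least two of the
#' signatures).
#'
#' @param signatures list of [gene_signature()] objects in one namespace.
#' @param min_support integer in `[1, length(signatures)]`.
#' @param label label for the returned signature.
#' @return a [gene_signature()] whose genes have support `>= min_support`;
#'   possibly empty.
#' @export
consensus <- function(signatures, min_support = 2L, label = NULL) {
  check_signature_list(signatures)
  m <- length(signatures)
  if (!is.numeric(min_support) || length(min_support) != 1L ||
      min_support < 1L || min_support > m) {
    stop_contract("min_support must be in [1, %d]", m)
  }
  counts <- table(unlist(lapply(signatures, `[[`, "genes"),
                         use.names = FALSE))
  genes <- names(counts)[counts >= min_support]
  labels <- vapply(signatures, `[[`, "", "label")
  label <- label %||% sprintf("consensus>=%d(%s)", as.integer(min_support),
                              paste(labels, collapse = ","))
  gene_signature(label, genes,
                 provenance = signatures[[1L]]$provenance,
                 namespace = signatures[[1L]]$namespace, allow_empty = TRUE)
}

#' Overlap bookkeeping for two gene sets
#'
#' @param a,b character vectors (deduplicated internally).
#' @return named list with `n_a`, `n_b`, `intersection`, `union`; the
#'   inclusion-exclusion identity `union = n_a + n_b - intersection` holds
#'   exactly.
#' @export
overlap_stats <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  list(n_a = length(a), n_b = length(b),
       intersection = length(intersect(a, b)),
       union = length(union(a, b)))
}

#' Read a one-gene-per-line signature file
#' @param path file path (`#` lines ignored).
#' @inheritParams gene_signature
#' @return a [gene_signature()].
#' @export
read_gene_list <- function(path, label = basename(path), provenance = "omics",
                           namespace = "ensembl_gene") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!grepl("^#", lines)])
  gene_signature(label, lines[nzchar(lines)], provenance = provenance,
                 namespace = namespace, allow_empty = TRUE)
}

#' Write a consolidation summary as TSV (gene, sources)
#' @param x a `consolidated_signature`.
#' @param path output path.
#' @param header provenance comment lines.
#' @return the path, invisibly.
#' @export
write_consolidation_tsv <- function(x, path, header = character()) {
  df <- data.frame(
    gene = x$genes,
    sources = vapply(x$sources, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  write_tsv_report(df, path, header)
}
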