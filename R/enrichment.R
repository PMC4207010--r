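# Fisher's exact enrichment of feature sets in pathways or process segments,
# with Benjamini-Hochberg correction.

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper over the standard step-up procedure
#' (`stats::p.adjust(method = "BH")`): sorted ascending,
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, returned in input order.
#'
#' @param pvalues numeric vector with all values in `(0, 1]`.
#' @return adjusted values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (anyNA(pvalues) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop_contract("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Fisher's exact enrichment of a feature set in annotations
#'
#' One-sided (enrichment-only) test per annotation: with population
#' `|universe|`, successes = annotation size inside the universe, draws =
#' `|feature_set|`, the p-value is the hypergeometric upper tail
#' `P(X >= a)` at the observed overlap `a`. P-values are Benjamini-Hochberg
#' adjusted across the tested annotations and results sorted by `q`, then
#' `p`. Annotations with no overlap with the universe are skipped with a
#' warning.
#'
#' @param feature_set gene set (character vector or [gene_signature()]);
#'   must be contained in `universe`.
#' @param annotations named list of pathway annotations (see [read_gmt()]) or
#'   of character gene vectors.
#' @param universe background gene set (e.g. all nodes of the consolidated
#'   network, or all annotated genes; the choice changes p-values and is
#'   recorded in the output attributes).
#' @param alpha significance level applied to the adjusted values.
#' @return data.frame with `set_id`, the 2x2 counts `a`, `b`, `c`, `d`
#'   (in-set & annotated, in-set & not, not-in-set & annotated, neither),
#'   `odds_ratio`, `p`, `q`, `significant`; attribute `universe_size`.
#' @export
fisher_enrichment <- function(feature_set, annotations, universe,
                              alpha = 0.05) {
  if (inherits(feature_set, "gene_signature")) feature_set <- feature_set$genes
  feature_set <- unique(as.character(feature_set))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop_contract("universe must be non-empty")
  if (!all(feature_set %in% universe)) {
    stop_contract("feature_set must be a subset of the universe")
  }
  ann_sets <- lapply(annotations, function(p) {
    if (is.list(p)) unique(as.character(p$genes)) else unique(as.character(p))
  })
  ids <- names(ann_sets) %||% as.character(seq_along(ann_sets))
  N <- length(universe)
  n_draw <- length(feature_set)
  rows <- list()
  for (i in seq_along(ann_sets)) {
    ann <- intersect(ann_sets[[i]], universe)
    if (length(ann) == 0L) {
      warning(sprintf("annotation '%s' has no overlap with the universe; skipped",
                      ids[[i]]), call. = FALSE)
      next
    }
    K <- length(ann)
    a <- length(intersect(feature_set, ann))
    b <- n_draw - a
    cc <- K - a
    d <- N - K - b
    p <- stats::phyper(a - 1L, K, N - K, n_draw, lower.tail = FALSE)
    or <- if (b == 0L || cc == 0L) Inf else (a * d) / (b * cc)
    if (a == 0L) or <- 0
    rows[[length(rows) + 1L]] <- data.frame(
      set_id = ids[[i]], a = a, b = b, c = cc, d = d, odds_ratio = or,
      p = min(p, 1), stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    out <- data.frame(set_id = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "universe_size") <- N
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= alpha
  out <- out[order(out$q, out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "universe_size") <- N
  attr(out, "alpha") <- alpha
  out
}

#' Enrichment of a feature set in the segments of a process model
#'
#' Convenience wrapper testing each process segment as an annotation, with
#' the substrate nodes as the default universe.
#'
#' @param model a [process_model()].
#' @param feature_set gene set to test (intersected with the universe).
#' @param universe background; defaults to the model substrate nodes.
#' @param alpha significance level.
#' @return see [fisher_enrichment()]; `set_id` holds segment ids.
#' @export
segment_enrichment <- function(model, feature_set,
                               universe = igraph::V(model$substrate)$name,
                               alpha = 0.05) {
  if (inherits(feature_set, "gene_signature")) feature_set <- feature_set$genes
  feature_set <- intersect(unique(as.character(feature_set)), universe)
  ann <- stats::setNames(
    lapply(model$segments, `[[`, "genes"),
    vapply(model$segments, function(s) as.character(s$segment_id), "")
  )
  fisher_enrichment(feature_set, ann, universe, alpha = alpha)
}

#' Write enrichment results as TSV
#' @param results data.frame from [fisher_enrichment()].
#' @param path output path.
#' @param header provenance comment lines.
#' @return the path, invisibly.
#' @export
write_enrichment_tsv <- function(results, path, header = character()) {
  header <- c(header, sprintf("universe_size=%s alpha=%s",
                              attr(results, "universe_size") %||% "NA",
                              attr(results, "alpha") %||% "NA"))
  write_tsv_report(results, path, header)
}
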