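# Interference of a drug mechanism-of-action model with a disease model on
# the level of feature overlap, and the annotated segment report.

#' Map interference between a drug model and a disease model
#'
#' Intersects every drug segment with every disease segment on gene identity
#' (not interaction structure) and keeps pairs with at least `min_overlap`
#' shared genes, sorted by overlap size (descending). A hypergeometric
#' p-value per pair (population = union of both substrates) is reported for
#' ranking, so a stricter overlap cut can be applied downstream.
#'
#' @param drug_model,disease_model [process_model()] objects sharing one
#'   namespace.
#' @param min_overlap minimum overlap size for a pair to be reported.
#' @return data.frame with `drug_segment_id`, `disease_segment_id`,
#'   `overlap_size`, `overlap_genes` (semicolon-joined), `hyper_p`.
#' @export
interference_map <- function(drug_model, disease_model, min_overlap = 1L) {
  stopifnot(inherits(drug_model, "process_model"),
            inherits(disease_model, "process_model"))
  ns_a <- net_namespace(drug_model$substrate)
  ns_b <- net_namespace(disease_model$substrate)
  if (!identical(ns_a, ns_b)) {
    stop_contract("models use different namespaces: '%s' vs '%s'", ns_a, ns_b)
  }
  population <- union(igraph::V(drug_model$substrate)$name,
                      igraph::V(disease_model$substrate)$name)
  N <- length(population)
  out <- list()
  for (ds in drug_model$segments) {
    for (ps in disease_model$segments) {
      ov <- intersect(ds$genes, ps$genes)
      if (length(ov) < min_overlap) next
      K <- length(ds$genes)
      n <- length(ps$genes)
      hyper_p <- stats::phyper(length(ov) - 1L, K, N - K, n,
                               lower.tail = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        drug_segment_id = ds$segment_id,
        disease_segment_id = ps$segment_id,
        overlap_size = length(ov),
        overlap_genes = paste(sort(ov), collapse = ";"),
        hyper_p = hyper_p,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(drug_segment_id = integer(),
                      disease_segment_id = integer(),
                      overlap_size = integer(), overlap_genes = character(),
                      hyper_p = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$overlap_size, res$disease_segment_id,
                   res$drug_segment_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate disease segments with interference, biomarkers and enrichment
#'
#' Builds the per-segment interference report: for each disease segment the
#' total interference overlap (summed over its pairs), its biomarker and
#' target candidate members, and its significantly enriched pathways.
#'
#' @param model the disease [process_model()].
#' @param interference data.frame from [interference_map()] against a drug
#'   model.
#' @param biomarkers,targets character gene sets (may be empty).
#' @param enrichment optional data.frame of [fisher_enrichment()] results
#'   keyed by segment id (`set_id`), e.g. one row per (segment, pathway)
#'   test with a `pathway` column; only rows with `significant == TRUE` are
#'   attached.
#' @param interfering_only restrict the report to segments with interference
#'   (default); `FALSE` reports the full model.
#' @return data.frame with `segment_id`, `n_genes`, `interference_overlap`,
#'   `biomarker_candidates`, `target_candidates`, `enriched_pathways`
#'   (semicolon-joined).
#' @export
annotate_segments <- function(model, interference, biomarkers = character(),
                              targets = character(), enrichment = NULL,
                              interfering_only = TRUE) {
  stopifnot(inherits(model, "process_model"))
  seg_ids <- vapply(model$segments, `[[`, 0L, "segment_id")
  if (nrow(interference) > 0L &&
      !all(interference$disease_segment_id %in% seg_ids)) {
    bad <- setdiff(interference$disease_segment_id, seg_ids)
    stop_contract("unknown segment id(s) in interference: %s",
                  paste(bad, collapse = ", "))
  }
  biomarkers <- unique(as.character(biomarkers))
  targets <- unique(as.character(targets))
  rows <- lapply(model$segments, function(s) {
    pairs <- interference[interference$disease_segment_id == s$segment_id, ,
                          drop = FALSE]
    total_overlap <- sum(pairs$overlap_size)
    bm <- intersect(biomarkers, s$genes)
    tg <- intersect(targets, s$genes)
    ep <- character()
    if (!is.null(enrichment) && nrow(enrichment) > 0L) {
      er <- enrichment[enrichment$set_id == as.character(s$segment_id) &
                         enrichment$significant, , drop = FALSE]
      ep <- if ("pathway" %in% names(er)) er$pathway else er$set_id
    }
    data.frame(
      segment_id = s$segment_id,
      n_genes = length(s$genes),
      interference_overlap = total_overlap,
      biomarker_candidates = paste(sort(bm), collapse = ";"),
      target_candidates = paste(sort(tg), collapse = ";"),
      enriched_pathways = paste(ep, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  if (interfering_only) {
    res <- res[res$interference_overlap > 0L, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Model-level annotation summary
#'
#' Counts how many of the given biomarker and target candidates fall inside
#' the model's process segments.
#'
#' @param model a [process_model()].
#' @param biomarkers,targets character gene sets.
#' @return list with `biomarkers_total`, `biomarkers_in_model`,
#'   `targets_total`, `targets_in_model`.
#' @export
model_annotation_summary <- function(model, biomarkers = character(),
                                     targets = character()) {
  biomarkers <- unique(as.character(biomarkers))
  targets <- unique(as.character(targets))
  seg_genes <- unique(unlist(lapply(model$segments, `[[`, "genes")))
  list(
    biomarkers_total = length(biomarkers),
    biomarkers_in_model = length(intersect(biomarkers, seg_genes)),
    targets_total = length(targets),
    targets_in_model = length(intersect(targets, seg_genes))
  )
}

#' Write an interference report as TSV
#' @param report data.frame from [annotate_segments()] or
#'   [interference_map()].
#' @param path output path.
#' @param header provenance comment lines.
#' @return the path, invisibly.
#' @export
write_interference_tsv <- function(report, path, header = character()) {
  write_tsv_report(report, path, header)
}
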