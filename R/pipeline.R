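# End-to-end orchestration: run the full study (consolidate -> model ->
# relations -> enrich -> interfere) with deterministic, seed-stamped outputs.

#' Assemble a run configuration
#'
#' Either pass the study objects directly (as produced by
#' [synthetic_interference_study()] or loaded via the graphio readers), or a
#' YAML file with paths (`disease_network`, `drug_network`,
#' `disease_signature`, `drug_signature`, `pathways`, `biomarkers`,
#' `targets`) plus settings.
#'
#' @param study list with `disease_network`, `drug_network`,
#'   `disease_signature`, `drug_signature`, and optionally `pathways`,
#'   `biomarkers`, `targets`.
#' @param seed master seed; every stage derives its own substream from it.
#' @param n_perm permutation draws for relation scoring.
#' @param alpha significance level for relations and enrichment.
#' @param min_overlap interference reporting threshold.
#' @param universe_mode sampling universe for the permutation null.
#' @param params [mcode_params()].
#' @return a `run_config` list.
#' @export
run_config <- function(study, seed = 1L, n_perm = 99L, alpha = 0.05,
                       min_overlap = 1L, universe_mode = "substrate",
                       params = mcode_params()) {
  stopifnot(is.list(study),
            !is.null(study$disease_network), !is.null(study$disease_signature))
  structure(list(study = study, seed = as.integer(seed),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 min_overlap = as.integer(min_overlap),
                 universe_mode = universe_mode, params = params),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The YAML names input files (TSV edge lists, gene lists, GMT) and settings;
#' every referenced path must exist.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    p2 <- if (file.exists(p)) p else file.path(base, p)
    if (!file.exists(p2)) stop_contract("input not found: %s", p)
    p2
  }
  ns <- cfg$namespace %||% "ensembl_gene"
  study <- list(
    disease_network = read_network_tsv(resolve(cfg$disease_network),
                                       namespace = ns),
    disease_signature = read_gene_list(resolve(cfg$disease_signature),
                                       namespace = ns),
    drug_network = if (!is.null(cfg$drug_network)) {
      read_network_tsv(resolve(cfg$drug_network), namespace = ns)
    },
    drug_signature = if (!is.null(cfg$drug_signature)) {
      read_gene_list(resolve(cfg$drug_signature), namespace = ns,
                     provenance = "drug:config")
    },
    pathways = if (!is.null(cfg$pathways)) {
      read_gmt(resolve(cfg$pathways), namespace = ns)
    },
    biomarkers = if (!is.null(cfg$biomarkers)) {
      read_gene_list(resolve(cfg$biomarkers), namespace = ns)$genes
    } else {
      character()
    },
    targets = if (!is.null(cfg$targets)) {
      read_gene_list(resolve(cfg$targets), namespace = ns)$genes
    } else {
      character()
    }
  )
  run_config(study, seed = cfg$seed %||% 1L, n_perm = cfg$n_perm %||% 99L,
             alpha = cfg$alpha %||% 0.05,
             min_overlap = cfg$min_overlap %||% 1L,
             universe_mode = cfg$universe_mode %||% "substrate")
}

#' Run the full modelling pipeline
#'
#' Builds the disease (and, when present, drug) process model, scores
#' inter-segment relations against the permutation null, runs segment
#' enrichment of the pathway collection, computes drug/disease interference
#' and writes all reports as seed-stamped TSV plus a JSON run summary.
#' Identical config and seed give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose log per-stage cardinalities (mapped, isolates removed,
#'   segments, genes in segments).
#' @return invisibly, a list with `disease_model`, `drug_model`,
#'   `interference`, `segment_report`, `enrichment` and `summary`.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- config$study
  say <- function(...) if (verbose) message(sprintf(...))
  stamp <- function(stage) {
    c(sprintf("molproc run: stage=%s seed=%d n_perm=%d alpha=%s min_overlap=%d",
              stage, config$seed, config$n_perm, format(config$alpha),
              config$min_overlap),
      sprintf("mcode: degree_cutoff=%d vwp=%s k_core=%d haircut=%s fluff=%s",
              config$params$degree_cutoff,
              format(config$params$node_score_cutoff),
              config$params$k_core_filter, config$params$haircut,
              config$params$fluff))
  }

  disease_model <- process_model(study$disease_network,
                                 study$disease_signature,
                                 params = config$params, name = "disease")
  say("disease model: mapped=%d isolates_removed=%d segments=%d genes_in_segments=%d",
      disease_model$report$mapped, disease_model$report$isolates_removed,
      disease_model$report$n_segments, disease_model$report$genes_in_segments)
  disease_model <- score_model_relations(
    disease_model, universe_mode = config$universe_mode,
    n_perm = config$n_perm, seed = derive_seed(config$seed, "disease_relations"),
    alpha = config$alpha
  )
  write_process_model(disease_model,
                      file.path(out_dir, "disease_segments.tsv"),
                      graphml_path = file.path(out_dir, "disease_model.graphml"),
                      header = stamp("disease_model"))
  write_relations_tsv(disease_model,
                      file.path(out_dir, "disease_relations.tsv"),
                      header = stamp("disease_relations"))

  drug_model <- NULL
  interference <- NULL
  segment_report <- NULL
  if (!is.null(study$drug_network) && !is.null(study$drug_signature)) {
    drug_model <- process_model(study$drug_network, study$drug_signature,
                                params = config$params, name = "drug")
    say("drug model: mapped=%d isolates_removed=%d segments=%d genes_in_segments=%d",
        drug_model$report$mapped, drug_model$report$isolates_removed,
        drug_model$report$n_segments, drug_model$report$genes_in_segments)
    write_process_model(drug_model, file.path(out_dir, "drug_segments.tsv"),
                        graphml_path = file.path(out_dir, "drug_model.graphml"),
                        header = stamp("drug_model"))
    interference <- interference_map(drug_model, disease_model,
                                     min_overlap = config$min_overlap)
    write_interference_tsv(interference,
                           file.path(out_dir, "interference_pairs.tsv"),
                           header = stamp("interference_pairs"))
  }

  enrichment <- NULL
  if (!is.null(study$pathways)) {
    universe <- igraph::V(disease_model$substrate)$name
    study$pathways <- Filter(function(p) {
      length(intersect(p$genes, universe)) > 0L
    }, study$pathways)
    enr <- lapply(seq_along(disease_model$segments), function(i) {
      s <- disease_model$segments[[i]]
      res <- fisher_enrichment(intersect(s$genes, universe), study$pathways,
                               universe, alpha = config$alpha)
      if (nrow(res)) {
        data.frame(set_id = as.character(s$segment_id), pathway = res$set_id,
                   a = res$a, p = res$p, q = res$q,
                   significant = res$significant, stringsAsFactors = FALSE)
      }
    })
    enrichment <- do.call(rbind, enr)
    if (!is.null(enrichment)) {
      write_tsv_report(enrichment, file.path(out_dir, "segment_enrichment.tsv"),
                       stamp("segment_enrichment"))
    }
  }

  if (!is.null(interference)) {
    segment_report <- annotate_segments(
      disease_model, interference,
      biomarkers = study$biomarkers %||% character(),
      targets = study$targets %||% character(),
      enrichment = enrichment
    )
    write_interference_tsv(segment_report,
                           file.path(out_dir, "interference_segments.tsv"),
                           header = stamp("interference_segments"))
  }

  ann <- model_annotation_summary(disease_model,
                                  study$biomarkers %||% character(),
                                  study$targets %||% character())
  run_summary <- list(
    package = "molproc",
    version = as.character(utils::packageVersion("molproc")),
    seed = config$seed,
    n_perm = config$n_perm,
    alpha = config$alpha,
    min_overlap = config$min_overlap,
    universe_mode = config$universe_mode,
    mcode = config$params[c("degree_cutoff", "node_score_cutoff",
                            "k_core_filter", "max_depth", "haircut", "fluff")],
    disease = summary(disease_model)[c("mapped", "isolates_removed",
                                       "retained", "n_segments",
                                       "genes_in_segments", "size_median",
                                       "size_min", "size_max")],
    drug = if (!is.null(drug_model)) {
      summary(drug_model)[c("mapped", "isolates_removed", "retained",
                            "n_segments", "genes_in_segments", "size_median",
                            "size_min", "size_max")]
    },
    interference_pairs = if (!is.null(interference)) nrow(interference),
    interfering_segments = if (!is.null(segment_report)) nrow(segment_report),
    annotation = ann
  )
  jsonlite::write_json(run_summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(disease_model = disease_model, drug_model = drug_model,
                 interference = interference, segment_report = segment_report,
                 enrichment = enrichment, summary = run_summary))
}
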