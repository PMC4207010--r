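# Synthetic study generators: planted-partition interactomes, multi-study
# signatures with controlled overlap, drug-signature families with a known
# consensus core, ortholog maps, and a cardinality-exact interference study.
#
# Two construction modes exist side by side: probabilistic generators (for
# recovery and calibration experiments) and cardinality-exact constructions
# that honour requested set sizes and overlaps to the gene, so printed
# set-algebra can be reproduced on demand.

#' Synthetic study configuration
#'
#' @param n_background number of background genes outside the planted
#'   modules.
#' @param modules integer vector of planted module sizes (each >= 3).
#' @param p_in,p_out within- and between-module edge probabilities.
#' @param signature_coverage fraction of a designated module's genes sampled
#'   into a signature.
#' @param signature_noise number of background genes added per signature,
#'   as a fraction of the signature's module size.
#' @param n_drug_signatures number of drug signatures in a family.
#' @param drug_core_size number of consensus-core genes in a drug family.
#' @param seed mandatory RNG seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_background = 0L, modules = c(12L, 12L, 12L, 12L, 12L),
                         p_in = 0.9, p_out = 0.02, signature_coverage = 1,
                         signature_noise = 0, n_drug_signatures = 6L,
                         drug_core_size = 100L, seed) {
  if (missing(seed)) stop_contract("seed is mandatory")
  if (any(c(p_in, p_out, signature_coverage) < 0) ||
      any(c(p_in, p_out, signature_coverage) > 1) || signature_noise < 0) {
    stop_contract("probabilities and fractions must lie in [0, 1]")
  }
  if (any(modules < 3L)) stop_contract("module sizes must be >= 3")
  structure(list(n_background = as.integer(n_background),
                 modules = as.integer(modules), p_in = p_in, p_out = p_out,
                 signature_coverage = signature_coverage,
                 signature_noise = signature_noise,
                 n_drug_signatures = as.integer(n_drug_signatures),
                 drug_core_size = as.integer(drug_core_size),
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_gene_ids <- function(n, prefix = "G") {
  sprintf("%s%05d", prefix, seq_len(n))
}

#' Generate a planted-partition interactome
#'
#' Stochastic block model: within-module pairs connected with probability
#' `p_in`, all other pairs (including background genes) with `p_out`.
#' Background genes form their own sparse block. Deterministic given the
#' config seed.
#'
#' @param config a [synth_config()].
#' @param prefix gene identifier prefix.
#' @return list with `network` (`igraph`, possibly containing isolated
#'   vertices) and `labels` (named integer vector; module index per gene, 0
#'   for background).
#' @export
generate_network <- function(config, prefix = "G") {
  stopifnot(inherits(config, "synth_config"))
  sizes <- c(config$modules, config$n_background)
  n_mod <- length(config$modules)
  pm <- matrix(config$p_out, n_mod + 1L, n_mod + 1L)
  diag(pm)[seq_len(n_mod)] <- config$p_in
  pm[n_mod + 1L, n_mod + 1L] <- config$p_out
  keep <- sizes > 0L
  g <- with_seed(config$seed, {
    igraph::sample_sbm(sum(sizes), pref.matrix = pm[keep, keep, drop = FALSE],
                       block.sizes = sizes[keep])
  })
  ids <- synth_gene_ids(sum(sizes), prefix)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_graph_attr(g, "name", "synthetic_interactome")
  g <- igraph::set_graph_attr(g, "namespace", "synthetic")
  labels <- rep(c(seq_len(n_mod), 0L)[keep], sizes[keep])
  names(labels) <- ids
  list(network = g, labels = labels)
}

#' Generate module-anchored gene signatures
#'
#' Each signature samples `signature_coverage` of the genes of one designated
#' module plus `signature_noise * module size` random background genes.
#'
#' @param network_labels list from [generate_network()].
#' @param config a [synth_config()].
#' @param module_of integer vector assigning a module to each signature;
#'   defaults to one signature per module.
#' @param provenance provenance label for the signatures.
#' @return list of [gene_signature()] objects.
#' @export
generate_signatures <- function(network_labels, config,
                                module_of = NULL, provenance = "omics") {
  stopifnot(inherits(config, "synth_config"))
  labels <- network_labels$labels
  module_of <- module_of %||% seq_along(config$modules)
  background <- names(labels)[labels == 0L]
  with_seed(derive_seed(config$seed, "signatures"), {
    lapply(seq_along(module_of), function(i) {
      m <- module_of[[i]]
      pool <- names(labels)[labels == m]
      k <- round(config$signature_coverage * length(pool))
      genes <- sort(sample(pool, k))
      n_noise <- round(config$signature_noise * length(pool))
      if (n_noise > 0L) {
        genes <- c(genes, sample(background, min(n_noise, length(background))))
      }
      gene_signature(sprintf("study_%02d", i), genes, provenance = provenance,
                     namespace = "synthetic")
    })
  })
}

#' Construct two gene sets with exact sizes and exact overlap
#'
#' Cardinality-exact construction used to reproduce printed set-algebra
#' (e.g. an omics set of 516 and a literature set of 414 sharing exactly 49).
#'
#' @param n_a,n_b set sizes.
#' @param overlap exact intersection size.
#' @param universe character vector of available gene identifiers, or an
#'   integer universe size (identifiers are generated).
#' @param labels labels for the two signatures.
#' @param provenance length-2 provenance labels.
#' @param namespace identifier namespace label.
#' @return list of two [gene_signature()] objects with
#'   `overlap_stats(a, b)` equal to the request.
#' @export
exact_overlap_pair <- function(n_a, n_b, overlap,
                               universe = n_a + n_b - overlap,
                               labels = c("set_a", "set_b"),
                               provenance = c("omics", "literature"),
                               namespace = "synthetic") {
  if (overlap > min(n_a, n_b)) stop_contract("overlap exceeds a set size")
  if (is.numeric(universe) && length(universe) == 1L) {
    universe <- synth_gene_ids(universe)
  }
  need <- n_a + n_b - overlap
  if (length(universe) < need) {
    stop_contract("universe of %d genes cannot host %d + %d with overlap %d",
                  length(universe), n_a, n_b, overlap)
  }
  shared <- universe[seq_len(overlap)]
  only_a <- universe[overlap + seq_len(n_a - overlap)]
  only_b <- universe[n_a + seq_len(n_b - overlap)]
  list(
    gene_signature(labels[[1L]], c(shared, only_a), provenance[[1L]],
                   namespace = namespace),
    gene_signature(labels[[2L]], c(shared, only_b), provenance[[2L]],
                   namespace = namespace)
  )
}

#' Generate a drug-signature family with a planted consensus core
#'
#' Core genes are placed into at least two signatures each (per the support
#' pattern); filler genes appear in exactly one signature, topping each
#' signature up to its requested size. By construction
#' `consensus(family, min_support = 2)` returns exactly the planted core.
#'
#' @param sizes per-signature feature counts (one per drug signature).
#' @param core_support integer vector of per-core-gene support counts, all
#'   `>= 2` and `<= length(sizes)`; its length is the core size.
#' @param drug_names optional drug names (defaults to `drug_1`, ...).
#' @param namespace identifier namespace label.
#' @return list with `signatures` (list of [gene_signature()] with
#'   `drug:<name>` provenance), `core` (character vector) and `total`
#'   (sum of the per-signature sizes, the feature count before
#'   deduplication).
#' @export
generate_drug_family <- function(sizes, core_support,
                                 drug_names = NULL, namespace = "synthetic") {
  m <- length(sizes)
  if (any(core_support < 2L) || any(core_support > m)) {
    stop_contract("core support counts must lie in [2, %d]", m)
  }
  if (sum(core_support) > sum(sizes)) {
    stop_contract("support pattern does not fit the signature sizes")
  }
  drug_names <- drug_names %||% sprintf("drug_%d", seq_len(m))
  core <- synth_gene_ids(length(core_support), "DC")
  remaining <- as.integer(sizes)
  members <- rep(list(character()), m)
  # place high-support genes first, always into the signatures with most room
  for (i in order(-core_support)) {
    s <- core_support[[i]]
    pick <- order(-remaining, seq_len(m))[seq_len(s)]
    if (any(remaining[pick] <= 0L)) {
      stop_contract("support pattern infeasible for the given sizes")
    }
    for (j in pick) {
      members[[j]] <- c(members[[j]], core[[i]])
      remaining[[j]] <- remaining[[j]] - 1L
    }
  }
  n_fill <- sum(remaining)
  fillers <- synth_gene_ids(n_fill, "DF")
  offset <- 0L
  for (j in seq_len(m)) {
    if (remaining[[j]] > 0L) {
      members[[j]] <- c(members[[j]], fillers[offset + seq_len(remaining[[j]])])
      offset <- offset + remaining[[j]]
    }
  }
  sigs <- lapply(seq_len(m), function(j) {
    gene_signature(drug_names[[j]], members[[j]],
                   provenance = paste0("drug:", drug_names[[j]]),
                   namespace = namespace)
  })
  list(signatures = sigs, core = sort(core), total = sum(sizes))
}

#' Generate a many-to-many ortholog map
#'
#' Each source gene receives 0, 1 or 2 targets according to the fanout
#' probabilities; deterministic given the seed.
#'
#' @param source_genes character vector of source identifiers.
#' @param fanout named numeric vector with names `"0"`, `"1"`, `"2"` giving
#'   the probabilities of no, one, or two targets; must sum to 1.
#' @param seed RNG seed.
#' @param source_namespace,target_namespace namespace labels.
#' @return an [id_mapping()].
#' @export
generate_ortholog_map <- function(source_genes, fanout = c("0" = 0.1,
                                                           "1" = 0.8,
                                                           "2" = 0.1),
                                  seed = 1L, source_namespace = "source",
                                  target_namespace = "target") {
  if (!setequal(names(fanout), c("0", "1", "2")) ||
      abs(sum(fanout) - 1) > 1e-9) {
    stop_contract("fanout needs probabilities for 0, 1, 2 targets summing to 1")
  }
  counts <- with_seed(seed, {
    sample(c(0L, 1L, 2L), length(source_genes), replace = TRUE,
           prob = fanout[c("0", "1", "2")])
  })
  src <- rep(source_genes, counts)
  tgt <- sprintf("T%06d", seq_len(sum(counts)))
  out <- id_mapping(src, tgt, source_namespace, target_namespace)
  attr(out, "fanout_counts") <- table(factor(counts, levels = 0:2))
  out
}

# Disjoint-clique network whose cliques become the model's process segments;
# `clique_genes` is a list of character vectors.
clique_network <- function(clique_genes, name, namespace = "synthetic") {
  edges <- do.call(rbind, lapply(clique_genes, function(genes) {
    if (length(genes) < 2L) return(NULL)
    t(utils::combn(sort(genes), 2L))
  }))
  interaction_network(edges, nodes = unique(unlist(clique_genes)),
                      name = name, namespace = namespace)
}

#' Cardinality-exact drug/disease interference study
#'
#' Constructs a complete synthetic study whose printed cardinalities mirror a
#' real disease/drug analysis: a disease network of 23 disjoint dense
#' segments (200 genes; sizes 3-29, median 6) of which four (29, 11, 20 and
#' 16 genes) share exactly 7, 2, 3 and 2 genes with segments of a 12-segment
#' drug model (92 genes; sizes 3-19, median 8); a biomarker panel of 54
#' candidates of which exactly 22 fall inside disease segments (with all four
#' interfering segments holding at least one); and a target panel.
#'
#' @param seed RNG seed (the construction itself is deterministic; the seed
#'   is recorded and used for any downstream permutation scoring).
#' @return list with `disease_network`, `drug_network`, `disease_signature`,
#'   `drug_signature`, `biomarkers`, `targets`, `pathways`, `seed` and
#'   `expected` (the planted cardinalities).
#' @export
synthetic_interference_study <- function(seed = 1L) {
  disease_sizes <- c(29L, 25L, 20L, 16L, 11L, 9L, 8L, 8L, 7L, 7L, 6L, 6L,
                     6L, 6L, 5L, 5L, 5L, 4L, 4L, 4L, 3L, 3L, 3L)
  drug_sizes <- c(19L, 9L, 9L, 9L, 8L, 8L, 8L, 7L, 5L, 4L, 3L, 3L)
  stopifnot(sum(disease_sizes) == 200L, sum(drug_sizes) == 92L)
  disease_genes <- synth_gene_ids(200L, "DN")
  # partition disease genes into cliques
  idx <- cumsum(c(0L, disease_sizes))
  disease_cliques <- lapply(seq_along(disease_sizes), function(i) {
    disease_genes[(idx[[i]] + 1L):idx[[i + 1L]]]
  })
  # overlaps with the drug model: disease segments of sizes 29/11/20/16
  # share 7/2/3/2 genes with drug segments of sizes 19/9/9/8
  shared <- list(
    disease_cliques[[1L]][1:7],   # size 29 -> overlap 7
    disease_cliques[[5L]][1:2],   # size 11 -> overlap 2
    disease_cliques[[3L]][1:3],   # size 20 -> overlap 3
    disease_cliques[[4L]][1:2]    # size 16 -> overlap 2
  )
  drug_own <- synth_gene_ids(92L - 14L, "MOA")
  own_sizes <- drug_sizes - c(7L, 2L, 3L, 2L, rep(0L, 8L))
  jdx <- cumsum(c(0L, own_sizes))
  drug_cliques <- lapply(seq_along(drug_sizes), function(i) {
    own <- drug_own[seq_len(own_sizes[[i]]) + jdx[[i]]]
    if (i <= 4L) c(shared[[i]], own) else own
  })
  disease_network <- clique_network(disease_cliques, "disease_interactome")
  drug_network <- clique_network(drug_cliques, "drug_interactome")
  # biomarkers: 22 inside disease segments (>=1 in each interfering segment),
  # 32 outside the model
  in_model <- c(disease_cliques[[1L]][8L],        # interfering, size 29
                disease_cliques[[5L]][3:6],       # interfering, size 11
                disease_cliques[[3L]][4L],        # interfering, size 20
                disease_cliques[[4L]][3L],        # interfering, size 16
                disease_cliques[[2L]][1:5],
                disease_cliques[[6L]][1:5],
                disease_cliques[[7L]][1:5])
  stopifnot(length(in_model) == 22L)
  biomarkers <- c(in_model, synth_gene_ids(32L, "BMX"))
  targets <- c(disease_cliques[[1L]][9:12], synth_gene_ids(12L, "TGX"))
  pathways <- list(
    PW1 = list(pathway_id = "PW1", name = "segment-1-like pathway",
               genes = disease_cliques[[1L]], namespace = "synthetic"),
    PW2 = list(pathway_id = "PW2", name = "segment-3-like pathway",
               genes = disease_cliques[[3L]], namespace = "synthetic"),
    PW3 = list(pathway_id = "PW3", name = "background pathway",
               genes = synth_gene_ids(40L, "PWX"), namespace = "synthetic")
  )
  list(
    disease_network = disease_network,
    drug_network = drug_network,
    disease_signature = gene_signature("disease_consensus", disease_genes,
                                       provenance = "omics",
                                       namespace = "synthetic"),
    drug_signature = gene_signature("drug_consensus",
                                    unique(unlist(drug_cliques)),
                                    provenance = "drug:consensus",
                                    namespace = "synthetic"),
    biomarkers = biomarkers,
    targets = targets,
    pathways = pathways,
    seed = as.integer(seed),
    expected = list(
      disease_segments = 23L, disease_genes_in_segments = 200L,
      drug_segments = 12L, drug_genes_in_segments = 92L,
      interference_overlaps = c("29" = 7L, "11" = 2L, "20" = 3L, "16" = 2L),
      biomarkers_total = 54L, biomarkers_in_model = 22L
    )
  )
}

#' Induced-subgraph bookkeeping fixture
#'
#' Builds a network and a signature with exact mapping cardinalities: the
#' signature holds `n_signature` genes, `n_signature - n_mapped` of which are
#' absent from the network, `n_isolated` of the mapped genes interact only
#' with non-signature background genes (degree zero in the induced
#' subgraph), and the remainder interact among themselves (a ring).
#'
#' @param n_signature,n_mapped,n_isolated requested cardinalities (defaults
#'   881 / 880 / 246, retaining 634).
#' @return list with `network`, `signature` and `expected` (mapped, isolates
#'   removed, retained).
#' @export
synthetic_subgraph_study <- function(n_signature = 881L, n_mapped = 880L,
                                     n_isolated = 246L) {
  stopifnot(n_mapped <= n_signature, n_isolated < n_mapped)
  sig <- synth_gene_ids(n_signature, "SG")
  mapped <- sig[seq_len(n_mapped)]
  connected <- mapped[seq_len(n_mapped - n_isolated)]
  isolated <- mapped[(n_mapped - n_isolated + 1L):n_mapped]
  background <- synth_gene_ids(n_isolated, "BG")
  ring <- cbind(connected, c(connected[-1L], connected[[1L]]))
  tether <- cbind(isolated, background)
  network <- interaction_network(rbind(ring, tether), name = "subgraph_fixture",
                                 namespace = "synthetic")
  list(network = network,
       signature = gene_signature("bookkeeping", sig, namespace = "synthetic"),
       expected = list(mapped = n_mapped, isolates_removed = n_isolated,
                       retained = n_mapped - n_isolated))
}
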