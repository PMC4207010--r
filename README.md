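# molproc

Molecular process models of disease phenotypes and drug mechanism of action,
derived from gene signatures mapped onto a consolidated protein–protein
interaction network.

## What problem this solves

Gene signatures of a complex phenotype — differential-expression calls from
tissue transcriptomics plus disease-associated genes mined from the
literature — overlap poorly across studies and, as flat lists, say nothing
about the molecular processes they touch. `molproc` implements a
network-based workflow for users in systems biology / systems pharmacology:

1. **Consolidate** interaction networks from several source databases onto
   one gene namespace (plain union of nodes and edges; undirected, simple).
2. **Consolidate signatures** with per-gene provenance, and build k-of-m
   **consensus signatures** for drug families (default: features seen in at
   least 2 member signatures).
3. **Build a process model**: map the signature onto the network, extract
   the induced subgraph, drop degree-zero nodes, and segment the remainder
   with an MCODE-style algorithm. Each vertex `v` is weighted
   `w(v) = k · density(K)` where `K` is the highest k-core of the graph
   induced on the closed neighbourhood `N[v]` and
   `density = 2|E|/(|V|(|V|−1))`; segments grow greedily from the
   highest-weighted seeds, admitting neighbours with
   `w(u) ≥ w(seed)·(1 − VWP)` (VWP = 0.2) whose own top core already meets
   the segment, then are filtered to contain a 2-core and trimmed to their
   2-core (haircut).
4. **Score inter-segment relations** against a permutation null: observed
   cross-segment interaction counts vs. counts between two random node sets
   of matching sizes, `p = (1 + #{null ≥ obs})/(n_perm + 1)`,
   Benjamini–Hochberg adjusted.
5. **Enrichment**: one-sided Fisher's exact tests (hypergeometric upper
   tail) of feature sets in pathways or segments, BH adjusted.
6. **Interference**: intersect a drug model with a disease model on gene
   identity; disease segments overlapping drug segments, annotated with the
   biomarker candidates they contain, nominate predictive-biomarker-bearing
   processes.

Synthetic generators (planted-partition interactomes, signatures with exact
sizes and overlaps, drug families with a planted consensus core, ortholog
maps) make every stage testable without any external downloads.

## Worked example

A synthetic study with planted cardinalities: a disease model of 23 dense
segments over 200 genes and a drug model of 12 segments over 92 genes, four
of whose segments overlap disease segments.

```r
library(molproc)

study   <- synthetic_interference_study(seed = 1)
disease <- process_model(study$disease_network, study$disease_signature,
                         name = "disease")
summary(disease)
#> Molecular process model 'disease'
#>   signature genes: 200, mapped: 200, isolates removed: 0, retained: 200
#>   segments: 23; genes in segments: 200
#>   segment sizes: median 6.0, min 3, max 29

drug  <- process_model(study$drug_network, study$drug_signature, name = "drug")
pairs <- interference_map(drug, disease)
pairs[, c("drug_segment_id", "disease_segment_id", "overlap_size", "hyper_p")]
#>   drug_segment_id disease_segment_id overlap_size     hyper_p
#> 1               1                  1            7 0.001363058
#> 2               2                  3            3 0.020339647
#> 3               3                  4            2 0.088305262
#> 4               4                  5            2 0.044094169

report <- annotate_segments(disease, pairs, biomarkers = study$biomarkers)
report[, c("segment_id", "n_genes", "interference_overlap",
           "biomarker_candidates")]
#>   segment_id n_genes interference_overlap            biomarker_candidates
#> 1          1      29                    7                         DN00008
#> 2          3      20                    3                         DN00058
#> 3          4      16                    2                         DN00077
#> 4          5      11                    2 DN00093;DN00094;DN00095;DN00096
```

Reading: four disease segments (of 29, 20, 16 and 11 genes) interfere with
the drug mechanism-of-action model, sharing 7, 3, 2 and 2 genes with it; all
four contain biomarker candidates, which are thereby candidates for
*predicting* response to the drug rather than merely tracking the disease.
The `hyper_p` column ranks the overlaps against a hypergeometric background
(population = union of both substrates).

The full pipeline — models, permutation-scored relations, segment
enrichment, interference report, seed-stamped TSV/GraphML/JSON outputs — is
one call:

```r
res <- run_pipeline(run_config(study, seed = 1, n_perm = 999), "out/")
```

A thin command-line wrapper with `simulate` / `model` / `interfere` /
`pipeline` subcommands lives at `inst/cli/molproc.R`.

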