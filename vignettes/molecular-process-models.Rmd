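---
title: "Molecular process models from gene signatures on interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular process models from gene signatures on interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molproc)
```

## The problem

Omics profiling of a complex clinical phenotype — the motivating case is
diabetic nephropathy, the major cause of end-stage renal disease — produces
gene signatures: sets of protein-coding genes differentially regulated in
patient tissue, complemented by genes associated with the disease in the
literature. Individually these signatures overlap poorly across studies.
molproc implements a workflow that turns such signatures into a *molecular
process model*: the signatures are consolidated, mapped onto a protein-protein
interaction network merged from multiple source databases on one gene
namespace, and the signature-induced subgraph is segmented into densely
connected *process segments*, each read as a molecular process afflicted with
the phenotype. The same construction applied to drug-perturbation signatures
(e.g. the kidney expression response to a family of ACE inhibitors in the
rat, orthology-mapped to human) yields a mechanism-of-action model. Genes
shared between drug segments and disease segments — the *interference* of the
two models — nominate disease processes a drug actually touches, and
biomarker candidates inside those segments become candidate *predictive*
markers of drug response.

## The pipeline, step by step

1. **Interactome consolidation** (`read_interaction_table()`,
   `map_ids()`, `merge_networks()`). Interaction tables from different
   databases are read (two-column TSV or minimal PSI-MI-TAB, columns 1–2),
   translated onto a common gene namespace and merged by plain node/edge
   union. Networks are undirected and simple: self-loops are dropped and
   duplicate edges collapsed at read time, because the segmentation below
   scores vertices with loop-free densities. How duplicate interactions with
   conflicting evidence across databases should be weighted is not modelled;
   the merge is a union and confidence scores are out of scope.
2. **Signature consolidation** (`consolidate()`, `consensus()`). Multi-study
   signatures are united with per-gene provenance retained, so reports can
   distinguish omics-derived, literature-derived and doubly supported
   features. For a drug family, `consensus(signatures, min_support = 2)`
   keeps genes seen in at least two member signatures; 2 is the default
   because a feature observed for a single compound of a family is weak
   evidence for the class mechanism.
3. **Model building** (`process_model()`). The consolidated signature is
   intersected with the network, the induced subgraph extracted, degree-zero
   nodes (signature genes interacting with no other signature gene) removed,
   and the remainder segmented (next section). The returned object carries
   the substrate graph, the segment list and a bookkeeping report
   (signature size, mapped, isolates removed, retained, genes in segments).
4. **Inter-segment relations** (`score_model_relations()`). Every segment
   pair is scored by its observed cross-segment interaction count,
   contrasted against the counts between two random node sets of matching
   sizes drawn without replacement from a sampling universe. The empirical
   p-value uses the add-one correction `(1 + #{null >= obs}) / (n_perm + 1)`
   and is Benjamini-Hochberg adjusted across pairs.
5. **Enrichment** (`fisher_enrichment()`). One-sided Fisher tests (the
   hypergeometric upper tail) of feature sets in pathways or segments, BH
   adjusted. Only enrichment is tested, not depletion.
6. **Interference** (`interference_map()`, `annotate_segments()`). Drug and
   disease segments are intersected on gene identity only — interaction
   structure plays no role at this stage — and each interfering disease
   segment is annotated with its overlap size, biomarker/target members and
   significantly enriched pathways.

## The segmentation algorithm

Segmentation follows the MCODE scheme of k-core vertex weighting with its
canonical defaults (`mcode_params()`: degree cutoff 2, node score cutoff
(VWP) 0.2, k-core filter 2, maximum depth 100, haircut on, fluff off).

**Scoring.** A vertex below the degree cutoff scores 0. Otherwise the graph
induced on its closed neighbourhood is reduced to its highest k-core (the
non-empty k-core with maximal k), and the score is `k * density` of that
core, with `density = 2|E| / (|V|(|V|-1))`. In any clique K~n~ every vertex
therefore scores exactly `n - 1`.

**Growth.** Segments are seeded greedily at the highest-scoring unassigned
vertex and grown breadth-first; a neighbour may join when its score is at
least `(1 - VWP)` times the seed score. This package adds one condition to
the classical growth rule: a candidate joins only when its *own* highest-core
set already intersects the growing segment (*core reachability*). The score
threshold alone cannot distinguish a dense region's interior from an equally
dense region across a sparse bridge — in two 4-cliques joined by a single
edge all eight vertices score 3.0, so a pure score threshold would absorb
both cliques into one segment. Core reachability encodes that a vertex
belongs with the dense neighbourhood it is actually embedded in: the bridge
endpoint's top core is its own clique, which does not contain any member of
the opposite segment, so growth stops at the bridge and the two cliques
become two segments. The same mechanism is what lets the algorithm recover
planted modules from stochastic block models with sparse inter-module noise
(see the recovery test: five 12-node modules, within-module edge probability
0.9, between 0.02, mean adjusted Rand index above 0.8 over 20 seeds).

**Post-processing.** A grown segment is discarded when it contains no 2-core
(so every reported segment has at least three genes); the haircut then trims
the segment to its 2-core, removing tree-like appendages. Haircut to the
2-core is a fixed point, so a single application suffices. Fluff (off by
default) adds unassigned neighbours whose closed-neighbourhood density
exceeds the fluff threshold. No minimum-size filter beyond the k-core filter
is applied. All ties — seed choice among equal scores, neighbour visiting
order — are broken lexicographically on the gene identifier, which makes the
segmentation a pure function of the graph, independent of input row order.

## The permutation null

The null for an inter-segment relation matches the two node-set *sizes* but
not their degrees; this is deliberate — the reference procedure specifies
size-matched random node sets, and a degree-preserving (configuration-model)
null is declared a non-goal. Consequences worth knowing: in substrates that
are themselves dense and modular, random draws that split a dense region
produce large null counts, so moderate bridging between two segments can be
unremarkable under this null — significance calls are conservative there. The
sampling universe defaults to the substrate nodes (`universe_mode =
"substrate"`); sampling from the full network is available, and since the
reference procedure does not state its universe, the choice is exposed and
recorded in all outputs. With `n_perm` permutations the smallest attainable
p is `1/(n_perm + 1)`; the default 999 resolves the conventional 0.05 level
comfortably after BH adjustment across segment pairs. `z` scores are
reported for description only, never used for decisions (the null standard
deviation can be 0, e.g. on complete graphs).

## Enrichment universes

The Fisher universe is a declared parameter, not a constant: all nodes of
the consolidated network is the default recommendation, all annotated genes
an alternative; the reference analysis does not name its background. The
universe size is written into output headers and attributes, because
p-values move with it.

## The synthetic-data generators

Every stage is testable without downloads via two kinds of generators:

* **Probabilistic** — planted-partition interactomes
  (`generate_network()`, delegating to an established stochastic-block-model
  sampler under a caller-supplied seed), module-anchored signatures with
  coverage and background noise, and fanout-controlled ortholog maps. These
  emulate the *statistical* structure of the real inputs (modular
  interactome, signatures covering a subset of modules, many-to-many
  orthology); they do not emulate the heavy-tailed degrees, evidence biases
  or study-specific platform effects of real interactomes, so passing
  recovery tests demonstrate algorithmic correctness, not real-data
  performance.
* **Cardinality-exact** — constructions honouring requested set sizes and
  overlaps to the gene: `exact_overlap_pair()` (e.g. 516 and 414 sharing
  exactly 49, consolidating to 881), `generate_drug_family()` (six
  signatures of sizes 442/535/526/558/572/519 totalling 3152 memberships
  over 2058 unique genes, with a planted 661-gene consensus core, 228 genes
  in exactly two and 433 in exactly three signatures),
  `synthetic_subgraph_study()` (880 mapped genes of which 246 are isolates,
  retaining 634) and `synthetic_interference_study()` (a 23-segment disease
  model of 200 genes, sizes 3–29 with median 6, a 12-segment drug model of
  92 genes, sizes 3–19 with median 8, planted overlaps of 7/2/3/2 genes on
  disease segments of 29/11/20/16 genes, and a 54-gene biomarker panel with
  exactly 22 members inside the model). The interference study builds its
  models from disjoint dense cliques so that segmentation provably returns
  the planted segments; it exercises arithmetic and reporting, not
  segmentation difficulty.

## Numerical and design choices

* Empirical p-values are never 0 (add-one correction) and BH adjustment is
  delegated to the standard step-up implementation.
* Fisher p-values are computed from the hypergeometric tail; the test suite
  cross-checks them against exhaustive enumeration of all draws for
  universes up to 15 genes at 1e-12.
* Identifier mapping under `policy = "expand"` rewires each edge to all
  target combinations and re-simplifies; two interactors collapsing onto one
  target yield a self-loop, which is dropped. `drop_ambiguous` removes
  sources without exactly one target; expansion is the default because it
  preserves signal through many-to-many orthology.
* Degenerate inputs are legal where the science allows: empty networks and
  empty induced subgraphs yield models with zero segments; a consensus can
  be empty; contract violations (overlapping sets where disjointness is
  required, namespace mismatches, out-of-range supports) raise errors
  immediately.
* Problem sizes in the test suite (planted partitions of 60 nodes, 200-run
  calibration at 99 permutations, exhaustive oracles on graphs of up to 10
  vertices) were chosen as the smallest sizes at which the tested properties
  are meaningful and stable.

## Known limitations

* The merge has no notion of interaction confidence or evidence type.
* Segmentation is non-overlapping by construction; a gene shared by two
  biological processes is assigned to at most one segment.
* The size-matched null ignores degree structure (see above).
* Orthology expansion can inflate dense regions when fanouts are large.
* Interference is gene-identity overlap; it makes no claim about direction
  of effect, binding, or clinical response.
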