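---
title: "Methods: multi-evidence inference of TF-target networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-evidence inference of TF-target networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tfregnet` infers transcription-factor (TF) to target-gene (TG) regulatory
edges by fusing four weak but complementary evidence layers — perturbation
co-expression, promoter binding-site content, annotation agreement, and
curated interaction records — into a single ranked confidence score. This
vignette describes the model and every consequential design choice; the
README shows a worked end-to-end run.

```{r setup}
library(tfregnet)
```

## The inference model

The pipeline assumes a perturbation compendium: a set of two-group
(mutant vs control) expression experiments, each perturbing a regulator,
measured on a shared gene panel. The working hypothesis is the classic
module one: genes that respond coherently across perturbations, share
functional annotation, and carry a common binding-site motif in their
conserved promoter regions are likely targets of the TF family that binds
that motif.

### 1. Candidate selection

`test_differential_expression()` applies, per gene and experiment, an
unpaired two-group Student's t-test (pooled variance by default, Welch by
flag), a fold-change filter on the linear scale and a Present-call
fraction filter. A gene is flagged when p <= 0.05, max(FC, 1/FC) >= 1.5
and at least 67% of the experiment's measurements carry a Present call.
`select_candidate_genes()` keeps genes flagged in at least
`min_experiments` distinct experiments. The function default is 5, the
setting appropriate for a large compendium in which regulators share many
targets; `infer_tf_network()` defaults to 1 because in the benchmark
design each TF is perturbed exactly once and a module responds in exactly
one experiment — requiring five would empty the candidate list by
construction, not by biology.

Choices worth noting: no multiple-testing correction is applied (the
filters are deliberately raw, as the conjunction of three filters is
already conservative); fold change is the ratio of linear-scale group
means, with values assumed log2; a zero-variance gene gets p = 1 when
the group means coincide and p = 0 otherwise, which keeps degenerate
synthetic inputs well-defined; the Present fraction pools both groups of
the experiment.

### 2. FLAME fuzzy clustering

Candidates are grouped by fuzzy clustering via local approximation of
membership with the conventional parameters kNN = 7, at most 500
approximation steps and a 35% membership cutoff. Distances are
1 − Pearson correlation across all samples, so clusters collect
expression *patterns*. Per-gene density is the reciprocal mean distance
to the k nearest neighbors. A gene denser than all its neighbors seeds a
cluster (a cluster-supporting object, CSO); density ties break by
lexicographic identifier so a flat plateau yields exactly one seed. A
gene below all its neighbors and below mean − 2 SD of all densities is
an outlier. All remaining genes start from uniform memberships and are
repeatedly replaced by the density-weighted average of their neighbors'
membership rows; rows remain convex combinations at every step, and the
fixed point solves the associated linear system (this equivalence is
tested directly). Iteration stops when the largest row change drops
below 1e-6.

The 35% membership threshold is read as an assignment *cutoff* (a row
summing to one can then support at most two clusters, which is exactly
the "genes may belong to more than one cluster" behavior the method is
chosen for); reading it as a range width would be the main alternative
interpretation.

### 3. Annotation agreement and enrichment

Functional similarity between two annotated entities is Cohen's kappa on
the 2×2 presence/absence table of their term sets over the catalog's
term universe, clamped to [0, 1] (agreement no better than chance is
reported as 0). Unannotated entities produce missing entries, never
zeros. Cluster-level themes come from a one-sided Fisher exact
(hypergeometric tail) test per term; a term is reported when p < 0.01
and it covers more than 20% of the cluster. The term universe is the
catalog itself, since no external annotation service is consulted.

### 4. Promoter motif analysis

The TFBS score between a motif family and a gene is three-valued: 0 (no
conserved hit), 1 (one conserved hit), 2 (multiple conserved hits).
Conserved hits in either window class count; non-conserved hits never
do. Over-representation of a motif among a cluster's hit-bearing genes
is an exact one-sided hypergeometric test against a background of all
hit-table genes outside the cluster, at alpha 0.005 for the distal
conserved-region (ECR) window and 0.05 for the proximal promoter
(−1000..+200 around the TSS, 0-based half-open; both windows are
configurable). The hypergeometric test stands in for the
motif-scanning programs a genome-scale study would run; it makes the
same enriched/not-enriched call from the hit table with a reproducible
exact statistic.

Motif importance averages the ranking orders of the ECR, promoter and
frequency analyses (frequency = mean conserved hits per cluster gene; it
is Not Determined for motifs that fail promoter enrichment and such ND
ranks are simply skipped in the average). Average ranks are mapped
linearly onto a heatmap score in [−2.5, 2.5] and onto the importance
weight I in [0.8, 1.2], best rank highest; a single motif (or an all-tie)
degenerates to the midpoint (0 and 1.0). Rank ties take average
(fractional) ranks.

### 5. Correlation and interaction evidence

TF–TG co-expression is the plain Pearson coefficient across all pooled
samples (per-experiment correlation is available by subsetting).
Interaction records collapse to the four-level score: 0 no evidence; 1 a
single computational/high-throughput source or low co-citation; 2 more
than one resource *and* co-citation >= 10; 3 direct experimental
evidence or a multi-source curated record. Conflicts resolve to the
maximum. "More than one resource" counts distinct provenance tags when
records carry them, otherwise distinct source classes.

### 6. Integration: Score, Support, Confidence

Each layer is scaled to [0, 1] with fixed maps (TFBS /2, interaction /3,
kappa as-is, correlation rectified at 0 — negative co-expression is not
treated as evidence *for* regulation, though a signed mode exists). The
four scaled matrices are summed and min-max rescaled over the whole
matrix into Score(Ti, Gj). The evidence matrices span the full motif
vocabulary rather than only the cluster's enriched families: with a
single family the within-cluster min-max would merely rank that family's
targets against each other and assign its weakest true target a Score of
exactly 0, while the non-enriched families provide the near-zero
baseline the normalization needs.

Both axes are clustered hierarchically (average linkage, Euclidean
distance on the concatenated scaled-layer feature rows — the linkage and
metric are unconstrained choices; average linkage is the conventional
compromise for block-structured similarity data). Support between a TF
cluster and a TG cluster is the mean Score over their Cartesian product;
pairs with Support >= 0.25 are retained. Within a retained pair, the
confidence of (Ti, Gj) is the product of five equally weighted factors:
Ti's mean link strength to the gene cluster, Gj's mean link strength to
the TF cluster, the pair's Support rescaled into [0.5, 1], the link
strength L(Ti, Gj) = 0.5 + 0.5·Score, and the importance weight I(Ti).
The multiplicative combination is implied by the factor ranges — floors
at 0.5 and weights straddling 1 are the signature of multiplicative
modifiers, and "equally weighted" is read as no exponents. The factor
tied to the cluster pair is instantiated as its Support, the only
defined inter-cluster quantity; it can be disabled by passing a
pre-filtered pair table with support fixed at 1. Raw products are
min-max normalized to [0, 1] over all scored pairs (globally by default;
per cluster pair by option), so the minimum pair maps to exactly 0 while
raw products are always strictly positive. Predictions are ranked by
confidence with deterministic identifier tie-breaks.

### 7. Network construction and validation

Connectivity is the number of distinct targets a TF keeps at a
confidence cutoff (0.5 by convention); a target predicted in several
clusters counts once in the total but appears in each per-cluster
column. Networks are built at a cutoff (0.6 conventionally), optionally
restricted to the top-k hub TFs, with per-edge cross-cluster frequency,
and export to SIF or attribute-complete GraphML.

Validation offers three instruments. (a) The binomial overlap test:
given a perturbation-response gene list, the p-value is the exact upper
binomial tail of the overlap with a predicted set, at background rate
|response|/|universe|. The universe is the candidate-gene set the
predictions were drawn from — using the whole gene panel would conflate
"the pipeline found responsive genes at all" with "high-confidence
predictions are enriched among them". The conventional positive set is
confidence > 0.55; the negative control is the set of genes whose best
confidence over the whole table is < 0.45. A per-TF negative control
(the TF's own low-ranked pairs) is degenerate at benchmark scale: the
planted modules are disjoint and the clusters nearly pure, so a TF's
low-confidence pairs are still overwhelmingly its *true* targets and
respond to its deletion just as the high-confidence ones do. (b) Known-pair
rank reports: the worst rank percentile of a TF's known targets among
the predictions. (c) Recovery metrics against a planted truth:
precision/recall over a cutoff grid and the Mann–Whitney area under the
ROC curve over all TF×gene pairs (unscored pairs count as 0).

## The synthetic benchmark

`synthetic_config()` fixes the benchmark condition: 200 genes, 6 TFs
each owning a disjoint 15-gene module, one knockout experiment per TF
with 3 mutant and 3 control arrays, within-group noise 0.25 (log2) and a
−1 log2 perturbation shift (a 4 SD effect), a 100-term annotation
universe with 10 terms per module shared at probability 0.7 over a 0.02
background, motif presence 0.8 for true targets against 0.1 background,
and interaction records covering 30% of true edges with geometric
co-citation counts of mean 8 (so both the <=10 and >=10 branches of the
interaction score occur in practice). Present calls are independent
flags at probability 0.9 — the original detection algorithm is not
reproducible and only the fraction filter downstream matters. All five
generators are deterministic in the configured seed.

What the generator deliberately does not emulate: probe-level noise and
normalization artifacts, correlated annotation structure (term
hierarchies), sequence-level motif scanning (hits are simulated at the
table level), overlapping or nested regulatory modules, and
combinatorial regulation. Passing the recovery suites therefore shows
the pipeline's statistics and plumbing are correct under the stated
generative model, not that the method's error rates transfer to real
compendia.

Benchmark problem sizes in the test suite (200 genes × 36 arrays per
run, 20 seeds for the recovery suites; smaller instances for the oracle
and bound checks) were chosen so the full suite documents behavior at a
scale where every statistic is exactly checkable.

## Numerical choices and degenerate inputs

* Hypergeometric and binomial tails are computed exactly
  (`phyper`/`pbinom`), never by normal approximation; tests compare them
  with brute-force enumeration.
* kappa with expected agreement 1 (both sets spanning the universe) is
  defined as 1 for identical sets and 0 otherwise.
* Constant expression profiles yield missing correlations (never 0),
  missing entries in evidence layers are imputed as 0 and flagged.
* Degenerate min-max cases: an all-equal summed evidence matrix maps to
  Score 1 when positive and 0 otherwise; an all-equal confidence vector
  maps to 1 (all pairs equally supported).
* kNN ties, CSO ties, hub ties and ranking ties all break
  lexicographically, making every stage deterministic.
* FLAME non-convergence within 500 steps is reported in the result, not
  fatal.

## Known limitations

The evidence fusion is unweighted by design — learning layer weights or
calibrating confidence probabilistically is out of scope. Annotation
kappa ignores ontology structure. The hypergeometric motif test ignores
hit multiplicity within a promoter (multiplicity enters only through the
TFBS score and the frequency ranking). Confidence values are
min-max-normalized per run and are therefore comparable within, not
across, analyses.
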