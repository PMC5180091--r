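---
title: "Ranking cancer driver genes with a positive-unlabeled random forest"
author: "puForest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking cancer driver genes with a positive-unlabeled random forest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puForest)
```

## The problem

Cancer driver genes — tumor suppressors (TSGs) whose loss promotes disease
and oncogenes (OGs) whose activation does — are usually found by looking for
excess mutations in tumor cohorts. Genes mutated rarely, or with atypical
patterns, escape that net. An alternative is similarity-based ranking: given
a small set of trustworthy drivers and a large table of gene-level properties
(genomic context, expression, protein size, post-translational modification
density, network centrality, functional annotations, tumor mutation
patterns), train a classifier to score every gene in the genome by how much
it resembles known drivers.

puForest implements this analysis end to end: assembling training labels
from heterogeneous evidence sources, preparing a mixed-type feature matrix,
fitting a positive-unlabeled (PU) random forest with exact out-of-bag
scoring, evaluating the ranking with a tiered precision-at-N protocol, and
computing the enrichment statistics that connect protein size, chromatin
biology and TSG function.

## Label assembly

Published driver lists disagree, so labels are built in tiers from a
gene-by-source membership table:

* **High confidence** — admitted by an ordered, declarative rule list: a
  curated base source taken wholesale, a census-plus-supporting-databases
  rule for deletion TSGs, curated deletion/amplification lists, a
  two-source intersection for amplified OGs, and vote rules over
  mutation-method sources whose candidates require a manual role call.
  Rules are data, not code: the published curation (which cannot be
  recomputed) ships as a programmatic fixture, `paperMembershipFixture()`,
  sized so the rule engine reproduces the published arithmetic — 84 TSGs
  and 81 OGs (165 drivers), 682 medium, 1,360 low, 15,972 background genes
  in a 19,486-gene universe, a 97-fold class imbalance.
* **Medium / low** — unions of designated genomics and secondary sources,
  with precedence high > medium > low > other > background.
* **Background (BG)** — genes with no source evidence; the negatives.

Genes re-admitted under a conflicting role raise an error unless an explicit
override resolves them; the one dual-role gene in the encoded curation
(MYCN) is resolved by a removal override, mirroring the published decision.
The curated deletion list names five genes where its description says four;
the fixture preserves the list verbatim and lets the removal override
resolve the arithmetic rather than silently editing it.

Training uses only high-confidence positives and BG negatives. Medium, low
and other-tier genes are excluded — they are the genes the ranking is meant
to recover.

## Feature preparation

The pipeline applies, in a fixed order:

1. **Sparse-feature removal** — a feature is dropped iff its
   first-to-second most-common-value frequency ratio exceeds 97/3 *and* its
   distinct values are fewer than 3% of the gene count. A missing marker
   counts as a value in both tallies. Note a tension inherited from the
   method description: counting missingness as an extra value *raises* the
   distinct-value count and so works against removal; we implement the
   criteria literally.
2. **Correlated-feature removal** — greedy elimination of pairs with
   |Spearman| > 0.95 (pairwise-complete, average ranks for ties), dropping
   the member with the greater mean absolute correlation; pair and member
   ties break lexicographically so the result is deterministic.
3. **k-nearest-neighbor imputation** (k = 5) — neighbors by Euclidean
   distance on standardized features restricted to mutually observed
   coordinates and rescaled by coordinate count (the method description is
   silent on scaling; unstandardized distances would let large-scale
   features dominate). A missing cell becomes the neighbor mean, falling
   back to the column median when all five neighbors also miss it.
   Observed cells are never altered. Binary cells imputed this way may be
   fractional in [0, 1].
4. **Encoding** — binary as 0/1, categoricals one-hot, continuous passed
   through, with an invertible column map.

Derived features follow the stated definitions: genomic density counts
genes within a ±4 Mb closed window around each gene center (self included —
inclusion shifts every count equally before normalization) divided by the
mean count; interaction counts average two databases, using the available
one when the other is missing; betweenness is unnormalized Brandes
centrality (via igraph); the tissue "variation" feature is implemented
exactly as the original feature table defines it — the mean divided by the
standard deviation, the *reciprocal* of the conventional coefficient of
variation — with a `conventional` switch; PTM site counts are divided by
CDS length.

## The positive-unlabeled forest

Treating all 15,972 BGs as negatives is PU learning: some "negatives" are
undiscovered drivers. Two design elements address this:

* **Stratified down-sampled bootstraps.** Each tree draws, with
  replacement, all-positives-many genes from the positive stratum (TSG/OG
  labels retained) plus the same number from the BG stratum — 165 + 165 at
  the published geometry. Each tree therefore sees a balanced problem and a
  *different* sliver of the BG pool, diluting any mislabeled negative.
* **Exact out-of-bag (OOB) posteriors.** Every tree records its in-bag
  multiset. A gene is scored by averaging leaf class proportions (soft
  votes) over exactly the trees that never drew it; never-trained genes are
  scored by all trees. With replacement, a positive is absent from a bag
  with probability (1 − 1/P)^P ≈ 0.367 at P = 165, so roughly a third of
  the ensemble scores each training gene.

Trees are CART: Gini impurity splits, `mtry = floor(sqrt(p))` features per
node (the standard classification default), midpoint thresholds, grown to
purity (`minNodeSize = 1`, no depth cap). Ties in impurity decrease break
toward the lowest feature index, then the lowest threshold, making trees
deterministic. Each tree runs its own counter-based RNG stream derived from
(master seed, tree index) — splitmix64 — so tree t is reproducible in
isolation and a parallel fit would agree bit-for-bit with a serial one.

Scores: `driver_score = P(TSG) + P(OG)` ranks genes as drivers;
`P(TSG) / (P(TSG) + P(OG))` separates TSGs from OGs. The ROC label
convention (TSG = 1) fixes the direction; the exact score formula for this
reduction was never published, so the conditional posterior given driver is
this package's documented choice — it is the only two-class reduction
consistent with the stated labels. Because of down-sampling, scores are calibrated for
*ranking*, not as true driver probabilities.

Soft votes (leaf proportions) rather than hard majority votes are used for
aggregation: with few OOB trees, hard votes quantize harshly. This is a
deviation risk relative to reference implementations that default to hard
votes; the direction of rankings agrees (checked against randomForest in
the test suite).

Whether the positive stratum was originally drawn with or without
replacement is not fully determined by the text; with replacement is the
default (as stated), and `replacePositives = FALSE` provides the
alternative.

## Evaluation protocol

`precisionAtN()` implements the tiered panel protocol: the high-confidence
panel excludes nothing; the medium panel first removes high-confidence
genes from the ranked list; the low panel removes high and medium. Precision
at N is then the fraction of the top N surviving genes in the target tier.
`cumulativeDetection()` is its unnormalized counterpart;
`tsgOgAuc()` is the Mann–Whitney AUC with midranks;
`stabilityAnalysis()` refits with a dropped fraction of positives (defaults:
10 replicates, 10% dropped — the original protocol is not public, so these
are this package's choices) and correlates the replicate rankings.
`featureSetContrast()` reruns the pipeline per feature subset and returns
the per-tier curves; orderings among curves are data-dependent and not
asserted.

## Enrichment statistics

`hypergeomUpperTail()` computes P(X ≥ k) exactly in log space (the upper
tail is *inclusive* — the convention is not stated in the source, so an
exclusive switch exists). `foldEnrichment()` is (k/n)/((K−k)/(N−n)).
`sizePercentiles()` uses max-rank ties (tied largest genes share the 100.0
percentile) and `topFraction()` keeps ties at the cut, so the top-5% set is
deterministic for integer amino-acid lengths. `intersectAndProfile()`
combines them: top-size genes ∩ annotation flag, driver composition inside
versus outside, and secondary-annotation sub-profiles.

On the printed counts these reproduce: P = 8.56 × 10⁻⁶ for 26 TSGs among
the 30 largest driver proteins; P = 2.3 × 10⁻²⁷ and a 61.6-fold (printed:
62-fold) TSG enrichment for 19 of 84 TSGs inside the 92-gene
large-chromatin set; 23% and 72% composition shares. The 10⁻²⁷-scale tail
only reproduces under the inclusive convention, which is further evidence
for P(X ≥ k) as the intended tail.

## The synthetic universe

Real inputs were compiled from resources that cannot be redistributed, so
`generateUniverse()` builds universes with the structure the analysis
assumes:

* class-conditional mean shifts (default 1.5 sd) on informative continuous
  features, alternating between TSG- and OG-shifted so the classes stay
  mutually separable; every third feature long-tailed (log-normal) to mimic
  expression- and size-like distributions;
* binary features enriched in drivers (0.40 vs 0.05), and a
  chromatin-organization flag at 0.5 in TSGs vs 0.1 elsewhere;
* log-normal CDS lengths (median ≈ 490 aa) with planted TSG∩chromatin genes
  inflated 3.8-fold — the fold difference reported between chromatin and
  non-chromatin tumor suppressors;
* planted sparse and (near-)duplicate features that the filters must remove
  by construction; completely-at-random missingness (default 5%; sparse
  columns stay complete, as near-constant annotation flags are);
* 15 evidence sources firing on true drivers with sensitivity 0.9, on BGs
  at rate 0.01, with 5% role miscalls;
* a preferential-attachment interaction graph and a single synthetic
  chromosome with uniform gene centers over 0–250 Mb (genomic density only
  needs local neighbor counts).

The default desk-scale universe is 2,000 genes with 40 TSGs and 40 OGs and
40 features; the full 19,486 × 131 geometry is supported but slow for
routine testing. Tests and the acceptance script use 2,000-gene universes
with 100–2,000 trees; the published full-scale run used 100,000 trees,
which the same code accepts.

What the generator does *not* emulate: mutation-calling noise, tumor-type
structure, feature dependence beyond the planted correlations, and
informative missingness. Passing tests therefore demonstrate that the
machinery recovers planted structure under MCAR missingness and independent
features — not that the real-data rankings would reproduce, which would
require the original compiled inputs.

## Numerical and design notes

* Effect sizes per class are free parameters of the generator, not
  estimates — the source reports no real-data effect sizes.
* Missingness is MCAR only; the imputation is distance-based and makes no
  mechanism claim.
* Constant features have undefined correlations, treated as 0 with a
  warning; a feature missing in every gene is an error at imputation (it
  should have been filtered).
* Degenerate forest inputs: identical rows with mixed labels become a
  majority-count leaf; a node whose sampled features are all constant
  becomes a leaf.
* Genes scored by zero OOB trees (possible only for training genes in tiny
  ensembles) carry NA posteriors and are excluded from rankings with a
  warning.
* The 32-bit fingerprints in the run manifest are content checks for
  reproducibility, not cryptographic hashes.

## A worked desk-scale run

```{r, eval = FALSE}
cfg <- simConfig(seed = 1)          # 2,000 genes, 40 TSG + 40 OG
u <- generateUniverse(cfg)
prep <- prepareFeatures(u$features)
training <- data.frame(gene_id = u$truth@geneId,
                       class = as.character(u$truth@trueClass))
fit <- fitForest(prep$matrix, training, forestConfig(nTrees = 2000, seed = 2))
pt <- oobPosteriors(fit, prep$matrix)
pt
head(sort(featureImportance(fit), decreasing = TRUE))
```

`runPipeline()` wires the same stages together behind a manifest, and
`scripts/acceptance.R` (repository root) recomputes the headline quantities
from scratch.
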