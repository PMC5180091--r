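# puForest

Positive-unlabeled random-forest ranking of cancer driver genes.

## What this is for

Most cancer driver genes are found by hunting for excess somatic mutations,
which misses drivers that are mutated rarely or atypically. An alternative
is similarity-based ranking: given a small set of high-confidence drivers —
tumor suppressor genes (TSGs) and oncogenes (OGs) — and a genome-wide table
of gene-level properties (genomic density, expression, protein size,
post-translational-modification density, interaction-network centrality,
functional annotations, tumor mutation patterns), score every gene by how
much it resembles known drivers. puForest implements that analysis for
computational cancer-genomics groups: label assembly from heterogeneous
evidence sources, feature preparation, the PU forest itself, the evaluation
protocol, and the enrichment statistics linking protein size and chromatin
biology to TSG function.

## The method

Labels are tiers: **high-confidence** drivers admitted by an ordered rule
list over evidence sources (84 TSGs + 81 OGs = 165 at the published
geometry), **medium/low/other** genes with weaker evidence (excluded from
training, used for evaluation), and **background** genes (BGs) with no
evidence (15,972), giving a ~97-fold class imbalance.

Because some "background" genes are undiscovered drivers, training is
positive-unlabeled. Each of the *T* trees (CART, Gini impurity,
mtry = ⌊√p⌋, grown to purity) draws a stratified down-sampled bootstrap:
165 positives plus 165 BGs, each with replacement, so every tree sees a
balanced problem and a different sliver of the BG pool. Every tree records
its exact in-bag multiset; a gene's posterior

> (P(TSG), P(OG), P(BG)), summing to 1

is the average of leaf class proportions over exactly the trees whose bag
excludes it (out-of-bag estimation; a positive is out of bag with
probability (1 − 1/165)¹⁶⁵ ≈ 0.367). Genes are ranked by
P(driver) = P(TSG) + P(OG); TSG-vs-OG separation uses
P(TSG)/(P(TSG)+P(OG)). Feature importance is mean Gini impurity decrease.

Evaluation is precision at N per confidence tier with panel exclusion
(medium panel excludes high-confidence genes from the ranked list, low
excludes both) plus the Mann–Whitney AUC for TSG-vs-OG. Enrichment uses the
exact hypergeometric upper tail P(X ≥ k), fold enrichment
(k/n)/((K−k)/(N−n)), Welch t-tests and max-rank size percentiles — on the
printed counts: P = 8.56 × 10⁻⁶ for 26 TSGs among the 30 largest driver
proteins, and a 62-fold TSG enrichment (P = 2.3 × 10⁻²⁷) in the 92 genes
that encode top-5% proteins and act in chromosome organization.

Real feature tables were compiled from resources that cannot be
redistributed, so the package ships a synthetic-universe generator
(`generateUniverse`) with planted class-conditional effects, degenerate
features, missingness, an evidence-source error model, a scale-free
interaction graph, and a planted TSG∩chromatin protein-size inflation. See
`vignettes/driver-gene-ranking.Rmd` for the full model description and
design decisions.

## Worked example

```r
library(puForest)

cfg <- simConfig(seed = 1)              # 2,000 genes, 40 TSG + 40 OG planted
u <- generateUniverse(cfg)
prep <- prepareFeatures(u$features)     # filter sparse/correlated, impute, encode
training <- data.frame(gene_id = u$truth@geneId,
                       class = as.character(u$truth@trueClass))
fit <- fitForest(prep$matrix, training, forestConfig(nTrees = 2000, seed = 2))
pt <- oobPosteriors(fit, prep$matrix)
fit
#> DriverForest: 2000 trees over 2000 training genes, 38 features
#>   per-tree bag: 80 positives + 80 background (seed 2)
pt
#> PosteriorTable: 2000 genes (2000 scored)
#>  gene_id  P_TSG   P_OG  P_BG driver_score
#>   G01766 0.0233 0.8765 0.100        0.900
#>   G01350 0.0256 0.8670 0.107        0.893
#>   G01395 0.0464 0.8284 0.125        0.875
#>   G00526 0.1502 0.7185 0.131        0.869
#>   G01017 0.7687 0.0706 0.161        0.839
head(sort(featureImportance(fit), decreasing = TRUE), 5)
#>    cont_03    cont_02    cont_10    cont_04    cont_07
#> 0.07035236 0.05673222 0.04944297 0.04740173 0.04445290
```

The top-ranked genes are planted drivers scored out-of-bag: `G01766` is
ranked almost pure OG (P_OG = 0.88), `G01017` almost pure TSG, and the most
important features are exactly the continuous features carrying the planted
class shift. Median driver score is 0.685 for planted drivers versus 0.177
for background genes in this run. The published arithmetic is reproduced by
the label rule engine:

```r
fx <- publishedCurationFixture()
hc <- assembleHighConfidence(fx$membership, fx$rules, fx$overrides)
table(hc$class)
#>  OG TSG
#>  81  84
hypergeomUpperTail(165, 84, 30, 26)
#> [1] 8.564915e-06
```

`runPipeline(simConfig(...), forestConfig(...), outputDir = "run1")` chains
simulate → labels → features → train → rank → evaluate → enrich with a
reproducibility manifest.

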