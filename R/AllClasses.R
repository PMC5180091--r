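#' @import methods
#' @importFrom stats median sd cor complete.cases pt runif rnorm rbinom rlnorm quantile setNames
#' @importFrom utils head write.table read.delim
NULL

TIER_LEVELS <- c("high_TSG", "high_OG", "medium", "low", "other", "background")
CLASS_LEVELS <- c("TSG", "OG", "BG")

#' Configuration of a synthetic gene universe
#'
#' Holds every parameter of the synthetic-universe generator: universe and
#' class sizes, feature counts and effect sizes, missingness, planted sparse
#' and duplicated features, the coding-sequence-length inflation applied to
#' tumor-suppressor genes with a chromatin-organization role, and the
#' evidence-source error model. All downstream outputs are pure functions of
#' this object (including its seed).
#'
#' @slot nGenes integer, universe size.
#' @slot nTsg,nOg integers, planted tumor-suppressor and oncogene counts.
#' @slot nContinuous,nBinary integers, feature counts by type.
#' @slot nInformative integer, number of continuous features carrying a
#'   class-conditional mean shift (capped at \code{nContinuous}).
#' @slot effectSize numeric, standardized mean shift per informative
#'   continuous feature.
#' @slot binaryEnrichment numeric length-2, Bernoulli rates for informative
#'   binary features in drivers vs background genes.
#' @slot missingRate numeric in [0,1), completely-at-random missing fraction.
#' @slot nSparse,nDuplicate integers, counts of planted degenerate features.
#' @slot sizeInflation numeric >= 1, multiplicative CDS-length factor for the
#'   planted TSG-and-chromatin genes.
#' @slot chromatinRateTsg,chromatinRateBg numeric, rates of the chromatin
#'   organization flag in TSGs and in all other genes.
#' @slot nSources integer, number of evidence sources emulated.
#' @slot sourceSensitivity,sourceFpr numeric, per-source detection rate for
#'   true drivers and false-positive rate for background genes.
#' @slot roleFlip numeric, probability that a source miscalls a driver's
#'   TSG/OG role.
#' @slot seed integer master seed.
#' @export
setClass("SimConfig", representation(
  nGenes = "integer", nTsg = "integer", nOg = "integer",
  nContinuous = "integer", nBinary = "integer", nInformative = "integer",
  effectSize = "numeric", binaryEnrichment = "numeric",
  missingRate = "numeric", nSparse = "integer", nDuplicate = "integer",
  sizeInflation = "numeric", chromatinRateTsg = "numeric",
  chromatinRateBg = "numeric", nSources = "integer",
  sourceSensitivity = "numeric", sourceFpr = "numeric", roleFlip = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nTsg + object@nOg >= object@nGenes)
    msg <- c(msg, "nTsg + nOg must be smaller than nGenes")
  rates <- c(object@binaryEnrichment, object@missingRate,
             object@sourceSensitivity, object@sourceFpr, object@roleFlip,
             object@chromatinRateTsg, object@chromatinRateBg)
  if (any(rates < 0 | rates > 1)) msg <- c(msg, "all rates must lie in [0,1]")
  if (object@missingRate >= 1) msg <- c(msg, "missingRate must be < 1")
  if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
  if (object@sizeInflation < 1) msg <- c(msg, "sizeInflation must be >= 1")
  if (object@nSparse + object@nDuplicate > object@nContinuous)
    msg <- c(msg, "planted sparse+duplicate features exceed nContinuous")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic universe
#'
#' Per-gene true class (TSG/OG/BG), the planted chromatin-organization flag,
#' and the names of the informative features. Kept separate from the feature
#' table so that truth can never leak into the classifier input.
#'
#' @slot geneId character vector of gene identifiers.
#' @slot trueClass factor with levels TSG, OG, BG.
#' @slot chromatinFlag logical, planted chromatin-organization membership.
#' @slot informativeFeatures character, names of features with planted signal.
#' @export
setClass("SimTruth", representation(
  geneId = "character", trueClass = "factor", chromatinFlag = "logical",
  informativeFeatures = "character"
))

setValidity("SimTruth", function(object) {
  if (length(object@geneId) != length(object@trueClass) ||
      length(object@geneId) != length(object@chromatinFlag))
    return("geneId, trueClass and chromatinFlag lengths differ")
  if (!identical(levels(object@trueClass), CLASS_LEVELS))
    return("trueClass levels must be TSG, OG, BG")
  TRUE
})

#' Gene-level feature table with declared column types
#'
#' One row per gene; columns are continuous, binary (0/1) or categorical
#' features, any cell may be missing (NA). The type declaration drives the
#' sparse-feature filter, the correlation filter and one-hot encoding.
#'
#' @slot data data.frame of features, rownames are gene identifiers.
#' @slot featureType named character, one of \code{"continuous"},
#'   \code{"binary"}, \code{"categorical"} per column of \code{data}.
#' @export
setClass("FeatureTable", representation(
  data = "data.frame", featureType = "character"
))

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (!identical(sort(names(object@featureType)), sort(names(object@data))))
    msg <- c(msg, "featureType names must match data columns")
  if (!all(object@featureType %in% c("continuous", "binary", "categorical")))
    msg <- c(msg, "featureType values must be continuous/binary/categorical")
  if (is.null(rownames(object@data)) || anyDuplicated(rownames(object@data)))
    msg <- c(msg, "data must have unique gene rownames")
  bin <- names(object@featureType)[object@featureType == "binary"]
  for (b in bin) {
    v <- object@data[[b]]
    # raw binary cells are 0/1; mean-imputed cells may be fractional in [0,1]
    if (!all(is.na(v) | (v >= 0 & v <= 1)))
      msg <- c(msg, sprintf("binary feature '%s' has values outside [0,1]", b))
  }
  if (length(msg)) msg else TRUE
})

#' Gene-by-source evidence membership with per-source role calls
#'
#' @slot membership logical matrix, genes x sources.
#' @slot role character matrix of the same shape: \code{"TSG"}, \code{"OG"} or
#'   \code{"unknown"} where membership is TRUE, NA elsewhere.
#' @slot sourceInfo data.frame with columns \code{name} and \code{category}
#'   (curated, mutation_method, cna, db, biomarker).
#' @export
setClass("SourceMembership", representation(
  membership = "matrix", role = "matrix", sourceInfo = "data.frame"
))

setValidity("SourceMembership", function(object) {
  msg <- character()
  if (!is.logical(object@membership)) msg <- c(msg, "membership must be logical")
  if (!identical(dim(object@membership), dim(object@role)))
    msg <- c(msg, "membership and role dimensions differ")
  if (!identical(colnames(object@membership), object@sourceInfo$name))
    msg <- c(msg, "sourceInfo$name must equal membership colnames")
  bad <- !object@membership & !is.na(object@role)
  if (any(bad)) msg <- c(msg, "role defined where membership is FALSE")
  ok <- object@role[object@membership]
  if (!all(is.na(ok) | ok %in% c("TSG", "OG", "unknown")))
    msg <- c(msg, "roles must be TSG/OG/unknown")
  if (length(msg)) msg else TRUE
})

#' Disjoint confidence-tier assignment over a gene universe
#'
#' Every gene carries exactly one tier: \code{high_TSG}, \code{high_OG},
#' \code{medium}, \code{low}, \code{other} or \code{background}. High-confidence
#' genes record which admission rule let them in.
#'
#' @slot tier named factor over the tier levels; names are gene identifiers.
#' @slot provenance named character, admission-rule label per high-confidence
#'   gene.
#' @export
setClass("LabelSet", representation(
  tier = "factor", provenance = "character"
))

setValidity("LabelSet", function(object) {
  msg <- character()
  if (!identical(levels(object@tier), TIER_LEVELS))
    msg <- c(msg, "tier levels must be the six canonical tiers")
  if (is.null(names(object@tier)) || anyDuplicated(names(object@tier)))
    msg <- c(msg, "tier must be named by unique gene ids")
  high <- names(object@tier)[object@tier %in% c("high_TSG", "high_OG")]
  if (!all(high %in% names(object@provenance)))
    msg <- c(msg, "every high-confidence gene needs a provenance entry")
  if (length(msg)) msg else TRUE
})

#' Ensemble configuration for the positive-unlabeled forest
#'
#' @slot nTrees integer, ensemble size (the full-scale analysis uses 1e5
#'   trees; desk-scale default 2000).
#' @slot mtry integer, features tried per split; 0 means use floor(sqrt(p)).
#' @slot minNodeSize integer, smallest node that may still be split.
#' @slot maxDepth integer depth bound; 0 means unbounded (grow to purity).
#' @slot seed integer master seed; tree t uses an independent stream derived
#'   from (seed, t) so trees are reproducible in any execution order.
#' @slot positiveDraw,bgDraw integers, per-tree stratified bootstrap sizes;
#'   0 means "number of positives" for both (the paired down-sampling design).
#' @slot replacePositives logical, sample the positive stratum with
#'   replacement (the stated design) or without.
#' @export
setClass("ForestConfig", representation(
  nTrees = "integer", mtry = "integer", minNodeSize = "integer",
  maxDepth = "integer", seed = "integer", positiveDraw = "integer",
  bgDraw = "integer", replacePositives = "logical"
))

setValidity("ForestConfig", function(object) {
  msg <- character()
  if (object@nTrees < 1L) msg <- c(msg, "nTrees must be >= 1")
  if (object@mtry < 0L) msg <- c(msg, "mtry must be >= 0")
  if (object@minNodeSize < 1L) msg <- c(msg, "minNodeSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Fitted positive-unlabeled random forest
#'
#' Stores the trees (flattened node arrays), the exact in-bag gene multiset of
#' every tree (required for out-of-bag scoring), per-feature accumulated Gini
#' importance, and the training metadata.
#'
#' @slot trees list of per-tree node matrices.
#' @slot inBag list of integer vectors; element t holds the row indices (into
#'   the training gene set) drawn into tree t's bag, with multiplicity.
#' @slot trainGeneIds character, gene ids of the rows trees were grown on.
#' @slot featureNames character, encoded feature columns.
#' @slot classLevels character, \code{c("TSG","OG","BG")}.
#' @slot importance numeric, per-feature Gini importance summed over trees.
#' @slot config the \linkS4class{ForestConfig} used.
#' @export
setClass("DriverForest", representation(
  trees = "list", inBag = "list", trainGeneIds = "character",
  featureNames = "character", classLevels = "character",
  importance = "numeric", config = "ForestConfig"
))

#' Per-gene out-of-bag class posteriors and driver ranking
#'
#' @slot table data.frame with columns gene_id, P_TSG, P_OG, P_BG,
#'   n_oob_trees, driver_score, rank. Genes scored by zero trees carry NA
#'   posteriors and NA rank.
#' @export
setClass("PosteriorTable", representation(table = "data.frame"))

setValidity("PosteriorTable", function(object) {
  need <- c("gene_id", "P_TSG", "P_OG", "P_BG", "n_oob_trees",
            "driver_score", "rank")
  if (!all(need %in% names(object@table)))
    return(paste("missing columns:", paste(setdiff(need, names(object@table)),
                                           collapse = ", ")))
  tb <- object@table
  ok <- tb$n_oob_trees > 0
  s <- tb$P_TSG[ok] + tb$P_OG[ok] + tb$P_BG[ok]
  if (length(s) && any(abs(s - 1) > 1e-9))
    return("posterior rows must sum to 1 wherever n_oob_trees > 0")
  TRUE
})

#' Count-based enrichment statistic
#'
#' Population of size N with K annotated successes; n draws contain k
#' successes. Carries the exact hypergeometric upper-tail probability
#' P(X >= k) and the fold enrichment of the in-set success rate over the
#' out-of-set rate.
#'
#' @slot N,K,n,k integers as above.
#' @slot pUpper numeric upper-tail probability.
#' @slot fold numeric fold enrichment (Inf when all successes are drawn).
#' @export
setClass("EnrichmentResult", representation(
  N = "integer", K = "integer", n = "integer", k = "integer",
  pUpper = "numeric", fold = "numeric"
))

setValidity("EnrichmentResult", function(object) {
  if (object@k > min(object@n, object@K)) return("k exceeds min(n, K)")
  if (object@k < 0L || object@K > object@N || object@n > object@N)
    return("counts out of range")
  TRUE
})

#' Welch two-sample t-test result
#'
#' @slot statistic numeric t statistic.
#' @slot df numeric Welch-Satterthwaite degrees of freedom.
#' @slot pValue numeric two-sided p-value.
#' @export
setClass("WelchResult", representation(
  statistic = "numeric", df = "numeric", pValue = "numeric"
))

#' Tiered precision-at-N curve
#'
#' @slot curve data.frame with columns tier, N, hits, precision.
#' @slot excluded character, genes removed from the ranked list before
#'   evaluation (the panel-exclusion protocol).
#' @export
setClass("PrecisionCurve", representation(
  curve = "data.frame", excluded = "character"
))
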