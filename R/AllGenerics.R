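#' @rdname accessors
#' @param x an object holding per-gene data.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("featureTypes", function(x) standardGeneric("featureTypes"))

#' @rdname accessors
#' @export
setGeneric("tiers", function(x) standardGeneric("tiers"))

#' @rdname accessors
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))

#' Accessors for puForest objects
#'
#' \code{geneIds} returns gene identifiers; \code{featureNames} and
#' \code{featureTypes} the feature columns and their declared types;
#' \code{tiers} the named tier factor of a \linkS4class{LabelSet};
#' \code{posteriors} the per-gene posterior data.frame of a
#' \linkS4class{PosteriorTable}.
#'
#' @name accessors
#' @aliases geneIds featureNames featureTypes tiers posteriors
NULL

setMethod("geneIds", "FeatureTable", function(x) rownames(x@data))
setMethod("geneIds", "SimTruth", function(x) x@geneId)
setMethod("geneIds", "SourceMembership", function(x) rownames(x@membership))
setMethod("geneIds", "LabelSet", function(x) names(x@tier))
setMethod("geneIds", "PosteriorTable", function(x) x@table$gene_id)
setMethod("featureNames", "FeatureTable", function(x) colnames(x@data))
setMethod("featureTypes", "FeatureTable", function(x) x@featureType)
setMethod("tiers", "LabelSet", function(x) x@tier)
setMethod("posteriors", "PosteriorTable", function(x) x@table)

#' @export
#' @describeIn FeatureTable-class number of genes and features.
setMethod("dim", "FeatureTable", function(x) dim(x@data))

#' @export
#' @describeIn FeatureTable-class the feature data.frame.
setMethod("as.data.frame", "FeatureTable",
          function(x, ...) x@data)

#' @export
#' @describeIn PosteriorTable-class the posterior data.frame.
setMethod("as.data.frame", "PosteriorTable",
          function(x, ...) x@table)

setMethod("show", "FeatureTable", function(object) {
  tt <- table(factor(object@featureType,
                     c("continuous", "binary", "categorical")))
  cat(sprintf("FeatureTable: %d genes x %d features (%d continuous, %d binary, %d categorical)\n",
              nrow(object@data), ncol(object@data),
              tt[["continuous"]], tt[["binary"]], tt[["categorical"]]))
  nmiss <- sum(is.na(as.matrix(object@data)))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss,
              100 * nmiss / max(1, prod(dim(object@data)))))
})

setMethod("show", "LabelSet", function(object) {
  cat("LabelSet over", length(object@tier), "genes\n")
  print(table(object@tier))
})

setMethod("show", "SourceMembership", function(object) {
  cat(sprintf("SourceMembership: %d genes x %d sources\n",
              nrow(object@membership), ncol(object@membership)))
  cat("  sources:", paste(head(colnames(object@membership), 8), collapse = ", "),
      if (ncol(object@membership) > 8) "..." else "", "\n")
})

setMethod("show", "DriverForest", function(object) {
  cat(sprintf("DriverForest: %d trees over %d training genes, %d features\n",
              length(object@trees), length(object@trainGeneIds),
              length(object@featureNames)))
  cat(sprintf("  per-tree bag: %d positives + %d background (seed %d)\n",
              object@config@positiveDraw, object@config@bgDraw,
              object@config@seed))
})

setMethod("show", "PosteriorTable", function(object) {
  tb <- object@table
  cat(sprintf("PosteriorTable: %d genes (%d scored)\n",
              nrow(tb), sum(tb$n_oob_trees > 0)))
  top <- tb[order(tb$rank), c("gene_id", "P_TSG", "P_OG", "P_BG",
                              "driver_score")]
  print(head(top, 5), row.names = FALSE, digits = 3)
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: k=%d of n=%d drawn vs K=%d of N=%d\n",
              object@k, object@n, object@K, object@N))
  cat(sprintf("  fold enrichment %.3g, upper-tail P = %.3g\n",
              object@fold, object@pUpper))
})

setMethod("show", "WelchResult", function(object) {
  cat(sprintf("Welch t = %.4f, df = %.2f, two-sided P = %.3g\n",
              object@statistic, object@df, object@pValue))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d genes (%d TSG, %d OG), %d continuous + %d binary features\n",
              object@nGenes, object@nTsg, object@nOg,
              object@nContinuous, object@nBinary))
  cat(sprintf("  effect size %.2f, missing rate %.2f, seed %d\n",
              object@effectSize, object@missingRate, object@seed))
})
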