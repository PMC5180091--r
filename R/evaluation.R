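#' Precision at N for one confidence tier with panel exclusions
#'
#' Genes of the excluded tiers are removed from the ranked list before any
#' counting (the left-to-right panel protocol: the high-confidence panel
#' excludes nothing, the medium panel excludes high, the low panel excludes
#' high and medium). Precision at N is then the fraction of the top N
#' remaining genes that belong to the target tier — equivalently the fraction
#' of detected genes at depth N.
#'
#' @param ranking character vector of gene ids, best first.
#' @param labels a \linkS4class{LabelSet} covering the ranked genes.
#' @param tier target tier name.
#' @param excludeTiers character vector of tiers removed from the list first.
#' @param nMax deepest N evaluated (truncated to the filtered list length,
#'   with a warning).
#' @return a \linkS4class{PrecisionCurve} whose \code{curve} has columns
#'   \code{tier}, \code{N}, \code{hits}, \code{precision}.
#' @examples
#' lab <- new("LabelSet",
#'   tier = factor(setNames(rep(c("medium", "background"), c(3, 7)),
#'                          letters[1:10]),
#'                 levels = c("high_TSG", "high_OG", "medium", "low",
#'                            "other", "background")),
#'   provenance = character())
#' precisionAtN(letters[1:10], lab, "medium", nMax = 5)
#' @export
precisionAtN <- function(ranking, labels, tier,
                         excludeTiers = character(), nMax = 200L) {
  tiers <- labels@tier
  keep <- !(as.character(tiers[ranking]) %in% excludeTiers)
  filtered <- ranking[keep]
  if (nMax > length(filtered)) {
    warning("nMax exceeds filtered list length; truncated to ",
            length(filtered))
    nMax <- length(filtered)
  }
  isHit <- as.character(tiers[filtered[seq_len(nMax)]]) == tier
  hits <- cumsum(isHit)
  curve <- data.frame(tier = tier, N = seq_len(nMax), hits = hits,
                      precision = hits / seq_len(nMax))
  new("PrecisionCurve", curve = curve, excluded = ranking[!keep])
}

#' Cumulative detection counts for one tier
#'
#' Same exclusion semantics as \code{\link{precisionAtN}} but reports the
#' unnormalized non-decreasing count of target-tier genes among the top N.
#'
#' @inheritParams precisionAtN
#' @return data.frame with columns \code{tier}, \code{N}, \code{hits}.
#' @export
cumulativeDetection <- function(ranking, labels, tier,
                                excludeTiers = character(),
                                nMax = length(ranking)) {
  pc <- precisionAtN(ranking, labels, tier, excludeTiers, nMax)
  pc@curve[, c("tier", "N", "hits")]
}

#' Area under the ROC curve for TSG-versus-OG separation
#'
#' Uses only the high-confidence positives: TSG labels are 1, OG labels 0,
#' and the score is the conditional posterior of being a TSG given driver,
#' P(TSG) / (P(TSG) + P(OG)), from out-of-bag estimation. The AUC is the
#' Mann-Whitney rank statistic with midranks for ties. Positives whose
#' driver posterior mass is zero (or undefined) are dropped with a warning.
#'
#' @param posteriorTable a \linkS4class{PosteriorTable}.
#' @param labels a \linkS4class{LabelSet} providing the high_TSG / high_OG
#'   tiers.
#' @return the AUC, a number in [0, 1].
#' @export
tsgOgAuc <- function(posteriorTable, labels) {
  tb <- posteriorTable@table
  tiers <- labels@tier
  sel <- tb$gene_id %in% names(tiers)[tiers %in% c("high_TSG", "high_OG")]
  tb <- tb[sel, ]
  denom <- tb$P_TSG + tb$P_OG
  bad <- is.na(denom) | denom == 0
  if (any(bad)) {
    warning(sum(bad), " positive(s) with zero driver posterior dropped")
    tb <- tb[!bad, ]
    denom <- denom[!bad]
  }
  score <- tb$P_TSG / denom
  y <- as.integer(tiers[tb$gene_id] == "high_TSG")
  .rankAuc(score, y)
}

.rankAuc <- function(score, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("need both classes for an AUC")
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Ranking stability under training-set perturbation
#'
#' Refits the forest \code{nReplicates} times with a random fraction of the
#' positives removed from training (each class must retain at least one gene)
#' and reports the pairwise Spearman correlations between the replicate
#' driver-score vectors over the genes that are never positives.
#'
#' @param X numeric feature matrix over the universe.
#' @param trainLabels full training table (\code{gene_id}, \code{class}).
#' @param config a \linkS4class{ForestConfig}; replicate r refits with seed
#'   \code{config@seed + r}.
#' @param nReplicates number of perturbed refits (>= 2).
#' @param dropFraction fraction of positives removed per replicate.
#' @param seed seed for the drop draws.
#' @return list with \code{correlations} (pairwise Spearman values) and
#'   \code{median}.
#' @export
stabilityAnalysis <- function(X, trainLabels, config = forestConfig(),
                              nReplicates = 10L, dropFraction = 0.1,
                              seed = 1L) {
  stopifnot(nReplicates >= 2)
  posIdx <- which(trainLabels$class %in% c("TSG", "OG"))
  nonPos <- setdiff(rownames(X), trainLabels$gene_id[posIdx])
  scores <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(nReplicates), function(r) {
      nDrop <- floor(dropFraction * length(posIdx))
      drop <- if (nDrop > 0) sample(posIdx, nDrop) else integer()
      kept <- trainLabels[setdiff(seq_len(nrow(trainLabels)), drop), ]
      if (!all(c("TSG", "OG") %in% kept$class))
        stop("dropFraction removed every gene of one positive class")
      cfg <- config
      cfg@seed <- config@seed + as.integer(r)
      fit <- fitForest(X, kept, cfg)
      pt <- oobPosteriors(fit, X)@table
      setNames(pt$driver_score, pt$gene_id)[nonPos]
    })
  })
  pairs <- utils::combn(nReplicates, 2)
  cors <- apply(pairs, 2, function(p)
    cor(scores[[p[1]]], scores[[p[2]]], method = "spearman",
        use = "complete.obs"))
  list(correlations = cors, median = median(cors))
}

#' Precision curves under contrasting feature subsets
#'
#' Refits the forest once per named feature subset and computes the tiered
#' precision curves (high-confidence panel excludes nothing; medium excludes
#' high; low excludes high and medium) for each, the design used to compare
#' all features, non-tumor features and tumor-genomics-only features. The
#' orderings among the resulting curves are data-dependent; this harness only
#' guarantees every curve is defined on the common grid.
#'
#' @param X numeric feature matrix over the universe.
#' @param trainLabels training table.
#' @param labels a \linkS4class{LabelSet}.
#' @param featureSets named list of character vectors of column names.
#' @param config a \linkS4class{ForestConfig}.
#' @param nMax curve depth.
#' @return nested list: per feature set, per tier, a
#'   \linkS4class{PrecisionCurve}.
#' @export
featureSetContrast <- function(X, trainLabels, labels, featureSets,
                               config = forestConfig(), nMax = 200L) {
  panels <- list(
    high = list(tier = c("high_TSG", "high_OG"), exclude = character()),
    medium = list(tier = "medium", exclude = c("high_TSG", "high_OG")),
    low = list(tier = "low", exclude = c("high_TSG", "high_OG", "medium")))
  lapply(featureSets, function(cols) {
    missing <- setdiff(cols, colnames(X))
    if (length(missing))
      stop("feature set references unknown columns: ",
           paste(missing, collapse = ", "))
    fit <- fitForest(X[, cols, drop = FALSE], trainLabels, config)
    rk <- rankGenes(oobPosteriors(fit, X[, cols, drop = FALSE]), "driver")
    lapply(panels, function(p) {
      if (length(p$tier) > 1) {
        # combined high panel: hits in either high tier
        pc1 <- precisionAtN(rk, labels, p$tier[1], p$exclude, nMax)
        pc2 <- precisionAtN(rk, labels, p$tier[2], p$exclude, nMax)
        cv <- pc1@curve
        cv$hits <- cv$hits + pc2@curve$hits
        cv$precision <- cv$hits / cv$N
        cv$tier <- "high"
        new("PrecisionCurve", curve = cv, excluded = pc1@excluded)
      } else {
        precisionAtN(rk, labels, p$tier, p$exclude, nMax)
      }
    })
  })
}
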