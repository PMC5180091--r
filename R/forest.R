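#' @useDynLib puForest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Build a forest configuration
#'
#' @param nTrees ensemble size (desk-scale default 2000; the full-scale
#'   analysis uses 100,000).
#' @param mtry features tried per split; 0 selects floor(sqrt(p)) at fit time.
#' @param minNodeSize smallest splittable node (1 grows trees to purity).
#' @param maxDepth depth bound, 0 for none.
#' @param seed master seed; tree t draws from an independent counter-based
#'   stream derived from (seed, t), so results are identical in any fitting
#'   order (serial or parallel).
#' @param positiveDraw,bgDraw per-tree stratified bootstrap sizes; 0 means
#'   "number of positives" for both, the paired down-sampling design that
#'   counters the roughly 97-fold background excess.
#' @param replacePositives sample the positive stratum with replacement
#'   (default, the stated design) or without.
#' @return a validated \linkS4class{ForestConfig}.
#' @export
forestConfig <- function(nTrees = 2000L, mtry = 0L, minNodeSize = 1L,
                         maxDepth = 0L, seed = 1L, positiveDraw = 0L,
                         bgDraw = 0L, replacePositives = TRUE) {
  new("ForestConfig", nTrees = as.integer(nTrees), mtry = as.integer(mtry),
      minNodeSize = as.integer(minNodeSize), maxDepth = as.integer(maxDepth),
      seed = as.integer(seed), positiveDraw = as.integer(positiveDraw),
      bgDraw = as.integer(bgDraw),
      replacePositives = isTRUE(replacePositives))
}

.strata <- function(trainLabels) {
  pos <- which(trainLabels$class %in% c("TSG", "OG"))
  bg <- which(trainLabels$class == "BG")
  if (!length(pos) || !length(bg)) stop("empty stratum")
  list(pos = pos, bg = bg)
}

.draws <- function(config, nPos) {
  c(pos = if (config@positiveDraw > 0L) config@positiveDraw else nPos,
    bg = if (config@bgDraw > 0L) config@bgDraw
         else if (config@positiveDraw > 0L) config@positiveDraw else nPos)
}

#' Draw one tree's stratified training bag
#'
#' Samples \code{positiveDraw} genes with replacement from the positive
#' stratum (TSG and OG labels retained) plus \code{bgDraw} genes with
#' replacement from the background stratum, deterministically from
#' (\code{config@seed}, \code{treeIndex}).
#'
#' @param trainLabels data.frame with \code{gene_id} and \code{class}.
#' @param config a \linkS4class{ForestConfig}.
#' @param treeIndex 1-based tree index.
#' @return list with \code{gene_id} (the bag multiset) and \code{class}.
#' @export
sampleTrainingSet <- function(trainLabels, config, treeIndex = 1L) {
  st <- .strata(trainLabels)
  d <- .draws(config, length(st$pos))
  bag <- .cppSampleBag(st$pos, st$bg, d[["pos"]], d[["bg"]],
                       config@replacePositives, config@seed,
                       as.integer(treeIndex))$bag
  list(gene_id = trainLabels$gene_id[bag], class = trainLabels$class[bag])
}

#' Fit the positive-unlabeled random forest
#'
#' Grows \code{nTrees} CART trees (Gini impurity splits, \code{mtry} features
#' per node, midpoint thresholds, ties broken toward the lowest feature index
#' then the lowest threshold) on stratified down-sampled bootstraps, storing
#' every tree's exact in-bag gene multiset so out-of-bag posteriors can be
#' computed later for any gene.
#'
#' @param X numeric feature matrix with gene rownames, covering at least the
#'   training genes (typically the whole universe).
#' @param trainLabels data.frame (\code{gene_id}, \code{class} in TSG/OG/BG);
#'   only these genes are used for fitting.
#' @param config a \linkS4class{ForestConfig}.
#' @return a \linkS4class{DriverForest}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3,
#'             dimnames = list(sprintf("g%02d", 1:20), c("a", "b", "c")))
#' X[1:6, 1] <- X[1:6, 1] + 3
#' lab <- data.frame(gene_id = rownames(X),
#'                   class = c(rep("TSG", 3), rep("OG", 3), rep("BG", 14)))
#' fit <- fitForest(X, lab, forestConfig(nTrees = 50, seed = 9))
#' fit
#' @export
fitForest <- function(X, trainLabels, config = forestConfig()) {
  validObject(config)
  miss <- setdiff(trainLabels$gene_id, rownames(X))
  if (length(miss))
    stop("training genes absent from X: ", paste(head(miss, 5), collapse = ", "))
  if (anyNA(X)) stop("X must be complete (impute first)")
  Xtr <- X[trainLabels$gene_id, , drop = FALSE]
  y <- match(trainLabels$class, CLASS_LEVELS) - 1L
  st <- .strata(trainLabels)
  d <- .draws(config, length(st$pos))
  mtry <- if (config@mtry > 0L) min(config@mtry, ncol(X))
          else max(1L, floor(sqrt(ncol(X))))
  fit <- .cppFitForest(Xtr, y, st$pos, st$bg, config@nTrees, mtry,
                       config@minNodeSize, config@maxDepth, config@seed,
                       d[["pos"]], d[["bg"]], config@replacePositives)
  imp <- setNames(fit$importance, colnames(X))
  # store the resolved per-tree draws so the model is self-describing
  config@positiveDraw <- as.integer(d[["pos"]])
  config@bgDraw <- as.integer(d[["bg"]])
  new("DriverForest", trees = fit$trees,
      inBag = lapply(fit$trees, `[[`, "in_bag"),
      trainGeneIds = trainLabels$gene_id, featureNames = colnames(X),
      classLevels = CLASS_LEVELS, importance = imp, config = config)
}

#' Out-of-bag class posteriors for every gene
#'
#' For each gene, averages the leaf class proportions (soft votes) over
#' exactly the trees whose in-bag multiset excludes it. Training genes are
#' scored only by trees that did not draw them; genes outside the training
#' set (medium/low/other tiers) were never in any bag and are scored by all
#' trees. The driver score is P(TSG) + P(OG) and the rank orders genes by
#' descending driver score with lexicographic gene-id tie-break. Because of
#' the per-tree down-sampling these scores are calibrated for ranking, not as
#' true driver probabilities.
#'
#' @param forest a fitted \linkS4class{DriverForest}.
#' @param X numeric matrix over the gene universe (same columns as fitting).
#' @return a \linkS4class{PosteriorTable}; genes scored by zero trees carry
#'   NA posteriors and rank, with a warning.
#' @export
oobPosteriors <- function(forest, X) {
  if (!identical(colnames(X), forest@featureNames))
    stop("X columns differ from the fitted feature set")
  trainRow <- match(rownames(X), forest@trainGeneIds)
  trainRow[is.na(trainRow)] <- 0L
  res <- .cppOobPosteriors(forest@trees, X, as.integer(trainRow))
  post <- res$posterior
  nOob <- res$n_oob
  undef <- nOob == 0L
  if (any(undef)) {
    warning(sum(undef), " gene(s) scored by zero out-of-bag trees; ",
            "posteriors undefined and excluded from ranking")
    post[undef, ] <- NA_real_
  }
  tb <- data.frame(gene_id = rownames(X), P_TSG = post[, 1], P_OG = post[, 2],
                   P_BG = post[, 3], n_oob_trees = nOob,
                   driver_score = post[, 1] + post[, 2], rank = NA_integer_)
  ok <- !undef
  ord <- order(-tb$driver_score[ok], tb$gene_id[ok])
  tb$rank[which(ok)[ord]] <- seq_len(sum(ok))
  new("PosteriorTable", table = tb)
}

#' Rank genes by a posterior score
#'
#' @param posteriorTable a \linkS4class{PosteriorTable}.
#' @param mode \code{"driver"} (P_TSG + P_OG), \code{"TSG"} or \code{"OG"}.
#' @return character vector of gene ids, best first; ties broken
#'   lexicographically; undefined genes omitted.
#' @export
rankGenes <- function(posteriorTable, mode = c("driver", "TSG", "OG")) {
  mode <- match.arg(mode)
  tb <- posteriorTable@table
  score <- switch(mode, driver = tb$P_TSG + tb$P_OG, TSG = tb$P_TSG,
                  OG = tb$P_OG)
  ok <- tb$n_oob_trees > 0
  tb$gene_id[ok][order(-score[ok], tb$gene_id[ok])]
}

#' Gini feature importance
#'
#' Per-feature impurity decrease, weighted by the fraction of the bag reaching
#' each split, summed within trees and averaged over the ensemble. Features
#' never selected score 0.
#'
#' @param forest a fitted \linkS4class{DriverForest}.
#' @return named numeric vector, one entry per feature column.
#' @export
featureImportance <- function(forest) {
  forest@importance / length(forest@trees)
}

#' Gini impurity decrease of a single split
#'
#' Worked-arithmetic helper: given parent and child class-count vectors,
#' returns imp(parent) - (nL/n) imp(L) - (nR/n) imp(R) with
#' imp = 1 - sum((c/n)^2). A perfect split of a balanced two-class parent,
#' \code{giniDecrease(c(5,5), c(5,0), c(0,5))}, equals 0.5.
#'
#' @param parent,left,right class-count vectors (same length).
#' @return numeric impurity decrease.
#' @export
giniDecrease <- function(parent, left, right) {
  stopifnot(all(parent == left + right))
  imp <- function(c) { n <- sum(c); if (n == 0) 0 else 1 - sum((c / n)^2) }
  n <- sum(parent)
  imp(parent) - sum(left) / n * imp(left) - sum(right) / n * imp(right)
}

#' Write posterior and importance tables
#'
#' @param posteriorTable a \linkS4class{PosteriorTable}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writePosteriors <- function(posteriorTable, path) {
  write.table(posteriorTable@table, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}
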