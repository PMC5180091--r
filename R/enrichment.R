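#' Exact hypergeometric upper tail
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of at least k
#' annotated genes among n drawn without replacement from a universe of N
#' containing K annotated. Computed in log space by summing exact pmf terms
#' (log binomial coefficients via \code{lchoose}, combined with a
#' log-sum-exp), so small tails keep full relative precision. Set
#' \code{inclusive = FALSE} for the strict tail P(X > k).
#'
#' @param N population size.
#' @param K annotated genes in the population.
#' @param n draws.
#' @param k observed annotated draws.
#' @param inclusive include the observed count in the tail (default TRUE).
#' @return tail probability in (0, 1]; k greater than min(n, K) returns 0
#'   with a warning.
#' @examples
#' hypergeomUpperTail(165, 84, 30, 26)  # 8.56e-6
#' @export
hypergeomUpperTail <- function(N, K, n, k, inclusive = TRUE) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N)
    stop("invalid counts: need 0 <= K, n <= N and k >= 0")
  lo <- if (inclusive) k else k + 1
  hi <- min(n, K)
  if (lo > hi) {
    warning("k exceeds min(n, K); upper tail is 0")
    return(0)
  }
  kk <- lo:hi
  lp <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  m <- max(lp)
  exp(m + log(sum(exp(lp - m))))
}

.hypergeomLowerTail <- function(N, K, n, k) {
  # P(X <= k); complements the upper tail exactly in log space
  hi <- min(n, K)
  lo <- max(0, n - (N - K))
  if (k < lo) return(0)
  kk <- lo:min(k, hi)
  lp <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  m <- max(lp)
  exp(m + log(sum(exp(lp - m))))
}

#' Fold enrichment of a category inside a gene set
#'
#' Ratio of the in-set success rate to the out-of-set success rate:
#' (k/n) / ((K-k)/(N-n)). Scale-invariant in the four counts. When every
#' annotated gene is inside the set (K = k) the ratio is infinite.
#'
#' @inheritParams hypergeomUpperTail
#' @return numeric ratio (0 when k = 0; Inf when K = k).
#' @examples
#' foldEnrichment(19, 92, 84, 19486)  # 61.6, rounds to 62
#' @export
foldEnrichment <- function(k, n, K, N) {
  if (n >= N) stop("n must be smaller than N")
  if (K == k) return(Inf)
  (k / n) / ((K - k) / (N - n))
}

#' Count-based enrichment of a category inside a selected gene set
#'
#' @inheritParams hypergeomUpperTail
#' @param inclusive tail convention passed to
#'   \code{\link{hypergeomUpperTail}}.
#' @return an \linkS4class{EnrichmentResult} carrying the counts, the exact
#'   upper-tail probability and the fold enrichment.
#' @export
enrichmentTest <- function(N, K, n, k, inclusive = TRUE) {
  new("EnrichmentResult", N = as.integer(N), K = as.integer(K),
      n = as.integer(n), k = as.integer(k),
      pUpper = hypergeomUpperTail(N, K, n, k, inclusive),
      fold = foldEnrichment(k, n, K, N))
}

#' Welch two-sample t-test
#'
#' t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny) with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value from the t distribution. Both
#' samples need n >= 2 and at least one a positive variance.
#'
#' @param x,y numeric samples (NA dropped).
#' @return a \linkS4class{WelchResult}.
#' @export
welchT <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) stop("both samples have zero variance")
  sx <- vx / length(x); sy <- vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  new("WelchResult", statistic = t, df = df,
      pValue = 2 * pt(-abs(t), df))
}

#' Protein-size percentiles over a gene universe
#'
#' Percentile of each coding-sequence length as 100 * rank / N with maximum
#' rank for ties (tied largest genes share the 100.0 percentile); genes with
#' missing lengths are excluded with a warning. \code{topFraction} selects
#' the genes at or above the (1 - q) cut, keeping ties at the boundary.
#'
#' @param cdsLengths named numeric vector of CDS lengths (amino acids).
#' @return named numeric percentiles in (0, 100].
#' @export
sizePercentiles <- function(cdsLengths) {
  if (any(cdsLengths <= 0, na.rm = TRUE)) stop("lengths must be positive")
  miss <- is.na(cdsLengths)
  if (any(miss)) {
    warning(sum(miss), " gene(s) without a CDS length excluded")
    cdsLengths <- cdsLengths[!miss]
  }
  r <- rank(cdsLengths, ties.method = "max")
  100 * r / length(cdsLengths)
}

#' @rdname sizePercentiles
#' @param q fraction selected (default 0.05 for the top 5\% largest).
#' @return \code{topFraction}: character vector of selected gene names.
#' @export
topFraction <- function(cdsLengths, q = 0.05) {
  pct <- sizePercentiles(cdsLengths)
  names(pct)[pct >= 100 * (1 - q)]
}

#' Profile driver-gene composition of the large-protein annotation set
#'
#' Selects the genes in the top \code{q} size fraction that carry the primary
#' annotation (chromosome organization by default), then reports how the
#' driver classes distribute inside versus outside that set: counts and
#' shares of high-confidence TSGs and OGs (and, optionally, of a supplied
#' predicted-TSG set), the enrichment test for the TSG inside-versus-outside
#' contrast, and sub-profiles over secondary annotation columns (which may be
#' declared mutually exclusive or overlapping).
#'
#' @param cdsLengths named numeric vector over the universe.
#' @param annotations data.frame of 0/1 annotation flags, rownames = genes;
#'   must contain \code{primaryFlag}.
#' @param labels a \linkS4class{LabelSet}.
#' @param predictedTsg optional character vector of predicted TSG gene ids.
#' @param q size fraction (default 0.05).
#' @param primaryFlag column of \code{annotations} defining the set.
#' @param secondaryFlags columns profiled inside the selected set.
#' @param inclusive tail convention for the enrichment test.
#' @return list with \code{selected} (gene ids), \code{composition}
#'   (data.frame of counts and shares), \code{enrichment}
#'   (\linkS4class{EnrichmentResult} for high-confidence TSGs) and
#'   \code{secondary} (per-flag counts and shares within the set).
#' @export
intersectAndProfile <- function(cdsLengths, annotations, labels,
                                predictedTsg = NULL, q = 0.05,
                                primaryFlag = "chromosome_organization",
                                secondaryFlags = character(),
                                inclusive = TRUE) {
  if (!primaryFlag %in% names(annotations))
    stop("annotation column absent: ", primaryFlag)
  miss <- setdiff(secondaryFlags, names(annotations))
  if (length(miss)) stop("annotation column absent: ",
                         paste(miss, collapse = ", "))
  universe <- names(cdsLengths)[!is.na(cdsLengths)]
  big <- topFraction(cdsLengths, q)
  flagged <- rownames(annotations)[annotations[[primaryFlag]] == 1]
  selected <- intersect(big, flagged)

  tiers <- labels@tier
  hcTsg <- names(tiers)[tiers == "high_TSG"]
  hcOg <- names(tiers)[tiers == "high_OG"]
  inSet <- function(g) sum(g %in% selected)
  comp <- data.frame(
    group = c("high_TSG", "high_OG"),
    total = c(length(hcTsg), length(hcOg)),
    inside = c(inSet(hcTsg), inSet(hcOg)))
  if (!is.null(predictedTsg))
    comp <- rbind(comp, data.frame(group = "predicted_TSG",
                                   total = length(predictedTsg),
                                   inside = inSet(predictedTsg)))
  comp$share_pct <- 100 * comp$inside / pmax(comp$total, 1)

  enr <- if (length(selected) && length(selected) < length(universe))
    enrichmentTest(N = length(universe), K = length(hcTsg),
                   n = length(selected), k = inSet(hcTsg), inclusive)
  else new("EnrichmentResult", N = length(universe),
           K = length(hcTsg), n = length(selected), k = 0L,
           pUpper = 1, fold = 0)

  secondary <- if (length(secondaryFlags)) {
    counts <- vapply(secondaryFlags, function(f)
      sum(annotations[selected, f] == 1, na.rm = TRUE), integer(1))
    data.frame(flag = secondaryFlags, count = counts,
               share_pct = 100 * counts / max(1, length(selected)))
  } else NULL

  list(selected = selected, composition = comp, enrichment = enr,
       secondary = secondary)
}
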