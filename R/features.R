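#' Local gene density along the genome
#'
#' For each gene, counts the genes on the same chromosome (the gene itself
#' included) whose center position lies within \code{windowBp} of its own
#' center — a closed window \code{[center - windowBp, center + windowBp]} —
#' then divides every count by the mean count, so the output has mean exactly
#' 1. Genes without coordinates get a missing density and are excluded from
#' both counting and the mean.
#'
#' @param coords data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{center_bp}.
#' @param windowBp half-window in base pairs (default 4 Mb).
#' @return named numeric vector of densities (NA where coordinates missing).
#' @examples
#' co <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
#'                  center_bp = c(1e6, 2e6, 10e6))
#' genomicDensity(co)  # 1.2, 1.2, 0.6
#' @export
genomicDensity <- function(coords, windowBp = 4e6) {
  out <- setNames(rep(NA_real_, nrow(coords)), coords$gene_id)
  ok <- !is.na(coords$chrom) & !is.na(coords$center_bp)
  counts <- rep(NA_real_, nrow(coords))
  for (ch in unique(coords$chrom[ok])) {
    idx <- which(ok & coords$chrom == ch)
    pos <- coords$center_bp[idx]
    counts[idx] <- vapply(pos, function(p)
      sum(abs(pos - p) <= windowBp), numeric(1))
  }
  out[ok] <- counts[ok] / mean(counts[ok])
  out
}

#' Average interaction count over two interaction databases
#'
#' The per-gene number of protein-protein interactions is the arithmetic mean
#' of the counts reported by two sources; when one source is missing the
#' available count is used, and when both are missing the feature is missing.
#'
#' @param countsA,countsB non-negative integer vectors (NA allowed), parallel
#'   over genes.
#' @return numeric vector of averaged counts.
#' @export
ppiCount <- function(countsA, countsB) {
  stopifnot(length(countsA) == length(countsB))
  rowMeans(cbind(countsA, countsB), na.rm = TRUE) |>
    (\(x) { x[is.nan(x)] <- NA_real_; x })()
}

#' Betweenness centrality of genes in an interaction network
#'
#' Unnormalized shortest-path betweenness (Brandes' algorithm via igraph) on
#' the undirected simple graph induced by the edge list. Self-loops are
#' dropped with a warning and duplicate edges collapsed; genes absent from
#' the graph score 0.
#'
#' @param edges two-column data.frame of undirected edges.
#' @param geneIds optional character vector of the full gene universe; the
#'   result is expanded to it with zeros.
#' @return named numeric vector of betweenness values.
#' @export
betweennessCentrality <- function(edges, geneIds = NULL) {
  self <- edges[[1]] == edges[[2]]
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped")
    edges <- edges[!self, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g)
  b <- igraph::betweenness(g, directed = FALSE)
  if (is.null(geneIds)) return(b)
  out <- setNames(rep(0, length(geneIds)), geneIds)
  out[names(b)] <- b
  out
}

#' Median and variation of expression across tissues
#'
#' Per gene: the median over non-missing tissue values and the variation
#' statistic printed in the source feature table — the mean divided by the
#' sample standard deviation (the reciprocal of the conventional coefficient
#' of variation; set \code{conventional = TRUE} for sd/mean). Variation is
#' missing when the standard deviation is zero or fewer than two tissues are
#' observed.
#'
#' @param expression numeric gene x tissue matrix.
#' @param conventional use sd/mean instead of the as-printed mean/sd.
#' @return data.frame with columns \code{median_expression},
#'   \code{expression_variation}, rownames as in \code{expression}.
#' @export
tissueSummary <- function(expression, conventional = FALSE) {
  med <- apply(expression, 1, median, na.rm = TRUE)
  med[!is.finite(med)] <- NA_real_
  vr <- apply(expression, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    s <- sd(x)
    if (s == 0) return(NA_real_)
    if (conventional) s / mean(x) else mean(x) / s
  })
  data.frame(median_expression = med, expression_variation = vr,
             row.names = rownames(expression))
}

#' Length-normalized post-translational-modification site counts
#'
#' @param siteCounts numeric matrix or data.frame, genes x PTM types.
#' @param cdsLengthAa positive coding-sequence length in amino acids per gene
#'   (NA makes all of that gene's normalized counts missing).
#' @return matrix of counts divided by CDS length.
#' @export
normalizePtm <- function(siteCounts, cdsLengthAa) {
  m <- as.matrix(siteCounts)
  stopifnot(nrow(m) == length(cdsLengthAa))
  if (any(cdsLengthAa <= 0, na.rm = TRUE))
    stop("cdsLengthAa must be positive")
  sweep(m, 1, cdsLengthAa, "/")
}

.valueTallies <- function(v) {
  # missing markers count as a value for both frequency and uniqueness
  tab <- sort(table(as.character(v), useNA = "ifany"), decreasing = TRUE)
  tab
}

#' Remove sparse (near-constant) features
#'
#' A feature is removed iff both criteria hold: the frequency ratio of its
#' most common to second most common value exceeds \code{freqRatio} (97/3 by
#' default; a single-valued feature has infinite ratio), and its number of
#' distinct values is below \code{uniquePct} percent of the number of genes.
#' A missing marker counts as a value in both tallies, so heavily missing
#' features contribute an extra level rather than being ignored.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param freqRatio frequency-ratio threshold (default 97/3).
#' @param uniquePct unique-value percentage threshold (default 3).
#' @return list with \code{table} (filtered \linkS4class{FeatureTable}) and
#'   \code{removed} (data.frame feature, freq_ratio, unique_pct).
#' @export
removeSparse <- function(table, freqRatio = 97 / 3, uniquePct = 3) {
  df <- table@data
  n <- nrow(df)
  stats <- lapply(df, function(v) {
    tab <- .valueTallies(v)
    ratio <- if (length(tab) < 2) Inf else tab[1] / tab[2]
    c(ratio = unname(ratio), upct = 100 * length(tab) / n)
  })
  ratio <- vapply(stats, `[[`, numeric(1), "ratio")
  upct <- vapply(stats, `[[`, numeric(1), "upct")
  drop <- ratio > freqRatio & upct < uniquePct
  removed <- data.frame(feature = names(df)[drop],
                        freq_ratio = unname(ratio[drop]),
                        unique_pct = unname(upct[drop]))
  keep <- names(df)[!drop]
  list(table = new("FeatureTable", data = df[, keep, drop = FALSE],
                   featureType = table@featureType[keep]),
       removed = removed)
}

.spearmanMatrix <- function(df) {
  num <- vapply(df, function(v) suppressWarnings(as.numeric(v)), numeric(nrow(df)))
  num <- matrix(num, nrow = nrow(df), dimnames = list(NULL, names(df)))
  constant <- apply(num, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2 || sd(v) == 0
  })
  if (any(constant))
    warning("constant feature(s) treated as uncorrelated: ",
            paste(names(df)[constant], collapse = ", "))
  cm <- suppressWarnings(cor(num, method = "spearman",
                             use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  diag(cm) <- 0
  cm
}

#' Remove highly inter-correlated features
#'
#' Greedy elimination on the pairwise-complete Spearman correlation matrix
#' (average ranks for ties): repeatedly take the pair with the largest
#' absolute correlation above \code{threshold} and drop the member with the
#' greater mean absolute correlation against all remaining features, until no
#' pair exceeds the threshold. Pairs tied in |rho| and members tied in mean
#' correlation break lexicographically on feature name, so the output is
#' deterministic; exactly one member of an exact-duplicate pair survives.
#' Constant features have undefined correlations, treated as 0 with a
#' warning.
#'
#' @param table a \linkS4class{FeatureTable} (categorical columns are rank-
#'   coded through their numeric representation).
#' @param threshold absolute Spearman threshold (default 0.95).
#' @return list with \code{table} (filtered) and \code{removed} (data.frame
#'   feature, partner, abs_correlation).
#' @export
removeCorrelated <- function(table, threshold = 0.95) {
  df <- table@data
  cm <- .spearmanMatrix(df)
  keep <- colnames(cm)
  removed <- data.frame(feature = character(), partner = character(),
                        abs_correlation = numeric())
  repeat {
    sub <- abs(cm[keep, keep, drop = FALSE])
    if (length(keep) < 2 || max(sub) <= threshold) break
    idx <- which(sub == max(sub), arr.ind = TRUE)
    # deterministic pair choice: lexicographic on the two names
    pairs <- t(apply(idx, 1, function(r) sort(keep[r])))
    pairs <- unique(pairs)
    pick <- pairs[order(pairs[, 1], pairs[, 2])[1], ]
    meanAbs <- rowMeans(sub[pick, , drop = FALSE])
    loser <- if (meanAbs[1] > meanAbs[2]) pick[1]
             else if (meanAbs[2] > meanAbs[1]) pick[2]
             else sort(pick)[2]
    removed <- rbind(removed, data.frame(
      feature = loser, partner = setdiff(pick, loser),
      abs_correlation = max(sub)))
    keep <- setdiff(keep, loser)
  }
  list(table = new("FeatureTable", data = df[, keep, drop = FALSE],
                   featureType = table@featureType[keep]),
       removed = removed)
}

#' Impute missing cells by the mean of the k nearest genes
#'
#' For every gene with missing cells, the \code{k} nearest genes are found by
#' Euclidean distance over standardized (zero-mean, unit-variance) features,
#' restricted to coordinates observed in both genes and rescaled by the number
#' of shared coordinates, so genes with different missingness patterns remain
#' comparable. Each missing cell becomes the mean of the feature over those
#' neighbors; if all \code{k} neighbors also miss the feature the column
#' median over all genes is used. Observed cells are returned bit-identical.
#'
#' @param table a \linkS4class{FeatureTable} with numeric-encodable columns.
#' @param k neighbor count (default 5).
#' @return a complete \linkS4class{FeatureTable}.
#' @export
imputeKnn <- function(table, k = 5) {
  df <- table@data
  if (nrow(df) < k + 1) stop("need at least k+1 genes")
  num <- vapply(df, function(v) suppressWarnings(as.numeric(v)),
                numeric(nrow(df)))
  num <- matrix(num, nrow = nrow(df), dimnames = dimnames(df))
  allMissing <- colSums(!is.na(num)) == 0
  if (any(allMissing))
    stop("feature(s) missing in every gene: ",
         paste(colnames(num)[allMissing], collapse = ", "))
  mu <- colMeans(num, na.rm = TRUE)
  sg <- apply(num, 2, sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  z <- sweep(sweep(num, 2, mu, "-"), 2, sg, "/")
  med <- apply(num, 2, median, na.rm = TRUE)

  out <- df
  needs <- which(rowSums(is.na(num)) > 0)
  obs <- !is.na(z)
  for (i in needs) {
    shared <- obs & matrix(obs[i, ], nrow(z), ncol(z), byrow = TRUE)
    diff2 <- (z - matrix(z[i, ], nrow(z), ncol(z), byrow = TRUE))^2
    diff2[!shared] <- 0
    nShared <- rowSums(shared)
    d <- sqrt(rowSums(diff2) / pmax(nShared, 1))
    d[nShared == 0] <- Inf
    d[i] <- Inf
    nb <- order(d, rownames(z))[seq_len(k)]
    for (j in which(is.na(num[i, ]))) {
      v <- num[nb, j]
      out[i, j] <- if (all(is.na(v))) med[j] else mean(v, na.rm = TRUE)
    }
  }
  new("FeatureTable", data = out, featureType = table@featureType)
}

#' Encode a complete feature table as a numeric matrix
#'
#' Binary columns map to 0/1, categorical columns to one-hot indicator blocks
#' (one column per declared level), continuous columns pass through. The
#' returned column map is invertible: it records, for every matrix column,
#' the source feature and (for indicators) the level.
#'
#' @param table a complete \linkS4class{FeatureTable}.
#' @param levelsMap optional named list fixing categorical level sets (levels
#'   outside the set are an error).
#' @return list with \code{matrix} (genes x encoded columns) and
#'   \code{columnMap} (data.frame column, feature, level).
#' @export
encodeFeatures <- function(table, levelsMap = NULL) {
  df <- table@data
  if (anyNA(df)) stop("encodeFeatures requires a complete table")
  cols <- list(); mapRows <- list()
  for (f in names(df)) {
    ty <- table@featureType[[f]]
    if (ty == "categorical") {
      lv <- if (!is.null(levelsMap[[f]])) levelsMap[[f]]
            else sort(unique(as.character(df[[f]])))
      seen <- unique(as.character(df[[f]]))
      if (length(setdiff(seen, lv)))
        stop("unseen categorical level in '", f, "': ",
             paste(setdiff(seen, lv), collapse = ", "))
      for (l in lv) {
        cn <- paste0(f, "=", l)
        cols[[cn]] <- as.numeric(df[[f]] == l)
        mapRows[[cn]] <- data.frame(column = cn, feature = f, level = l)
      }
    } else {
      cols[[f]] <- as.numeric(df[[f]])
      mapRows[[f]] <- data.frame(column = f, feature = f, level = NA)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(df)
  list(matrix = m, columnMap = do.call(rbind, unname(mapRows)))
}

#' Run the full feature-preparation pipeline
#'
#' Fixed stage order: sparse-feature removal, correlated-feature removal,
#' k-nearest-neighbor imputation, then numeric encoding. The two removal
#' stages only drop columns (values are never altered) and imputation leaves
#' observed cells bit-identical.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param freqRatio,uniquePct,corrThreshold,k filter and imputation settings.
#' @return list with \code{matrix}, \code{columnMap}, \code{table} (the
#'   filtered, imputed \linkS4class{FeatureTable}) and \code{removed}
#'   (combined removal report with a \code{reason} column).
#' @export
prepareFeatures <- function(table, freqRatio = 97 / 3, uniquePct = 3,
                            corrThreshold = 0.95, k = 5) {
  s <- removeSparse(table, freqRatio, uniquePct)
  cRes <- removeCorrelated(s$table, corrThreshold)
  imp <- imputeKnn(cRes$table, k)
  enc <- encodeFeatures(imp)
  removed <- rbind(
    if (nrow(s$removed))
      data.frame(feature = s$removed$feature, reason = "sparse",
                 statistic = s$removed$freq_ratio) else NULL,
    if (nrow(cRes$removed))
      data.frame(feature = cRes$removed$feature, reason = "correlated",
                 statistic = cRes$removed$abs_correlation) else NULL)
  list(matrix = enc$matrix, columnMap = enc$columnMap, table = imp,
       removed = removed)
}
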