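#' Build a synthetic-universe configuration
#'
#' Defaults describe the desk-scale study universe: 2,000 genes with 40
#' planted tumor suppressors and 40 oncogenes, 30 continuous plus 10 binary
#' features of which 10 continuous carry a standardized class shift of 1.5,
#' 5\% completely-at-random missing cells, two planted sparse and two planted
#' duplicated features, a 3.8-fold coding-sequence-length inflation for
#' TSGs with a chromatin-organization role (matching the fold difference
#' observed between chromatin and non-chromatin tumor suppressors), and 15
#' noisy evidence sources. The full-scale geometry (19,486 genes, 131
#' features, 84/81 positives) is supported by the same generator but is slow
#' for routine testing.
#'
#' @param nGenes,nTsg,nOg universe and planted class sizes.
#' @param nContinuous,nBinary feature counts by declared type.
#' @param nInformative continuous features carrying a class-conditional shift.
#' @param effectSize standardized mean shift per informative feature.
#' @param binaryEnrichment length-2 rates: informative binary features fire at
#'   \code{binaryEnrichment[1]} in drivers and \code{binaryEnrichment[2]} in
#'   background genes.
#' @param missingRate fraction of feature cells set missing, completely at
#'   random.
#' @param nSparse,nDuplicate planted degenerate feature counts (both carved
#'   from the continuous block).
#' @param sizeInflation multiplicative CDS-length factor for planted
#'   TSG-and-chromatin genes.
#' @param chromatinRateTsg,chromatinRateBg chromatin-organization flag rates.
#' @param nSources,sourceSensitivity,sourceFpr,roleFlip evidence-source model.
#' @param seed integer master seed; all outputs are pure functions of the
#'   configuration.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nGenes = 300, nTsg = 10, nOg = 10, seed = 7)
#' cfg
#' @export
simConfig <- function(nGenes = 2000L, nTsg = 40L, nOg = 40L,
                      nContinuous = 30L, nBinary = 10L, nInformative = 10L,
                      effectSize = 1.5, binaryEnrichment = c(0.4, 0.05),
                      missingRate = 0.05, nSparse = 2L, nDuplicate = 2L,
                      sizeInflation = 3.8, chromatinRateTsg = 0.5,
                      chromatinRateBg = 0.1, nSources = 15L,
                      sourceSensitivity = 0.9, sourceFpr = 0.01,
                      roleFlip = 0.05, seed = 1L) {
  if (nTsg + nOg >= nGenes)
    stop("configuration error: nTsg + nOg must be smaller than nGenes")
  new("SimConfig",
      nGenes = as.integer(nGenes), nTsg = as.integer(nTsg),
      nOg = as.integer(nOg), nContinuous = as.integer(nContinuous),
      nBinary = as.integer(nBinary),
      nInformative = as.integer(min(nInformative, nContinuous)),
      effectSize = effectSize, binaryEnrichment = binaryEnrichment,
      missingRate = missingRate, nSparse = as.integer(nSparse),
      nDuplicate = as.integer(nDuplicate), sizeInflation = sizeInflation,
      chromatinRateTsg = chromatinRateTsg, chromatinRateBg = chromatinRateBg,
      nSources = as.integer(nSources),
      sourceSensitivity = sourceSensitivity, sourceFpr = sourceFpr,
      roleFlip = roleFlip, seed = as.integer(seed))
}

#' Generate a synthetic gene universe
#'
#' Draws a feature table, ground truth, gene coordinates, a protein-interaction
#' graph and a tissue-expression matrix with the statistical structure the
#' driver-gene analysis assumes: class-conditional mean shifts on informative
#' continuous features (alternating between TSG- and OG-shifted so the two
#' driver classes remain separable), log-normal size- and expression-like
#' features, a chromatin-organization flag enriched in TSGs, a log-normal CDS
#' length with the planted TSG-and-chromatin genes inflated by
#' \code{sizeInflation}, planted sparse and (near-)duplicate features that the
#' filtering stage must remove by construction, and completely-at-random
#' missing cells.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a list with elements \code{features} (\linkS4class{FeatureTable}),
#'   \code{truth} (\linkS4class{SimTruth}), \code{coords} (data.frame gene_id,
#'   chrom, center_bp), \code{graph} (two-column edge data.frame) and
#'   \code{expression} (gene x 27 tissue matrix).
#' @details Outputs are bit-identical for equal configurations (the seed is
#'   part of the configuration) and never include the true class among the
#'   feature columns.
#' @examples
#' u <- generateUniverse(simConfig(nGenes = 200, nTsg = 8, nOg = 8, seed = 3))
#' dim(u$features)
#' table(u$truth@trueClass)
#' @export
generateUniverse <- function(config) {
  validObject(config)
  withr::with_seed(config@seed, .generateUniverse(config))
}

.generateUniverse <- function(config) {
  n <- config@nGenes
  ids <- sprintf("G%05d", seq_len(n))
  cls <- factor(rep("BG", n), levels = CLASS_LEVELS)
  pos <- sample.int(n, config@nTsg + config@nOg)
  cls[pos[seq_len(config@nTsg)]] <- "TSG"
  cls[pos[config@nTsg + seq_len(config@nOg)]] <- "OG"

  chromRate <- ifelse(cls == "TSG", config@chromatinRateTsg,
                      config@chromatinRateBg)
  chrom <- rbinom(n, 1L, chromRate) == 1L

  nCont <- config@nContinuous
  nPlain <- nCont - config@nSparse - config@nDuplicate
  nInf <- min(config@nInformative, nPlain)
  contNames <- sprintf("cont_%02d", seq_len(nPlain))
  cont <- matrix(NA_real_, n, nPlain, dimnames = list(ids, contNames))
  informative <- character()
  for (j in seq_len(nPlain)) {
    shift <- numeric(n)
    if (j <= nInf) {
      # odd informative features shift TSGs, even shift OGs: drivers separate
      # from background and the two driver classes from each other
      target <- if (j %% 2L == 1L) "TSG" else "OG"
      shift[cls == target] <- config@effectSize
      informative <- c(informative, contNames[j])
    }
    z <- rnorm(n, mean = shift)
    # every third feature is long-tailed (expression/size-like)
    cont[, j] <- if (j %% 3L == 0L) exp(z) else z
  }

  dup <- NULL
  if (config@nDuplicate > 0L) {
    dup <- matrix(NA_real_, n, config@nDuplicate,
                  dimnames = list(ids, sprintf("dup_%02d",
                                               seq_len(config@nDuplicate))))
    for (j in seq_len(config@nDuplicate)) {
      src <- cont[, ((j - 1L) %% nPlain) + 1L]
      dup[, j] <- if (j %% 2L == 0L) src
                  else src + rnorm(n, sd = sd(src) * 1e-3)
    }
  }

  sparse <- NULL
  if (config@nSparse > 0L) {
    sparse <- matrix(0, n, config@nSparse,
                     dimnames = list(ids, sprintf("sparse_%02d",
                                                  seq_len(config@nSparse))))
    # 1% minor value: frequency ratio 99/1 > 97/3 and two distinct values,
    # i.e. the sparse-filter removal criteria hold by construction for n > 67
    nMinor <- max(1L, floor(0.01 * n))
    for (j in seq_len(config@nSparse))
      sparse[sample.int(n, nMinor), j] <- j + 0.5
  }

  binNames <- sprintf("bin_%02d", seq_len(config@nBinary))
  bin <- matrix(NA_real_, n, config@nBinary, dimnames = list(ids, binNames))
  nBinInf <- ceiling(config@nBinary / 2)
  for (j in seq_len(config@nBinary)) {
    rate <- if (j <= nBinInf)
      ifelse(cls != "BG", config@binaryEnrichment[1], config@binaryEnrichment[2])
    else rep(0.1, n)
    bin[, j] <- rbinom(n, 1L, rate)
  }
  if (config@nBinary > 0L)
    informative <- c(informative, binNames[seq_len(nBinInf)])

  cds <- exp(rnorm(n, 6.2, 0.6))
  inflate <- cls == "TSG" & chrom
  cds[inflate] <- cds[inflate] * config@sizeInflation
  cds <- round(cds)

  df <- data.frame(cont, check.names = FALSE)
  if (!is.null(dup)) df <- cbind(df, as.data.frame(dup))
  if (!is.null(sparse)) df <- cbind(df, as.data.frame(sparse))
  df <- cbind(df, as.data.frame(bin))
  df$go_chromosome_organization <- as.numeric(chrom)
  df$cds_length_aa <- cds
  rownames(df) <- ids

  types <- setNames(rep("continuous", ncol(df)), colnames(df))
  types[c(binNames, "go_chromosome_organization")] <- "binary"
  if (config@missingRate > 0) {
    m <- matrix(runif(n * ncol(df)) < config@missingRate, n, ncol(df))
    # planted sparse columns emulate near-constant annotation flags, which
    # come complete; missingness there would mask the removal criteria
    m[, grepl("^sparse_", colnames(df))] <- FALSE
    df[m] <- NA
  }
  ft <- new("FeatureTable", data = df, featureType = types)

  truth <- new("SimTruth", geneId = ids, trueClass = cls,
               chromatinFlag = chrom, informativeFeatures = informative)

  coords <- data.frame(gene_id = ids, chrom = "chr1",
                       center_bp = round(runif(n, 1, 250e6)))

  graph <- .samplePaEdges(n, m = 2L, ids = ids)

  expr <- matrix(rlnorm(n * 27, meanlog = 2, sdlog = 1), n, 27,
                 dimnames = list(ids, sprintf("tissue_%02d", 1:27)))

  list(features = ft, truth = truth, coords = coords, graph = graph,
       expression = expr)
}

.samplePaEdges <- function(n, m, ids) {
  g <- igraph::sample_pa(n, m = m, directed = FALSE)
  e <- igraph::as_edgelist(g, names = FALSE)
  data.frame(from = ids[e[, 1]], to = ids[e[, 2]])
}

#' Generate a preferential-attachment protein-interaction graph
#'
#' Connected scale-free graph over gene identifiers, emulating the heavy-tailed
#' degree distribution of protein-interaction networks; deterministic given
#' the seed.
#'
#' @param nGenes number of nodes; gene ids are \code{G00001 ...}.
#' @param mAttach edges added per incoming node (>= 1).
#' @param seed integer seed.
#' @return two-column data.frame of undirected edges (\code{from}, \code{to}).
#' @examples
#' generatePpiGraph(5, 1, seed = 2)
#' @export
generatePpiGraph <- function(nGenes, mAttach = 2L, seed = 1L) {
  if (mAttach < 1L) stop("mAttach must be >= 1")
  if (nGenes < mAttach + 1L)
    stop("nGenes must exceed mAttach")
  ids <- sprintf("G%05d", seq_len(nGenes))
  withr::with_seed(as.integer(seed), .samplePaEdges(nGenes, mAttach, ids))
}

#' Generate a noisy multi-source evidence membership table
#'
#' Each emulated source marks a true driver with probability
#' \code{sourceSensitivity} and a background gene with probability
#' \code{sourceFpr}; a member driver's TSG/OG role call is flipped with
#' probability \code{roleFlip}, and background false positives carry role
#' \code{"unknown"}. Source categories cycle through curated, mutation_method,
#' cna, db and biomarker.
#'
#' @param truth a \linkS4class{SimTruth} from \code{\link{generateUniverse}}.
#' @param config the matching \linkS4class{SimConfig}.
#' @return a \linkS4class{SourceMembership}.
#' @export
generateSourceMembership <- function(truth, config) {
  validObject(truth); validObject(config)
  withr::with_seed(config@seed + 1L, {
    n <- length(truth@geneId)
    nS <- config@nSources
    srcNames <- sprintf("source_%02d", seq_len(nS))
    cats <- rep(c("curated", "mutation_method", "cna", "db", "biomarker"),
                length.out = nS)
    isDriver <- truth@trueClass != "BG"
    member <- matrix(FALSE, n, nS, dimnames = list(truth@geneId, srcNames))
    role <- matrix(NA_character_, n, nS, dimnames = dimnames(member))
    for (s in seq_len(nS)) {
      p <- ifelse(isDriver, config@sourceSensitivity, config@sourceFpr)
      hit <- runif(n) < p
      member[, s] <- hit
      flip <- runif(n) < config@roleFlip
      called <- as.character(truth@trueClass)
      called[flip & called == "TSG"] <- "OG"
      called[flip & called == "OG"] <- "TSG"
      role[hit & isDriver, s] <- called[hit & isDriver]
      role[hit & !isDriver, s] <- "unknown"
    }
    new("SourceMembership", membership = member, role = role,
        sourceInfo = data.frame(name = srcNames, category = cats))
  })
}

#' Write the synthetic universe to tab-separated files
#'
#' Emits features, truth, membership, coordinates, edge-list and expression
#' tables with header rows; missing cells are written empty.
#'
#' @param universe list returned by \code{\link{generateUniverse}}.
#' @param membership optional \linkS4class{SourceMembership}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeUniverse <- function(universe, membership = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wrt <- function(d, f) {
    path <- file.path(dir, f)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    path
  }
  ft <- cbind(gene_id = geneIds(universe$features),
              as.data.frame(universe$features))
  tr <- data.frame(gene_id = universe$truth@geneId,
                   true_class = as.character(universe$truth@trueClass),
                   chromatin_flag = as.integer(universe$truth@chromatinFlag))
  ex <- cbind(gene_id = rownames(universe$expression),
              as.data.frame(universe$expression))
  out <- c(wrt(ft, "features.tsv"), wrt(tr, "truth.tsv"),
           wrt(universe$coords, "coordinates.tsv"),
           wrt(universe$graph, "edges.tsv"), wrt(ex, "expression.tsv"))
  if (!is.null(membership)) {
    mb <- cbind(gene_id = geneIds(membership),
                as.data.frame(membership@membership))
    out <- c(out, wrt(mb, "membership.tsv"))
  }
  invisible(out)
}
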