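# End-to-end orchestration over the synthetic path: simulate -> labels ->
# features -> train -> rank -> evaluate -> enrich, with a manifest recording
# config hash, seeds and per-stage table shapes. State is carried in an RDS
# file inside the output directory so stage subsets can resume a run.

PIPELINE_STAGES <- c("simulate", "labels", "features", "train", "rank",
                     "evaluate", "enrich")

.fnv1a <- function(x) {
  # 32-bit FNV-1a over serialized bytes; cheap content fingerprint for the
  # run manifest (not cryptographic). Large objects are fingerprinted by
  # their first 64 KiB plus total length. The xor works on the low byte only
  # (b < 256), keeping the state a double below 2^32.
  bytes <- as.integer(serialize(x, NULL, version = 2))
  n <- length(bytes)
  if (n > 65536L) bytes <- c(bytes[1:65536], n %% 256L)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

#' Run the full analysis pipeline on a synthetic universe
#'
#' Executes, in order, the requested subset of: \code{simulate} (universe and
#' evidence membership), \code{labels} (majority-vote high-confidence set and
#' tier partition), \code{features} (filtering, imputation, encoding),
#' \code{train} (the positive-unlabeled forest), \code{rank} (out-of-bag
#' posteriors and driver ranking), \code{evaluate} (tiered precision curves
#' and the TSG-vs-OG AUC) and \code{enrich} (the large-protein by
#' chromatin-annotation profile). Every stochastic stage derives its seed
#' from the configurations, so a rerun with an identical configuration
#' reproduces every artifact bit-for-bit. A stage whose inputs are absent
#' stops with the name of the stage to run first.
#'
#' @param simCfg a \linkS4class{SimConfig}.
#' @param forestCfg a \linkS4class{ForestConfig}.
#' @param filter list of feature-pipeline settings (\code{freqRatio},
#'   \code{uniquePct}, \code{corrThreshold}, \code{k}).
#' @param evalCfg list with \code{nMax} (precision-curve depth).
#' @param enrichCfg list with \code{q} (size fraction).
#' @param outputDir directory receiving TSV artifacts, the manifest and the
#'   resumable state file.
#' @param stages character subset of the seven stages, applied in canonical
#'   order.
#' @return invisibly, the pipeline state (a list of stage outputs).
#' @export
runPipeline <- function(simCfg = simConfig(), forestCfg = forestConfig(),
                        filter = list(freqRatio = 97 / 3, uniquePct = 3,
                                      corrThreshold = 0.95, k = 5),
                        evalCfg = list(nMax = 200L),
                        enrichCfg = list(q = 0.05),
                        outputDir, stages = PIPELINE_STAGES) {
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  if (!length(stages)) stop("no valid stages requested")
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
  statePath <- file.path(outputDir, "state.rds")
  state <- if (file.exists(statePath)) readRDS(statePath) else list()
  manifestPath <- file.path(outputDir, "manifest.tsv")
  manifest <- if (file.exists(manifestPath))
    read.delim(manifestPath) else NULL
  cfgHash <- .fnv1a(list(simCfg, forestCfg, filter, evalCfg, enrichCfg))

  need <- function(what, stage) {
    if (is.null(state[[what]]))
      stop("stage '", stage, "' needs outputs of stage '", what,
           "'; run that stage first")
    state[[what]]
  }
  note <- function(stage, obj, rows, cols) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, config_hash = cfgHash, seed = simCfg@seed,
      forest_seed = forestCfg@seed, rows = rows, cols = cols,
      checksum = .fnv1a(obj)))
  }
  tsv <- function(d, f) write.table(d, file.path(outputDir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE, na = "")

  for (stage in stages) {
    if (stage == "simulate") {
      u <- generateUniverse(simCfg)
      mb <- generateSourceMembership(u$truth, simCfg)
      writeUniverse(u, mb, outputDir)
      state$simulate <- list(universe = u, membership = mb)
      note(stage, state$simulate, nrow(u$features@data), ncol(u$features@data))
    } else if (stage == "labels") {
      sim <- need("simulate", stage)
      mb <- sim$membership
      nS <- ncol(mb@membership)
      rules <- list(list(type = "majority_vote",
                         sources = colnames(mb@membership),
                         minCount = ceiling(nS / 2), label = "majority_vote"))
      hc <- assembleHighConfidence(mb, rules)
      labels <- assignTiers(mb, hc,
                            list(medium = colnames(mb@membership),
                                 low = character()))
      writeLabels(labels, file.path(outputDir, "labels.tsv"))
      training <- buildTrainingLabels(labels)
      state$labels <- list(labelSet = labels, training = training)
      note(stage, state$labels, length(labels@tier), 1L)
    } else if (stage == "features") {
      sim <- need("simulate", stage)
      prep <- prepareFeatures(sim$universe$features,
                              freqRatio = filter$freqRatio,
                              uniquePct = filter$uniquePct,
                              corrThreshold = filter$corrThreshold,
                              k = filter$k)
      tsv(cbind(gene_id = rownames(prep$matrix),
                as.data.frame(prep$matrix)), "feature_matrix.tsv")
      if (!is.null(prep$removed)) tsv(prep$removed, "removed_features.tsv")
      state$features <- prep
      note(stage, prep$matrix, nrow(prep$matrix), ncol(prep$matrix))
    } else if (stage == "train") {
      feats <- need("features", stage)
      lab <- need("labels", stage)
      fit <- fitForest(feats$matrix, lab$training, forestCfg)
      state$train <- fit
      note(stage, fit@importance, length(fit@trees),
           length(fit@featureNames))
    } else if (stage == "rank") {
      fit <- need("train", stage)
      feats <- need("features", stage)
      pt <- oobPosteriors(fit, feats$matrix)
      writePosteriors(pt, file.path(outputDir, "predictions.tsv"))
      imp <- featureImportance(fit)
      tsv(data.frame(feature = names(imp), importance = unname(imp)),
          "importance.tsv")
      state$rank <- pt
      note(stage, pt@table, nrow(pt@table), ncol(pt@table))
    } else if (stage == "evaluate") {
      pt <- need("rank", stage)
      lab <- need("labels", stage)
      rk <- rankGenes(pt, "driver")
      tier <- lab$labelSet@tier
      curves <- NULL
      addCurve <- function(t, excl) {
        if (!any(tier == t)) return(NULL)
        n <- min(evalCfg$nMax, sum(!(as.character(tier[rk]) %in% excl)))
        precisionAtN(rk, lab$labelSet, t, excl, n)@curve
      }
      curves <- rbind(addCurve("high_TSG", character()),
                      addCurve("high_OG", character()),
                      addCurve("medium", c("high_TSG", "high_OG")))
      if (!is.null(curves)) tsv(curves, "precision_curves.tsv")
      auc <- if (any(tier == "high_TSG") && any(tier == "high_OG"))
        tsgOgAuc(pt, lab$labelSet) else NA_real_
      tsv(data.frame(metric = "tsg_og_auc", value = auc), "auc.tsv")
      state$evaluate <- list(curves = curves, auc = auc)
      note(stage, state$evaluate, if (is.null(curves)) 0L else nrow(curves), 4L)
    } else if (stage == "enrich") {
      sim <- need("simulate", stage)
      lab <- need("labels", stage)
      ft <- sim$universe$features@data
      cds <- setNames(ft$cds_length_aa, rownames(ft))
      ann <- data.frame(
        chromosome_organization = ifelse(is.na(ft$go_chromosome_organization),
                                         0, ft$go_chromosome_organization),
        row.names = rownames(ft))
      prof <- suppressWarnings(
        intersectAndProfile(cds, ann, lab$labelSet, q = enrichCfg$q))
      tsv(prof$composition, "enrichment_composition.tsv")
      e <- prof$enrichment
      tsv(data.frame(N = e@N, K = e@K, n = e@n, k = e@k, fold = e@fold,
                     p_upper = e@pUpper), "enrichment.tsv")
      state$enrich <- prof
      note(stage, prof$composition, nrow(prof$composition), 4L)
    }
  }
  saveRDS(state, statePath)
  tsv(manifest, "manifest.tsv")
  invisible(state)
}
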