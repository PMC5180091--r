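test_that("stratified bags have the paired size and are seed-deterministic", {
  cfg <- forestConfig(seed = 3L)
  bag1 <- sampleTrainingSet(smallTraining, cfg, treeIndex = 1L)
  P <- sum(smallTraining$class != "BG")
  expect_length(bag1$gene_id, 2L * P)
  expect_equal(sum(bag1$class != "BG"), P)
  expect_equal(sum(bag1$class == "BG"), P)
  expect_identical(bag1, sampleTrainingSet(smallTraining, cfg, 1L))
  expect_false(identical(bag1, sampleTrainingSet(smallTraining, cfg, 2L)))

  noBg <- smallTraining[smallTraining$class != "BG", ]
  expect_error(sampleTrainingSet(noBg, cfg), "empty stratum")
})

test_that("bootstrap exclusion fractions match the analytic formulas", {
  posIds <- smallTraining$gene_id[smallTraining$class != "BG"]
  bgIds <- smallTraining$gene_id[smallTraining$class == "BG"]
  P <- length(posIds)
  nBg <- length(bgIds)
  cfg <- forestConfig(seed = 11L)
  nT <- 2000L
  exclPos <- numeric(nT)
  bgIn <- numeric(nT)
  for (t in seq_len(nT)) {
    bag <- sampleTrainingSet(smallTraining, cfg, t)
    exclPos[t] <- mean(!(posIds %in% bag$gene_id))
    bgIn[t] <- mean(bgIds %in% bag$gene_id)
  }
  expPos <- (1 - 1 / P)^P
  sdPos <- sqrt(expPos * (1 - expPos) / (P * nT))
  expect_lt(abs(mean(exclPos) - expPos), 3 * sdPos)

  expBg <- 1 - (1 - 1 / nBg)^P
  sdBg <- sqrt(expBg * (1 - expBg) / (nBg * nT))
  expect_lt(abs(mean(bgIn) - expBg), 3 * sdBg)
})

test_that("the worked Gini split arithmetic holds", {
  expect_equal(giniDecrease(c(5, 5), c(5, 0), c(0, 5)), 0.5)
  expect_equal(giniDecrease(c(4, 4), c(2, 2), c(2, 2)), 0)
})

test_that("one-feature separable data grows a depth-1 perfect tree", {
  ids <- sprintf("g%02d", 1:20)
  X <- matrix(c(rep(0, 10), rep(1, 10)), 20, 1,
              dimnames = list(ids, "sep"))
  lab <- data.frame(gene_id = ids,
                    class = c(rep("TSG", 10), rep("BG", 10)))
  fit <- fitForest(X, lab, forestConfig(nTrees = 1L, seed = 1L))
  tree <- fit@trees[[1]]
  expect_equal(sum(tree$feature >= 0), 1L)  # a single internal node
  # every in-bag row classified correctly by its leaf
  pt <- suppressWarnings(oobPosteriors(fit, X))
  tb <- posteriors(pt)
  oob <- tb[tb$n_oob_trees > 0, ]
  expect_true(all(oob$P_TSG[match(oob$gene_id, ids) <= 10] == 1))
  expect_true(all(oob$P_BG[match(oob$gene_id, ids) > 10] == 1))
})

test_that("identical rows with mixed labels collapse to a majority leaf", {
  ids <- sprintf("g%02d", 1:10)
  X <- matrix(1, 10, 2, dimnames = list(ids, c("a", "b")))
  lab <- data.frame(gene_id = ids,
                    class = c(rep("TSG", 4), rep("BG", 6)))
  fit <- fitForest(X, lab, forestConfig(nTrees = 3L, seed = 2L))
  for (tree in fit@trees) expect_equal(tree$feature, -1L)
  expect_true(all(featureImportance(fit) == 0))
})

test_that("single-tree bags match the sampler stream and flag in-bag genes", {
  cfg <- forestConfig(nTrees = 1L, seed = 21L)
  fit <- fitForest(smallPrep$matrix, smallTraining, cfg)
  bagGenes <- fit@trainGeneIds[fit@inBag[[1]]]
  expect_identical(bagGenes,
                   sampleTrainingSet(smallTraining, cfg, 1L)$gene_id)
  expect_warning(pt <- oobPosteriors(fit, smallPrep$matrix), "zero out-of-bag")
  tb <- posteriors(pt)
  inBag <- tb$gene_id %in% bagGenes
  expect_true(all(is.na(tb$P_TSG[inBag])))
  expect_true(all(is.na(tb$rank[inBag])))
})

test_that("forests are reproducible and posteriors normalized", {
  cfg <- forestConfig(nTrees = 150L, seed = 31L)
  fit1 <- fitForest(smallPrep$matrix, smallTraining, cfg)
  fit2 <- fitForest(smallPrep$matrix, smallTraining, cfg)
  pt1 <- posteriors(oobPosteriors(fit1, smallPrep$matrix))
  pt2 <- posteriors(oobPosteriors(fit2, smallPrep$matrix))
  expect_identical(pt1, pt2)
  ok <- pt1$n_oob_trees > 0
  expect_true(all(abs(pt1$P_TSG[ok] + pt1$P_OG[ok] + pt1$P_BG[ok] - 1) < 1e-9))
})

test_that("genes outside training are scored by every tree", {
  # hold some positives out of training: they are never bagged
  held <- smallTraining$gene_id[smallTraining$class == "TSG"][1:5]
  train <- smallTraining[!(smallTraining$gene_id %in% held), ]
  cfg <- forestConfig(nTrees = 100L, seed = 41L)
  fit <- fitForest(smallPrep$matrix, train, cfg)
  tb <- posteriors(oobPosteriors(fit, smallPrep$matrix))
  expect_true(all(tb$n_oob_trees[tb$gene_id %in% held] == 100L))
})

test_that("ranking orders by the selected posterior with stable ties", {
  tb <- data.frame(
    gene_id = c("gB", "gA", "gC"),
    P_TSG = c(0.5, 0.1, 0.40),
    P_OG = c(0.3, 0.6, 0.40),
    P_BG = c(0.2, 0.3, 0.20),
    n_oob_trees = 10L, driver_score = c(0.8, 0.7, 0.8),
    rank = NA_integer_)
  pt <- new("PosteriorTable", table = tb)
  expect_identical(rankGenes(pt, "driver"), c("gB", "gC", "gA"))
  expect_identical(rankGenes(pt, "TSG"), c("gB", "gC", "gA"))
  expect_identical(rankGenes(pt, "OG"), c("gA", "gC", "gB"))
  # driver rank is invariant to swapping P_TSG and P_OG within a gene
  tb2 <- tb; tb2$P_TSG <- tb$P_OG; tb2$P_OG <- tb$P_TSG
  expect_identical(rankGenes(new("PosteriorTable", table = tb2), "driver"),
                   rankGenes(pt, "driver"))
})

test_that("importance concentrates on informative features", {
  fit <- fitForest(smallPrep$matrix, smallTraining,
                   forestConfig(nTrees = 300L, seed = 51L))
  imp <- featureImportance(fit)
  expect_true(all(imp >= 0))
  inf <- intersect(smallUniverse$truth@informativeFeatures, names(imp))
  noise <- setdiff(names(imp), c(inf, "go_chromosome_organization",
                                 "cds_length_aa"))
  expect_gt(mean(imp[inf]), mean(imp[noise]))

  # a feature that perfectly separates classes dominates
  ids <- sprintf("h%02d", 1:30)
  X <- cbind(sep = c(rep(0, 10), rep(1, 20)),
             noise = rep(c(0.3, 0.7), 15))
  rownames(X) <- ids
  lab <- data.frame(gene_id = ids,
                    class = c(rep("TSG", 10), rep("BG", 20)))
  fit2 <- fitForest(X, lab, forestConfig(nTrees = 100L, mtry = 2L, seed = 6L))
  imp2 <- featureImportance(fit2)
  expect_gt(imp2[["sep"]], imp2[["noise"]])
  expect_equal(which.max(imp2), c(sep = 1L))
})

test_that("Monte Carlo noise in posteriors shrinks like one over sqrt trees", {
  scoreAt <- function(nTrees, seed) {
    fit <- fitForest(smallPrep$matrix, smallTraining,
                     forestConfig(nTrees = nTrees, seed = seed))
    tb <- posteriors(oobPosteriors(fit, smallPrep$matrix))
    tb$driver_score[match("G00001", tb$gene_id)]
  }
  seeds <- 101:130
  sd50 <- sd(vapply(seeds, function(s) scoreAt(50L, s), numeric(1)))
  sd200 <- sd(vapply(seeds, function(s) scoreAt(200L, s), numeric(1)))
  # quadrupling the ensemble should roughly halve the Monte Carlo sd
  expect_lt(sd200 / sd50, 0.75)
  expect_gt(sd200 / sd50, 0.25)
})

test_that("driver scores agree in direction with the reference forest", {
  skip_if_not_installed("randomForest")
  u <- smallUniverse
  y <- factor(smallTraining$class, levels = c("TSG", "OG", "BG"))
  fit <- fitForest(smallPrep$matrix, smallTraining,
                   forestConfig(nTrees = 500L, seed = 61L))
  ours <- posteriors(oobPosteriors(fit, smallPrep$matrix))
  rf <- randomForest::randomForest(
    smallPrep$matrix, y, ntree = 500,
    strata = factor(y != "BG"), sampsize = c(32, 32))
  ref <- predict(rf, smallPrep$matrix, type = "prob")
  refDriver <- ref[, "TSG"] + ref[, "OG"]
  rho <- cor(ours$driver_score, refDriver[ours$gene_id], method = "spearman",
             use = "complete.obs")
  expect_gt(rho, 0.5)
})
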