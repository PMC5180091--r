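test_that("hypergeometric upper tail reproduces the driver-size result", {
  # 26 TSGs among the 30 largest of 84 TSGs + 81 OGs
  p <- hypergeomUpperTail(N = 165, K = 84, n = 30, k = 26)
  expect_equal(signif(p, 3), 8.56e-06)

  # 19 of 84 TSGs inside the 92-gene top-5%-size chromatin set, genome-wide
  p92 <- hypergeomUpperTail(N = 19486, K = 84, n = 92, k = 19)
  expect_equal(signif(p92, 2), 2.3e-27)
})

test_that("hypergeometric tails match brute-force subset enumeration", {
  for (N in c(4L, 7L, 10L)) {
    for (K in 0:N) {
      for (n in 1:N) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeomUpperTail(N, K, n, k),
                       bruteHyperUpper(N, K, n, k), tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("hypergeometric tail edge cases and identities hold", {
  expect_equal(hypergeomUpperTail(100, 30, 10, 0), 1)
  expect_warning(p0 <- hypergeomUpperTail(10, 3, 4, 5), "upper tail is 0")
  expect_equal(p0, 0)
  expect_error(hypergeomUpperTail(10, 12, 3, 1), "invalid counts")

  # complement identity in log-space round trip
  for (k in 1:5)
    expect_equal(hypergeomUpperTail(20, 8, 6, k) +
                   puForest:::.hypergeomLowerTail(20, 8, 6, k - 1), 1,
                 tolerance = 1e-12)

  # strict-tail switch
  expect_equal(hypergeomUpperTail(20, 8, 6, 2, inclusive = FALSE),
               hypergeomUpperTail(20, 8, 6, 3))

  # reference distribution cross-check at extreme tails
  expect_equal(hypergeomUpperTail(19486, 84, 92, 19),
               stats::phyper(18, 84, 19486 - 84, 92, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("fold enrichment reproduces the 62-fold large-TSG contrast", {
  fold <- foldEnrichment(k = 19, n = 92, K = 84, N = 19486)
  expect_equal(round(fold), 62)
  expect_equal(fold, 61.6, tolerance = 0.01)

  # equal prevalence inside and out: ratio 1
  expect_equal(foldEnrichment(5, 50, 15, 150), 1)
  expect_equal(foldEnrichment(0, 50, 15, 150), 0)
  expect_equal(foldEnrichment(15, 50, 15, 150), Inf)
  # scale invariance in all four counts
  expect_equal(foldEnrichment(19, 92, 84, 19486),
               foldEnrichment(19 * 3, 92 * 3, 84 * 3, 19486 * 3))
})

test_that("Welch t matches the reference and its invariances", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  w <- welchT(x, y)
  ref <- stats::t.test(x, y)
  expect_equal(w@statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w@df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w@pValue, ref$p.value, tolerance = 1e-12)
  expect_equal(w@statistic, -1.095445, tolerance = 1e-6)
  expect_equal(w@df, 6)

  same <- welchT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same@statistic, 0)
  expect_equal(same@pValue, 1)

  expect_equal(welchT(x, y)@statistic, -welchT(y, x)@statistic)
  expect_error(welchT(c(1, 1), c(1, 1)), "zero variance")
  expect_error(welchT(1, c(1, 2)), "n >= 2")
})

test_that("size percentiles use max-rank ties and keep boundary ties", {
  lens <- setNames(seq_len(1000) + 0.0, sprintf("g%04d", 1:1000))
  pct <- sizePercentiles(lens)
  expect_equal(unname(pct[which.max(lens)]), 100)
  expect_equal(unname(pct[["g0950"]]), 95)

  tied <- setNames(c(10, 20, 20), c("a", "b", "c"))
  pctT <- sizePercentiles(tied)
  expect_equal(pctT[["b"]], pctT[["c"]])
  expect_equal(unname(pctT[["b"]]), 100)

  expect_warning(p2 <- sizePercentiles(setNames(c(5, NA, 7), c("a", "b", "c"))),
                 "excluded")
  expect_false("b" %in% names(p2))
  expect_error(sizePercentiles(c(a = -1)), "positive")

  # the 95.0-percentile gene sits exactly on the cut and is kept
  top <- topFraction(lens, 0.05)
  expect_length(top, 51L)
  expect_true(all(lens[top] >= 950))
})

test_that("the large-protein chromatin profile reproduces the printed shares", {
  # universe of 19,486 genes with distinct lengths; the annotated set is 92
  # genes inside the top-5% size cut; 19 of 84 TSGs and 1 of 81 OGs inside
  n <- 19486L
  ids <- sprintf("g%05d", seq_len(n))
  lens <- setNames(seq_len(n) + 0.0, ids)
  topIds <- ids[n - seq_len(975) + 1]        # top 5% by length
  setIds <- topIds[1:92]
  ann <- data.frame(chromosome_organization = as.numeric(ids %in% setIds),
                    chromatin_modification = as.numeric(ids %in% setIds[1:66]),
                    row.names = ids)
  tierVec <- setNames(rep("background", n), ids)
  tierVec[c(setIds[1:19], ids[1:65])] <- "high_TSG"     # 19 inside, 65 out
  tierVec[c(setIds[20], ids[66:145])] <- "high_OG"      # 1 inside, 80 out
  lab <- makeLabelSet(tierVec)

  prof <- intersectAndProfile(lens, ann, lab, q = 0.05,
                              secondaryFlags = "chromatin_modification")
  expect_length(prof$selected, 92L)
  comp <- prof$composition
  expect_equal(comp$inside[comp$group == "high_TSG"], 19L)
  expect_equal(round(comp$share_pct[comp$group == "high_TSG"]), 23)
  expect_equal(comp$inside[comp$group == "high_OG"], 1L)
  expect_equal(round(prof$secondary$share_pct), 72)
  expect_equal(prof$enrichment@k, 19L)
  expect_equal(round(prof$enrichment@fold), 62)

  # empty annotation: empty set, zero fold
  ann0 <- data.frame(chromosome_organization = rep(0, n), row.names = ids)
  prof0 <- intersectAndProfile(lens, ann0, lab, q = 0.05)
  expect_length(prof0$selected, 0L)
  expect_equal(prof0$enrichment@fold, 0)

  expect_error(intersectAndProfile(lens, ann, lab, primaryFlag = "nope"),
               "annotation column absent")
})

test_that("planted size inflation strengthens the enrichment signal", {
  mk <- function(inflation, seed) {
    cfg <- simConfig(nGenes = 1500L, nTsg = 60L, nOg = 60L,
                     sizeInflation = inflation, missingRate = 0,
                     chromatinRateTsg = 0.5, seed = seed)
    u <- generateUniverse(cfg)
    ft <- u$features@data
    lens <- setNames(ft$cds_length_aa, rownames(ft))
    ann <- data.frame(chromosome_organization = ft$go_chromosome_organization,
                      row.names = rownames(ft))
    tierVec <- setNames(rep("background", length(u$truth@geneId)),
                        u$truth@geneId)
    tierVec[u$truth@trueClass == "TSG"] <- "high_TSG"
    tierVec[u$truth@trueClass == "OG"] <- "high_OG"
    intersectAndProfile(lens, ann, makeLabelSet(tierVec),
                        q = 0.05)$enrichment@pUpper
  }
  for (seed in c(5L, 6L, 7L))
    expect_lt(mk(3.8, seed), mk(1, seed))
})

test_that("enrichment results validate their count bounds", {
  e <- enrichmentTest(100, 20, 10, 5)
  expect_s4_class(e, "EnrichmentResult")
  expect_error(new("EnrichmentResult", N = 10L, K = 3L, n = 4L, k = 5L,
                   pUpper = 0.1, fold = 1), "exceeds")
})
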