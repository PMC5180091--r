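test_that("genomic density matches hand enumeration and normalizes to mean 1", {
  co <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                   center_bp = c(1e6, 2e6, 10e6))
  expect_equal(unname(genomicDensity(co)), c(1.2, 1.2, 0.6))

  one <- data.frame(gene_id = "solo", chrom = "chr1", center_bp = 5e6)
  expect_equal(unname(genomicDensity(one)), 1)

  same <- data.frame(gene_id = letters[1:4], chrom = "chr2",
                     center_bp = rep(7e6, 4))
  expect_equal(unname(genomicDensity(same)), rep(1, 4))

  # missing coordinates: missing density, excluded from the mean
  co2 <- rbind(co, data.frame(gene_id = "d", chrom = NA, center_bp = NA))
  d <- genomicDensity(co2)
  expect_true(is.na(d[["d"]]))
  expect_equal(mean(d, na.rm = TRUE), 1)

  # different chromosomes never see each other
  co3 <- data.frame(gene_id = c("x", "y"), chrom = c("chr1", "chr2"),
                    center_bp = c(1e6, 1e6))
  expect_equal(unname(genomicDensity(co3)), c(1, 1))
})

test_that("interaction counts average the two sources, tolerating one missing", {
  expect_equal(ppiCount(3, 5), 4)
  expect_equal(ppiCount(0, 0), 0)
  expect_equal(ppiCount(7, NA), 7)
  expect_true(is.na(ppiCount(NA, NA)))
})

test_that("betweenness matches the brute-force oracle on small graphs", {
  path <- data.frame(from = c("a", "b"), to = c("b", "c"))
  b <- betweennessCentrality(path)
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 1, 0))

  star <- data.frame(from = "hub", to = paste0("leaf", 1:4))
  b2 <- betweennessCentrality(star)
  expect_equal(unname(b2[["hub"]]), choose(4, 2))
  expect_true(all(b2[paste0("leaf", 1:4)] == 0))

  withr::with_seed(99, {
    for (rep in 1:5) {
      n <- sample(5:12, 1)
      nodes <- paste0("n", seq_len(n))
      ed <- t(utils::combn(nodes, 2))
      keep <- runif(nrow(ed)) < 0.4
      ed <- as.data.frame(ed[keep, , drop = FALSE])
      if (nrow(ed) == 0) next
      names(ed) <- c("from", "to")
      got <- betweennessCentrality(ed, geneIds = nodes)
      want <- bruteBetweenness(ed, nodes)
      expect_equal(got[nodes], want[nodes], tolerance = 1e-9)
    }
  })

  expect_warning(
    betweennessCentrality(data.frame(from = c("a", "a"), to = c("a", "b"))),
    "self-loop")
})

test_that("tissue summary uses the as-printed variation (mean over sd)", {
  e <- rbind(c(1, 2, 3), c(5, 5, 5), c(NA, NA, NA))
  rownames(e) <- c("g1", "g2", "g3")
  ts <- tissueSummary(e)
  expect_equal(ts["g1", "median_expression"], 2)
  expect_equal(ts["g1", "expression_variation"], 2)  # mean 2 / sd 1
  expect_equal(ts["g2", "median_expression"], 5)
  expect_true(is.na(ts["g2", "expression_variation"]))  # sd 0
  expect_true(all(is.na(ts["g3", ])))

  conv <- tissueSummary(e, conventional = TRUE)
  expect_equal(conv["g1", "expression_variation"], 0.5)
})

test_that("PTM counts are normalized by CDS length elementwise", {
  counts <- cbind(acetyl = c(10, 0), phospho = c(4, 8))
  rownames(counts) <- c("g1", "g2")
  out <- normalizePtm(counts, c(1000, 400))
  expect_equal(out["g1", "acetyl"], 0.01)
  expect_equal(out["g2", "acetyl"], 0)
  oracle <- counts
  for (i in 1:2) oracle[i, ] <- counts[i, ] / c(1000, 400)[i]
  expect_equal(out, oracle)
  expect_error(normalizePtm(counts, c(1000, 0)), "positive")
  expect_true(all(is.na(normalizePtm(counts, c(1000, NA))["g2", ])))
})

test_that("sparse filter requires both the ratio and uniqueness criteria", {
  df <- data.frame(
    nearly_const = c(rep("A", 99), "B"),             # 99 > 97/3, 2% unique
    balanced = rep(c(0, 1), 50),                     # ratio 1
    all_distinct = seq_len(100) + 0.5,               # 100% unique
    row.names = sprintf("g%03d", 1:100))
  ft <- makeFeatureTable(df, setNames(c("categorical", "binary", "continuous"),
                                      names(df)))
  res <- removeSparse(ft)
  expect_identical(res$removed$feature, "nearly_const")
  expect_setequal(featureNames(res$table), c("balanced", "all_distinct"))

  # a missing marker counts as a value: NA as the runner-up drags the
  # frequency ratio below threshold and the feature is kept
  df2 <- data.frame(mostly_missing = c(rep(1, 90), rep(NA, 10)),
                    row.names = sprintf("g%03d", 1:100))
  res2 <- removeSparse(makeFeatureTable(df2))
  expect_equal(nrow(res2$removed), 0L)

  # single-valued feature: infinite ratio, removed iff uniqueness also holds
  df3 <- data.frame(constant = rep(3.3, 100),
                    row.names = sprintf("g%03d", 1:100))
  res3 <- removeSparse(makeFeatureTable(df3))
  expect_identical(res3$removed$feature, "constant")
})

test_that("sparse filter matches the near-zero-variance reference", {
  skip_if_not_installed("caret")
  withr::with_seed(17, {
    df <- data.frame(
      a = sample(c(0, 1), 200, TRUE, prob = c(0.99, 0.01)),
      b = rnorm(200),
      c = sample(c(0, 1), 200, TRUE),
      d = c(rep(0, 197), 1, 2, 3),
      row.names = sprintf("g%03d", 1:200))
  })
  ours <- removeSparse(makeFeatureTable(df))$removed$feature
  ref <- names(df)[caret::nearZeroVar(df, freqCut = 97 / 3, uniqueCut = 3)]
  expect_setequal(ours, ref)
})

test_that("correlation filter removes exactly one member of a duplicate pair", {
  withr::with_seed(23, {
    x <- rnorm(500); y <- rnorm(500)
    df <- data.frame(f = x, f_copy = x, indep = y,
                     row.names = sprintf("g%03d", 1:500))
  })
  res <- removeCorrelated(makeFeatureTable(df))
  expect_equal(nrow(res$removed), 1L)
  expect_true(res$removed$feature %in% c("f", "f_copy"))
  expect_true("indep" %in% featureNames(res$table))

  # postcondition: no surviving pair above threshold
  cm <- cor(res$table@data, method = "spearman",
            use = "pairwise.complete.obs")
  diag(cm) <- 0
  expect_lte(max(abs(cm)), 0.95)

  # two independent standard normals stay
  res2 <- removeCorrelated(makeFeatureTable(df[, c("f", "indep")]))
  expect_equal(nrow(res2$removed), 0L)

  # constant feature: undefined correlations treated as zero, with warning
  df3 <- data.frame(const = rep(1, 500), z = rnorm(500),
                    row.names = sprintf("g%03d", 1:500))
  expect_warning(res3 <- removeCorrelated(makeFeatureTable(df3)), "constant")
  expect_equal(nrow(res3$removed), 0L)
})

test_that("kNN imputation is exact on degenerate fixtures", {
  # complete table: idempotence
  df <- data.frame(a = rnorm(10), b = rnorm(10),
                   row.names = sprintf("g%02d", 1:10))
  ft <- makeFeatureTable(df)
  expect_identical(imputeKnn(ft, k = 3)@data, df)

  # six identical genes, one missing cell: neighbors share the value
  df2 <- data.frame(a = rep(2, 6), b = rep(5, 6),
                    row.names = sprintf("g%02d", 1:6))
  df2$b[1] <- NA
  out2 <- imputeKnn(makeFeatureTable(df2), k = 5)
  expect_equal(out2@data$b[1], 5)
  # observed cells bit-identical
  expect_identical(out2@data$a, df2$a)
  expect_identical(out2@data$b[-1], df2$b[-1])

  # the 5 nearest neighbors all miss the feature: column-median fallback.
  # gene g01 sits at x=0 with neighbors g02..g06 nearby, all missing b;
  # the far genes g07..g12 carry b.
  df3 <- data.frame(
    x = c(0, 0.1, 0.2, 0.15, 0.05, 0.12, 100, 101, 102, 103, 104, 105),
    b = c(NA, NA, NA, NA, NA, NA, 7, 8, 9, 10, 11, 12),
    row.names = sprintf("g%02d", 1:12))
  out3 <- imputeKnn(makeFeatureTable(df3), k = 5)
  expect_equal(out3@data$b[1], median(c(7, 8, 9, 10, 11, 12)))

  # a feature missing everywhere should have been removed upstream
  df4 <- data.frame(a = rnorm(8), b = rep(NA_real_, 8),
                    row.names = sprintf("g%02d", 1:8))
  expect_error(imputeKnn(makeFeatureTable(df4)), "every gene")
})

test_that("encoding one-hots categoricals and round-trips the column map", {
  df <- data.frame(cont = c(1.5, 2.5, 3.5),
                   cat = c("low", "high", "low"),
                   row.names = c("g1", "g2", "g3"))
  ft <- makeFeatureTable(df, setNames(c("continuous", "categorical"),
                                      names(df)))
  enc <- encodeFeatures(ft)
  expect_equal(colnames(enc$matrix), c("cont", "cat=high", "cat=low"))
  expect_equal(unname(rowSums(enc$matrix[, c("cat=high", "cat=low")])),
               rep(1, 3))
  expect_setequal(unique(enc$columnMap$feature), c("cont", "cat"))

  # pure continuous: identity
  ft2 <- makeFeatureTable(df["cont"])
  expect_equal(encodeFeatures(ft2)$matrix[, 1], setNames(df$cont, rownames(df)))

  # unseen level against a fixed level set
  expect_error(encodeFeatures(ft, levelsMap = list(cat = c("low", "mid"))),
               "unseen categorical level")
})

test_that("the pipeline applies sparse, correlation then imputation in order", {
  u <- generateUniverse(simConfig(nGenes = 300L, nTsg = 12L, nOg = 12L,
                                  seed = 77L))
  prep <- prepareFeatures(u$features)
  expect_false(anyNA(prep$matrix))
  reasons <- split(prep$removed$feature, prep$removed$reason)
  expect_true(all(grepl("^sparse_", reasons$sparse)))
  expect_true(length(reasons$correlated) >= 1)
  # observed cells survive filtering and imputation bit-identically
  raw <- u$features@data
  imp <- prep$table@data
  for (f in colnames(imp)) {
    obs <- !is.na(raw[[f]])
    expect_identical(imp[[f]][obs], raw[[f]][obs])
  }
})
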