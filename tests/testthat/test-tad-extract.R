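test_that("label runs become tiling segments", {
  seg <- segmentsFromLabels(c(1, 1, 2, 2, 2, 1))
  expect_equal(seg$startBin, c(0L, 2L, 5L))
  expect_equal(seg$endBin, c(1L, 4L, 5L))
  expect_equal(seg$label, c(1L, 2L, 1L))

  expect_equal(nrow(segmentsFromLabels(rep(3, 7))), 1L)

  seg2 <- segmentsFromLabels(c(NA, 1, 1))
  expect_equal(seg2$class, c("GAP", "UNCLASSIFIED"))
  expect_equal(seg2$startBin, c(0L, 1L))

  # tiling property over random label vectors
  set.seed(5)
  for (i in 1:10) {
    lab <- sample(c(1:3, NA), 25, replace = TRUE)
    s <- segmentsFromLabels(lab)
    expect_equal(s$startBin[1], 0L)
    expect_equal(s$endBin[nrow(s)], 24L)
    if (nrow(s) > 1) {
      expect_equal(s$startBin[-1], s$endBin[-nrow(s)] + 1L)
    }
  }
})

test_that("segment classification applies the minimum TAD size", {
  seg <- data.frame(startBin = c(0L, 5L, 9L), endBin = c(4L, 8L, 9L),
                    label = c(1L, 2L, NA), class = c("UNCLASSIFIED",
                                                     "UNCLASSIFIED", "GAP"))
  # at 40 kb bins: 5 bins = 200 kb >= 180 kb -> TAD; 4 bins = 160 kb -> not
  out <- classifySegments(seg, extractionConfig(), resolution = 40000L)
  expect_equal(out$class, c("TAD", "BOUNDARY", "GAP"))

  # unitless: bin threshold applies
  out2 <- classifySegments(seg, extractionConfig(minTadBins = 5L),
                           resolution = NA)
  expect_equal(out2$class, c("TAD", "BOUNDARY", "GAP"))
  expect_error(
    classifySegments(seg, extractionConfig(minTadBins = NULL),
                     resolution = NA),
    "minTadBins")
})

test_that("TAD quality equals intra minus inter on the 6x6 hand example", {
  v <- matrix(1, 6, 6)
  v[1:3, 1:3] <- 5
  v[4:6, 4:6] <- 5
  m <- ContactMatrix(v)
  tads <- data.frame(startBin = c(0L, 3L), endBin = c(2L, 5L))
  expect_equal(tadQuality(m, tads, 1), 4)
  expect_equal(tadQuality(m, tads, 2), 4)

  # identical intra and inter means give quality zero
  flat <- ContactMatrix(matrix(3, 6, 6))
  expect_equal(tadQuality(flat, tads, 1), 0)
})

test_that("TAD quality matches the brute-force cell-averaging oracle", {
  m <- randomContactMatrix(12, seed = 19)
  v <- contactValues(m)
  tads <- list(c(0L, 3L), c(4L, 7L), c(8L, 11L))
  tadDf <- data.frame(startBin = sapply(tads, `[`, 1),
                      endBin = sapply(tads, `[`, 2))
  for (i in 1:3) {
    expect_equal(tadQuality(m, tadDf, i), oracleQuality(v, tads, i),
                 tolerance = 1e-12)
    expect_equal(tadQuality(m, tadDf, i,
                            extractionConfig(includeDiagonal = TRUE)),
                 oracleQuality(v, tads, i, includeDiagonal = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("raising within-TAD contacts by c raises quality by exactly c", {
  m <- randomContactMatrix(12, seed = 23)
  v <- contactValues(m)
  tadDf <- data.frame(startBin = c(0L, 4L, 8L), endBin = c(3L, 7L, 11L))
  q0 <- tadQuality(m, tadDf, 2)
  v2 <- v
  v2[5:8, 5:8] <- v2[5:8, 5:8] + 2.5
  expect_equal(tadQuality(ContactMatrix(v2), tadDf, 2), q0 + 2.5)
})

test_that("extractTads composes segmentation, classes and scores", {
  gen <- plantedFixture(noiseSd = 0)
  f <- buildDiagonalFeatures(gen$matrix)
  a <- kmeansCluster(f, 5, seed = 1)
  ts <- extractTads(gen$matrix, a)
  expect_equal(tadTable(ts)$startBin, c(0L, 8L, 14L, 20L, 25L))
  expect_equal(tadTable(ts)$endBin, c(7L, 13L, 19L, 24L, 29L))
  expect_equal(tadQualities(ts), rep(8, 5))
  expect_equal(overallQuality(ts), 8)

  # single cluster spans all non-gap bins as one TAD
  one <- makeCA(rep(1L, 30))
  one@binIndex <- 0:29
  ts1 <- extractTads(gen$matrix, one)
  expect_equal(nrow(tadTable(ts1)), 1L)
  expect_equal(tadTable(ts1)$endBin, 29L)

  # alternating labels leave only boundaries
  alt <- makeCA(rep(c(1L, 2L), 15))
  ts2 <- extractTads(gen$matrix, alt)
  expect_equal(nrow(tadTable(ts2)), 0L)
  expect_equal(overallQuality(ts2), -Inf)
})

test_that("extraction is invariant to cluster-label permutation", {
  gen <- plantedFixture(noiseSd = 1, seed = 3)
  f <- buildDiagonalFeatures(gen$matrix)
  a <- kmeansCluster(f, 5, seed = 2)
  perm <- c(3L, 5L, 1L, 2L, 4L)
  b <- makeCA(perm[clusterLabels(a)], k = 5)
  tsA <- extractTads(gen$matrix, a)
  tsB <- extractTads(gen$matrix, b)
  expect_equal(tadTable(tsA)[, c("startBin", "endBin", "quality")],
               tadTable(tsB)[, c("startBin", "endBin", "quality")])
})

test_that("gap bins re-enter as GAP segments", {
  gen <- generateBlockMatrix(plantedSpec(
    20, list(c(0, 8), c(12, 19)), noiseSd = 0, gapBins = 9:11))
  f <- buildDiagonalFeatures(gen$matrix)
  expect_equal(excludedBins(f), 9:11)
  a <- kmeansCluster(f, 2, seed = 1)
  ts <- extractTads(gen$matrix, a)
  seg <- tadSegments(ts)
  expect_equal(seg$class[seg$startBin == 9], "GAP")
  expect_equal(tadTable(ts)$startBin, c(0L, 12L))
})

test_that("best TAD set selection maximizes quality with smallest-K ties", {
  gen <- plantedFixture(noiseSd = 0)
  sel <- selectBestTadSet(gen$matrix, kRange = c(2, 14), seed = 1)
  expect_equal(tadTable(sel$best)$startBin, c(0L, 8L, 14L, 20L, 25L))
  expect_equal(tadTable(sel$best)$endBin, c(7L, 13L, 19L, 24L, 29L))
  expect_equal(nrow(sel$perK), 13L)
  # the winner attains the maximum of the per-K curve at the smallest K
  top <- sel$perK$k[which.max(sel$perK$overallQuality)]
  expect_equal(sel$best@kUsed, top)

  # single-K range returns that K
  sel5 <- selectBestTadSet(gen$matrix, kRange = c(5, 5), seed = 1)
  expect_equal(sel5$best@kUsed, 5L)
})
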