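test_that("distance metrics match their definitions", {
  expect_equal(binDistance(c(0, 0), c(3, 4), "euclidean"), 5)
  expect_equal(binDistance(c(0, 0), c(3, 4), "cityblock"), 7)
  expect_equal(binDistance(c(1, 2, 3), c(2, 4, 6), "pearson"), 0)
  expect_equal(binDistance(c(1, 2, 3), c(3, 2, 1), "pearson"), 2)
  expect_error(binDistance(c(1, 1), c(1, 2), "pearson"), "constant")
  expect_error(binDistance(1:3, 1:4, "euclidean"), "equal length")
})

test_that("k-means separates well-separated groups and handles k = n", {
  gen <- generateBlockMatrix(plantedSpec(12, list(c(0, 5), c(6, 11)),
                                         intraMean = 10, interMean = 0.1,
                                         noiseSd = 0.01, seed = 5))
  f <- buildDiagonalFeatures(gen$matrix)
  lab <- clusterLabels(kmeansCluster(f, 2, seed = 1))
  expect_length(unique(lab[1:6]), 1L)
  expect_length(unique(lab[7:12]), 1L)
  expect_false(lab[1] == lab[12])

  f5 <- buildDiagonalFeatures(randomContactMatrix(5, seed = 2))
  a5 <- kmeansCluster(f5, 5, seed = 1)
  expect_length(unique(clusterLabels(a5)), 5L)
  expect_equal(a5@withinVariance, 0)
  expect_error(kmeansCluster(f5, 6, seed = 1), "exceeds")
})

test_that("k-means is deterministic given a seed and restarts help", {
  gen <- plantedFixture(noiseSd = 2, seed = 9)
  f <- buildDiagonalFeatures(gen$matrix)
  a1 <- kmeansCluster(f, 5, seed = 42)
  a2 <- kmeansCluster(f, 5, seed = 42)
  expect_identical(clusterLabels(a1), clusterLabels(a2))
  aMulti <- kmeansCluster(f, 5, seed = 7, nRestarts = 10)
  aSingle <- kmeansCluster(f, 5, seed = 7, nRestarts = 1)
  expect_lte(aMulti@withinVariance, aSingle@withinVariance + 1e-9)
})

test_that("all algorithm/metric combinations recover zero-noise blocks", {
  gen <- plantedFixture(noiseSd = 0)
  f <- buildDiagonalFeatures(gen$matrix)
  truthLab <- rep(1:5, times = c(8, 6, 6, 5, 5))
  sameUpToRelabel <- function(lab) {
    length(unique(lab)) == 5L &&
      all(tapply(lab, truthLab, function(x) length(unique(x))) == 1L)
  }
  for (metric in c("euclidean", "pearson", "cityblock")) {
    expect_true(sameUpToRelabel(
      clusterLabels(kmeansCluster(f, 5, metric, seed = 1))),
      label = paste("KM", metric))
    expect_true(sameUpToRelabel(
      clusterLabels(hierarchicalCluster(f, 5, metric))),
      label = paste("HC", metric))
  }
  expect_true(sameUpToRelabel(clusterLabels(emCluster(f, 5, seed = 1))))
})

test_that("hierarchical clustering honors k = 1 and linkage limits", {
  f <- buildDiagonalFeatures(randomContactMatrix(6, seed = 13))
  expect_length(unique(clusterLabels(hierarchicalCluster(f, 1))), 1L)
  expect_error(hierarchicalCluster(f, 2, metric = "pearson",
                                   linkage = "ward"), "euclidean")
})

test_that("EM on identical duplicate rows yields a single label", {
  f <- makeFT(matrix(5, 6, 8))
  a <- emCluster(f, 3, seed = 1)
  expect_length(unique(clusterLabels(a)), 1L)
})

test_that("rule-of-thumb K estimate rounds sqrt(n/2) with floor 2", {
  expect_identical(estimateKHan(30), 4L)
  expect_identical(estimateKHan(2), 2L)
  expect_identical(estimateKHan(200), 10L)
  expect_error(estimateKHan(1), ">= 2")
})

test_that("K search window is +/-10 clipped to [2, n-1]", {
  expect_identical(kSearchWindow(4, 30), c(2L, 14L))
  expect_identical(kSearchWindow(15, 1000), c(5L, 25L))
  expect_identical(kSearchWindow(2, 4), c(2L, 3L))
})

test_that("elbow selects the planted cluster number", {
  gen <- plantedFixture(noiseSd = 0)
  f <- buildDiagonalFeatures(gen$matrix)
  e <- elbowK(f, 2, 10, seed = 1)
  expect_identical(e$kElbow, 5L)
  expect_equal(nrow(e$curve), 9L)
  expect_true(all(diff(e$curve$varianceExplained) > -1e-6))

  gen2 <- generateBlockMatrix(plantedSpec(20, list(c(0, 9), c(10, 19)),
                                          noiseSd = 1, seed = 7))
  f2 <- buildDiagonalFeatures(gen2$matrix)
  expect_identical(elbowK(f2, 2, 6, seed = 7)$kElbow, 2L)

  expect_warning(elbowK(f2, 2, 50, seed = 1), "clipped")
  expect_error(elbowK(f2, 1, 5), ">= 2")
})

test_that("Davies-Bouldin matches hand-computed values", {
  # two 1-D clusters {0,2} and {10,12}: d_i = 1, separation 10, DBI 0.2
  f <- makeFT(matrix(c(0, 2, 10, 12), ncol = 1))
  a <- makeCA(c(1, 1, 2, 2))
  expect_equal(daviesBouldin(f, a, "euclidean"), 0.2)

  # two singleton clusters have zero spread: DBI = 0
  expect_equal(daviesBouldin(makeFT(matrix(c(0, 10), ncol = 1)),
                             makeCA(c(1, 2)), "euclidean"), 0)

  # identical centroids are a diagnosable error
  expect_error(daviesBouldin(makeFT(matrix(c(0, 2, 1, 1), ncol = 1)),
                             makeCA(c(1, 1, 2, 2)), "euclidean"),
               "centroid")
  expect_error(daviesBouldin(f, makeCA(rep(1, 4)), "euclidean"),
               ">= 2")
})

test_that("silhouette matches hand values, conventions and bounds", {
  f <- makeFT(matrix(c(0, 1, 10, 11), ncol = 1))
  a <- makeCA(c(1, 1, 2, 2))
  s <- silhouetteIndex(f, a, "euclidean")
  expect_equal(s$perPoint[1], 9.5 / 10.5)

  # zero-spread separated clusters: SI = 1
  fz <- makeFT(matrix(c(0, 0, 10, 10), ncol = 1))
  expect_equal(silhouetteIndex(fz, a, "euclidean")$si, 1)

  # all singletons: SI = 0 by convention
  expect_equal(silhouetteIndex(f, makeCA(1:4), "euclidean")$si, 0)

  expect_error(silhouetteIndex(f, makeCA(rep(1, 4)), "euclidean"),
               ">= 2 clusters")
})

test_that("quality indices match brute-force oracles on random instances", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(6:20, 1)
    k <- sample(2:5, 1)
    metric <- sample(c("euclidean", "pearson", "cityblock"), 1)
    X <- matrix(rnorm(n * 6), n, 6)
    labels <- sample(rep(seq_len(k), length.out = n))
    f <- makeFT(X)
    a <- makeCA(labels, k = k, metric = metric)
    expect_equal(daviesBouldin(f, a, metric), oracleDBI(X, labels, metric),
                 tolerance = 1e-9)
    si <- silhouetteIndex(f, a, metric)
    expect_equal(si$si, oracleSI(X, labels, metric), tolerance = 1e-9)
    expect_true(all(si$perPoint >= -1 - 1e-12 & si$perPoint <= 1 + 1e-12))
    expect_gte(daviesBouldin(f, a, metric), 0)
  }
})

test_that("euclidean per-point silhouettes agree with cluster package", {
  skip_if_not_installed("cluster")
  set.seed(31)
  X <- matrix(rnorm(40), 10, 4)
  labels <- sample(rep(1:3, length.out = 10))
  s <- silhouetteIndex(makeFT(X), makeCA(labels), "euclidean")
  ref <- cluster::silhouette(labels, dist(X))
  expect_equal(s$perPoint, as.numeric(ref[, "sil_width"]),
               tolerance = 1e-9)
})
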