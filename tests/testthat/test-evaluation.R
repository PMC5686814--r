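test_that("match cases follow exact-match / containment / overlap rules", {
  b <- makeTadSet(list(c(1L, 8L), c(9L, 14L), c(15L, 20L)), 25L)
  # exact boundary match
  expect_equal(matchCase(c(9L, 14L), b, tol = 0L), "A")
  # containment of two or more sub-TADs
  expect_equal(matchCase(c(1L, 20L), b, tol = 0L), "B")
  # overlap without match or double containment
  expect_equal(matchCase(c(1L, 10L), makeTadSet(list(c(5L, 15L)), 20L)),
               "C")
  # a single contained sub-TAD is a conflict, not containment
  expect_equal(matchCase(c(0L, 10L), makeTadSet(list(c(2L, 6L)), 20L)),
               "C")
  # disjoint support
  expect_equal(matchCase(c(0L, 3L), makeTadSet(list(c(10L, 15L)), 20L)),
               "none")
  # tolerance admits near-matches
  expect_equal(matchCase(c(9L, 14L),
                         makeTadSet(list(c(10L, 15L)), 20L), tol = 1L),
               "A")
})

test_that("consistency percentage counts cases A and B", {
  a <- makeTadSet(list(c(1L, 8L), c(9L, 14L)), 20L)
  bSame <- makeTadSet(list(c(1L, 8L), c(9L, 14L)), 20L)
  expect_equal(consistencyPercentage(a, bSame)$percentDetected, 100)

  bHalf <- makeTadSet(list(c(1L, 8L), c(16L, 19L)), 20L)
  rep <- consistencyPercentage(a, bHalf)
  expect_equal(rep$percentDetected, 50)
  expect_equal(rep$perTad$case, c("A", "none"))

  bOff <- makeTadSet(list(c(16L, 19L)), 20L)
  expect_equal(consistencyPercentage(a, bOff)$percentDetected, 0)

  empty <- makeTadSet(list(), 20L)
  expect_error(consistencyPercentage(empty, bSame), "no TADs")
})

test_that("every TAD set is 100% consistent with itself", {
  set.seed(12)
  for (i in 1:8) {
    n <- sample(20:60, 1)
    cuts <- sort(sample(2:(n - 2), sample(2:5, 1)))
    starts <- c(0L, cuts)
    ends <- c(cuts - 1L, n - 1L)
    keep <- which(ends - starts >= 2L)
    if (length(keep) < 1) next
    doms <- Map(c, starts[keep], ends[keep])
    x <- makeTadSet(doms, n)
    rep <- consistencyPercentage(x, x, tol = 0L)
    expect_equal(rep$percentDetected, 100)
    expect_true(all(rep$perTad$case == "A"))
  }
})

test_that("case classification is exhaustive and exclusive", {
  set.seed(44)
  b <- makeTadSet(list(c(0L, 5L), c(6L, 11L), c(20L, 25L)), 30L)
  for (i in 1:20) {
    s <- sample(0:27, 1); e <- s + sample(1:(29 - s), 1)
    expect_true(matchCase(c(s, e), b) %in% c("A", "B", "C", "none"))
  }
})

test_that("peaks planted at borders produce a profile peaking at 0", {
  gen <- plantedFixture(noiseSd = 0, resolution = 40000L, chrom = "chr2")
  truth <- gen$truth
  peaks <- generateBoundaryPeaks(truth, 40000L, peaksPerBoundary = 2L,
                                 backgroundRate = 0, seed = 5)
  prof <- boundaryPeakEnrichment(truth, peaks, resolution = 40000L,
                                 windowBins = 2L)
  p <- prof$profile
  expect_equal(p$meanPeakCount[p$offsetBin == 0], 2)
  expect_true(all(p$meanPeakCount[p$offsetBin == 0] >=
                  p$meanPeakCount[p$offsetBin != 0]))
  expect_equal(prof$nBoundaries,
               length(unique(c(tadTable(truth)$startBin,
                               tadTable(truth)$endBin))))
})

test_that("enrichment scales linearly with peak density", {
  gen <- plantedFixture(noiseSd = 0, resolution = 40000L, chrom = "chr2")
  peaks <- generateBoundaryPeaks(gen$truth, 40000L, peaksPerBoundary = 1L,
                                 backgroundRate = 0.5, seed = 9)
  prof1 <- boundaryPeakEnrichment(gen$truth, peaks, 40000L, windowBins = 1L)
  doubled <- c(peaks, peaks)
  prof2 <- boundaryPeakEnrichment(gen$truth, doubled, 40000L,
                                  windowBins = 1L)
  expect_equal(prof2$profile$meanPeakCount,
               2 * prof1$profile$meanPeakCount)
})

test_that("an empty peak set warns and yields a zero profile", {
  gen <- plantedFixture(noiseSd = 0, resolution = 40000L)
  expect_warning(
    prof <- boundaryPeakEnrichment(gen$truth, GenomicRanges::GRanges(),
                                   40000L),
    "empty")
  expect_true(all(prof$profile$meanPeakCount == 0))
})
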