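# Shared fixtures and independent brute-force oracles.

# the five planted domains used throughout (0-based inclusive bins,
# 30-bin matrix): 0-7, 8-13, 14-19, 20-24, 25-29
plantedDomains30 <- function() {
  list(c(0L, 7L), c(8L, 13L), c(14L, 19L), c(20L, 24L), c(25L, 29L))
}

plantedFixture <- function(noiseSd = 0, seed = 1L, ...) {
  generateBlockMatrix(plantedSpec(30L, plantedDomains30(),
                                  noiseSd = noiseSd, seed = seed, ...))
}

# build a TadSet tiling 0..nBins-1 from a list of TAD ranges; the bins
# between TADs become boundaries
makeTadSet <- function(domains, nBins, chrom = "chrU", resolution = NA) {
  labels <- rep(0L, nBins)
  for (d in seq_along(domains)) {
    labels[(domains[[d]][1]:domains[[d]][2]) + 1L] <- d
  }
  seg <- segmentsFromLabels(labels, nBins)
  seg$class <- ifelse(seg$label >= 1L, "TAD", "BOUNDARY")
  new("TadSet", segments = seg,
      tadQualities = rep(NA_real_, sum(seg$class == "TAD")),
      overallQuality = NA_real_, chrom = chrom,
      resolution = if (is.na(resolution)) NA_integer_ else
        as.integer(resolution))
}

# bespoke feature table / assignment constructors for index tests
makeFT <- function(X) {
  X <- as.matrix(X)
  new("FeatureTable", features = X, binIndex = seq_len(nrow(X)) - 1L,
      excludedBins = integer(0), nBins = nrow(X))
}

makeCA <- function(labels, k = length(unique(labels)),
                   metric = "euclidean") {
  new("ClusterAssignment", labels = as.integer(labels),
      binIndex = seq_along(labels) - 1L, k = as.integer(k),
      algorithm = "KM", metric = metric, seed = NA_integer_,
      withinVariance = NA_real_)
}

# ---- independent oracles (plain loops, no shared code paths) ----

oracleDist <- function(u, v, metric) {
  if (metric == "euclidean") return(sqrt(sum((u - v)^2)))
  if (metric == "cityblock") return(sum(abs(u - v)))
  1 - cor(u, v)
}

oracleCentroid <- function(X, metric) {
  if (metric == "cityblock") apply(X, 2, median) else colMeans(X)
}

oracleDBI <- function(X, labels, metric) {
  ids <- sort(unique(labels))
  cent <- lapply(ids, function(g) {
    oracleCentroid(X[labels == g, , drop = FALSE], metric)
  })
  d <- sapply(seq_along(ids), function(g) {
    mem <- which(labels == ids[g])
    mean(sapply(mem, function(p) oracleDist(X[p, ], cent[[g]], metric)))
  })
  Dis <- sapply(seq_along(ids), function(i) {
    max(sapply(setdiff(seq_along(ids), i), function(j) {
      (d[i] + d[j]) / oracleDist(cent[[i]], cent[[j]], metric)
    }))
  })
  mean(Dis)
}

oracleSI <- function(X, labels, metric) {
  ids <- sort(unique(labels))
  n <- nrow(X)
  s <- numeric(n)
  for (p in seq_len(n)) {
    own <- which(labels == labels[p] & seq_len(n) != p)
    if (!length(own)) { s[p] <- 0; next }
    a <- mean(sapply(own, function(q) oracleDist(X[p, ], X[q, ], metric)))
    b <- min(sapply(setdiff(ids, labels[p]), function(g) {
      mean(sapply(which(labels == g),
                  function(q) oracleDist(X[p, ], X[q, ], metric)))
    }))
    s[p] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(sapply(ids, function(g) mean(s[labels == g])))
}

# cell-by-cell quality of TAD i: mean over upper-triangle in-block cells
# minus the mean over the rectangles to the adjacent TADs
oracleQuality <- function(v, tads, i, includeDiagonal = FALSE) {
  rng <- tads[[i]]
  cells <- c()
  for (a in rng[1]:rng[2]) for (b in rng[1]:rng[2]) {
    if (b > a || (includeDiagonal && b == a)) {
      cells <- c(cells, v[a + 1, b + 1])
    }
  }
  intra <- mean(cells)
  inters <- c()
  for (j in c(i - 1, i + 1)) {
    if (j >= 1 && j <= length(tads)) {
      other <- tads[[j]]
      rect <- c()
      for (a in rng[1]:rng[2]) for (b in other[1]:other[2]) {
        rect <- c(rect, v[a + 1, b + 1])
      }
      inters <- c(inters, mean(rect))
    }
  }
  intra - mean(inters)
}

# a random symmetric non-negative matrix
randomContactMatrix <- function(n, seed) {
  set.seed(seed)
  v <- matrix(runif(n * n, 0, 10), n, n)
  ContactMatrix((v + t(v)) / 2)
}
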