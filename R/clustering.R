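.METRICS <- c("euclidean", "pearson", "cityblock")
.ALGORITHMS <- c("KM", "HC", "EM")

.checkMetric <- function(metric) {
  match.arg(metric, .METRICS)
}

#' Distance between two contact-profile vectors
#'
#' Supported metrics: \code{euclidean} (L2), \code{cityblock} (L1) and
#' \code{pearson} (1 - r, the Pearson correlation distance, in [0, 2]).
#'
#' @param u,v numeric vectors of equal length.
#' @param metric one of "euclidean", "pearson", "cityblock".
#' @return a non-negative scalar.
#' @examples
#' binDistance(c(0, 0), c(3, 4), "euclidean")  # 5
#' @export
binDistance <- function(u, v, metric = "euclidean") {
  metric <- .checkMetric(metric)
  if (length(u) != length(v)) stop("vectors must have equal length")
  switch(metric,
    euclidean = sqrt(sum((u - v)^2)),
    cityblock = sum(abs(u - v)),
    pearson = {
      if (sd(u) == 0 || sd(v) == 0) {
        stop("pearson distance undefined for a constant vector")
      }
      1 - cor(u, v)
    })
}

# pairwise distance matrix between rows of X
.pairwiseDist <- function(X, metric) {
  metric <- .checkMetric(metric)
  switch(metric,
    euclidean = as.matrix(dist(X, method = "euclidean")),
    cityblock = as.matrix(dist(X, method = "manhattan")),
    pearson = {
      sds <- apply(X, 1L, sd)
      if (any(sds == 0)) {
        stop("pearson distance undefined: constant feature row(s) ",
             paste(which(sds == 0), collapse = ", "))
      }
      d <- 1 - cor(t(X))
      d[d < 0] <- 0   # numerical guard
      diag(d) <- 0
      d
    })
}

# n x k matrix of distances from rows of X to rows of C
.distToCenters <- function(X, C, metric) {
  switch(metric,
    euclidean = {
      d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
      sqrt(pmax(d2, 0))
    },
    cityblock = {
      k <- nrow(C)
      vapply(seq_len(k),
             function(j) rowSums(abs(sweep(X, 2L, C[j, ]))),
             numeric(nrow(X)))
    },
    pearson = {
      r <- suppressWarnings(cor(t(X), t(C)))
      r[is.na(r)] <- 0   # constant centers: treat as uncorrelated
      1 - r
    })
}

# metric-optimal centroid of rows of X: L1 -> coordinate median, else mean
.centroid <- function(X, metric) {
  if (metric == "cityblock") apply(X, 2L, median) else colMeans(X)
}

.centroidsFromLabels <- function(X, labels, metric) {
  ids <- sort(unique(labels))
  C <- do.call(rbind, lapply(ids, function(g) {
    .centroid(X[labels == g, , drop = FALSE], metric)
  }))
  rownames(C) <- ids
  C
}

# cancellation-free variant of .distToCenters for the validity indices,
# where agreement with a direct computation matters more than speed
.distToCentersExact <- function(X, C, metric) {
  if (metric != "euclidean") return(.distToCenters(X, C, metric))
  vapply(seq_len(nrow(C)), function(g) {
    sqrt(rowSums(sweep(X, 2L, C[g, ])^2))
  }, numeric(nrow(X)))
}

# within-cluster sums under a metric: list(sumDist, sumSq)
.withinSums <- function(X, labels, metric) {
  C <- .centroidsFromLabels(X, labels, metric)
  ids <- as.integer(rownames(C))
  d <- numeric(nrow(X))
  for (g in seq_along(ids)) {
    mem <- labels == ids[g]
    d[mem] <- .distToCenters(X[mem, , drop = FALSE],
                             C[g, , drop = FALSE], metric)[, 1L]
  }
  list(sumDist = sum(d), sumSq = sum(d^2))
}

.newAssignment <- function(labels, f, k, algorithm, metric, seed, withinSS) {
  new("ClusterAssignment",
      labels = as.integer(labels),
      binIndex = binIndex(f),
      k = as.integer(k),
      algorithm = algorithm,
      metric = metric,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      withinVariance = withinSS)
}

# one Lloyd run from given initial centers; returns labels + objective
.lloyd <- function(X, centers, metric, maxIter = 100L) {
  labels <- rep(0L, nrow(X))
  for (iter in seq_len(maxIter)) {
    d <- .distToCenters(X, centers, metric)
    newLabels <- max.col(-d, ties.method = "first")
    # re-seed empty clusters from the point farthest from its center
    assigned <- d[cbind(seq_len(nrow(X)), newLabels)]
    for (g in seq_len(nrow(centers))) {
      if (!any(newLabels == g)) {
        far <- which.max(assigned)
        if (assigned[far] <= 0) next   # all points coincide with centers
        centers[g, ] <- X[far, ]
        d <- .distToCenters(X, centers, metric)
        newLabels <- max.col(-d, ties.method = "first")
        assigned <- d[cbind(seq_len(nrow(X)), newLabels)]
      }
    }
    if (identical(newLabels, labels)) break
    labels <- newLabels
    for (g in unique(labels)) {
      centers[g, ] <- .centroid(X[labels == g, , drop = FALSE], metric)
    }
  }
  d <- .distToCenters(X, centers, metric)
  assigned <- d[cbind(seq_len(nrow(X)), labels)]
  list(labels = labels, centers = centers,
       sumDist = sum(assigned), sumSq = sum(assigned^2))
}

#' K-means clustering of contact features
#'
#' Lloyd's algorithm with metric-aware centroids (coordinate mean for
#' euclidean/pearson, coordinate median for cityblock, which minimizes the
#' L1 within-cluster sum). The best of \code{nRestarts} random
#' initializations by within-cluster sum of distances is returned; runs
#' are deterministic given \code{seed}. Clusters that empty out are
#' re-seeded from the point farthest from its assigned center.
#'
#' @param f a [FeatureTable-class].
#' @param k number of clusters (2 <= k <= number of feature rows).
#' @param metric one of "euclidean", "pearson", "cityblock".
#' @param seed integer seed controlling initialization.
#' @param nRestarts number of random restarts (default 10).
#' @return A [ClusterAssignment-class].
#' @export
kmeansCluster <- function(f, k, metric = "euclidean", seed = 1L,
                          nRestarts = 10L) {
  stopifnot(is(f, "FeatureTable"))
  metric <- .checkMetric(metric)
  X <- featureMatrix(f)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k = ", k, " exceeds the ", n, " feature rows")
  if (metric == "pearson") .pairwiseDist(X[1L, , drop = FALSE], metric)
  best <- NULL
  set.seed(as.integer(seed))
  for (r in seq_len(nRestarts)) {
    init <- sample.int(n, k)
    run <- .lloyd(X, X[init, , drop = FALSE], metric)
    if (is.null(best) || run$sumDist < best$sumDist) best <- run
  }
  .newAssignment(best$labels, f, k, "KM", metric, seed, best$sumSq)
}

#' Agglomerative hierarchical clustering of contact features
#'
#' Builds the pairwise dissimilarity under the chosen metric and cuts the
#' agglomerative tree at \code{k} clusters. Average linkage is the default
#' because it is well defined for arbitrary dissimilarities (including the
#' Pearson correlation distance); ward linkage requires euclidean.
#'
#' @inheritParams kmeansCluster
#' @param linkage one of "average", "single", "complete", "ward".
#' @return A [ClusterAssignment-class].
#' @export
hierarchicalCluster <- function(f, k, metric = "euclidean",
                                linkage = "average") {
  stopifnot(is(f, "FeatureTable"))
  metric <- .checkMetric(metric)
  linkage <- match.arg(linkage, c("average", "single", "complete", "ward"))
  if (linkage == "ward" && metric != "euclidean") {
    stop("ward linkage is only supported with the euclidean metric")
  }
  X <- featureMatrix(f)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k = ", k, " exceeds the ", n, " feature rows")
  d <- stats::as.dist(.pairwiseDist(X, metric))
  method <- if (linkage == "ward") "ward.D2" else linkage
  labels <- cutree(hclust(d, method = method), k = k)
  ws <- .withinSums(X, labels, metric)
  .newAssignment(labels, f, k, "HC", metric, NULL, ws$sumSq)
}

#' Gaussian-mixture (EM) clustering of contact features
#'
#' Fits a k-component Gaussian mixture with diagonal covariances by
#' expectation-maximization, initialized from a seeded k-means run, and
#' assigns each bin to its maximum-posterior component. Component
#' variances are floored at \code{1e-8} times the overall data variance
#' to keep degenerate (zero-spread) components well defined. Convergence:
#' log-likelihood change below 1e-6 or 300 iterations.
#'
#' @inheritParams kmeansCluster
#' @return A [ClusterAssignment-class].
#' @export
emCluster <- function(f, k, seed = 1L) {
  stopifnot(is(f, "FeatureTable"))
  X <- featureMatrix(f)
  n <- nrow(X); d <- ncol(X)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k = ", k, " exceeds the ", n, " feature rows")
  varFloor <- 1e-8 * max(mean(apply(X, 2L, stats::var)), 1e-300)

  init <- kmeansCluster(f, k, metric = "euclidean", seed = seed,
                        nRestarts = 5L)
  labels <- clusterLabels(init)
  ids <- sort(unique(labels))
  mu <- matrix(0, k, d); sig2 <- matrix(1, k, d); w <- numeric(k)
  for (g in seq_len(k)) {
    mem <- labels == (if (g <= length(ids)) ids[g] else ids[1L])
    if (!any(mem)) mem <- rep(TRUE, n)
    mu[g, ] <- colMeans(X[mem, , drop = FALSE])
    v <- apply(X[mem, , drop = FALSE], 2L, stats::var)
    v[is.na(v)] <- 0
    sig2[g, ] <- pmax(v, varFloor)
    w[g] <- mean(mem)
  }
  w <- w / sum(w)

  logLik <- -Inf
  for (iter in seq_len(300L)) {
    # E step: log N(x | mu_g, diag(sig2_g)) per point/component
    lp <- vapply(seq_len(k), function(g) {
      sq <- sweep(sweep(X, 2L, mu[g, ])^2, 2L, sig2[g, ], "/")
      -0.5 * (d * log(2 * pi) + sum(log(sig2[g, ])) + rowSums(sq))
    }, numeric(n))
    lp <- sweep(lp, 2L, log(pmax(w, 1e-300)), "+")
    m <- apply(lp, 1L, max)
    ll <- sum(m + log(rowSums(exp(lp - m))))
    resp <- exp(lp - m - log(rowSums(exp(lp - m))))
    # M step
    nk <- colSums(resp)
    w <- pmax(nk, 1e-12) / sum(pmax(nk, 1e-12))
    for (g in seq_len(k)) {
      if (nk[g] < 1e-10) next
      mu[g, ] <- colSums(resp[, g] * X) / nk[g]
      sig2[g, ] <- pmax(colSums(resp[, g] *
                                sweep(X, 2L, mu[g, ])^2) / nk[g], varFloor)
    }
    if (is.finite(logLik) && abs(ll - logLik) < 1e-6) {
      logLik <- ll
      break
    }
    logLik <- ll
  }
  labels <- max.col(lp, ties.method = "first")
  ws <- .withinSums(X, labels, "euclidean")
  .newAssignment(labels, f, k, "EM", "euclidean", seed, ws$sumSq)
}

.clusterDispatch <- function(f, k, algorithm, metric, seed,
                             nRestarts = 10L, linkage = "average") {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  switch(algorithm,
    KM = kmeansCluster(f, k, metric = metric, seed = seed,
                       nRestarts = nRestarts),
    HC = hierarchicalCluster(f, k, metric = metric, linkage = linkage),
    EM = emCluster(f, k, seed = seed))
}

#' Rule-of-thumb estimate of the number of clusters
#'
#' The simple estimate K = sqrt(n / 2) for a dataset of n points, rounded
#' to the nearest integer with a floor of 2.
#'
#' @param n number of data points (clustered bins).
#' @return integer cluster-number estimate (>= 2).
#' @examples
#' estimateKHan(30)  # 4
#' @export
estimateKHan <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be >= 2")
  max(2L, as.integer(round(sqrt(n / 2))))
}

#' Search window around an estimated cluster number
#'
#' Flexibility window of +/- 10 clusters around the estimate, clipped to
#' the feasible range [2, n - 1].
#'
#' @param kEst estimated number of clusters (>= 2).
#' @param n number of data points.
#' @return integer vector \code{c(kLo, kHi)}.
#' @examples
#' kSearchWindow(4, 30)  # c(2, 14)
#' @export
kSearchWindow <- function(kEst, n) {
  kEst <- as.integer(kEst); n <- as.integer(n)
  if (kEst < 2L) stop("kEst must be >= 2")
  c(max(2L, kEst - 10L), min(n - 1L, kEst + 10L))
}

#' Elbow-method selection of the number of clusters
#'
#' Clusters the features for each K in \code{kMin..kMax}, computes the
#' percentage of variance explained (100 * (1 - within / total), with
#' within-cluster and total sums of squared metric distances to the
#' respective centroids), and locates the elbow of the curve: the K whose
#' point lies farthest above the chord drawn from the one-cluster anchor
#' (K = 1, 0% explained) to the last scanned K. This integral curvature
#' measure is markedly more stable under sampling noise than a pointwise
#' second difference. Ties break toward the smallest K. On data without
#' block structure the curve is featureless and the returned K is not
#' meaningful; inspect the curve.
#'
#' @inheritParams kmeansCluster
#' @param kMin,kMax inclusive K range (kMin >= 2). kMax is clipped with a
#'   warning when it reaches the number of feature rows.
#' @param algorithm "KM", "HC" or "EM".
#' @return list with \code{kElbow} (integer) and \code{curve}
#'   (data.frame with columns k, varianceExplained).
#' @export
elbowK <- function(f, kMin = 2L, kMax = 10L, algorithm = "KM",
                   metric = "euclidean", seed = 1L, nRestarts = 10L) {
  stopifnot(is(f, "FeatureTable"))
  metric <- .checkMetric(metric)
  X <- featureMatrix(f)
  n <- nrow(X)
  kMin <- as.integer(kMin); kMax <- as.integer(kMax)
  if (kMin < 2L) stop("kMin must be >= 2")
  if (kMax <= kMin) stop("kMax must exceed kMin")
  if (kMax >= n) {
    warning("kMax clipped from ", kMax, " to ", n - 1L)
    kMax <- n - 1L
  }
  gc <- .centroid(X, metric)
  totSq <- sum(.distToCenters(X, matrix(gc, nrow = 1L), metric)^2)
  ks <- kMin:kMax
  ve <- vapply(ks, function(k) {
    a <- .clusterDispatch(f, k, algorithm, metric, seed, nRestarts)
    ws <- .withinSums(X, clusterLabels(a), metric)
    100 * (1 - ws$sumSq / totSq)
  }, numeric(1))
  # elbow = point of maximal vertical distance above the chord from the
  # analytic anchor (K = 1 explains 0%) to (kMax, ve[kMax]); an integral
  # curvature measure that is far less noise-sensitive than a pointwise
  # second difference
  x <- c(1L, ks); y <- c(0, ve)
  chord <- y[1] + (y[length(y)] - y[1]) * (x - x[1]) / (x[length(x)] - x[1])
  dev <- (y - chord)[-1L]
  kElbow <- ks[which.max(dev)]
  list(kElbow = as.integer(kElbow),
       curve = data.frame(k = ks, varianceExplained = ve))
}

#' Davies-Bouldin index of a clustering
#'
#' DBI = mean over clusters of D_i, where D_i = max_{j != i} R_ij and
#' R_ij = (d_i + d_j) / d_ij; d_i is the mean distance of cluster-i
#' members to their centroid and d_ij the centroid-centroid distance.
#' Lower is better.
#'
#' @param f a [FeatureTable-class].
#' @param a a [ClusterAssignment-class] on the same features.
#' @param metric distance metric (defaults to the assignment's own).
#' @return non-negative scalar.
#' @export
daviesBouldin <- function(f, a, metric = a@metric) {
  stopifnot(is(f, "FeatureTable"), is(a, "ClusterAssignment"))
  metric <- .checkMetric(metric)
  X <- featureMatrix(f)
  labels <- clusterLabels(a)
  ids <- sort(unique(labels))
  if (length(ids) < 2L) stop("need >= 2 non-empty clusters")
  C <- .centroidsFromLabels(X, labels, metric)
  di <- vapply(seq_along(ids), function(g) {
    mem <- labels == ids[g]
    mean(.distToCentersExact(X[mem, , drop = FALSE],
                             C[g, , drop = FALSE], metric))
  }, numeric(1))
  dij <- .distToCentersExact(C, C, metric)
  offDiag <- dij[upper.tri(dij)]
  if (any(offDiag == 0)) {
    stop("identical centroids (zero separation) between clusters; ",
         "DBI undefined")
  }
  R <- outer(di, di, "+") / dij
  diag(R) <- -Inf
  mean(apply(R, 1L, max))
}

#' Silhouette index of a clustering
#'
#' Per point j: a_j is the mean distance to the other members of its
#' cluster, b_j the smallest mean distance to the members of another
#' cluster, and s_j = (b_j - a_j) / max(a_j, b_j). Singleton clusters get
#' s_j = 0. The index is the mean over clusters of the per-cluster mean
#' silhouette (range [-1, 1], higher is better).
#'
#' @inheritParams daviesBouldin
#' @return list with \code{si} (scalar) and \code{perPoint} (numeric
#'   vector of s_j in bin order).
#' @export
silhouetteIndex <- function(f, a, metric = a@metric) {
  stopifnot(is(f, "FeatureTable"), is(a, "ClusterAssignment"))
  metric <- .checkMetric(metric)
  X <- featureMatrix(f)
  labels <- clusterLabels(a)
  ids <- sort(unique(labels))
  if (length(ids) < 2L) stop("need >= 2 clusters for a silhouette")
  D <- .pairwiseDist(X, metric)
  n <- nrow(X)
  s <- numeric(n)
  for (j in seq_len(n)) {
    own <- labels == labels[j]
    if (sum(own) == 1L) { s[j] <- 0; next }
    aj <- mean(D[j, own & seq_len(n) != j])
    bj <- min(vapply(ids[ids != labels[j]],
                     function(g) mean(D[j, labels == g]), numeric(1)))
    s[j] <- if (max(aj, bj) == 0) 0 else (bj - aj) / max(aj, bj)
  }
  si <- mean(vapply(ids, function(g) mean(s[labels == g]), numeric(1)))
  list(si = si, perPoint = s)
}
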