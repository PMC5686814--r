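#' Specification of a planted block matrix
#'
#' Describes a synthetic contact matrix with planted domains: bins in
#' the same domain interact around \code{intraMean}, all other pairs
#' around \code{interMean}, optionally modulated by a power-law distance
#' decay and truncated Gaussian (or Poisson) noise. The defaults
#' (intraMean 10, interMean 2, noiseSd 1) give a contrast typical of
#' normalized Hi-C blocks and are the conditions used throughout the
#' package's validation.
#'
#' @param nBins number of bins N.
#' @param domains list of inclusive 0-based bin ranges \code{c(start,
#'   end)}, non-overlapping and sorted.
#' @param intraMean mean within-domain contact (default 10).
#' @param interMean mean between-domain contact (default 2, must be
#'   below intraMean).
#' @param noiseSd Gaussian noise standard deviation (default 1).
#' @param gapBins 0-based indices of bins zeroed to emulate unmappable
#'   regions.
#' @param distanceDecay exponent d of the (1 + |i - j|)^(-d) decay
#'   (default 0: none).
#' @param seed integer seed.
#' @param noiseModel "gaussian" (truncated at 0) or "poisson" (count
#'   realism; noiseSd ignored).
#' @param resolution optional bin width in bp (NA: unitless).
#' @param chrom chromosome label.
#' @return a list of class "PlantedSpec".
#' @export
plantedSpec <- function(nBins, domains, intraMean = 10, interMean = 2,
                        noiseSd = 1, gapBins = integer(0),
                        distanceDecay = 0, seed = 1L,
                        noiseModel = c("gaussian", "poisson"),
                        resolution = NA, chrom = "chrU") {
  noiseModel <- match.arg(noiseModel)
  nBins <- as.integer(nBins)
  domains <- lapply(domains, function(d) as.integer(d[1:2]))
  starts <- vapply(domains, `[`, integer(1), 1L)
  ends <- vapply(domains, `[`, integer(1), 2L)
  if (any(starts > ends)) stop("domain start exceeds end")
  ord <- order(starts)
  if (length(domains) > 1L &&
      any(starts[ord][-1] <= ends[ord][-length(ord)])) {
    stop("overlapping planted domains")
  }
  if (any(starts < 0L) || any(ends >= nBins)) {
    stop("domain outside [0, nBins - 1]")
  }
  if (interMean >= intraMean) stop("intraMean must exceed interMean")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (distanceDecay < 0) stop("distanceDecay must be non-negative")
  structure(list(nBins = nBins, domains = domains[ord],
                 intraMean = intraMean, interMean = interMean,
                 noiseSd = noiseSd, gapBins = as.integer(gapBins),
                 distanceDecay = distanceDecay, seed = as.integer(seed),
                 noiseModel = noiseModel, resolution = resolution,
                 chrom = chrom),
            class = "PlantedSpec")
}

# truth TadSet from a bin->domain membership vector (0 = background,
# NA = gap); planted domains are TADs regardless of size
.truthTadSet <- function(m, domVec) {
  seg <- segmentsFromLabels(ifelse(is.na(domVec), NA_integer_,
                                   as.integer(domVec)), length(domVec))
  seg$class <- ifelse(is.na(seg$label), "GAP",
                      ifelse(seg$label >= 1L, "TAD", "BOUNDARY"))
  .tadSetFromSegments(m, seg, extractionConfig())
}

.domainMembership <- function(nBins, domains, gapBins) {
  domVec <- rep(0L, nBins)
  for (d in seq_along(domains)) {
    domVec[(domains[[d]][1]:domains[[d]][2]) + 1L] <- d
  }
  if (length(gapBins)) domVec[gapBins + 1L] <- NA_integer_
  domVec
}

#' Generate a block-structured contact matrix with planted domains
#'
#' Deterministic given the spec's seed. The returned truth TadSet holds
#' the planted domains (as TAD segments, inter-domain bins as
#' boundaries, gap bins as gaps) with their realized quality scores.
#'
#' @param spec a [plantedSpec()].
#' @return list with \code{matrix} (a [ContactMatrix-class]) and
#'   \code{truth} (a [TadSet-class]).
#' @examples
#' sp <- plantedSpec(10, list(c(0, 4), c(5, 9)), noiseSd = 0)
#' gen <- generateBlockMatrix(sp)
#' tadTable(gen$truth)
#' @export
generateBlockMatrix <- function(spec) {
  stopifnot(inherits(spec, "PlantedSpec"))
  n <- spec$nBins
  domVec <- .domainMembership(n, spec$domains, spec$gapBins)
  same <- outer(domVec, domVec,
                function(a, b) !is.na(a) & !is.na(b) & a == b & a >= 1L)
  base <- ifelse(same, spec$intraMean, spec$interMean)
  if (spec$distanceDecay > 0) {
    idx <- seq_len(n)
    base <- base * (1 + abs(outer(idx, idx, "-")))^(-spec$distanceDecay)
  }
  set.seed(spec$seed)
  if (spec$noiseModel == "poisson") {
    up <- matrix(0, n, n)
    up[upper.tri(up, diag = TRUE)] <-
      rpois(n * (n + 1) / 2, base[upper.tri(base, diag = TRUE)])
    v <- up + t(up) - diag(diag(up))
  } else {
    noise <- matrix(0, n, n)
    noise[upper.tri(noise, diag = TRUE)] <-
      rnorm(n * (n + 1) / 2, 0, spec$noiseSd)
    noise <- noise + t(noise) - diag(diag(noise))
    v <- pmax(base + noise, 0)
  }
  if (length(spec$gapBins)) {
    v[spec$gapBins + 1L, ] <- 0
    v[, spec$gapBins + 1L] <- 0
  }
  m <- ContactMatrix(v, resolution = spec$resolution, chrom = spec$chrom)
  list(matrix = m, truth = .truthTadSet(m, domVec))
}

#' Generate a nested (two-level) block matrix
#'
#' Outer domains contain sub-domains; contacts within a sub-domain are
#' strongest, within an outer domain intermediate, and background
#' weakest, so a first clustering pass resolves the outer domains and
#' re-clustering resolves the sub-domains.
#'
#' @param nBins number of bins.
#' @param outerDomains list of inclusive 0-based ranges.
#' @param subDomains list of inclusive 0-based ranges, each nested in
#'   some outer domain.
#' @param subMean,outerMean,interMean three-level contact means
#'   (sub > outer > background).
#' @param noiseSd Gaussian noise sd.
#' @param gapBins 0-based gap bin indices.
#' @param seed integer seed.
#' @param resolution optional bin width in bp.
#' @param chrom chromosome label.
#' @return list with \code{matrix}, \code{truthOuter} and
#'   \code{truthSub} ([TadSet-class] per level).
#' @export
generateNestedMatrix <- function(nBins, outerDomains, subDomains,
                                 subMean = 14, outerMean = 8,
                                 interMean = 2, noiseSd = 1,
                                 gapBins = integer(0), seed = 1L,
                                 resolution = NA, chrom = "chrU") {
  if (!(subMean > outerMean && outerMean > interMean)) {
    stop("means must satisfy subMean > outerMean > interMean")
  }
  n <- as.integer(nBins)
  outerVec <- .domainMembership(n, lapply(outerDomains, as.integer),
                                gapBins)
  subVec <- .domainMembership(n, lapply(subDomains, as.integer), gapBins)
  inSub <- which(subVec >= 1L)
  if (any(is.na(outerVec[inSub]) | outerVec[inSub] == 0L)) {
    stop("every sub-domain must be nested inside an outer domain")
  }
  sameOuter <- outer(outerVec, outerVec,
                     function(a, b) !is.na(a) & !is.na(b) & a == b & a >= 1L)
  sameSub <- outer(subVec, subVec,
                   function(a, b) !is.na(a) & !is.na(b) & a == b & a >= 1L)
  base <- matrix(interMean, n, n)
  base[sameOuter] <- outerMean
  base[sameSub] <- subMean
  set.seed(as.integer(seed))
  noise <- matrix(0, n, n)
  noise[upper.tri(noise, diag = TRUE)] <- rnorm(n * (n + 1) / 2, 0, noiseSd)
  noise <- noise + t(noise) - diag(diag(noise))
  v <- pmax(base + noise, 0)
  if (length(gapBins)) {
    v[gapBins + 1L, ] <- 0
    v[, gapBins + 1L] <- 0
  }
  m <- ContactMatrix(v, resolution = resolution, chrom = chrom)
  list(matrix = m,
       truthOuter = .truthTadSet(m, outerVec),
       truthSub = .truthTadSet(m, subVec))
}

#' Generate peaks concentrated at planted TAD borders
#'
#' Places \code{peaksPerBoundary} short peaks inside every border bin
#' (each TAD's start and end bin) and a Poisson background of
#' \code{backgroundRate} peaks per non-border bin. Deterministic given
#' the seed.
#'
#' @param truth a [TadSet-class] with at least one TAD.
#' @param resolution bin width in bp.
#' @param peaksPerBoundary peaks planted per border bin (default 2).
#' @param backgroundRate Poisson mean of background peaks per non-border
#'   bin (default 0).
#' @param seed integer seed.
#' @param peakWidth width of each peak in bp (default resolution / 10,
#'   at least 2).
#' @return a sorted GRanges of peaks.
#' @export
generateBoundaryPeaks <- function(truth, resolution, peaksPerBoundary = 2L,
                                  backgroundRate = 0, seed = 1L,
                                  peakWidth = NULL) {
  stopifnot(is(truth, "TadSet"))
  resolution <- as.integer(resolution)
  if (is.null(peakWidth)) peakWidth <- max(2L, resolution %/% 10L)
  tb <- tadTable(truth)
  if (!nrow(tb)) stop("truth TadSet has no TADs")
  borders <- sort(unique(c(tb$startBin, tb$endBin)))
  seg <- tadSegments(truth)
  allBins <- 0:(max(seg$endBin))
  others <- setdiff(allBins, borders)
  set.seed(as.integer(seed))
  placePeaks <- function(bin, count) {
    if (count == 0L) return(NULL)
    # uniform placement with the whole peak (hence its midpoint) in-bin
    start0 <- bin * resolution +
      floor(runif(count, 0, resolution - peakWidth))
    data.frame(start0 = start0, end0 = start0 + peakWidth)
  }
  rows <- c(lapply(borders, placePeaks, count = as.integer(peaksPerBoundary)),
            lapply(others, function(b) placePeaks(b, rpois(1, backgroundRate))))
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    seqnames = chromName(truth),
    ranges = IRanges::IRanges(start = rows$start0 + 1, end = rows$end0))
  GenomicRanges::sort(gr)
}
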