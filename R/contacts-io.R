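#' Read a dense whitespace-delimited contact matrix
#'
#' Expects N rows of N whitespace-separated numbers. Small asymmetries
#' (max |M[i,j] - M[j,i]| <= 1e-6 * max(M)) are averaged away; larger ones
#' are an error, as are negative or non-finite entries.
#'
#' @param path path to the text file.
#' @param resolution bin width in bp (NA for unitless matrices).
#' @param chrom chromosome label.
#' @return A [ContactMatrix-class].
#' @export
readDenseMatrix <- function(path, resolution = NA, chrom = "chrU") {
  if (!file.exists(path)) stop("no such file: ", path)
  rows <- readLines(path)
  rows <- rows[nzchar(trimws(rows))]
  if (!length(rows)) stop("empty matrix file: ", path)
  parsed <- lapply(strsplit(trimws(rows), "[ \t]+"), function(x) {
    suppressWarnings(as.numeric(x))
  })
  lens <- lengths(parsed)
  if (length(unique(lens)) != 1L || lens[1] != length(parsed)) {
    stop("matrix file is not square: ", length(parsed), " rows, widths ",
         paste(unique(lens), collapse = "/"))
  }
  m <- do.call(rbind, parsed)
  if (any(is.na(m))) stop("non-numeric or NaN entry in matrix file")
  if (any(is.infinite(m))) stop("infinite entry in matrix file")
  if (any(m < 0)) stop("negative entry in matrix file")
  ContactMatrix(m, resolution = resolution, chrom = chrom)
}

#' Read a sparse 3-column contact list
#'
#' Each row is \code{i j count} with 0-based bin indices. Unlisted cells
#' are zero and each listed \code{(i, j)} implies \code{(j, i)}.
#'
#' @param path path to the text file.
#' @param nBins number of bins N of the full matrix.
#' @inheritParams readDenseMatrix
#' @return A [ContactMatrix-class].
#' @export
readSparseTriples <- function(path, nBins, resolution = NA, chrom = "chrU") {
  if (!file.exists(path)) stop("no such file: ", path)
  nBins <- as.integer(nBins)
  m <- matrix(0, nBins, nBins)
  info <- file.info(path)
  txt <- readLines(path)
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt)) {
    tab <- read.table(text = txt, header = FALSE)
    if (ncol(tab) < 3L) stop("sparse file needs 3 columns (i j count)")
    i <- as.integer(tab[[1]]); j <- as.integer(tab[[2]])
    x <- as.numeric(tab[[3]])
    if (any(is.na(i) | is.na(j) | is.na(x))) {
      stop("non-numeric entry in sparse file")
    }
    if (any(i < 0 | j < 0 | i >= nBins | j >= nBins)) {
      stop("bin index out of range [0, ", nBins - 1L, "]")
    }
    if (anyDuplicated(paste(i, j))) stop("duplicate (i, j) rows")
    if (any(x < 0)) stop("negative contact count")
    m[cbind(i + 1L, j + 1L)] <- x
    m[cbind(j + 1L, i + 1L)] <- x
  }
  ContactMatrix(m, resolution = resolution, chrom = chrom)
}

#' Write a dense contact matrix as whitespace-delimited text
#'
#' @param m a [ContactMatrix-class].
#' @param path output path.
#' @export
writeDenseMatrix <- function(m, path) {
  stopifnot(is(m, "ContactMatrix"))
  write.table(format(contactValues(m), digits = 15, trim = TRUE,
                     scientific = FALSE),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.bedLines <- function(seg, chrom, resolution, name) {
  sprintf("%s\t%d\t%d\t%s", chrom,
          seg$startBin * resolution, (seg$endBin + 1L) * resolution, name)
}

#' Write a TadSet as BED tracks
#'
#' TAD segments go to \code{path} as BED4 (0-based half-open bp,
#' name "TAD"). Boundary and gap segments are written to companion files
#' \code{<path>.boundaries.bed} and \code{<path>.gaps.bed}.
#'
#' @param tads a [TadSet-class].
#' @param path output BED path for the TAD track.
#' @param resolution bin width in bp; defaults to the TadSet's own.
#' @return invisibly, the paths written.
#' @export
writeTadsBed <- function(tads, path, resolution = resolutionBp(tads)) {
  stopifnot(is(tads, "TadSet"))
  if (is.na(resolution)) {
    stop("resolution is required to write BED output for a unitless TadSet")
  }
  resolution <- as.integer(resolution)
  seg <- tadSegments(tads)
  chrom <- chromName(tads)
  paths <- c(TAD = path,
             BOUNDARY = paste0(path, ".boundaries.bed"),
             GAP = paste0(path, ".gaps.bed"))
  for (cls in names(paths)) {
    sub <- seg[seg$class == cls, , drop = FALSE]
    hdr <- paste0("# ", tolower(cls), " segments (", chrom, ", ",
                  resolution, " bp bins)")
    lines <- if (nrow(sub)) .bedLines(sub, chrom, resolution, cls) else
      character(0)
    writeLines(c(hdr, lines), paths[[cls]])
  }
  invisible(paths)
}

#' Read TAD intervals from a BED file into a TadSet
#'
#' Reconstructs a bin-level TadSet from BED intervals (0-based half-open
#' bp) at a known resolution; bins not covered by any interval become
#' boundary segments. Used by the comparison tools to consume annotations
#' produced by other callers.
#'
#' @param path BED file with at least chrom/start/end columns.
#' @param resolution bin width in bp.
#' @param nBins total bins of the chromosome; defaults to the last
#'   interval's end bin + 1.
#' @return A [TadSet-class] with class TAD for listed intervals.
#' @export
readTadsBed <- function(path, resolution, nBins = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  resolution <- as.integer(resolution)
  txt <- readLines(path)
  txt <- txt[nzchar(trimws(txt)) & !startsWith(trimws(txt), "#") &
             !startsWith(trimws(txt), "track")]
  if (!length(txt)) {
    seg <- data.frame(startBin = integer(0), endBin = integer(0),
                      label = integer(0), class = character(0))
    return(new("TadSet", segments = seg, tadQualities = numeric(0),
               overallQuality = -Inf, resolution = resolution))
  }
  tab <- read.table(text = txt, header = FALSE)
  if (ncol(tab) < 3L) stop("BED file needs >= 3 columns")
  start <- as.numeric(tab[[2]]); end <- as.numeric(tab[[3]])
  if (any(start >= end)) stop("BED interval with start >= end")
  startBin <- as.integer(start %/% resolution)
  endBin <- as.integer((end - 1) %/% resolution)
  ord <- order(startBin)
  startBin <- startBin[ord]; endBin <- endBin[ord]
  if (any(startBin[-1] <= endBin[-length(endBin)])) {
    stop("overlapping TAD intervals in BED input")
  }
  if (is.null(nBins)) nBins <- endBin[length(endBin)] + 1L
  chrom <- as.character(tab[[1]][ord[1]])
  # tile: gaps between listed TADs become boundary segments
  seg <- list(); cursor <- 0L
  for (t in seq_along(startBin)) {
    if (startBin[t] > cursor) {
      seg[[length(seg) + 1L]] <- data.frame(
        startBin = cursor, endBin = startBin[t] - 1L,
        label = NA_integer_, class = "BOUNDARY")
    }
    seg[[length(seg) + 1L]] <- data.frame(
      startBin = startBin[t], endBin = endBin[t],
      label = t, class = "TAD")
    cursor <- endBin[t] + 1L
  }
  if (cursor < nBins) {
    seg[[length(seg) + 1L]] <- data.frame(
      startBin = cursor, endBin = as.integer(nBins) - 1L,
      label = NA_integer_, class = "BOUNDARY")
  }
  seg <- do.call(rbind, seg)
  nTad <- sum(seg$class == "TAD")
  new("TadSet", segments = seg, tadQualities = rep(NA_real_, nTad),
      overallQuality = NA_real_, chrom = chrom, resolution = resolution)
}

#' Read ChIP-seq peaks from a BED file
#'
#' At least three columns (chrom, start, end; 0-based half-open) are
#' required; extra columns are ignored. Peaks are returned sorted.
#'
#' @param path BED file path.
#' @return A sorted [GenomicRanges::GRanges] of peak intervals.
#' @export
readPeaksBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path)
  txt <- txt[nzchar(trimws(txt)) & !startsWith(trimws(txt), "#") &
             !startsWith(trimws(txt), "track")]
  if (!length(txt)) {
    return(GenomicRanges::GRanges())
  }
  tab <- read.table(text = txt, header = FALSE)
  if (ncol(tab) < 3L) stop("peak BED needs >= 3 columns")
  start <- as.numeric(tab[[2]]); end <- as.numeric(tab[[3]])
  if (any(start >= end)) {
    stop("peak with start >= end (BED is 0-based half-open)")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(tab[[1]]),
    ranges = IRanges::IRanges(start = start + 1, end = end))
  GenomicRanges::sort(gr)
}

#' Write peaks as BED
#'
#' @param peaks a GRanges of peaks.
#' @param path output path.
#' @export
writePeaksBed <- function(peaks, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,
                   end = GenomicRanges::end(peaks))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
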