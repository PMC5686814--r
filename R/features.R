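#' Build per-bin contact-profile features
#'
#' Each bin i on the matrix diagonal is represented by the concatenation
#' of row i and column i of the contact matrix: a 2N-vector describing the
#' bin's complete interaction profile. For a symmetric matrix the two
#' halves coincide; the 2N form is kept because it is the representation
#' the clustering operates on for a general contact (i, j). Bins whose
#' entire row is zero carry no information and are excluded as gaps.
#'
#' @param m a [ContactMatrix-class].
#' @param logTransform apply log1p to the matrix values before building
#'   features (default off; raw counts are used).
#' @return A [FeatureTable-class] with one row per non-gap bin.
#' @examples
#' m <- ContactMatrix(matrix(c(1, 2, 2, 3), 2))
#' featureMatrix(buildDiagonalFeatures(m))
#' @export
buildDiagonalFeatures <- function(m, logTransform = FALSE) {
  stopifnot(is(m, "ContactMatrix"))
  v <- contactValues(m)
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 bins to build features")
  if (logTransform) v <- log1p(v)
  gap <- which(rowSums(v != 0) == 0L) - 1L   # 0-based
  keep <- setdiff(seq_len(n) - 1L, gap)
  feats <- cbind(v[keep + 1L, , drop = FALSE],
                 t(v[, keep + 1L, drop = FALSE]))
  dimnames(feats) <- NULL
  new("FeatureTable",
      features = feats,
      binIndex = as.integer(keep),
      excludedBins = as.integer(gap),
      nBins = n)
}
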