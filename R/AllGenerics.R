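#' Accessors for TADclust classes
#'
#' @param x a TADclust object.
#' @name accessors
NULL

#' @describeIn accessors numeric matrix of contact values.
#' @export
setGeneric("contactValues", function(x) standardGeneric("contactValues"))

#' @describeIn accessors number of bins N.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @describeIn accessors bin resolution in bp (NA when unitless).
#' @export
setGeneric("resolutionBp", function(x) standardGeneric("resolutionBp"))

#' @describeIn accessors chromosome label.
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @describeIn accessors feature matrix (one row per non-gap bin).
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @describeIn accessors 0-based gap bin indices excluded from clustering.
#' @export
setGeneric("excludedBins", function(x) standardGeneric("excludedBins"))

#' @describeIn accessors 0-based bin index per feature row / label.
#' @export
setGeneric("binIndex", function(x) standardGeneric("binIndex"))

#' @describeIn accessors integer cluster labels.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @describeIn accessors segment table (all classes) of a TadSet.
#' @export
setGeneric("tadSegments", function(x) standardGeneric("tadSegments"))

#' @describeIn accessors TAD-only segment table with quality column.
#' @export
setGeneric("tadTable", function(x) standardGeneric("tadTable"))

#' @describeIn accessors per-TAD quality scores.
#' @export
setGeneric("tadQualities", function(x) standardGeneric("tadQualities"))

#' @describeIn accessors overall (mean) TAD quality of a set.
#' @export
setGeneric("overallQuality", function(x) standardGeneric("overallQuality"))

setMethod("contactValues", "ContactMatrix", function(x) x@values)
setMethod("nBins", "ContactMatrix", function(x) nrow(x@values))
setMethod("resolutionBp", "ContactMatrix", function(x) x@resolution)
setMethod("chromName", "ContactMatrix", function(x) x@chrom)

setMethod("featureMatrix", "FeatureTable", function(x) x@features)
setMethod("excludedBins", "FeatureTable", function(x) x@excludedBins)
setMethod("binIndex", "FeatureTable", function(x) x@binIndex)
setMethod("nBins", "FeatureTable", function(x) x@nBins)

setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)
setMethod("binIndex", "ClusterAssignment", function(x) x@binIndex)

setMethod("tadSegments", "TadSet", function(x) x@segments)
setMethod("tadQualities", "TadSet", function(x) x@tadQualities)
setMethod("overallQuality", "TadSet", function(x) x@overallQuality)
setMethod("resolutionBp", "TadSet", function(x) x@resolution)
setMethod("chromName", "TadSet", function(x) x@chrom)
setMethod("tadTable", "TadSet", function(x) {
  tad <- x@segments[x@segments$class == "TAD", , drop = FALSE]
  tad$quality <- x@tadQualities
  rownames(tad) <- NULL
  tad
})

setMethod("show", "ContactMatrix", function(object) {
  n <- nrow(object@values)
  cat("ContactMatrix:", object@chrom, "-", n, "x", n, "bins")
  if (!is.na(object@resolution)) {
    cat(" @", object@resolution, "bp")
  } else {
    cat(" (unitless)")
  }
  cat("\n  total contacts:", format(sum(object@values)),
      " zero rows:", sum(rowSums(object@values) == 0), "\n")
})

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object@features), "bins x",
      ncol(object@features), "features;",
      length(object@excludedBins), "gap bin(s) excluded\n")
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment:", object@algorithm,
      if (object@algorithm != "EM") paste0("(", object@metric, ")") else "",
      "k =", object@k, "->", length(unique(object@labels)),
      "non-empty cluster(s) over", length(object@labels), "bins\n")
})

setMethod("show", "TadSet", function(object) {
  seg <- object@segments
  cat("TadSet:", object@chrom, "-",
      sum(seg$class == "TAD"), "TADs,",
      sum(seg$class == "BOUNDARY"), "boundaries,",
      sum(seg$class == "GAP"), "gaps",
      "(k =", object@kUsed, ")\n")
  if (length(object@tadQualities)) {
    cat("  overall quality:", format(object@overallQuality, digits = 4),
        "\n")
  } else {
    cat("  no TADs called\n")
  }
})
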