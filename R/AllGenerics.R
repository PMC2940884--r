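#' @include AllClasses.R
NULL

#' Rescale a peak table to its base peak
#'
#' Divides every intensity by the largest intensity in the table, so the base
#' peak has relative intensity exactly 1. Peak order, identifiers and
#' coordinates are untouched, and all pairwise intensity ratios are
#' preserved (the operation is idempotent).
#'
#' @param table a [PeakTable-class] (or [ChemicalFingerprint-class]).
#' @return An object of the same class with relative intensities.
#' @examples
#' pt <- peakTable(data.frame(featureId = c("a", "b", "c"),
#'                            mz = c(100, 200, 300), rt = c(1, 2, 3),
#'                            intensity = c(50, 25, 5)))
#' intensities(normalizeToBasePeak(pt))   # 1.0 0.5 0.1
#' @export
setGeneric("normalizeToBasePeak",
           function(table) standardGeneric("normalizeToBasePeak"))

#' @rdname ticCoverage
#' @export
setGeneric("ticCoverage",
           function(table, fingerprint, threshold = 0.015)
               standardGeneric("ticCoverage"))

#' @rdname matchFeatures
#' @export
setGeneric("matchFeatures",
           function(fpA, fpB, mzTol = 0.01, rtTol = 0.5,
                    by = c("auto", "id", "tolerance"))
               standardGeneric("matchFeatures"))

#' @rdname psi
#' @export
setGeneric("psi",
           function(pair, method = c("pearson", "spearman"),
                    weighted = FALSE, ...) standardGeneric("psi"))

#' @rdname conventionalR
#' @export
setGeneric("conventionalR",
           function(pair, method = c("pearson", "spearman"))
               standardGeneric("conventionalR"))

#' @rdname outlierFeatures
#' @export
setGeneric("outlierFeatures",
           function(result, lowRThreshold = 0.9, bins = 40L)
               standardGeneric("outlierFeatures"))

#' @rdname panelSimilarity
#' @export
setGeneric("panelSimilarity",
           function(a, b, method = c("pearson", "spearman"),
                    weighted = FALSE) standardGeneric("panelSimilarity"))

## ---- accessors --------------------------------------------------------------

#' Accessors for phytopsi objects
#'
#' Small, read-only views of the S4 containers: `peaks()` returns the peak
#' `data.frame` of a table or fingerprint, `intensities()` its intensity
#' vector (named by feature), `nPeaks()`/`nFeatures()` the number of
#' features, `batchId()` the batch label, `featureKeys()` the shared keys of
#' a matched pair or result, `perFeatureR()` and `featureWeights()` the
#' per-feature correlation scores and slope weights of a
#' [SimilarityResult-class].
#'
#' @param x a phytopsi object.
#' @return The corresponding slot value (see details above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))

#' @rdname accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname accessors
#' @export
setGeneric("batchId", function(x) standardGeneric("batchId"))

#' @rdname accessors
#' @export
setGeneric("featureKeys", function(x) standardGeneric("featureKeys"))

#' @rdname accessors
#' @export
setGeneric("perFeatureR", function(x) standardGeneric("perFeatureR"))

#' @rdname accessors
#' @export
setGeneric("featureWeights", function(x) standardGeneric("featureWeights"))

#' @rdname accessors
#' @export
setMethod("peaks", "PeakTable", function(x) x@peaks)

#' @rdname accessors
#' @export
setMethod("peaks", "ChemicalFingerprint", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("intensities", "PeakTable",
          function(x) stats::setNames(x@peaks$intensity, x@peaks$featureId))

#' @rdname accessors
#' @export
setMethod("intensities", "ChemicalFingerprint",
          function(x) stats::setNames(x@features$intensity,
                                      x@features$featureId))

#' @rdname accessors
#' @export
setMethod("nPeaks", "PeakTable", function(x) nrow(x@peaks))

#' @rdname accessors
#' @export
setMethod("nFeatures", "ChemicalFingerprint", function(x) nrow(x@features))

#' @rdname accessors
#' @export
setMethod("nFeatures", "MatchedPair", function(x) length(x@featureKeys))

#' @rdname accessors
#' @export
setMethod("nFeatures", "SimilarityResult", function(x) x@nFeatures)

#' @rdname accessors
#' @export
setMethod("nFeatures", "BioresponsePanel", function(x) length(x@genes))

#' @rdname accessors
#' @export
setMethod("batchId", "PeakTable", function(x) x@batchId)

#' @rdname accessors
#' @export
setMethod("batchId", "ChemicalFingerprint", function(x) x@batchId)

#' @rdname accessors
#' @export
setMethod("batchId", "BioresponsePanel", function(x) x@batchId)

#' @rdname accessors
#' @export
setMethod("batchId", "GeneReplicateSet", function(x) x@batchId)

#' @rdname accessors
#' @export
setMethod("featureKeys", "MatchedPair", function(x) x@featureKeys)

#' @rdname accessors
#' @export
setMethod("featureKeys", "SimilarityResult", function(x) x@featureKeys)

#' @rdname accessors
#' @export
setMethod("featureKeys", "RatioMatrix", function(x) x@featureKeys)

#' @rdname accessors
#' @export
setMethod("perFeatureR", "SimilarityResult", function(x) x@perFeatureR)

#' @rdname accessors
#' @export
setMethod("featureWeights", "SimilarityResult", function(x) x@weights)

## ---- show methods -----------------------------------------------------------

setMethod("show", "PeakTable", function(object) {
    cat(sprintf("PeakTable: batch %s, replicate %s, %d peaks (%s mode)\n",
                object@batchId, object@replicateId, nrow(object@peaks),
                object@ionMode))
    if (nrow(object@peaks))
        print(utils::head(object@peaks, 5L), row.names = FALSE)
    if (nrow(object@peaks) > 5L)
        cat(sprintf("... %d more peaks\n", nrow(object@peaks) - 5L))
})

setMethod("show", "ChemicalFingerprint", function(object) {
    cat(sprintf("ChemicalFingerprint: batch %s, %d QC peaks\n",
                object@batchId, nrow(object@features)))
    if (length(object@selectionParams))
        cat("  selection:",
            paste(names(object@selectionParams), unlist(object@selectionParams),
                  sep = "=", collapse = ", "), "\n")
})

setMethod("show", "MatchedPair", function(object) {
    cat(sprintf("MatchedPair: %d shared features (%s)\n",
                length(object@featureKeys), object@provenance))
})

setMethod("show", "SimilarityResult", function(object) {
    cat(sprintf(
        "SimilarityResult: PSI = %.4f (%s%s, N = %d), conventional R = %.4f\n",
        object@psi, object@method,
        if (object@weighted) ", slope-weighted" else ", unweighted",
        object@nFeatures, object@conventionalR))
    cat(sprintf("  per-feature R: min %.4f / median %.4f / max %.4f\n",
                min(object@perFeatureR), stats::median(object@perFeatureR),
                max(object@perFeatureR)))
})

setMethod("show", "BioresponsePanel", function(object) {
    cat(sprintf("BioresponsePanel: batch %s, %d signature genes\n",
                object@batchId, length(object@genes)))
})

setMethod("show", "GeneReplicateSet", function(object) {
    cat(sprintf("GeneReplicateSet: batch %s, %d replicate(s) [%s genes]\n",
                object@batchId, length(object@replicates),
                paste(vapply(object@replicates, nrow, 0L), collapse = ", ")))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: %d features, seed %d, %s intensities, %s noise (cv %.3g)\n",
        object@nFeatures, object@seed, object@intensityLaw,
        object@noiseModel, object@noiseCv))
})

setMethod("show", "ComparisonReport", function(object) {
    cat(sprintf("ComparisonReport: reference %s, %d compared batch(es)\n",
                object@referenceBatch, nrow(object@rows)))
    print(object@rows, row.names = FALSE)
})
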