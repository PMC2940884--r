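#' @import methods
NULL

## ---- internal validators for peak data.frames -------------------------------

.validPeakFrame <- function(df, requirePositive = FALSE) {
    msgs <- character()
    needed <- c("featureId", "mz", "rt", "intensity")
    missing <- setdiff(needed, colnames(df))
    if (length(missing))
        return(sprintf("missing peak column(s): %s",
                       paste(missing, collapse = ", ")))
    if (anyDuplicated(df$featureId))
        msgs <- c(msgs, "duplicate featureId values")
    if (nrow(df)) {
        if (!is.numeric(df$mz) || any(!is.finite(df$mz)) || any(df$mz <= 0))
            msgs <- c(msgs, "mz must be finite and > 0")
        if (!is.numeric(df$rt) || any(!is.finite(df$rt)) || any(df$rt < 0))
            msgs <- c(msgs, "rt must be finite and >= 0")
        if (!is.numeric(df$intensity) || any(!is.finite(df$intensity)))
            msgs <- c(msgs, "intensity must be finite")
        else if (requirePositive && any(df$intensity <= 0))
            msgs <- c(msgs, "all intensities must be > 0")
        else if (!requirePositive && any(df$intensity < 0))
            msgs <- c(msgs, "intensity must be >= 0")
    }
    if (length(msgs)) msgs else TRUE
}

.emptyPeakFrame <- function() {
    data.frame(featureId = character(), mz = numeric(), rt = numeric(),
               intensity = numeric(), source = character(),
               stringsAsFactors = FALSE)
}

## ---- PeakTable --------------------------------------------------------------

#' PeakTable: one replicate's integrated LC/MS peak list
#'
#' A `PeakTable` holds the already-integrated peaks of a single LC/MS run of
#' one extract batch: for every peak a unique feature identifier, the
#' mass-to-charge ratio in amu, the retention time in minutes, the integrated
#' ion-count intensity, and an optional herb-source label (e.g. one of the
#' four constituent herbs, coded "S", "P", "G", "Z").
#'
#' @slot batchId character(1), the extract batch the run belongs to.
#' @slot replicateId character(1), identifier of the injection/replicate.
#' @slot ionMode one of `"positive"`, `"negative"`, `"none"`.
#' @slot peaks `data.frame` with columns `featureId`, `mz`, `rt`,
#'   `intensity` and optionally `source`.
#'
#' @seealso [peakTable()] for the user-facing constructor,
#'   [normalizeToBasePeak()], [selectFingerprintPeaks()].
#' @exportClass PeakTable
setClass("PeakTable",
    representation(batchId = "character", replicateId = "character",
                   ionMode = "character", peaks = "data.frame"),
    prototype(batchId = NA_character_, replicateId = NA_character_,
              ionMode = "none", peaks = .emptyPeakFrame()))

setValidity("PeakTable", function(object) {
    msgs <- character()
    if (length(object@ionMode) != 1L ||
        !object@ionMode %in% c("positive", "negative", "none"))
        msgs <- c(msgs, "ionMode must be 'positive', 'negative' or 'none'")
    v <- .validPeakFrame(object@peaks)
    if (!isTRUE(v)) msgs <- c(msgs, v)
    if (length(msgs)) msgs else TRUE
})

#' Construct a PeakTable
#'
#' @param peaks data.frame with columns `featureId`, `mz`, `rt`, `intensity`
#'   (optional `source`).
#' @param batchId,replicateId identifiers (default `NA`).
#' @param ionMode `"positive"`, `"negative"` or `"none"`.
#' @return A [PeakTable-class] object.
#' @examples
#' pt <- peakTable(data.frame(featureId = c("f1", "f2", "f3"),
#'                            mz = c(271.06, 447.09, 481.1),
#'                            rt = c(12.5, 25.6, 33.1),
#'                            intensity = c(1200, 800, 150)),
#'                 batchId = "B1", replicateId = "r1")
#' nPeaks(pt)
#' @export
peakTable <- function(peaks, batchId = NA_character_,
                      replicateId = NA_character_, ionMode = "none") {
    peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
    peaks$featureId <- as.character(peaks$featureId)
    if (is.null(peaks$source)) peaks$source <- NA_character_
    new("PeakTable", batchId = as.character(batchId),
        replicateId = as.character(replicateId),
        ionMode = ionMode, peaks = peaks)
}

## ---- ChemicalFingerprint ----------------------------------------------------

#' ChemicalFingerprint: the selected QC peak pattern of a batch
#'
#' The ordered set of quantifiable peaks chosen to characterise one batch
#' (the study system uses a 39-peak pattern). All intensities are strictly
#' positive. Similarity scoring needs at least 3 matched features (enforced
#' at [MatchedPair-class] construction); smaller fingerprints remain valid
#' inputs for coverage computations like [ticCoverage()].
#'
#' @slot batchId character(1).
#' @slot features `data.frame` as in [PeakTable-class], all intensities > 0,
#'   ordered by retention time.
#' @slot selectionParams named list recording the thresholds used to select
#'   the peaks (may be empty for synthetic or imported fingerprints).
#' @exportClass ChemicalFingerprint
setClass("ChemicalFingerprint",
    representation(batchId = "character", features = "data.frame",
                   selectionParams = "list"),
    prototype(batchId = NA_character_, features = .emptyPeakFrame(),
              selectionParams = list()))

setValidity("ChemicalFingerprint", function(object) {
    msgs <- character()
    v <- .validPeakFrame(object@features, requirePositive = TRUE)
    if (!isTRUE(v)) msgs <- c(msgs, v)
    if (nrow(object@features) < 1L)
        msgs <- c(msgs, "a fingerprint needs >= 1 feature")
    if (length(msgs)) msgs else TRUE
})

#' Construct a ChemicalFingerprint
#'
#' @param features data.frame of peaks (strictly positive intensities).
#' @param batchId character(1).
#' @param selectionParams named list of selection thresholds.
#' @return A [ChemicalFingerprint-class].
#' @export
chemicalFingerprint <- function(features, batchId = NA_character_,
                                selectionParams = list()) {
    features <- as.data.frame(features, stringsAsFactors = FALSE)
    features$featureId <- as.character(features$featureId)
    if (is.null(features$source)) features$source <- NA_character_
    new("ChemicalFingerprint", batchId = as.character(batchId),
        features = features, selectionParams = selectionParams)
}

## ---- MatchedPair -------------------------------------------------------------

#' MatchedPair: features common to two batches with paired intensities
#'
#' The input to every similarity statistic: N shared feature identities and
#' the two strictly positive intensity vectors. Unmatched features are never
#' zero-imputed; they are dropped at matching time.
#'
#' @slot featureKeys character vector of N shared feature identities.
#' @slot valuesA,valuesB numeric vectors, length N, strictly positive.
#' @slot provenance character(1) describing how matching was done.
#' @exportClass MatchedPair
setClass("MatchedPair",
    representation(featureKeys = "character", valuesA = "numeric",
                   valuesB = "numeric", provenance = "character"),
    prototype(provenance = "unspecified"))

setValidity("MatchedPair", function(object) {
    msgs <- character()
    n <- length(object@featureKeys)
    if (length(object@valuesA) != n || length(object@valuesB) != n)
        msgs <- c(msgs, "featureKeys, valuesA and valuesB lengths differ")
    if (n < 3L)
        msgs <- c(msgs, "a matched pair needs >= 3 features")
    if (anyDuplicated(object@featureKeys))
        msgs <- c(msgs, "duplicate feature keys")
    if (any(!is.finite(object@valuesA)) || any(object@valuesA <= 0) ||
        any(!is.finite(object@valuesB)) || any(object@valuesB <= 0))
        msgs <- c(msgs, "all paired values must be finite and > 0")
    if (length(msgs)) msgs else TRUE
})

#' Construct a MatchedPair
#'
#' @param featureKeys character vector of shared feature identities.
#' @param valuesA,valuesB positive intensity vectors of the two batches.
#' @param provenance how the pairing was obtained.
#' @return A [MatchedPair-class].
#' @examples
#' mp <- matchedPair(c("a", "b", "c"), c(1, 2, 4), c(2, 4, 8))
#' psi(mp)
#' @export
matchedPair <- function(featureKeys, valuesA, valuesB,
                        provenance = "by explicit vectors") {
    new("MatchedPair", featureKeys = as.character(featureKeys),
        valuesA = as.numeric(valuesA), valuesB = as.numeric(valuesB),
        provenance = provenance)
}

## ---- DilutionSeries ---------------------------------------------------------

#' DilutionSeries: concentration/response pairs for a linearity check
#'
#' @slot concentrations strictly increasing positive values in mg/mL.
#' @slot responses intensities, same length.
#' @exportClass DilutionSeries
setClass("DilutionSeries",
    representation(concentrations = "numeric", responses = "numeric"))

setValidity("DilutionSeries", function(object) {
    msgs <- character()
    if (length(object@concentrations) != length(object@responses))
        msgs <- c(msgs, "concentrations and responses lengths differ")
    if (length(object@concentrations) < 3L)
        msgs <- c(msgs, "a dilution series needs >= 3 points")
    if (any(object@concentrations <= 0))
        msgs <- c(msgs, "concentrations must be > 0")
    if (is.unsorted(object@concentrations, strictly = TRUE))
        msgs <- c(msgs, "concentrations must be strictly increasing")
    if (length(msgs)) msgs else TRUE
})

#' Construct a DilutionSeries
#'
#' @param concentrations strictly increasing positive values (mg/mL).
#' @param responses measured intensities.
#' @return A [DilutionSeries-class].
#' @export
dilutionSeries <- function(concentrations, responses) {
    new("DilutionSeries", concentrations = as.numeric(concentrations),
        responses = as.numeric(responses))
}

## ---- RatioMatrix ------------------------------------------------------------

#' RatioMatrix: pairwise intensity-ratio matrix of a fingerprint
#'
#' The N measured intensities sit on the diagonal; off-diagonal element
#' (i, j) holds the ratio value_i / value_j, so element (i, j) x (j, i) = 1
#' and there are N(N-1)/2 independent ratios. Row i without its diagonal is
#' the feature-i ratio vector used by the PSI per-feature correlations.
#'
#' @slot mat numeric N x N matrix; diagonal = source values, off-diagonal =
#'   ratios.
#' @slot featureKeys optional character vector of feature identities.
#' @exportClass RatioMatrix
setClass("RatioMatrix",
    representation(mat = "matrix", featureKeys = "character"))

setValidity("RatioMatrix", function(object) {
    m <- object@mat
    msgs <- character()
    if (nrow(m) != ncol(m) || nrow(m) < 3L)
        msgs <- c(msgs, "ratio matrix must be square with N >= 3")
    else {
        d <- diag(m)
        if (any(!is.finite(d)) || any(d <= 0))
            msgs <- c(msgs, "diagonal values must be finite and > 0")
        off <- m * t(m)
        diag(off) <- 1
        if (max(abs(off - 1)) > 1e-9)
            msgs <- c(msgs, "reciprocal symmetry violated: M[i,j]*M[j,i] != 1")
    }
    if (length(object@featureKeys) &&
        length(object@featureKeys) != nrow(m))
        msgs <- c(msgs, "featureKeys length must match matrix size")
    if (length(msgs)) msgs else TRUE
})

## ---- SimilarityResult -------------------------------------------------------

#' SimilarityResult: PSI score with per-feature detail
#'
#' Carries the PSI (the average, optionally slope-weighted, of the N
#' per-feature ratio-vector correlations), the per-feature scores, the slope
#' weights, and the conventional correlation R of the raw paired values.
#'
#' @slot psi numeric(1) in [-1, 1].
#' @slot perFeatureR numeric(N), each in [-1, 1].
#' @slot weights numeric(N), non-negative slope weights in [0, 1]
#'   (direction-averaged; see [slopeWeights()]).
#' @slot method `"pearson"` or `"spearman"`.
#' @slot weighted logical(1): whether `psi` is the weight-renormalised mean.
#' @slot conventionalR numeric(1), plain correlation of the value vectors.
#' @slot nFeatures integer(1), N >= 3.
#' @slot featureKeys character(N).
#' @exportClass SimilarityResult
setClass("SimilarityResult",
    representation(psi = "numeric", perFeatureR = "numeric",
                   weights = "numeric", method = "character",
                   weighted = "logical", conventionalR = "numeric",
                   nFeatures = "integer", featureKeys = "character"))

setValidity("SimilarityResult", function(object) {
    msgs <- character()
    n <- object@nFeatures
    if (n < 3L) msgs <- c(msgs, "nFeatures must be >= 3")
    if (length(object@perFeatureR) != n || length(object@weights) != n)
        msgs <- c(msgs, "per-feature vectors must have length nFeatures")
    if (any(abs(object@perFeatureR) > 1 + 1e-9))
        msgs <- c(msgs, "per-feature scores must lie in [-1, 1]")
    if (abs(object@psi) > 1 + 1e-9)
        msgs <- c(msgs, "psi must lie in [-1, 1]")
    if (any(object@weights < 0 | object@weights > 1))
        msgs <- c(msgs, "weights must lie in [0, 1]")
    expected <- if (isTRUE(object@weighted)) {
        sw <- sum(object@weights)
        if (sw > 0) sum(object@weights * object@perFeatureR) / sw else NA_real_
    } else mean(object@perFeatureR)
    if (is.finite(expected) && abs(expected - object@psi) > 1e-9)
        msgs <- c(msgs, "psi does not equal the (weighted) mean of perFeatureR")
    if (length(msgs)) msgs else TRUE
})

## ---- gene expression types --------------------------------------------------

.validGeneFrame <- function(df) {
    msgs <- character()
    if (!all(c("gene", "signedFold") %in% colnames(df)))
        return("gene table needs columns 'gene' and 'signedFold'")
    if (anyDuplicated(df$gene))
        msgs <- c(msgs, "duplicate gene symbols within a replicate")
    if (any(!nzchar(df$gene)))
        msgs <- c(msgs, "empty gene symbol")
    if (nrow(df) && (any(!is.finite(df$signedFold)) ||
                     any(abs(df$signedFold) < 1)))
        msgs <- c(msgs, "signed fold changes must satisfy |fold| >= 1")
    if (length(msgs)) msgs else TRUE
}

#' GeneReplicateSet: replicate gene-expression measurements of one batch
#'
#' Each replicate is a table of gene symbols with signed fold changes versus
#' an untreated control: +f means f-fold up-regulation, -f means f-fold
#' down-regulation, so |f| >= 1 by convention.
#'
#' @slot batchId character(1).
#' @slot replicates named list of `data.frame`s with columns `gene`,
#'   `signedFold`; genes unique within a replicate.
#' @exportClass GeneReplicateSet
setClass("GeneReplicateSet",
    representation(batchId = "character", replicates = "list"))

setValidity("GeneReplicateSet", function(object) {
    msgs <- character()
    if (!length(object@replicates))
        msgs <- c(msgs, "at least one replicate is required")
    for (i in seq_along(object@replicates)) {
        v <- .validGeneFrame(object@replicates[[i]])
        if (!isTRUE(v))
            msgs <- c(msgs, sprintf("replicate %d: %s", i,
                                    paste(v, collapse = "; ")))
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a GeneReplicateSet
#'
#' @param replicates a `data.frame` (single replicate) or list of
#'   `data.frame`s with columns `gene`, `signedFold`.
#' @param batchId character(1).
#' @return A [GeneReplicateSet-class].
#' @export
geneReplicateSet <- function(replicates, batchId = NA_character_) {
    if (is.data.frame(replicates)) replicates <- list(r1 = replicates)
    replicates <- lapply(replicates, function(df) {
        df <- as.data.frame(df, stringsAsFactors = FALSE)
        df$gene <- as.character(df$gene)
        df$signedFold <- as.numeric(df$signedFold)
        df
    })
    if (is.null(names(replicates)))
        names(replicates) <- paste0("r", seq_along(replicates))
    new("GeneReplicateSet", batchId = as.character(batchId),
        replicates = replicates)
}

#' BioresponsePanel: a gene-expression signature of a batch
#'
#' An ordered panel of signature genes with strictly positive expression
#' ratios (treatment/control); down-regulated genes are stored as reciprocal
#' ratios so the panel can feed the ratio-matrix similarity machinery.
#'
#' @slot batchId character(1).
#' @slot genes ordered character vector, >= 3 genes, unique.
#' @slot ratios positive numeric vector, same length.
#' @exportClass BioresponsePanel
setClass("BioresponsePanel",
    representation(batchId = "character", genes = "character",
                   ratios = "numeric"))

setValidity("BioresponsePanel", function(object) {
    msgs <- character()
    if (length(object@genes) != length(object@ratios))
        msgs <- c(msgs, "genes and ratios lengths differ")
    if (length(object@genes) < 3L)
        msgs <- c(msgs, "a panel needs >= 3 genes")
    if (anyDuplicated(object@genes))
        msgs <- c(msgs, "duplicate genes in panel")
    if (any(!is.finite(object@ratios)) || any(object@ratios <= 0))
        msgs <- c(msgs, "all ratios must be finite and > 0")
    if (length(msgs)) msgs else TRUE
})

#' Construct a BioresponsePanel
#'
#' @param genes ordered character vector of signature genes.
#' @param ratios positive expression ratios (treatment/control), same order.
#' @param batchId character(1).
#' @return A [BioresponsePanel-class].
#' @export
bioresponsePanel <- function(genes, ratios, batchId = NA_character_) {
    new("BioresponsePanel", batchId = as.character(batchId),
        genes = as.character(genes), ratios = as.numeric(ratios))
}

## ---- SyntheticSpec ----------------------------------------------------------

#' SyntheticSpec: parameters of the synthetic-data generators
#'
#' A seeded description of the validation scenarios: fingerprint size,
#' intensity law, noise model and magnitude, optional single-feature
#' perturbation, and m/z / retention-time ranges and jitter. All generators
#' are pure functions of a spec, so the same spec always reproduces the
#' same fixture.
#'
#' @slot nFeatures integer, >= 3 (default 39, the size of the study's
#'   chemical fingerprint).
#' @slot seed integer master seed; per-generator streams are derived from it.
#' @slot intensityLaw `"log-uniform"` (over \eqn{[10^2, 10^5]} ion counts,
#'   the dynamic range an LC/MS fingerprint spans) or `"uniform"` (over
#'   (0.1, 100]).
#' @slot noiseCv base coefficient of variation of multiplicative intensity
#'   noise (default 0.03 = 3 percent on the base peak).
#' @slot noiseModel `"counting"` (per-feature CV scaled by
#'   \eqn{\sqrt{I_{max}/I_i}}, capped at 1, emulating ion-counting
#'   statistics) or `"constant"` (one CV for every feature).
#' @slot outlierIndex integer position of the feature perturbed in
#'   single-outlier mode (`NA` = unset).
#' @slot outlierFactor multiplicative perturbation, > 0 (default 10).
#' @slot mzRange,rtRange numeric(2): m/z interval in amu, retention-time
#'   interval in minutes.
#' @slot jitter numeric(2): standard deviations of (mz, rt) replicate jitter.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(nFeatures = "integer", seed = "integer",
                   intensityLaw = "character", noiseCv = "numeric",
                   noiseModel = "character", outlierIndex = "integer",
                   outlierFactor = "numeric", mzRange = "numeric",
                   rtRange = "numeric", jitter = "numeric"),
    prototype(nFeatures = 39L, seed = 1L, intensityLaw = "log-uniform",
              noiseCv = 0.03, noiseModel = "counting",
              outlierIndex = NA_integer_, outlierFactor = 10,
              mzRange = c(100, 1000), rtRange = c(0, 65),
              jitter = c(mz = 0.002, rt = 0.05)))

setValidity("SyntheticSpec", function(object) {
    msgs <- character()
    if (object@nFeatures < 3L) msgs <- c(msgs, "nFeatures must be >= 3")
    if (!object@intensityLaw %in% c("log-uniform", "uniform"))
        msgs <- c(msgs, "intensityLaw must be 'log-uniform' or 'uniform'")
    if (!object@noiseModel %in% c("counting", "constant"))
        msgs <- c(msgs, "noiseModel must be 'counting' or 'constant'")
    if (object@noiseCv < 0) msgs <- c(msgs, "noiseCv must be >= 0")
    if (!is.na(object@outlierIndex) &&
        (object@outlierIndex < 1L || object@outlierIndex > object@nFeatures))
        msgs <- c(msgs, "outlierIndex out of range")
    if (object@outlierFactor <= 0) msgs <- c(msgs, "outlierFactor must be > 0")
    if (length(object@mzRange) != 2L || diff(object@mzRange) <= 0)
        msgs <- c(msgs, "mzRange must be an increasing interval")
    if (length(object@rtRange) != 2L || diff(object@rtRange) <= 0)
        msgs <- c(msgs, "rtRange must be an increasing interval")
    if (length(object@jitter) != 2L || any(object@jitter < 0))
        msgs <- c(msgs, "jitter must be two non-negative sds")
    if (length(msgs)) msgs else TRUE
})

#' Construct a SyntheticSpec
#'
#' @param nFeatures number of features (default 39).
#' @param seed integer master seed.
#' @param intensityLaw `"log-uniform"` or `"uniform"`.
#' @param noiseCv base CV of multiplicative noise.
#' @param noiseModel `"counting"` or `"constant"`.
#' @param outlierIndex feature perturbed in single-outlier mode.
#' @param outlierFactor multiplicative perturbation (> 0).
#' @param mzRange,rtRange coordinate ranges (amu; minutes).
#' @param jitter (mz, rt) jitter standard deviations.
#' @return A [SyntheticSpec-class].
#' @examples
#' spec <- syntheticSpec(nFeatures = 39, seed = 7)
#' fp <- genFingerprint(spec)
#' @export
syntheticSpec <- function(nFeatures = 39, seed = 1,
                          intensityLaw = c("log-uniform", "uniform"),
                          noiseCv = 0.03,
                          noiseModel = c("counting", "constant"),
                          outlierIndex = NA, outlierFactor = 10,
                          mzRange = c(100, 1000), rtRange = c(0, 65),
                          jitter = c(mz = 0.002, rt = 0.05)) {
    new("SyntheticSpec", nFeatures = as.integer(nFeatures),
        seed = as.integer(seed), intensityLaw = match.arg(intensityLaw),
        noiseCv = noiseCv, noiseModel = match.arg(noiseModel),
        outlierIndex = as.integer(outlierIndex),
        outlierFactor = outlierFactor, mzRange = as.numeric(mzRange),
        rtRange = as.numeric(rtRange), jitter = as.numeric(jitter))
}

## ---- ComparisonReport -------------------------------------------------------

#' ComparisonReport: one reference batch versus many candidates
#'
#' One row per compared batch (PSI, conventional R, N, method, weighting,
#' outlier count, pass/fail against a similarity threshold), plus the
#' per-feature detail of every comparison and the parameters used.
#'
#' @slot referenceBatch character(1).
#' @slot rows `data.frame` with columns `batchId`, `psi`, `conventionalR`,
#'   `nFeatures`, `method`, `weighted`, `outlierCount`, `pass`, `note`.
#' @slot detail named list (per batch) of per-feature `data.frame`s.
#' @slot params named list of the comparison parameters, recorded verbatim.
#' @slot version character(1), package version.
#' @slot timestamp character(1).
#' @exportClass ComparisonReport
setClass("ComparisonReport",
    representation(referenceBatch = "character", rows = "data.frame",
                   detail = "list", params = "list", version = "character",
                   timestamp = "character"))

setValidity("ComparisonReport", function(object) {
    msgs <- character()
    ok <- object@rows$psi
    ok <- ok[is.finite(ok)]
    if (length(ok) && any(abs(ok) > 1 + 1e-9))
        msgs <- c(msgs, "psi values must lie in [-1, 1]")
    rr <- object@rows$conventionalR
    rr <- rr[is.finite(rr)]
    if (length(rr) && any(abs(rr) > 1 + 1e-9))
        msgs <- c(msgs, "R values must lie in [-1, 1]")
    if (length(msgs)) msgs else TRUE
})
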