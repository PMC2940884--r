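#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Build the pairwise intensity-ratio matrix
#'
#' Places the N intensities of a fingerprint on the diagonal of an N x N
#' matrix and the ratio value_i / value_j in every off-diagonal cell (i, j).
#' The matrix is reciprocal-symmetric, so its N(N-1)/2 upper-triangle cells
#' carry the complete relative-abundance information of the pattern; row i
#' without its diagonal (the feature-i ratio vector, see
#' [featureRatioVector()]) describes feature i relative to every other
#' feature.
#'
#' @param values N >= 3 strictly positive intensities.
#' @param featureKeys optional character vector of feature identities.
#' @return A [RatioMatrix-class].
#' @examples
#' m <- ratioMatrix(c(1, 2, 4))
#' featureRatioVector(m, 1)   # 0.5 0.25
#' @export
ratioMatrix <- function(values, featureKeys = character()) {
    values <- as.numeric(values)
    if (length(values) < 3L)
        .dataError("ratio matrix needs >= 3 values, got %d", length(values))
    if (any(!is.finite(values)) || any(values <= 0))
        .dataError("ratio matrix values must be finite and > 0")
    m <- outer(values, values, "/")
    diag(m) <- values
    new("RatioMatrix", mat = m, featureKeys = as.character(featureKeys))
}

#' Extract a feature's ratio vector
#'
#' Row `i` of a [RatioMatrix-class] without the diagonal cell: the N-1
#' ratios value_i / value_j in ascending j order. Indices are 1-based.
#'
#' @param m a [RatioMatrix-class].
#' @param i feature index, 1 <= i <= N.
#' @return numeric vector of length N - 1.
#' @export
featureRatioVector <- function(m, i) {
    stopifnot(is(m, "RatioMatrix"))
    n <- nrow(m@mat)
    i <- as.integer(i)
    if (length(i) != 1L || is.na(i) || i < 1L || i > n)
        .usageError("feature index must lie in 1..%d", n)
    m@mat[i, -i]
}

## ratio vectors for all features at once (rows, diagonal removed),
## as an N x (N-1) matrix -- the vectorised workhorse behind psi().
.ratioRows <- function(m) {
    n <- nrow(m@mat)
    t(vapply(seq_len(n), function(i) m@mat[i, -i], numeric(n - 1L)))
}

#' Per-feature ratio-vector correlations
#'
#' For every feature i, correlates the feature-i ratio vector of batch A
#' with that of batch B (Pearson by default, Spearman with average ranks as
#' the robust alternative). Identical vectors score exactly 1. A constant
#' ratio vector (which arises when all of a batch's other intensities are
#' equal) has no defined correlation; the fallback score is 1 when both
#' vectors are constant (equal-ranked by convention) and 0 when only one is,
#' with a logged warning.
#'
#' @param ma,mb [RatioMatrix-class] objects of equal size, same feature
#'   order.
#' @param method `"pearson"` or `"spearman"`.
#' @return numeric vector of N scores, each in [-1, 1].
#' @seealso [psi()] which averages these scores.
#' @export
featureCorrelations <- function(ma, mb, method = c("pearson", "spearman")) {
    stopifnot(is(ma, "RatioMatrix"), is(mb, "RatioMatrix"))
    method <- match.arg(method)
    n <- nrow(ma@mat)
    if (nrow(mb@mat) != n)
        .dataError("ratio matrix sizes differ: %d vs %d", n, nrow(mb@mat))
    ra <- .ratioRows(ma)
    rb <- .ratioRows(mb)
    vapply(seq_len(n), function(i) {
        xa <- ra[i, ]
        xb <- rb[i, ]
        if (identical(xa, xb)) return(1)
        .corFallback(xa, xb, method, context = sprintf("feature %d", i))
    }, numeric(1))
}

#' Slope weights for per-feature scores
#'
#' For each feature i, fits the least-squares slope s_i of batch B's ratio
#' vector regressed on batch A's and converts it to a weight
#' w_i = min(s_i, 1/s_i), which is 1 when the two ratio vectors lie on the
#' identity line and decays symmetrically as the slope departs from 1 in
#' either direction (clipped to [0, 1]; a non-positive slope gives weight
#' 0). Identical batches, or batches differing by a common scale factor,
#' give all weights exactly 1. A zero-variance regressor yields weight 0
#' with a warning.
#'
#' @param ma,mb [RatioMatrix-class] objects of equal size.
#' @return numeric vector of N weights in [0, 1].
#' @export
slopeWeights <- function(ma, mb) {
    stopifnot(is(ma, "RatioMatrix"), is(mb, "RatioMatrix"))
    n <- nrow(ma@mat)
    if (nrow(mb@mat) != n)
        .dataError("ratio matrix sizes differ: %d vs %d", n, nrow(mb@mat))
    ra <- .ratioRows(ma)
    rb <- .ratioRows(mb)
    vapply(seq_len(n), function(i) {
        xa <- ra[i, ]
        xb <- rb[i, ]
        v <- stats::var(xa)
        if (v == 0) {
            .log("warn", "zero-variance regressor for feature %d; weight 0", i)
            return(0)
        }
        s <- stats::cov(xa, xb) / v
        if (s <= 0) return(0)
        min(s, 1 / s, 1)
    }, numeric(1))
}

## weights used for weighted PSI aggregation and outlier scoring:
## per-feature average of the A->B and B->A slope weights, which makes the
## weighted statistic symmetric in its arguments by construction.
.symmetricWeights <- function(ma, mb) {
    (slopeWeights(ma, mb) + slopeWeights(mb, ma)) / 2
}

#' Phytomics Similarity Index
#'
#' The PSI of two matched fingerprints: each batch's intensities are
#' expanded into a pairwise ratio matrix, the feature-i ratio vectors of the
#' two batches are correlated for every i, and the N per-feature scores are
#' averaged into one similarity value. 1.0 means the two patterns are
#' identical up to a common scale factor, values near 0 mean unrelated
#' patterns, and -1 perfect anti-correlation. With `weighted = TRUE` the
#' average is renormalised by the direction-averaged slope weights (see
#' [slopeWeights()]), down-weighting features whose ratio vectors agree in
#' shape but not in magnitude.
#'
#' The result also carries the conventional correlation R of the raw
#' intensity vectors for comparison: R weighs each feature once and is
#' dominated by the largest peaks, whereas every PSI feature score pools
#' that feature's N-1 ratios to all others, which makes the PSI far more
#' sensitive to distortions of the minor-constituent pattern.
#'
#' @param pair a [MatchedPair-class] (N >= 3 strictly positive paired
#'   values).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param weighted logical(1): slope-weighted average? Default `FALSE`.
#' @param ... unused.
#' @return A [SimilarityResult-class].
#' @examples
#' a <- c(120, 45, 1800, 6.2, 300)
#' identicalPair <- matchedPair(paste0("f", 1:5), a, a)
#' psi(identicalPair)@psi            # exactly 1
#' scaled <- matchedPair(paste0("f", 1:5), a, 3.7 * a)
#' psi(scaled)@psi                   # 1 up to floating tolerance
#' @export
setMethod("psi", "MatchedPair",
    function(pair, method = c("pearson", "spearman"), weighted = FALSE, ...) {
    method <- match.arg(method)
    ma <- ratioMatrix(pair@valuesA, pair@featureKeys)
    mb <- ratioMatrix(pair@valuesB, pair@featureKeys)
    r <- featureCorrelations(ma, mb, method)
    w <- .symmetricWeights(ma, mb)
    score <- if (weighted) {
        sw <- sum(w)
        if (sw == 0)
            .dataError("all slope weights are zero; weighted PSI undefined")
        sum(w * r) / sw
    } else mean(r)
    convR <- tryCatch(conventionalR(pair, method),
                      phytopsiDataError = function(e) NA_real_)
    new("SimilarityResult", psi = score, perFeatureR = r, weights = w,
        method = method, weighted = weighted, conventionalR = convR,
        nFeatures = length(r), featureKeys = pair@featureKeys)
})

#' @rdname psi
#' @export
setMethod("psi", "SimilarityResult",
    function(pair, method, weighted, ...) pair@psi)

#' Conventional correlation of two batches
#'
#' The plain Pearson (or Spearman) correlation of the two matched intensity
#' vectors -- the standard single-number similarity the PSI is designed to
#' sharpen.
#'
#' @param pair a [MatchedPair-class], or a [SimilarityResult-class] (the
#'   stored value is returned).
#' @param method `"pearson"` or `"spearman"`.
#' @return numeric(1) in [-1, 1].
#' @export
setMethod("conventionalR", "MatchedPair",
    function(pair, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    if (stats::sd(pair@valuesA) == 0 || stats::sd(pair@valuesB) == 0)
        .dataError("conventional R undefined for a constant value vector")
    stats::cor(pair@valuesA, pair@valuesB, method = method)
})

#' @rdname conventionalR
#' @export
setMethod("conventionalR", "SimilarityResult",
    function(pair, method) pair@conventionalR)

#' Flag outlier features and histogram the per-feature scores
#'
#' Features are scored by `perFeatureR * featureWeights` (the slope-adjusted
#' per-feature score). The correlation alone cannot expose a single
#' perturbed feature -- scaling one intensity rescales that feature's entire
#' ratio vector, leaving its correlation at exactly 1 -- but the slope of
#' its ratio-vector regression moves to the perturbation factor, so the
#' slope-adjusted score drops to about min(f, 1/f) for a factor-f outlier
#' while unperturbed features stay near 1. Scores are binned over [-1, 1]
#' with fixed-width bins so the outlier is visible in the histogram.
#'
#' @param result a [SimilarityResult-class].
#' @param lowRThreshold flag features with score < this value (default 0.9).
#' @param bins number of fixed-width histogram bins over [-1, 1]
#'   (default 40).
#' @return A list with `flagged` (integer indices), `flaggedKeys`,
#'   `scores` (the slope-adjusted per-feature scores) and `histogram`
#'   (data.frame `binLeft`, `binRight`, `count`).
#' @export
setMethod("outlierFeatures", "SimilarityResult",
    function(result, lowRThreshold = 0.9, bins = 40L) {
    bins <- as.integer(bins)
    stopifnot(bins >= 1L)
    score <- result@perFeatureR * result@weights
    flagged <- which(score < lowRThreshold)
    breaks <- seq(-1, 1, length.out = bins + 1L)
    idx <- findInterval(score, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    counts <- tabulate(idx, nbins = bins)
    if (length(flagged))
        .log("info", "%d feature(s) below score threshold %.3g: %s",
             length(flagged), lowRThreshold,
             paste(utils::head(result@featureKeys[flagged], 10L),
                   collapse = ", "))
    list(flagged = flagged,
         flaggedKeys = result@featureKeys[flagged],
         scores = score,
         histogram = data.frame(binLeft = breaks[-length(breaks)],
                                binRight = breaks[-1L],
                                count = counts))
})
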