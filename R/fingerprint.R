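#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' @rdname normalizeToBasePeak
#' @export
setMethod("normalizeToBasePeak", "PeakTable", function(table) {
    ints <- table@peaks$intensity
    if (!nrow(table@peaks) || all(ints == 0))
        .dataError("empty spectrum: no peak with intensity > 0")
    out <- table
    out@peaks$intensity <- ints / max(ints)
    out
})

#' @rdname normalizeToBasePeak
#' @export
setMethod("normalizeToBasePeak", "ChemicalFingerprint", function(table) {
    out <- table
    out@features$intensity <- table@features$intensity /
        max(table@features$intensity)
    out
})

#' Select quality-control fingerprint peaks from replicate injections
#'
#' Applies the fingerprint-selection rules to two or more replicate runs of
#' the same batch (shared feature-id namespace): a peak is retained when it
#' (a) appears in every replicate, (b) has mean relative intensity (fraction
#' of the base peak, averaged over replicates) above `minRelIntensity`, and
#' (c) has a coefficient of variation of its raw intensity across replicates
#' of at most `maxCv`. Retained peaks keep the per-feature mean of intensity
#' and of the m/z and retention-time coordinates, ordered by retention time.
#'
#' The defaults encode the study's selection rules for its 39-peak pattern:
#' relative intensity above 0.2 percent and reproducible integration in
#' three independent spectra; the reproducibility rule is quantified here as
#' a 30 percent CV ceiling, configurable and recorded in
#' `selectionParams`. Ten-fold linearity of each candidate peak is checked
#' separately on dilution-series data with [linearityCheck()], since
#' replicate tables carry no concentration axis.
#'
#' @param replicates list of >= 2 [PeakTable-class] objects.
#' @param minRelIntensity retained peaks need mean relative intensity above
#'   this fraction of the base peak (default 0.002).
#' @param maxCv ceiling on the across-replicate CV of intensity
#'   (default 0.30).
#' @param batchId batch label of the result; defaults to the first
#'   replicate's.
#' @return A [ChemicalFingerprint-class].
#' @export
selectFingerprintPeaks <- function(replicates, minRelIntensity = 0.002,
                                   maxCv = 0.30, batchId = NULL) {
    if (!is.list(replicates) || length(replicates) < 2L)
        .usageError("need at least 2 replicate peak tables, got %d",
                    if (is.list(replicates)) length(replicates) else 1L)
    if (!all(vapply(replicates, is, TRUE, "PeakTable")))
        .usageError("replicates must be PeakTable objects")
    if (!(minRelIntensity > 0 && minRelIntensity < 1))
        .usageError("minRelIntensity must lie in (0, 1)")
    if (maxCv <= 0)
        .usageError("maxCv must be > 0")

    frames <- lapply(replicates, function(x) x@peaks)
    ids <- Reduce(intersect, lapply(frames, `[[`, "featureId"))
    allIds <- unique(unlist(lapply(frames, `[[`, "featureId")))
    if (length(allIds) > length(ids))
        .log("info", "%d peak(s) absent from some replicate dropped",
             length(allIds) - length(ids))

    if (length(ids)) {
        raw <- sapply(frames, function(df) {
            df$intensity[match(ids, df$featureId)]
        })                                       # |ids| x nrep
        raw <- matrix(raw, nrow = length(ids))
        rel <- sapply(frames, function(df) {
            df$intensity[match(ids, df$featureId)] / max(df$intensity)
        })
        rel <- matrix(rel, nrow = length(ids))
        meanRel <- rowMeans(rel)
        mu <- rowMeans(raw)
        cv <- ifelse(mu > 0, apply(raw, 1L, stats::sd) / mu, Inf)
        keep <- meanRel > minRelIntensity & cv <= maxCv
        dropped <- ids[!keep]
        if (length(dropped))
            .log("info", "%d peak(s) failed intensity/CV rules: %s",
                 length(dropped),
                 paste(utils::head(dropped, 10L), collapse = ", "))
        ids <- ids[keep]
        raw <- raw[keep, , drop = FALSE]
    }
    if (!length(ids))
        .dataError("no quantifiable peaks survive the selection rules")

    first <- frames[[1L]]
    coord <- function(col) {
        m <- matrix(sapply(frames, function(df)
            df[[col]][match(ids, df$featureId)]), nrow = length(ids))
        rowMeans(m)
    }
    feat <- data.frame(featureId = ids, mz = coord("mz"), rt = coord("rt"),
                       intensity = rowMeans(raw),
                       source = if ("source" %in% colnames(first))
                           first$source[match(ids, first$featureId)]
                       else NA_character_,
                       stringsAsFactors = FALSE)
    feat <- feat[order(feat$rt, feat$mz), , drop = FALSE]
    rownames(feat) <- NULL
    chemicalFingerprint(feat,
        batchId = if (is.null(batchId)) replicates[[1L]]@batchId else batchId,
        selectionParams = list(minRelIntensity = minRelIntensity,
                               maxCv = maxCv,
                               nReplicates = length(replicates)))
}

#' Total-ion-current coverage of a fingerprint
#'
#' The fraction of a spectrum's total ion current carried by the fingerprint
#' peaks, counting only peaks at or above `threshold` times the base peak in
#' both numerator and denominator: sum of the table intensities of the
#' fingerprint features at/above threshold, divided by the sum of all table
#' intensities at/above threshold.
#'
#' @param table the full [PeakTable-class].
#' @param fingerprint a [ChemicalFingerprint-class] whose feature ids are a
#'   subset of the table's.
#' @param threshold relative-intensity threshold in [0, 1) (default 0.015).
#' @return numeric(1) in [0, 1].
#' @examples
#' pt <- peakTable(data.frame(featureId = c("a", "b", "c"),
#'                            mz = 1:3 * 100, rt = 1:3,
#'                            intensity = c(50, 30, 20)))
#' fp <- chemicalFingerprint(peaks(pt))
#' ticCoverage(pt, fp, threshold = 0)   # 1
#' @export
setMethod("ticCoverage", c("PeakTable", "ChemicalFingerprint"),
    function(table, fingerprint, threshold = 0.015) {
    if (!(threshold >= 0 && threshold < 1))
        .usageError("threshold must lie in [0, 1)")
    df <- table@peaks
    fpIds <- fingerprint@features$featureId
    if (!all(fpIds %in% df$featureId))
        .dataError("fingerprint features missing from table: %s",
                   paste(setdiff(fpIds, df$featureId), collapse = ", "))
    cut <- threshold * max(df$intensity)
    above <- df$intensity >= cut
    denom <- sum(df$intensity[above])
    if (denom == 0)
        .dataError("no peaks at or above the threshold")
    num <- sum(df$intensity[above & df$featureId %in% fpIds])
    num / denom
})

#' Match fingerprint features across two batches
#'
#' Pairs the features of two fingerprints, either by shared feature id
#' (preferred when both fingerprints use one namespace) or by coordinate
#' tolerance: candidate pairs with |dmz| <= `mzTol` and |drt| <= `rtTol`
#' are assigned greedily in order of the combined normalised distance
#' |dmz|/mzTol + |drt|/rtTol, each feature used at most once; a distance tie
#' is resolved toward the lower m/z and logged. The result is ordered by
#' batch A's retention time and must contain at least 3 matches. Unmatched
#' features are dropped (never zero-filled) with a logged count.
#'
#' @param fpA,fpB [ChemicalFingerprint-class] objects.
#' @param mzTol m/z tolerance in amu (default 0.01).
#' @param rtTol retention-time tolerance in minutes (default 0.5).
#' @param by `"auto"` (id when >= 3 ids are shared, else tolerance),
#'   `"id"`, or `"tolerance"`.
#' @return A [MatchedPair-class].
#' @export
setMethod("matchFeatures", c("ChemicalFingerprint", "ChemicalFingerprint"),
    function(fpA, fpB, mzTol = 0.01, rtTol = 0.5,
             by = c("auto", "id", "tolerance")) {
    by <- match.arg(by)
    if (mzTol <= 0 || rtTol <= 0)
        .usageError("mzTol and rtTol must be > 0")
    a <- fpA@features
    b <- fpB@features
    shared <- intersect(a$featureId, b$featureId)
    useId <- switch(by, id = TRUE, tolerance = FALSE,
                    auto = length(shared) >= 3L)
    if (useId) {
        if (length(shared) < 3L)
            .dataError("insufficient shared pattern: %d feature id(s) shared",
                       length(shared))
        unmatched <- (nrow(a) - length(shared)) + (nrow(b) - length(shared))
        if (unmatched > 0)
            .log("info", "%d unmatched feature(s) excluded", unmatched)
        ord <- order(a$rt[match(shared, a$featureId)])
        keys <- shared[ord]
        return(matchedPair(keys,
                           a$intensity[match(keys, a$featureId)],
                           b$intensity[match(keys, b$featureId)],
                           provenance = "by feature id"))
    }

    ## tolerance matching: greedy nearest neighbour on combined distance
    dm <- abs(outer(a$mz, b$mz, "-"))
    dr <- abs(outer(a$rt, b$rt, "-"))
    ok <- dm <= mzTol & dr <= rtTol
    if (!any(ok))
        .dataError("insufficient shared pattern: no candidate matches")
    dist <- dm / mzTol + dr / rtTol
    cand <- which(ok, arr.ind = TRUE)
    d <- dist[ok]
    ## ties resolved toward lower m/z (of batch A, then batch B)
    ordc <- order(d, a$mz[cand[, 1L]], b$mz[cand[, 2L]])
    if (anyDuplicated(d))
        .log("info", "distance tie(s) resolved toward lower m/z")
    cand <- cand[ordc, , drop = FALSE]
    usedA <- logical(nrow(a))
    usedB <- logical(nrow(b))
    ia <- integer()
    ib <- integer()
    for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1L]
        j <- cand[k, 2L]
        if (!usedA[i] && !usedB[j]) {
            usedA[i] <- TRUE
            usedB[j] <- TRUE
            ia <- c(ia, i)
            ib <- c(ib, j)
        }
    }
    if (length(ia) < 3L)
        .dataError("insufficient shared pattern: only %d match(es)",
                   length(ia))
    unmatched <- sum(!usedA) + sum(!usedB)
    if (unmatched > 0)
        .log("info", "%d unmatched feature(s) excluded", unmatched)
    ord <- order(a$rt[ia])
    ia <- ia[ord]
    ib <- ib[ord]
    matchedPair(paste(a$featureId[ia], b$featureId[ib], sep = "|"),
                a$intensity[ia], b$intensity[ib],
                provenance = sprintf(
                    "by tolerance (mzTol = %g amu, rtTol = %g min)",
                    mzTol, rtTol))
})

#' Linearity check of a dilution series
#'
#' Pearson correlation of response versus concentration over a dilution
#' series, with the acceptance rule used for fingerprint marker standards:
#' the series passes when r exceeds `minR` (default 0.99, the linearity
#' criterion applied over the 0.1--20 mg/mL range in the study system).
#'
#' @param series a [DilutionSeries-class].
#' @param minR pass threshold in (0, 1] (default 0.99).
#' @return list with `rValue` and `passed`.
#' @examples
#' s <- dilutionSeries(c(0.1, 1, 5, 20), c(11, 105, 498, 2010))
#' linearityCheck(s)
#' @export
linearityCheck <- function(series, minR = 0.99) {
    stopifnot(is(series, "DilutionSeries"))
    if (!(minR > 0 && minR <= 1))
        .usageError("minR must lie in (0, 1]")
    if (stats::sd(series@responses) == 0)
        .dataError("constant responses: correlation undefined")
    r <- stats::cor(series@concentrations, series@responses)
    list(rValue = r, passed = r > minR)
}
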