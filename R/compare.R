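#' @include AllClasses.R AllGenerics.R utils.R psi.R fingerprint.R bioresponse.R
NULL

#' Compare a reference batch against candidate batches
#'
#' Runs the full similarity workflow for one reference fingerprint or
#' bioresponse panel against a list of candidates: features are matched
#' ([matchFeatures()]; panels must share their gene list), the PSI and
#' conventional R computed ([psi()]), outliers counted, and one report row
#' emitted per batch, sorted by descending PSI, with a pass/fail call
#' against a similarity threshold (default 0.85, the level above which
#' batches are regarded as likely bioequivalent; configurable). A batch
#' that cannot be matched is recorded as a failed row, not an error.
#'
#' @param reference a [ChemicalFingerprint-class] or
#'   [BioresponsePanel-class].
#' @param others list of objects of the same class as `reference`.
#' @param method `"pearson"` or `"spearman"`.
#' @param weighted slope-weighted PSI? Default `FALSE`.
#' @param threshold pass threshold on PSI (default 0.85).
#' @param mzTol,rtTol matching tolerances for fingerprints.
#' @param matchBy matching strategy, see [matchFeatures()].
#' @param lowRThreshold outlier-flagging threshold (default 0.9).
#' @return A [ComparisonReport-class].
#' @examples
#' spec <- syntheticSpec(seed = 3)
#' ref <- genFingerprint(spec, batchId = "REF")
#' cmp <- genPair(spec, mode = "noisy")$b
#' report <- compareBatches(ref, list(ref, cmp))
#' report
#' @export
compareBatches <- function(reference, others,
                           method = c("pearson", "spearman"),
                           weighted = FALSE, threshold = 0.85,
                           mzTol = 0.01, rtTol = 0.5,
                           matchBy = c("auto", "id", "tolerance"),
                           lowRThreshold = 0.9) {
    method <- match.arg(method)
    matchBy <- match.arg(matchBy)
    if (!is.list(others)) others <- list(others)
    if (!length(others))
        .usageError("no batches to compare")
    isPanel <- is(reference, "BioresponsePanel")
    if (!isPanel && !is(reference, "ChemicalFingerprint"))
        .usageError("reference must be a ChemicalFingerprint or BioresponsePanel")

    rows <- list()
    detail <- list()
    for (k in seq_along(others)) {
        other <- others[[k]]
        id <- batchId(other)
        if (is.na(id) || !nzchar(id)) id <- sprintf("batch%d", k)
        res <- tryCatch({
            sim <- if (isPanel)
                panelSimilarity(reference, other, method = method,
                                weighted = weighted)
            else {
                mp <- matchFeatures(reference, other, mzTol = mzTol,
                                    rtTol = rtTol, by = matchBy)
                psi(mp, method = method, weighted = weighted)
            }
            out <- outlierFeatures(sim, lowRThreshold = lowRThreshold)
            detail[[id]] <- data.frame(
                featureKey = sim@featureKeys,
                perFeatureR = sim@perFeatureR,
                weight = sim@weights,
                score = out$scores,
                flagged = seq_len(sim@nFeatures) %in% out$flagged,
                stringsAsFactors = FALSE)
            data.frame(batchId = id, psi = sim@psi,
                       conventionalR = sim@conventionalR,
                       nFeatures = sim@nFeatures, method = method,
                       weighted = weighted,
                       outlierCount = length(out$flagged),
                       pass = sim@psi >= threshold, note = "",
                       stringsAsFactors = FALSE)
        }, phytopsiDataError = function(e) {
            .log("warn", "batch %s not comparable: %s", id,
                 conditionMessage(e))
            data.frame(batchId = id, psi = NA_real_,
                       conventionalR = NA_real_, nFeatures = NA_integer_,
                       method = method, weighted = weighted,
                       outlierCount = NA_integer_, pass = FALSE,
                       note = conditionMessage(e), stringsAsFactors = FALSE)
        })
        rows[[k]] <- res
    }
    rows <- do.call(rbind, rows)
    rows <- rows[order(-ifelse(is.na(rows$psi), -Inf, rows$psi)), ,
                 drop = FALSE]
    rownames(rows) <- NULL
    new("ComparisonReport",
        referenceBatch = as.character(batchId(reference)),
        rows = rows, detail = detail,
        params = list(method = method, weighted = weighted,
                      threshold = threshold, mzTol = mzTol, rtTol = rtTol,
                      matchBy = matchBy, lowRThreshold = lowRThreshold),
        version = as.character(utils::packageVersion("phytopsi")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Serialize a comparison report
#'
#' JSON is the canonical machine-readable form (all rows, per-feature
#' detail, parameters, version and timestamp); `"csv"` writes the summary
#' rows; `"text"` renders a human-readable table. Regenerating a report
#' from the same inputs yields an identical payload apart from the
#' timestamp field.
#'
#' @param report a [ComparisonReport-class].
#' @param path output file.
#' @param format `"json"`, `"csv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = c("json", "csv", "text")) {
    stopifnot(is(report, "ComparisonReport"))
    format <- match.arg(format)
    if (format == "json") {
        payload <- list(reference_batch = report@referenceBatch,
                        rows = report@rows, detail = report@detail,
                        params = report@params, version = report@version,
                        timestamp = report@timestamp)
        jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    } else if (format == "csv") {
        utils::write.table(report@rows, path, sep = ",", row.names = FALSE,
                           quote = TRUE)
    } else {
        lines <- c(sprintf("Reference batch: %s", report@referenceBatch),
                   sprintf("Method: %s (%s)  threshold: %g  N column: matched features",
                           report@params$method,
                           if (isTRUE(report@params$weighted))
                               "slope-weighted" else "unweighted",
                           report@params$threshold),
                   "",
                   utils::capture.output(print(report@rows,
                                               row.names = FALSE)))
        writeLines(lines, path)
    }
    invisible(path)
}

#' Read a JSON comparison report back
#'
#' @param path JSON file written by [writeReport()].
#' @return A [ComparisonReport-class].
#' @export
readReport <- function(path) {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    rows <- as.data.frame(payload$rows, stringsAsFactors = FALSE)
    detail <- payload$detail
    if (is.null(detail)) detail <- list()
    detail <- lapply(detail, function(d)
        as.data.frame(d, stringsAsFactors = FALSE))
    new("ComparisonReport",
        referenceBatch = payload$reference_batch, rows = rows,
        detail = detail, params = as.list(payload$params),
        version = payload$version, timestamp = payload$timestamp)
}
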