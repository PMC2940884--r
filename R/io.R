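#' @include AllClasses.R AllGenerics.R utils.R
NULL

## delimiter auto-detection: tab wins if the header contains one, else comma
.detectSep <- function(path) {
    header <- readLines(path, n = 1L, warn = FALSE)
    if (grepl("\t", header)) "\t" else ","
}

.readDelim <- function(path, sep = NULL) {
    if (!file.exists(path))
        .usageError("file not found: %s", path)
    if (is.null(sep)) sep <- .detectSep(path)
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      stringsAsFactors = FALSE, comment.char = "",
                      check.names = TRUE)
}

.requireColumns <- function(df, cols, path) {
    missing <- setdiff(cols, colnames(df))
    if (length(missing))
        .dataError("%s: missing required column(s): %s", path,
                   paste(missing, collapse = ", "))
}

.numericColumn <- function(df, col, path) {
    x <- df[[col]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
        .dataError("%s: non-numeric '%s' at data line(s) %s", path, col,
                   paste(utils::head(bad, 10L), collapse = ", "))
    v
}

#' Read peak tables from a delimited text file
#'
#' Reads comma- or tab-separated peak tables (delimiter auto-detected from
#' the header). Required columns: `feature_id`, `mz`, `rt_min`, `intensity`;
#' optional: `source`, `batch_id`, `replicate_id`. A long-format file with a
#' `replicate_id` column yields one [PeakTable-class] per replicate.
#' Malformed rows are reported with their line numbers.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` (default) auto-detects.
#' @param ionMode ion mode recorded on the tables (default "none").
#' @return A [PeakTable-class], or a named list of them for long-format
#'   input.
#' @export
readPeakTable <- function(path, sep = NULL, ionMode = "none") {
    df <- .readDelim(path, sep)
    .requireColumns(df, c("feature_id", "mz", "rt_min", "intensity"), path)
    out <- data.frame(featureId = as.character(df$feature_id),
                      mz = .numericColumn(df, "mz", path),
                      rt = .numericColumn(df, "rt_min", path),
                      intensity = .numericColumn(df, "intensity", path),
                      source = if ("source" %in% colnames(df))
                          as.character(df$source) else NA_character_,
                      stringsAsFactors = FALSE)
    batch <- if ("batch_id" %in% colnames(df)) df$batch_id
             else NA_character_
    if ("replicate_id" %in% colnames(df) &&
        length(unique(df$replicate_id)) > 1L) {
        reps <- split(seq_len(nrow(out)), df$replicate_id)
        return(lapply(reps, function(idx)
            peakTable(out[idx, , drop = FALSE],
                      batchId = batch[idx][1L],
                      replicateId = df$replicate_id[idx][1L],
                      ionMode = ionMode)))
    }
    repId <- if ("replicate_id" %in% colnames(df)) df$replicate_id[1L]
             else NA_character_
    tryCatch(peakTable(out, batchId = batch[1L], replicateId = repId,
                       ionMode = ionMode),
             error = function(e) .dataError("%s: %s", path, conditionMessage(e)))
}

#' Write a peak table (or fingerprint) to delimited text
#'
#' Writes the schema [readPeakTable()] reads back: columns `feature_id`,
#' `mz`, `rt_min`, `intensity`, `source`, `batch_id`, `replicate_id`.
#'
#' @param table a [PeakTable-class] or [ChemicalFingerprint-class].
#' @param path output file.
#' @param sep delimiter (default comma).
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(table, path, sep = ",") {
    df <- if (is(table, "ChemicalFingerprint")) table@features
          else table@peaks
    out <- data.frame(feature_id = df$featureId, mz = df$mz, rt_min = df$rt,
                      intensity = df$intensity,
                      source = if (is.null(df$source)) NA_character_
                               else df$source,
                      batch_id = table@batchId,
                      replicate_id = if (is(table, "PeakTable"))
                          table@replicateId else NA_character_,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Export / import a chemical fingerprint with its selection metadata
#'
#' `writeFingerprint()` writes the peak schema of [writePeakTable()] plus a
#' key-value sidecar file `<path>.meta` holding the selection parameters;
#' `readFingerprint()` reads both back.
#'
#' @param fingerprint a [ChemicalFingerprint-class].
#' @param path fingerprint file path (sidecar at `<path>.meta`).
#' @param sep delimiter (default comma).
#' @return `writeFingerprint()`: `path`, invisibly. `readFingerprint()`:
#'   a [ChemicalFingerprint-class].
#' @export
writeFingerprint <- function(fingerprint, path, sep = ",") {
    stopifnot(is(fingerprint, "ChemicalFingerprint"))
    writePeakTable(fingerprint, path, sep = sep)
    sp <- fingerprint@selectionParams
    meta <- c(sprintf("batch_id=%s", fingerprint@batchId),
              vapply(names(sp), function(k)
                  sprintf("%s=%s", k, format(sp[[k]])), ""))
    writeLines(meta, paste0(path, ".meta"))
    invisible(path)
}

#' @rdname writeFingerprint
#' @export
readFingerprint <- function(path, sep = NULL) {
    tab <- readPeakTable(path, sep)
    if (is.list(tab))
        .dataError("%s: a fingerprint file must hold a single replicate",
                   path)
    params <- list()
    metaPath <- paste0(path, ".meta")
    batch <- tab@batchId
    if (file.exists(metaPath)) {
        kv <- strsplit(readLines(metaPath, warn = FALSE), "=", fixed = TRUE)
        kv <- Filter(function(x) length(x) == 2L, kv)
        params <- stats::setNames(lapply(kv, function(x) {
            v <- suppressWarnings(as.numeric(x[2L]))
            if (is.na(v)) x[2L] else v
        }), vapply(kv, `[[`, "", 1L))
        if (!is.null(params$batch_id)) {
            batch <- as.character(params$batch_id)
            params$batch_id <- NULL
        }
    }
    chemicalFingerprint(tab@peaks, batchId = batch,
                        selectionParams = params)
}

#' Read gene tables from a delimited text file
#'
#' Required columns `gene`, `signed_fold`; optional `replicate_id` and
#' `batch_id`. Rows sharing a `replicate_id` form one replicate; a file
#' without the column is read as a single replicate. Duplicate genes within
#' a replicate are an error.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` auto-detects.
#' @return A [GeneReplicateSet-class].
#' @export
readGeneTable <- function(path, sep = NULL) {
    df <- .readDelim(path, sep)
    .requireColumns(df, c("gene", "signed_fold"), path)
    folds <- .numericColumn(df, "signed_fold", path)
    batch <- if ("batch_id" %in% colnames(df)) df$batch_id[1L]
             else NA_character_
    repIds <- if ("replicate_id" %in% colnames(df)) df$replicate_id
              else rep("r1", nrow(df))
    reps <- lapply(split(seq_len(nrow(df)), repIds), function(idx)
        data.frame(gene = as.character(df$gene[idx]),
                   signedFold = folds[idx], stringsAsFactors = FALSE))
    tryCatch(geneReplicateSet(reps, batchId = batch),
             error = function(e) .dataError("%s: %s", path, conditionMessage(e)))
}

#' Write a gene replicate set to delimited text
#'
#' @param reps a [GeneReplicateSet-class].
#' @param path output file.
#' @param sep delimiter (default comma).
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(reps, path, sep = ",") {
    stopifnot(is(reps, "GeneReplicateSet"))
    rows <- do.call(rbind, lapply(names(reps@replicates), function(r) {
        df <- reps@replicates[[r]]
        data.frame(gene = df$gene, signed_fold = df$signedFold,
                   replicate_id = r, batch_id = reps@batchId,
                   stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Read a dilution series
#'
#' Columns `conc_mg_per_ml` and `intensity`.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` auto-detects.
#' @return A [DilutionSeries-class].
#' @export
readDilutionSeries <- function(path, sep = NULL) {
    df <- .readDelim(path, sep)
    .requireColumns(df, c("conc_mg_per_ml", "intensity"), path)
    tryCatch(dilutionSeries(.numericColumn(df, "conc_mg_per_ml", path),
                            .numericColumn(df, "intensity", path)),
             error = function(e) .dataError("%s: %s", path, conditionMessage(e)))
}

#' Write histogram bins to CSV
#'
#' Writes the `histogram` component of [outlierFeatures()] as
#' `bin_left,bin_right,count`.
#'
#' @param histogram data.frame with `binLeft`, `binRight`, `count`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHistogram <- function(histogram, path) {
    utils::write.table(
        data.frame(bin_left = histogram$binLeft,
                   bin_right = histogram$binRight,
                   count = histogram$count),
        path, sep = ",", row.names = FALSE, quote = FALSE)
    invisible(path)
}
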