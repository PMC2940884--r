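#' @include AllClasses.R AllGenerics.R utils.R
NULL

## run expr under a dedicated seeded RNG stream, restoring the caller's
## RNG state afterwards so generators behave as pure functions of the spec
.withStream <- function(seed, stream, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(streamSeed(seed, stream))
    expr
}

.drawIntensities <- function(n, law) {
    switch(law,
           "log-uniform" = 10^stats::runif(n, 2, 5),
           "uniform"     = stats::runif(n, 0.1, 100))
}

## mean-one multiplicative log-normal factors at the requested CVs
.lnormFactors <- function(cv) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(length(cv), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## per-feature CVs for a noise draw on intensity vector `ints`
.noiseCvs <- function(spec, ints) {
    if (spec@noiseModel == "counting")
        pmin(spec@noiseCv * sqrt(max(ints) / ints), 1)
    else
        rep(spec@noiseCv, length(ints))
}

#' Generate a synthetic chemical fingerprint
#'
#' Draws `nFeatures` peaks with ids `f1..fn`: m/z and retention time uniform
#' over the spec's ranges (sorted by retention time, ids assigned in elution
#' order) and intensities from the spec's intensity law. Deterministic given
#' the spec's seed; the caller's RNG state is untouched.
#'
#' @param spec a [SyntheticSpec-class].
#' @param batchId character(1) label (default "SYN").
#' @return A [ChemicalFingerprint-class].
#' @examples
#' fp <- genFingerprint(syntheticSpec(nFeatures = 39, seed = 1))
#' nFeatures(fp)
#' @export
genFingerprint <- function(spec, batchId = "SYN") {
    stopifnot(is(spec, "SyntheticSpec"))
    .withStream(spec@seed, "fingerprint", {
        n <- spec@nFeatures
        mz <- stats::runif(n, spec@mzRange[1L], spec@mzRange[2L])
        rt <- stats::runif(n, spec@rtRange[1L], spec@rtRange[2L])
        ints <- .drawIntensities(n, spec@intensityLaw)
        ord <- order(rt)
        chemicalFingerprint(
            data.frame(featureId = paste0("f", seq_len(n)),
                       mz = mz[ord], rt = rt[ord], intensity = ints[ord],
                       source = NA_character_, stringsAsFactors = FALSE),
            batchId = batchId,
            selectionParams = list(synthetic = TRUE, seed = spec@seed,
                                   intensityLaw = spec@intensityLaw))
    })
}

#' Generate a fingerprint pair for a validation scenario
#'
#' Produces two fingerprints with shared feature keys, the second
#' transformed according to `mode`:
#' \describe{
#'   \item{identical}{an exact copy -- PSI is exactly 1 downstream.}
#'   \item{scaled}{every intensity multiplied by one drawn positive
#'     constant (log-uniform over one decade around 1) -- PSI is invariant.}
#'   \item{noisy}{each intensity multiplied by an independent mean-one
#'     log-normal factor. Under the default `"counting"` noise model the
#'     per-feature CV is `noiseCv * sqrt(Imax/Ii)` (capped at 1), emulating
#'     ion-counting statistics in which minor peaks are far less
#'     reproducible than major ones; `"constant"` applies `noiseCv`
#'     uniformly.}
#'   \item{single_outlier}{one feature (the spec's `outlierIndex`)
#'     multiplied by `outlierFactor`.}
#'   \item{random}{intensities of both members drawn independently from the
#'     intensity law -- unrelated patterns.}
#' }
#'
#' @param spec a [SyntheticSpec-class].
#' @param mode one of `"identical"`, `"scaled"`, `"noisy"`,
#'   `"single_outlier"`, `"random"`.
#' @return list with `a`, `b` (the two [ChemicalFingerprint-class]s) and
#'   `truth` (mode plus the drawn constant / perturbed index, for
#'   ground-truth checks).
#' @export
genPair <- function(spec, mode = c("identical", "scaled", "noisy",
                                   "single_outlier", "random")) {
    stopifnot(is(spec, "SyntheticSpec"))
    mode <- match.arg(mode)
    if (mode == "single_outlier" && is.na(spec@outlierIndex))
        .usageError("single_outlier mode requires spec outlierIndex")
    a <- genFingerprint(spec, batchId = "REF")
    intsA <- a@features$intensity
    truth <- list(mode = mode, constant = NA_real_,
                  outlierIndex = NA_integer_,
                  outlierFactor = NA_real_)
    intsB <- .withStream(spec@seed, paste0("pair/", mode), switch(mode,
        identical = intsA,
        scaled = {
            truth$constant <- 10^stats::runif(1, -0.5, 0.5)
            intsA * truth$constant
        },
        noisy = intsA * .lnormFactors(.noiseCvs(spec, intsA)),
        single_outlier = {
            truth$outlierIndex <- spec@outlierIndex
            truth$outlierFactor <- spec@outlierFactor
            out <- intsA
            out[spec@outlierIndex] <- out[spec@outlierIndex] * spec@outlierFactor
            out
        },
        random = .drawIntensities(spec@nFeatures, spec@intensityLaw)))
    b <- a
    b@batchId <- "CMP"
    b@features$intensity <- intsB
    list(a = a, b = b, truth = truth)
}

#' Generate replicate gene tables with planted regulated genes
#'
#' Emulates the replicate structure of a bioresponse experiment: `planted`
#' genes carry their true signed fold change with small multiplicative
#' replicate noise (log-normal on the ratio scale), while null genes
#' scatter near fold 1 (log2 ratio normal with sd `nullFoldSd`).
#' Deterministic given the spec's seed.
#'
#' @param spec a [SyntheticSpec-class] (its seed drives the draw).
#' @param nReplicates number of replicates (default 3).
#' @param planted `data.frame` with columns `gene`, `signedFold`
#'   (|fold| >= 1), or `NULL` for a pure-null set.
#' @param nNull number of unregulated background genes (default 50).
#' @param nullFoldSd sd of the null genes' log2 expression ratio
#'   (default 0.1).
#' @param replicateSd sd of the planted genes' replicate noise on the log
#'   ratio scale (default 0.05).
#' @param batchId character(1).
#' @return A [GeneReplicateSet-class].
#' @export
genReplicateGeneTables <- function(spec, nReplicates = 3L, planted = NULL,
                                   nNull = 50L, nullFoldSd = 0.1,
                                   replicateSd = 0.05, batchId = "SYN") {
    stopifnot(is(spec, "SyntheticSpec"))
    nReplicates <- as.integer(nReplicates)
    if (nReplicates < 1L)
        .usageError("nReplicates must be >= 1")
    if (!is.null(planted)) {
        planted <- as.data.frame(planted, stringsAsFactors = FALSE)
        stopifnot(all(c("gene", "signedFold") %in% colnames(planted)))
    }
    .withStream(spec@seed, "gene-tables", {
        nullGenes <- if (nNull > 0) paste0("null", seq_len(nNull))
                     else character()
        reps <- lapply(seq_len(nReplicates), function(r) {
            ratios <- numeric()
            genes <- character()
            if (!is.null(planted) && nrow(planted)) {
                base <- signedFoldToRatio(planted$signedFold)
                ratios <- base * exp(stats::rnorm(nrow(planted), 0,
                                                  replicateSd))
                genes <- planted$gene
            }
            if (length(nullGenes)) {
                ratios <- c(ratios,
                            2^stats::rnorm(length(nullGenes), 0, nullFoldSd))
                genes <- c(genes, nullGenes)
            }
            data.frame(gene = genes, signedFold = ratioToSignedFold(ratios),
                       stringsAsFactors = FALSE)
        })
        names(reps) <- paste0("r", seq_len(nReplicates))
        geneReplicateSet(reps, batchId = batchId)
    })
}

#' Generate replicate peak tables of one batch
#'
#' Re-injections of one synthetic batch: every replicate shares the base
#' fingerprint's feature ids, with intensities multiplied by independent
#' mean-one log-normal factors of CV `noiseCv` (constant across features,
#' as appropriate for repeat injections of one sample) and (m/z, rt)
#' jittered by the spec's `jitter` standard deviations. Deterministic given
#' the spec's seed; feeds [selectFingerprintPeaks()] and [matchFeatures()]
#' with known ground truth.
#'
#' @param spec a [SyntheticSpec-class].
#' @param nReplicates number of replicate tables, >= 2 (default 3).
#' @param batchId character(1).
#' @return list of [PeakTable-class] objects.
#' @export
genPeakTables <- function(spec, nReplicates = 3L, batchId = "SYN") {
    stopifnot(is(spec, "SyntheticSpec"))
    nReplicates <- as.integer(nReplicates)
    if (nReplicates < 2L)
        .usageError("nReplicates must be >= 2")
    base <- genFingerprint(spec, batchId = batchId)@features
    .withStream(spec@seed, "peak-tables", {
        lapply(seq_len(nReplicates), function(r) {
            n <- nrow(base)
            df <- base
            df$intensity <- base$intensity *
                .lnormFactors(rep(spec@noiseCv, n))
            df$mz <- base$mz + stats::rnorm(n, 0, spec@jitter[1L])
            df$rt <- pmax(0, base$rt + stats::rnorm(n, 0, spec@jitter[2L]))
            peakTable(df, batchId = batchId,
                      replicateId = paste0("r", r), ionMode = "positive")
        })
    })
}

#' Serialize / deserialize a SyntheticSpec as a flat key-value config
#'
#' `writeSyntheticSpec()` writes one `key=value` line per field;
#' `readSyntheticSpec()` reads it back into an identical spec
#' (round-trip safe).
#'
#' @param spec a [SyntheticSpec-class].
#' @param path config file path.
#' @return `writeSyntheticSpec()`: `path`, invisibly;
#'   `readSyntheticSpec()`: a [SyntheticSpec-class].
#' @export
writeSyntheticSpec <- function(spec, path) {
    stopifnot(is(spec, "SyntheticSpec"))
    num <- function(x) paste(format(x, digits = 17), collapse = ",")
    writeLines(c(
        sprintf("n_features=%d", spec@nFeatures),
        sprintf("seed=%d", spec@seed),
        sprintf("intensity_law=%s", spec@intensityLaw),
        sprintf("noise_cv=%s", num(spec@noiseCv)),
        sprintf("noise_model=%s", spec@noiseModel),
        sprintf("outlier_index=%s", ifelse(is.na(spec@outlierIndex), "NA",
                                           spec@outlierIndex)),
        sprintf("outlier_factor=%s", num(spec@outlierFactor)),
        sprintf("mz_range=%s", num(spec@mzRange)),
        sprintf("rt_range=%s", num(spec@rtRange)),
        sprintf("jitter=%s", num(spec@jitter))), path)
    invisible(path)
}

#' @rdname writeSyntheticSpec
#' @export
readSyntheticSpec <- function(path) {
    if (!file.exists(path))
        .usageError("config file not found: %s", path)
    kv <- strsplit(trimws(readLines(path, warn = FALSE)), "=", fixed = TRUE)
    kv <- Filter(function(x) length(x) == 2L, kv)
    cfg <- stats::setNames(vapply(kv, `[[`, "", 2L),
                           vapply(kv, `[[`, "", 1L))
    nums <- function(key) as.numeric(strsplit(cfg[[key]], ",")[[1L]])
    syntheticSpec(
        nFeatures = as.integer(cfg[["n_features"]]),
        seed = as.integer(cfg[["seed"]]),
        intensityLaw = cfg[["intensity_law"]],
        noiseCv = nums("noise_cv"),
        noiseModel = cfg[["noise_model"]],
        outlierIndex = if (cfg[["outlier_index"]] == "NA") NA
                       else as.integer(cfg[["outlier_index"]]),
        outlierFactor = nums("outlier_factor"),
        mzRange = nums("mz_range"),
        rtRange = nums("rt_range"),
        jitter = nums("jitter"))
}

#' Generate an ensemble of noisy batches around one reference
#'
#' One reference fingerprint plus `nBatches` candidate batches, each the
#' reference perturbed by an independent draw of the spec's noise model --
#' the multi-vendor comparison scenario in which many production batches
#' are scored against one clinical reference. Deterministic given the
#' spec's seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @param nBatches number of candidate batches (default 18).
#' @return list with `reference` (a [ChemicalFingerprint-class]) and
#'   `batches` (a list of fingerprints labelled `B1..Bn`).
#' @export
genBatchEnsemble <- function(spec, nBatches = 18L) {
    stopifnot(is(spec, "SyntheticSpec"))
    nBatches <- as.integer(nBatches)
    if (nBatches < 1L)
        .usageError("nBatches must be >= 1")
    ref <- genFingerprint(spec, batchId = "REF")
    ints <- ref@features$intensity
    cvs <- .noiseCvs(spec, ints)
    batches <- lapply(seq_len(nBatches), function(k) {
        .withStream(spec@seed, sprintf("ensemble/%d", k), {
            b <- ref
            b@batchId <- paste0("B", k)
            b@features$intensity <- ints * .lnormFactors(cvs)
            b
        })
    })
    list(reference = ref, batches = batches)
}
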