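#' @include AllClasses.R AllGenerics.R utils.R psi.R
NULL

#' Convert signed fold changes to positive expression ratios
#'
#' Signed fold changes follow the usual reporting convention: +f is f-fold
#' up-regulation, -f is f-fold down-regulation versus control, so |f| >= 1.
#' The ratio form (treatment/control) maps +f to f and -f to 1/f, keeping
#' every value strictly positive as the ratio-matrix machinery requires
#' (e.g. a 2.4-fold down-regulated gene becomes 1/2.4 ~ 0.4167).
#'
#' @param signedFold numeric vector, every |value| >= 1.
#' @return positive ratios, same length.
#' @seealso [ratioToSignedFold()] for the inverse.
#' @examples
#' signedFoldToRatio(c(2, -2.4, 1))   # 2, 0.41667, 1
#' @export
signedFoldToRatio <- function(signedFold) {
    signedFold <- as.numeric(signedFold)
    if (any(!is.finite(signedFold)) || any(abs(signedFold) < 1))
        .dataError("signed fold changes must satisfy |fold| >= 1")
    ifelse(signedFold > 0, signedFold, -1 / signedFold)
}

#' Convert positive ratios back to signed fold changes
#'
#' Inverse of [signedFoldToRatio()]: ratios >= 1 map to themselves, ratios
#' < 1 to -1/ratio.
#'
#' @param ratio strictly positive numeric vector.
#' @return signed fold changes with |value| >= 1.
#' @export
ratioToSignedFold <- function(ratio) {
    ratio <- as.numeric(ratio)
    if (any(!is.finite(ratio)) || any(ratio <= 0))
        .dataError("ratios must be finite and > 0")
    ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Genes regulated beyond a fold cutoff in every replicate
#'
#' Intersects the replicates of a [GeneReplicateSet-class]: a gene is
#' retained when |signed fold| >= `foldCutoff` in every replicate that set
#' contains. The retained set shrinks monotonically as the cutoff rises --
#' the behaviour that reduces a few hundred regulated genes to a small
#' reproducible core suitable for a signature panel.
#'
#' @param reps a [GeneReplicateSet-class] with >= 1 non-empty replicates.
#' @param foldCutoff fold-change cutoff, >= 1. Preset values commonly used:
#'   1.5, 1.7, 2.0, 3.0.
#' @return character vector of gene symbols (order of the first replicate).
#' @export
commonRegulatedGenes <- function(reps, foldCutoff = 2.0) {
    stopifnot(is(reps, "GeneReplicateSet"))
    if (foldCutoff < 1)
        .usageError("foldCutoff must be >= 1")
    if (any(vapply(reps@replicates, nrow, 0L) == 0L))
        .dataError("empty replicate in gene set")
    kept <- lapply(reps@replicates, function(df)
        df$gene[abs(df$signedFold) >= foldCutoff])
    common <- Reduce(intersect, kept)
    .log("info", "%d gene(s) pass |fold| >= %.2g in all %d replicate(s)",
         length(common), foldCutoff, length(reps@replicates))
    common
}

#' Build a bioresponse signature panel
#'
#' Assembles a [BioresponsePanel-class] from an ordered gene set and a table
#' of signed fold changes, converting folds to positive expression ratios
#' with [signedFoldToRatio()]. Panels compared with [panelSimilarity()] must
#' share the same genes in the same order, which this constructor fixes.
#'
#' @param genes ordered character vector of signature genes (unique,
#'   non-empty).
#' @param measurements `data.frame` with columns `gene`, `signedFold`
#'   (e.g. one replicate of a [GeneReplicateSet-class]).
#' @param batchId character(1).
#' @return A [BioresponsePanel-class].
#' @export
buildSignaturePanel <- function(genes, measurements,
                                batchId = NA_character_) {
    genes <- as.character(genes)
    if (!length(genes))
        .usageError("empty gene set")
    if (anyDuplicated(genes))
        .usageError("duplicate gene(s) requested: %s",
                    paste(unique(genes[duplicated(genes)]), collapse = ", "))
    measurements <- as.data.frame(measurements, stringsAsFactors = FALSE)
    v <- .validGeneFrame(measurements)
    if (!isTRUE(v)) .dataError(paste(v, collapse = "; "))
    idx <- match(genes, measurements$gene)
    if (anyNA(idx))
        .dataError("gene(s) missing from measurements: %s",
                   paste(genes[is.na(idx)], collapse = ", "))
    bioresponsePanel(genes,
                     signedFoldToRatio(measurements$signedFold[idx]),
                     batchId = batchId)
}

#' PSI between two bioresponse panels
#'
#' Scores the similarity of two batches' gene-expression signatures by
#' delegating the paired expression ratios to the PSI engine ([psi()]).
#' The panels must contain identical genes in identical order.
#'
#' @param a,b [BioresponsePanel-class] objects with identical gene lists.
#' @param method `"pearson"` or `"spearman"`.
#' @param weighted slope-weighted average? Default `FALSE`.
#' @return A [SimilarityResult-class].
#' @export
setMethod("panelSimilarity", c("BioresponsePanel", "BioresponsePanel"),
    function(a, b, method = c("pearson", "spearman"), weighted = FALSE) {
    if (!identical(a@genes, b@genes)) {
        diff <- union(setdiff(a@genes, b@genes), setdiff(b@genes, a@genes))
        .dataError("panels differ in genes or order; symmetric difference: %s",
                   if (length(diff)) paste(diff, collapse = ", ")
                   else "(same genes, different order)")
    }
    pair <- matchedPair(a@genes, a@ratios, b@ratios,
                        provenance = "by gene symbol")
    psi(pair, method = method, weighted = weighted)
})
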