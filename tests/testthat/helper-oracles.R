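# Independent oracles for the ratio-matrix similarity statistic.
# Deliberately written with explicit loops and textbook formulas, sharing no
# code with the package's vectorised implementation.

# Pearson correlation from centered sums, explicit loops.
pearsonByHand <- function(x, y) {
    n <- length(x)
    mx <- sum(x) / n
    my <- sum(y) / n
    sxy <- sxx <- syy <- 0
    for (k in seq_len(n)) {
        sxy <- sxy + (x[k] - mx) * (y[k] - my)
        sxx <- sxx + (x[k] - mx)^2
        syy <- syy + (y[k] - my)^2
    }
    sxy / sqrt(sxx * syy)
}

# Full ratio-matrix / row-correlation definition, brute force:
# build both N x N ratio matrices element by element, extract row i without
# its diagonal, correlate, average.
bruteForcePsi <- function(a, b) {
    n <- length(a)
    Ma <- matrix(NA_real_, n, n)
    Mb <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (i != j) {
                Ma[i, j] <- a[i] / a[j]
                Mb[i, j] <- b[i] / b[j]
            }
        }
    }
    scores <- numeric(n)
    for (i in seq_len(n)) {
        xa <- Ma[i, !is.na(Ma[i, ])]
        xb <- Mb[i, !is.na(Mb[i, ])]
        scores[i] <- pearsonByHand(xa, xb)
    }
    mean(scores)
}

# Reciprocal-vector leave-one-out closed form: row i of the ratio matrix is
# a_i * (1/a_j), a positive rescaling of the reciprocal vector, so the
# feature-i Pearson score equals cor(1/a[-i], 1/b[-i]).
reciprocalPsi <- function(a, b) {
    n <- length(a)
    scores <- vapply(seq_len(n), function(i)
        stats::cor(1 / a[-i], 1 / b[-i]), numeric(1))
    mean(scores)
}

# positive random intensity vectors for property loops
drawPositive <- function(n, seed) {
    set.seed(seed)
    10^runif(n, 2, 5)
}

toyFingerprint <- function(intensities, ids = NULL, batchId = "T") {
    n <- length(intensities)
    if (is.null(ids)) ids <- paste0("f", seq_len(n))
    chemicalFingerprint(
        data.frame(featureId = ids, mz = 100 + seq_len(n) * 10,
                   rt = seq_len(n), intensity = intensities,
                   stringsAsFactors = FALSE),
        batchId = batchId)
}

toyPeakTable <- function(intensities, ids = NULL, batchId = "T",
                         replicateId = "r1") {
    n <- length(intensities)
    if (is.null(ids)) ids <- paste0("f", seq_len(n))
    peakTable(data.frame(featureId = ids, mz = 100 + seq_len(n) * 10,
                         rt = seq_len(n), intensity = intensities,
                         stringsAsFactors = FALSE),
              batchId = batchId, replicateId = replicateId)
}
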