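# Ratio matrices, per-feature correlations, slope weights, PSI, R, outliers.

test_that("ratio matrix holds values on the diagonal and ratios off it", {
    m <- ratioMatrix(c(1, 2, 4))
    expect_identical(diag(m@mat), c(1, 2, 4))
    expect_equal(m@mat[1, 2], 0.5)
    expect_equal(m@mat[1, 3], 0.25)
    expect_equal(m@mat[3, 1], 4)
    # reciprocal symmetry and the count of independent off-diagonal cells
    off <- m@mat * t(m@mat)
    expect_equal(off[upper.tri(off)], rep(1, 3))

    expect_equal(featureRatioVector(m, 1), c(0.5, 0.25))
    mc <- ratioMatrix(c(2, 2, 2))
    expect_equal(featureRatioVector(mc, 2), c(1, 1))
    for (n in c(4L, 9L)) {
        mr <- ratioMatrix(drawPositive(n, seed = n))
        expect_length(featureRatioVector(mr, n), n - 1L)
    }
})

test_that("ratio matrix rejects short or non-positive input", {
    expect_error(ratioMatrix(c(1, 2)), ">= 3")
    expect_error(ratioMatrix(c(1, -2, 3)), "> 0")
    expect_error(ratioMatrix(c(1, 0, 3)), "> 0")
    m <- ratioMatrix(c(1, 2, 4))
    expect_error(featureRatioVector(m, 0), "index")
    expect_error(featureRatioVector(m, 4), "index")
})

test_that("per-feature correlations are exact for identical and scaled batches", {
    a <- drawPositive(8, seed = 42)
    ma <- ratioMatrix(a)
    expect_identical(featureCorrelations(ma, ma), rep(1, 8))
    # common scaling leaves every ratio unchanged
    mb <- ratioMatrix(3 * a)
    expect_equal(featureCorrelations(ma, mb), rep(1, 8), tolerance = 1e-12)
})

test_that("per-feature correlations match the explicit-loop oracle", {
    a <- c(1, 2, 3, 4)
    b <- c(1, 2, 3, 8)
    ma <- ratioMatrix(a)
    mb <- ratioMatrix(b)
    got <- featureCorrelations(ma, mb, "pearson")
    expected <- vapply(1:4, function(i)
        pearsonByHand(a[i] / a[-i], b[i] / b[-i]), numeric(1))
    expect_equal(got, expected, tolerance = 1e-12)
    expect_error(featureCorrelations(ma, ratioMatrix(drawPositive(5, 1))),
                 "sizes differ")
})

test_that("row and column Spearman scores agree; Pearson columns follow the raw vectors", {
    a <- drawPositive(7, seed = 11)
    b <- drawPositive(7, seed = 12)
    ma <- ratioMatrix(a)
    mb <- ratioMatrix(b)
    # column i is the reciprocal of row i up to a positive factor, so ranks
    # reverse in both batches and the Spearman score is unchanged
    rowScores <- featureCorrelations(ma, mb, "spearman")
    colScores <- vapply(1:7, function(i)
        stats::cor(ma@mat[-i, i], mb@mat[-i, i], method = "spearman"),
        numeric(1))
    expect_equal(rowScores, colScores, tolerance = 1e-9)
    # for Pearson the column score reduces to the leave-one-out raw
    # correlation (column i = a[-i]/a_i), a genuinely different statistic
    colPearson <- vapply(1:7, function(i)
        stats::cor(ma@mat[-i, i], mb@mat[-i, i]), numeric(1))
    expect_equal(colPearson,
                 vapply(1:7, function(i) stats::cor(a[-i], b[-i]),
                        numeric(1)),
                 tolerance = 1e-9)
})

test_that("constant ratio vectors fall back to the documented scores", {
    # all values equal in both batches: every ratio vector is constant 1
    pair <- matchedPair(c("a", "b", "c"), c(2, 2, 2), c(5, 5, 5))
    res <- suppressMessages(psi(pair))
    expect_identical(res@psi, 1)
    # one batch constant, the other not: fallback 0 with a warning message
    ma <- ratioMatrix(c(2, 2, 2))
    mb <- ratioMatrix(c(1, 2, 4))
    expect_message(scores <- featureCorrelations(ma, mb),
                   "constant ratio vector")
    expect_true(all(scores == 0))
})

test_that("slope weights are 1 for identical/scaled batches, small for an outlier", {
    a <- drawPositive(10, seed = 3)
    ma <- ratioMatrix(a)
    expect_identical(slopeWeights(ma, ma), rep(1, 10))
    expect_equal(slopeWeights(ma, ratioMatrix(2 * a)), rep(1, 10),
                 tolerance = 1e-12)
    b <- a
    b[4] <- 10 * a[4]
    w <- slopeWeights(ma, ratioMatrix(b))
    expect_equal(w[4], 0.1, tolerance = 1e-12)
    expect_true(all(w[-4] > 0.9))
    # numeric oracle: per-feature least-squares slope via lm
    sOracle <- vapply(seq_along(a), function(i) {
        xa <- a[i] / a[-i]
        xb <- b[i] / b[-i]
        unname(stats::coef(stats::lm(xb ~ xa))[2])
    }, numeric(1))
    wOracle <- pmin(pmax(pmin(sOracle, 1 / sOracle), 0), 1)
    expect_equal(w, wOracle, tolerance = 1e-9)
})

test_that("PSI is exactly 1 on identity and invariant to common scaling", {
    for (seed in 1:5) {
        a <- drawPositive(12, seed)
        pair <- matchedPair(paste0("f", 1:12), a, a)
        expect_identical(psi(pair)@psi, 1)
        for (const in c(0.1, 2, 1000)) {
            scaled <- matchedPair(paste0("f", 1:12), a, const * a)
            expect_equal(psi(scaled)@psi, 1, tolerance = 1e-9)
            expect_equal(conventionalR(scaled), 1, tolerance = 1e-9)
        }
    }
})

test_that("unweighted PSI is exactly symmetric; weighted PSI symmetric by construction", {
    for (seed in 1:10) {
        a <- drawPositive(9, seed)
        b <- a * rlnorm(9, 0, 0.4)
        ab <- matchedPair(paste0("f", 1:9), a, b)
        ba <- matchedPair(paste0("f", 1:9), b, a)
        expect_identical(psi(ab)@psi, psi(ba)@psi)
        expect_equal(psi(ab, weighted = TRUE)@psi,
                     psi(ba, weighted = TRUE)@psi, tolerance = 1e-12)
    }
})

test_that("PSI is invariant under a shared feature permutation", {
    set.seed(21)
    a <- drawPositive(11, 21)
    b <- a * rlnorm(11, 0, 0.3)
    base <- psi(matchedPair(paste0("f", 1:11), a, b))@psi
    for (k in 1:5) {
        perm <- sample(11)
        p <- psi(matchedPair(paste0("f", perm), a[perm], b[perm]))@psi
        expect_equal(p, base, tolerance = 1e-12)
    }
})

test_that("per-feature scores and PSI stay within [-1, 1] on random input", {
    for (seed in 1:20) {
        set.seed(seed)
        n <- sample(3:25, 1)
        a <- 10^runif(n, 2, 5)
        b <- 10^runif(n, 2, 5)
        res <- psi(matchedPair(paste0("f", seq_len(n)), a, b))
        expect_true(all(abs(res@perFeatureR) <= 1 + 1e-12))
        expect_true(abs(res@psi) <= 1 + 1e-12)
        expect_true(all(res@weights >= 0 & res@weights <= 1))
    }
})

test_that("PSI agrees with the reciprocal-vector closed form", {
    for (seed in 1:10) {
        a <- drawPositive(10, seed)
        b <- drawPositive(10, seed + 100)
        pair <- matchedPair(paste0("f", 1:10), a, b)
        expect_equal(psi(pair)@psi, reciprocalPsi(a, b), tolerance = 1e-10)
    }
})

test_that("conventional R reproduces hand-computed correlations", {
    p <- function(a, b) matchedPair(paste0("f", seq_along(a)), a, b)
    expect_equal(conventionalR(p(1:3, 1:3)), 1)
    expect_equal(conventionalR(p(1:3, 3:1)), -1)
    expect_equal(conventionalR(p(c(1, 2, 3, 4), c(1, 3, 2, 4))), 0.8)
    expect_error(conventionalR(p(c(2, 2, 2), 1:3)), "constant")
    # spearman on ranks
    expect_equal(conventionalR(p(c(1, 2, 3, 4), c(2, 8, 5, 90)),
                               method = "spearman"),
                 stats::cor(1:4, c(1, 3, 2, 4), method = "spearman"))
})

test_that("outlier flagging: none for identical batches, most for random pairs", {
    a <- drawPositive(15, 8)
    resId <- psi(matchedPair(paste0("f", 1:15), a, a))
    expect_length(outlierFeatures(resId, 0.9)$flagged, 0)

    b <- drawPositive(15, 9)
    resRnd <- psi(matchedPair(paste0("f", 1:15), a, b))
    expect_gt(length(suppressMessages(outlierFeatures(resRnd, 0.9))$flagged),
              7)
})

test_that("outlier histogram uses fixed-width bins covering [-1, 1]", {
    a <- drawPositive(10, 5)
    res <- psi(matchedPair(paste0("f", 1:10), a, a))
    out <- outlierFeatures(res, bins = 40)
    h <- out$histogram
    expect_equal(nrow(h), 40)
    expect_equal(h$binLeft[1], -1)
    expect_equal(h$binRight[40], 1)
    expect_equal(diff(h$binLeft), rep(0.05, 39), tolerance = 1e-12)
    expect_equal(sum(h$count), 10)   # every feature lands in a bin
    # identical batches: all scores exactly 1, in the last bin
    expect_equal(h$count[40], 10)
})

test_that("weighted PSI equals the weight-renormalised mean and errors on zero weights", {
    a <- drawPositive(8, 30)
    b <- a * rlnorm(8, 0, 0.2)
    res <- psi(matchedPair(paste0("f", 1:8), a, b), weighted = TRUE)
    expect_equal(res@psi, sum(res@weights * res@perFeatureR) / sum(res@weights),
                 tolerance = 1e-12)
    expect_true(res@weighted)
})
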