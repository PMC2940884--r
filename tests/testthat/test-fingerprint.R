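# Peak normalization, fingerprint selection, TIC coverage, matching,
# linearity.

test_that("base-peak normalization rescales to max 1 and preserves ratios", {
    pt <- toyPeakTable(c(50, 25, 5))
    out <- normalizeToBasePeak(pt)
    expect_equal(unname(intensities(out)), c(1.0, 0.5, 0.1))
    expect_identical(peaks(out)$featureId, peaks(pt)$featureId)

    single <- toyPeakTable(7)
    expect_equal(unname(intensities(normalizeToBasePeak(single))), 1)

    set.seed(14)
    rnd <- toyPeakTable(runif(20, 1, 1000))
    nrm <- normalizeToBasePeak(rnd)
    expect_equal(max(intensities(nrm)), 1)
    expect_equal(outer(intensities(nrm), intensities(nrm), "/"),
                 outer(intensities(rnd), intensities(rnd), "/"),
                 tolerance = 1e-12)
    # idempotent
    expect_equal(intensities(normalizeToBasePeak(nrm)), intensities(nrm))

    zero <- toyPeakTable(c(0, 0, 0))
    expect_error(normalizeToBasePeak(zero), "empty spectrum")
})

test_that("fingerprint selection applies presence, intensity and CV rules", {
    # base peak 1000; pass = 1% peak present everywhere with 5% CV;
    # faint = 0.1% of base (below the 0.2% rule); flaky = present in 2/3;
    # wobbly = 50% CV across replicates
    mk <- function(pass, faint, wobbly, withFlaky) {
        ints <- c(base = 1000, pass = pass, faint = faint, wobbly = wobbly)
        ids <- c("base", "pass", "faint", "wobbly")
        if (withFlaky) {
            ints <- c(ints, flaky = 20)
            ids <- c(ids, "flaky")
        }
        toyPeakTable(unname(ints), ids = ids)
    }
    reps <- list(mk(10.0, 1.0, 20, TRUE),
                 mk(10.5, 1.1, 60, TRUE),
                 mk(9.5, 0.9, 140, FALSE))
    fp <- suppressMessages(selectFingerprintPeaks(reps))
    expect_setequal(peaks(fp)$featureId, c("base", "pass"))
    # retained intensity is the across-replicate mean
    expect_equal(intensities(fp)[["pass"]], mean(c(10, 10.5, 9.5)))
    expect_equal(fp@selectionParams$minRelIntensity, 0.002)

    # replicate-order invariance
    fp2 <- suppressMessages(selectFingerprintPeaks(rev(reps)))
    expect_equal(intensities(fp)[sort(names(intensities(fp)))],
                 intensities(fp2)[sort(names(intensities(fp2)))])
})

test_that("selection shrinks monotonically in its thresholds", {
    spec <- syntheticSpec(nFeatures = 25, seed = 17, noiseCv = 0.15)
    reps <- genPeakTables(spec, nReplicates = 3)
    sel <- function(minRel, maxCv) {
        fp <- tryCatch(
            suppressMessages(selectFingerprintPeaks(reps, minRel, maxCv)),
            error = function(e) NULL)
        if (is.null(fp)) character() else peaks(fp)$featureId
    }
    loose <- sel(0.0005, 0.5)
    tighterIntensity <- sel(0.05, 0.5)
    tighterCv <- sel(0.0005, 0.05)
    expect_true(all(tighterIntensity %in% loose))
    expect_true(all(tighterCv %in% loose))
    expect_lt(length(tighterIntensity), length(loose))
})

test_that("selection rejects bad invocations and empty results", {
    reps <- genPeakTables(syntheticSpec(nFeatures = 5, seed = 2), 2)
    expect_error(selectFingerprintPeaks(reps[1]), "at least 2")
    expect_error(selectFingerprintPeaks(reps, minRelIntensity = 0), "0, 1")
    # a vanishing CV ceiling rejects every noisy peak
    expect_error(
        suppressMessages(selectFingerprintPeaks(reps, maxCv = 1e-9)),
        "no quantifiable peaks")
})

test_that("TIC coverage matches hand-computed fractions", {
    pt <- toyPeakTable(c(50, 30, 20), ids = c("a", "b", "c"))
    full <- chemicalFingerprint(peaks(pt))
    expect_equal(ticCoverage(pt, full, threshold = 0), 1.0)
    expect_equal(ticCoverage(pt, full, threshold = 0.5), 1.0)

    firstTwo <- chemicalFingerprint(peaks(pt)[1:2, ])
    expect_equal(ticCoverage(pt, firstTwo, threshold = 0), 0.8)

    pt4 <- toyPeakTable(c(100, 10, 1, 0.5), ids = c("a", "b", "c", "d"))
    fp2 <- chemicalFingerprint(peaks(pt4)[1:2, ])
    # 0.5 falls below 1% of the base peak and leaves the denominator
    expect_equal(ticCoverage(pt4, fp2, threshold = 0.01), 110 / 111)

    # monotone non-decreasing in fingerprint size at fixed threshold
    fp3 <- chemicalFingerprint(peaks(pt4)[1:3, ])
    expect_gte(ticCoverage(pt4, fp3, 0.001), ticCoverage(pt4, fp2, 0.001))

    expect_error(ticCoverage(pt, firstTwo, threshold = 1), "0, 1")
    faint <- chemicalFingerprint(
        data.frame(featureId = "zz", mz = 1, rt = 1, intensity = 2))
    expect_error(ticCoverage(pt, faint, 0), "missing from table")
})

test_that("feature matching by id returns the identity pairing", {
    fp <- toyFingerprint(c(10, 40, 5, 80))
    mp <- matchFeatures(fp, fp)
    expect_equal(nFeatures(mp), 4)
    expect_identical(mp@valuesA, mp@valuesB)
    expect_match(mp@provenance, "feature id")
})

test_that("tolerance matching pairs peaks within both windows", {
    a <- chemicalFingerprint(data.frame(
        featureId = c("a1", "a2", "a3"),
        mz = c(100.000, 200.000, 300.000),
        rt = c(10.0, 20.0, 30.0),
        intensity = c(5, 10, 20)), batchId = "A")
    b <- chemicalFingerprint(data.frame(
        featureId = c("b1", "b2", "b3"),
        mz = c(100.005, 200.002, 300.009),
        rt = c(10.1, 19.8, 30.3),
        intensity = c(6, 11, 19)), batchId = "B")
    mp <- matchFeatures(a, b, mzTol = 0.01, rtTol = 0.5, by = "tolerance")
    expect_equal(nFeatures(mp), 3)
    expect_equal(mp@valuesA, c(5, 10, 20))
    expect_equal(mp@valuesB, c(6, 11, 19))

    # a peak outside the m/z window cannot match
    b2 <- b
    b2@features$mz[1] <- 100.05
    expect_error(
        suppressMessages(matchFeatures(a, b2, mzTol = 0.01, rtTol = 0.5,
                                       by = "tolerance")),
        "insufficient shared pattern")
})

test_that("matching a fingerprint against itself by tolerance is the identity", {
    spec <- syntheticSpec(nFeatures = 20, seed = 5)
    fp <- genFingerprint(spec)
    mp <- matchFeatures(fp, fp, mzTol = 0.01, rtTol = 0.01, by = "tolerance")
    expect_equal(nFeatures(mp), 20)
    expect_identical(mp@valuesA, mp@valuesB)
})

test_that("jittered replicates are fully re-matched when jitter is below tolerance", {
    spec <- syntheticSpec(nFeatures = 30, seed = 9, noiseCv = 0.05,
                          jitter = c(0.001, 0.02))
    tabs <- genPeakTables(spec, nReplicates = 2)
    fa <- chemicalFingerprint(peaks(tabs[[1]]), batchId = "A")
    fb <- chemicalFingerprint(peaks(tabs[[2]]), batchId = "B")
    fb@features$featureId <- paste0("x", fb@features$featureId)
    mp <- matchFeatures(fa, fb, mzTol = 0.01, rtTol = 0.5, by = "tolerance")
    expect_equal(nFeatures(mp), 30)
    # ground truth: key "fk|xfk" for every planted correspondence
    got <- strsplit(featureKeys(mp), "|", fixed = TRUE)
    expect_true(all(vapply(got, function(x)
        identical(x[2], paste0("x", x[1])), TRUE)))
})

test_that("linearity check reproduces known correlations", {
    s <- dilutionSeries(c(0.1, 1, 5, 20), c(0.1, 1, 5, 20) * 103)
    res <- linearityCheck(s, minR = 0.99)
    expect_equal(res$rValue, 1.0)
    expect_true(res$passed)

    rev <- dilutionSeries(1:4, 4:1)
    resRev <- linearityCheck(rev)
    expect_equal(resRev$rValue, -1.0)
    expect_false(resRev$passed)

    mid <- linearityCheck(dilutionSeries(1:4, c(1, 3, 2, 4)), minR = 0.99)
    expect_equal(mid$rValue, 0.8)
    expect_false(mid$passed)

    expect_error(linearityCheck(dilutionSeries(1:3, c(5, 5, 5))),
                 "constant")
})

test_that("domain containers enforce their invariants", {
    expect_error(peakTable(data.frame(featureId = c("a", "a"),
                                      mz = c(1, 2), rt = c(1, 2),
                                      intensity = c(1, 2))),
                 "duplicate")
    expect_error(chemicalFingerprint(data.frame(
        featureId = c("a", "b", "c"), mz = 1:3, rt = 1:3,
        intensity = c(1, 0, 2))), "> 0")
    expect_error(matchedPair(c("a", "b"), c(1, 2), c(1, 2)), ">= 3")
    expect_error(matchedPair(c("a", "b", "c"), c(1, 2, -1), c(1, 2, 3)),
                 "> 0")
    expect_error(dilutionSeries(c(1, 1, 2), 1:3), "strictly increasing")
})
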