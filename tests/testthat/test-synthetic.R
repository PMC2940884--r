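# Seeded generators: determinism, ground truth, stream independence.

test_that("generators are pure functions of their spec", {
    spec <- syntheticSpec(nFeatures = 39, seed = 12)
    expect_identical(genFingerprint(spec), genFingerprint(spec))
    expect_identical(genPair(spec, "noisy"), genPair(spec, "noisy"))
    expect_identical(genPeakTables(spec, 3), genPeakTables(spec, 3))
    planted <- data.frame(gene = "s1", signedFold = 3)
    expect_identical(genReplicateGeneTables(spec, 3, planted),
                     genReplicateGeneTables(spec, 3, planted))
    # different seeds give different draws
    other <- syntheticSpec(nFeatures = 39, seed = 13)
    expect_false(identical(intensities(genFingerprint(spec)),
                           intensities(genFingerprint(other))))
})

test_that("generators leave the caller's RNG stream untouched", {
    set.seed(99)
    before <- .Random.seed
    invisible(genFingerprint(syntheticSpec(seed = 3)))
    invisible(genPair(syntheticSpec(seed = 3), "random"))
    expect_identical(.Random.seed, before)
})

test_that("generated fingerprints satisfy their container invariants", {
    for (seed in c(1, 2, 3)) {
        spec <- syntheticSpec(nFeatures = 39, seed = seed)
        fp <- genFingerprint(spec)
        expect_equal(nFeatures(fp), 39)
        df <- peaks(fp)
        expect_true(all(df$intensity > 0))
        expect_true(all(df$intensity <= 1e5 & df$intensity >= 1e2))
        expect_true(!is.unsorted(df$rt))
        expect_true(all(df$mz >= 100 & df$mz <= 1000))
        expect_identical(df$featureId, paste0("f", 1:39))
        expect_true(validObject(fp))
    }
})

test_that("pair modes implement their documented transforms", {
    spec <- syntheticSpec(nFeatures = 20, seed = 44, outlierIndex = 7,
                          outlierFactor = 10)
    idp <- genPair(spec, "identical")
    expect_identical(intensities(idp$a), intensities(idp$b))

    sc <- genPair(spec, "scaled")
    expect_equal(unname(intensities(sc$b) / intensities(sc$a)),
                 rep(sc$truth$constant, 20), tolerance = 1e-12)
    expect_gt(sc$truth$constant, 0)

    so <- genPair(spec, "single_outlier")
    ratio <- intensities(so$b) / intensities(so$a)
    expect_equal(unname(ratio[7]), 10, tolerance = 1e-12)
    expect_equal(unname(ratio[-7]), rep(1, 19))
    expect_equal(so$truth$outlierIndex, 7)

    rnd <- genPair(spec, "random")
    expect_identical(peaks(rnd$a)$featureId, peaks(rnd$b)$featureId)
    expect_false(identical(intensities(rnd$a), intensities(rnd$b)))

    expect_error(genPair(syntheticSpec(seed = 1), "single_outlier"),
                 "outlierIndex")
})

test_that("counting-model noise perturbs minor peaks more than major ones", {
    spec <- syntheticSpec(nFeatures = 39, seed = 6, noiseCv = 0.03,
                          noiseModel = "counting")
    ## pool relative deviations over several independent pairs
    devSmall <- devBig <- numeric()
    for (s in 1:20) {
        sp <- syntheticSpec(nFeatures = 39, seed = 1000 + s, noiseCv = 0.03)
        pr <- genPair(sp, "noisy")
        ia <- intensities(pr$a)
        dev <- abs(log(intensities(pr$b) / ia))
        small <- ia < stats::median(ia)
        devSmall <- c(devSmall, dev[small])
        devBig <- c(devBig, dev[!small])
    }
    expect_gt(mean(devSmall), 3 * mean(devBig))
})

test_that("noise_cv zero gives identical replicate intensities up to jitter", {
    spec <- syntheticSpec(nFeatures = 10, seed = 8, noiseCv = 0)
    tabs <- genPeakTables(spec, 2)
    expect_equal(unname(intensities(tabs[[1]])),
                 unname(intensities(tabs[[2]])), tolerance = 1e-12)
    expect_false(identical(peaks(tabs[[1]])$mz, peaks(tabs[[2]])$mz))
})

test_that("replicate gene tables plant signal and keep nulls quiet", {
    spec <- syntheticSpec(seed = 3)
    planted <- data.frame(gene = c("a", "b"), signedFold = c(3, -4))
    reps <- genReplicateGeneTables(spec, 3, planted, nNull = 60,
                                   nullFoldSd = 0.1)
    expect_s4_class(reps, "GeneReplicateSet")
    expect_equal(length(reps@replicates), 3)
    got <- suppressMessages(commonRegulatedGenes(reps, 2.0))
    expect_setequal(got, c("a", "b"))
    # a pure-null set yields a (near-)empty intersection at cutoff 1.5
    nullReps <- genReplicateGeneTables(spec, 3, planted = NULL, nNull = 100)
    expect_lte(length(suppressMessages(commonRegulatedGenes(nullReps, 1.5))),
               2)
})

test_that("spec round-trips through its key-value config form", {
    spec <- syntheticSpec(nFeatures = 17, seed = 202, intensityLaw = "uniform",
                          noiseCv = 0.12, noiseModel = "constant",
                          outlierIndex = 5, outlierFactor = 3.5)
    path <- tempfile(fileext = ".cfg")
    writeSyntheticSpec(spec, path)
    back <- readSyntheticSpec(path)
    expect_equal(back, spec)
    # and generators agree on the round-tripped spec
    expect_identical(genFingerprint(spec), genFingerprint(back))
})
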