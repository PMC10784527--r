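test_that("autosomal baseline sums chromosomes 1-22 minus 13/18/21", {
    ones <- chromCountTable(stats::setNames(rep(1L, 22), as.character(1:22)))
    expect_equal(autosomalBaseline(ones), 19L)
    expect_equal(autosomalBaseline(chromCountTable(c(X = 5L))), 0L)
    # generator bookkeeping: Na equals the simulator's own baseline tally
    tab <- simulateCounts(simSpec(nReads = 5e4, calib = shotgunCal,
                                  seed = 2))
    expect_equal(autosomalBaseline(tab),
                 sum(counts(tab)[baselineChromosomes()]))
})

test_that("ratio estimates carry positive pseudocount-based errors", {
    r0 <- ratioEstimate(0, 10000)
    expect_equal(ratioValue(r0), 0)
    expect_gt(ratioSE(r0), 0)
    r <- ratioEstimate(56, 1000)
    expect_equal(ratioValue(r), 0.056)
    expect_error(ratioEstimate(5, 0), "undefined ratio")
    expect_error(ratioEstimate(-1, 10), "non-negative")
})

test_that("delta-method se matches the Monte-Carlo spread of the ratio", {
    # draw (nC, nA) jointly from a binomial split of a fixed total, the
    # regime the delta method approximates
    set.seed(314)
    for (n in c(2000L, 50000L)) {
        p <- 0.056 / 1.056     # X share of X + baseline at two copies
        nC <- rbinom(10000, n, p)
        vals <- nC / (n - nC)
        est <- ratioEstimate(round(n * p), n - round(n * p))
        expect_equal(ratioSE(est), sd(vals), tolerance = 0.05,
                     label = paste("se at n =", n))
    }
})

test_that("copy assignment reproduces reference classifications", {
    cal <- shotgunCal
    # high-coverage Rx 0.033: one X, confident by band, large +z,
    # mosaic-annotated toward two copies with fraction ~0.18
    cc <- assignCopies(ratioEstimate(33000, 1e6), "X", cal)
    expect_equal(kHat(cc), 1L)
    expect_identical(callStatus(cc), "confident")
    expect_gt(zToCentroid(cc), 4)
    expect_equal(cc@mosaicFraction, (0.033 - 0.028) / (0.056 - 0.028),
                 tolerance = 1e-6)
    # Ry 0.0048: two copies of Y
    cy <- assignCopies(ratioEstimate(480, 1e5), "Y", cal)
    expect_equal(kHat(cy), 2L)
    expect_identical(callStatus(cy), "confident")
    # Ry 2.32e-5 at high coverage: zero copies
    cz <- assignCopies(ratioEstimate(23, 990000), "Y", cal)
    expect_equal(kHat(cz), 0L)
    expect_identical(callStatus(cz), "confident")
})

test_that("an exact midpoint between centroids is uncertain, never a copy call", {
    cal <- shotgunCal
    # 42/1000 = 0.042 sits exactly midway between r(1)=0.028 and r(2)=0.056
    cc <- assignCopies(ratioEstimate(42000, 1e6), "X", cal)
    expect_identical(callStatus(cc), "uncertain")
})

test_that("scaling all counts leaves ratios and calls unchanged but shrinks se", {
    base <- simulateCounts(simSpec(xCopies = 2, yCopies = 1, nReads = 2e4,
                                   calib = shotgunCal, seed = 77))
    scaled <- chromCountTable(counts(base) * 10L, sampleId = "scaled")
    k1 <- callKaryotype(base, shotgunCal)
    k2 <- callKaryotype(scaled, shotgunCal)
    expect_equal(ratioValue(k2@rx), ratioValue(k1@rx), tolerance = 1e-12)
    expect_equal(ratioValue(k2@ry), ratioValue(k1@ry), tolerance = 1e-12)
    expect_equal(kHat(k2@xCall), kHat(k1@xCall))
    expect_equal(kHat(k2@yCall), kHat(k1@yCall))
    expect_lt(ratioSE(k2@rx), ratioSE(k1@rx))
})

test_that("simulated karyotypes are recovered consistently at low coverage", {
    recovery <- function(x, y, truth, nReads, seedBase) {
        hits <- 0L
        for (r in 1:100) {
            tab <- simulateCounts(simSpec(xCopies = x, yCopies = y,
                                          nReads = nReads,
                                          calib = shotgunCal,
                                          seed = seedBase + r))
            if (iscn(callKaryotype(tab, shotgunCal)) == truth)
                hits <- hits + 1L
        }
        hits
    }
    # X-copy discrimination holds down to ~0.0001-fold (5,000 reads):
    # the X centroid gap spans ~12 expected reads of separation there
    expect_gte(recovery(2L, 0L, "46,XX", 5000, 1000), 99L)
    expect_gte(recovery(1L, 0L, "45,X0", 5000, 1100), 99L)
    # Y-copy discrimination (1 vs 2 copies ~ 12 vs 23 expected Y reads
    # at 5,000 total) needs more depth; at 100,000 reads all Y-bearing
    # karyotypes separate cleanly
    expect_gte(recovery(1L, 1L, "46,XY", 1e5, 1200), 99L)
    expect_gte(recovery(2L, 1L, "47,XXY", 1e5, 1300), 99L)
    expect_gte(recovery(1L, 2L, "47,XYY", 1e5, 1400), 99L)
})

test_that("different-sex mixtures sit mid-band on both axes and are flagged", {
    flagged <- 0L
    confidentAneuploid <- 0L
    for (r in 1:50) {
        tab <- simulateCounts(simSpec(
            xCopies = 1, yCopies = 1, nReads = 1e5, calib = shotgunCal,
            seed = 2000 + r,
            contaminant = list(xCopies = 2, yCopies = 0,
                               fraction = runif(1, 0.3, 0.7))))
        kc <- callKaryotype(tab, shotgunCal)
        if ("contamination_suspect" %in% callFlags(kc)) flagged <- flagged + 1L
        if (iscn(kc) %in% c("47,XXY", "47,XYY", "45,X0", "47,XXX"))
            confidentAneuploid <- confidentAneuploid + 1L
    }
    expect_gte(flagged, 48L)
    expect_equal(confidentAneuploid, 0L)
    # pure aneuploidies and euploids are never contamination-flagged
    for (k in list(c(2, 1), c(1, 1))) {
        tab <- simulateCounts(simSpec(xCopies = k[1], yCopies = k[2],
                                      nReads = 1e5, calib = shotgunCal,
                                      seed = 31))
        expect_false("contamination_suspect" %in%
                     callFlags(callKaryotype(tab, shotgunCal)))
    }
})

test_that("mosaic candidacy requires a large deviation toward an adjacent centroid", {
    cal <- shotgunCal
    atCentroid <- assignCopies(ratioEstimate(2800, 1e5), "X", cal)
    expect_true(is.na(atCentroid@mosaicFraction))
    lowZ <- assignCopies(ratioEstimate(30, 1000), "X", cal)  # z ~ 0.4
    expect_lt(abs(zToCentroid(lowZ)), 4)
    expect_false(mosaicCandidate(lowZ, cal)$candidate)
    # a 45,X0/46,XX-style intermediate at deep coverage
    mosaic <- assignCopies(ratioEstimate(33000, 1e6), "X", cal)
    mc <- mosaicCandidate(mosaic, cal)
    expect_true(mc$candidate)
    expect_equal(mc$fraction, 5 / 28, tolerance = 0.01)
})

test_that("cohort z-scores use the n-1 standard deviation", {
    expect_equal(cohortZ(3, c(0, 2)), 2 / sqrt(2), tolerance = 1e-12)
    expect_equal(cohortZ(5, c(4, 5, 6)), 0)
    expect_error(cohortZ(1, c(2, 2)), "zero")
    expect_error(cohortZ(1, 3), "at least 2")
    # construction: a value planted 5 sd above a simulated XY cohort
    set.seed(9)
    rx <- replicate(375, {
        tab <- simulateCounts(simSpec(xCopies = 1, yCopies = 1,
                                      nReads = 2e4, calib = shotgunCal,
                                      seed = sample.int(1e6, 1)))
        counts(tab)[["X"]] / autosomalBaseline(tab)
    })
    expect_equal(cohortZ(mean(rx) + 5 * sd(rx), rx), 5, tolerance = 1e-9)
})

test_that("an empty table yields a no-call, not an error", {
    empty <- chromCountTable(c(X = 0L))
    kc <- callKaryotype(empty, shotgunCal)
    expect_identical(iscn(kc), "NA")
    expect_true("no_call" %in% callFlags(kc))
    low <- chromCountTable(stats::setNames(rep(10L, 22), as.character(1:22)))
    expect_true("low_count" %in% callFlags(callKaryotype(low, shotgunCal)))
})
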