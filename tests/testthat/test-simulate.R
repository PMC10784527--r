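test_that("simulation is seed-deterministic and conserves the read total", {
    sp <- simSpec(xCopies = 2, yCopies = 1, nReads = 12345,
                  calib = shotgunCal, seed = 99)
    t1 <- simulateCounts(sp)
    t2 <- simulateCounts(sp)
    expect_identical(counts(t1), counts(t2))
    expect_equal(nTotal(t1), 12345L)
    # serialized TSVs are byte-identical
    dir <- withr::local_tempdir()
    p1 <- file.path(dir, "a.tsv"); p2 <- file.path(dir, "b.tsv")
    writeCountTable(t1, p1); writeCountTable(t2, p2)
    expect_identical(readLines(p1), readLines(p2))
    # a different seed changes the draw
    sp2 <- sp; sp2@seed <- 100L
    expect_false(identical(counts(simulateCounts(sp2)), counts(t1)))
})

test_that("simulated ratios match their closed-form expectations", {
    # pure karyotypes: Rx/Ry land within 3 Monte-Carlo SE of the centroids
    sp <- simSpec(xCopies = 2, yCopies = 0, nReads = 1e6,
                  calib = shotgunCal, seed = 5)
    tab <- simulateCounts(sp)
    rx <- counts(tab)[["X"]] / autosomalBaseline(tab)
    se <- ratioSE(ratioEstimate(counts(tab)[["X"]], autosomalBaseline(tab)))
    expect_lt(abs(rx - 0.056), 3 * se)

    spY <- simSpec(xCopies = 1, yCopies = 1, nReads = 1e6,
                   calib = shotgunCal, seed = 6)
    tabY <- simulateCounts(spY)
    ry <- counts(tabY)[["Y"]] / autosomalBaseline(tabY)
    seY <- ratioSE(ratioEstimate(counts(tabY)[["Y"]],
                                 autosomalBaseline(tabY)))
    expect_lt(abs(ry - 0.0026), 3 * seY)

    # 50:50 XX/XY mixture: expectations are the centroid midpoints
    spM <- simSpec(xCopies = 2, yCopies = 0, nReads = 1e6,
                   calib = shotgunCal, seed = 7,
                   contaminant = list(xCopies = 1, yCopies = 1,
                                      fraction = 0.5))
    exp <- expectedRatios(spM)
    expect_equal(exp$Rx, (0.056 + 0.028) / 2, tolerance = 1e-12)
    expect_equal(exp$Ry, 0.0026 / 2, tolerance = 1e-12)
    tabM <- simulateCounts(spM)
    rxM <- counts(tabM)[["X"]] / autosomalBaseline(tabM)
    seM <- ratioSE(ratioEstimate(counts(tabM)[["X"]],
                                 autosomalBaseline(tabM)))
    expect_lt(abs(rxM - exp$Rx), 3 * seM)
})

test_that("empirical cell frequencies converge to the multinomial probabilities", {
    sp <- simSpec(xCopies = 1, yCopies = 1, trisomies = "18",
                  nReads = 2000, calib = shotgunCal, seed = 1)
    p <- expectedRatios(sp)$p
    reps <- 2000L
    tot <- numeric(24)
    for (r in seq_len(reps)) {
        sp@seed <- r
        tot <- tot + counts(simulateCounts(sp))
    }
    phat <- tot / (2000 * reps)
    mcse <- sqrt(p * (1 - p) / (2000 * reps))
    expect_true(all(abs(phat - p) < 4 * mcse + 1e-12))
})

test_that("thinning preserves identity at 1, binomial moments below 1", {
    tab <- chromCountTable(c(X = 10000L, `1` = 10000L), sampleId = "t")
    expect_identical(counts(thinCounts(tab, 1, seed = 3)), counts(tab))
    expect_error(thinCounts(tab, 0), "fraction")
    expect_error(thinCounts(tab, 1.5), "fraction")
    draws <- vapply(1:400, function(s)
        counts(thinCounts(tab, 0.5, seed = s))[["X"]], numeric(1))
    expect_equal(mean(draws), 5000, tolerance = 0.01)
    expect_equal(sd(draws), 50, tolerance = 0.15)
})

test_that("count-level thinning matches a per-read retention oracle", {
    # oracle: expand the table to labelled reads, keep each independently
    tab <- chromCountTable(c(X = 2000L, `1` = 3000L, Y = 500L))
    reads <- rep(c("X", "1", "Y"), times = c(2000L, 3000L, 500L))
    f <- 0.3
    set.seed(123)
    oracle <- vapply(1:1000, function(i)
        sum(reads[runif(length(reads)) < f] == "X"), numeric(1))
    thinned <- vapply(1:1000, function(s)
        counts(thinCounts(tab, f, seed = 10000 + s))[["X"]], numeric(1))
    ks <- suppressWarnings(stats::ks.test(oracle, thinned))
    expect_gt(ks$p.value, 0.01)
})

test_that("thinning composes: f1 then f2 has the moments of f1*f2", {
    tab <- chromCountTable(c(`2` = 50000L))
    two_step <- vapply(1:500, function(s)
        counts(thinCounts(thinCounts(tab, 0.4, seed = s), 0.5,
                          seed = 70000 + s))[["2"]], numeric(1))
    one_step <- vapply(1:500, function(s)
        counts(thinCounts(tab, 0.2, seed = 140000 + s))[["2"]], numeric(1))
    expect_equal(mean(two_step), mean(one_step), tolerance = 0.01)
    expect_equal(sd(two_step), sd(one_step), tolerance = 0.15)
})

test_that("coverage converts to reads via genome size over fragment length", {
    expect_equal(coverageToReads(1e-4), 5167L)
    expect_equal(coverageToReads(1, genomeSize = 6e6, readLength = 100),
                 60000L)
    expect_error(coverageToReads(0), "fold")
})

test_that("the power experiment recovers truth per level and tracks variability", {
    sp <- simSpec(xCopies = 1, yCopies = 0, nReads = 5e5,
                  calib = shotgunCal, seed = 50)
    pr <- powerExperiment(sp, levels = c(1, 0.1, 0.01), replicates = 20,
                          calib = shotgunCal, seed = 50)
    s <- powerSummary(pr)
    expect_equal(nrow(powerReplicates(pr)), 60L)
    expect_equal(s$replicates, rep(20L, 3))
    expect_true(all(s$concordance >= 0.95))
    # Rx spread grows as coverage falls (levels sorted descending)
    expect_true(all(diff(s$Rx_sd) > 0))
    # reproducible under the same root seed, replicate-independent streams
    pr2 <- powerExperiment(sp, levels = c(1, 0.1, 0.01), replicates = 20,
                           calib = shotgunCal, seed = 50)
    expect_identical(powerReplicates(pr), powerReplicates(pr2))
})

test_that("a single full-level replicate on a fixed table reproduces its direct call", {
    tab <- simulateCounts(simSpec(xCopies = 2, yCopies = 1, nReads = 1e5,
                                  calib = shotgunCal, seed = 123))
    pr <- powerExperiment(tab, levels = 1, replicates = 1,
                          calib = shotgunCal, seed = 1)
    rep1 <- powerReplicates(pr)
    direct <- callKaryotype(tab, shotgunCal)
    expect_equal(rep1$x_call, kHat(direct@xCall))
    expect_equal(rep1$y_call, kHat(direct@yCall))
    expect_equal(rep1$Rx, ratioValue(direct@rx))
    expect_true(rep1$correct)
})
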