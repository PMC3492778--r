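test_that("all generators are bit-reproducible under a fixed seed", {
    pm <- PreferenceModel(s = 0.3, nTrials = 200, seed = 5)
    expect_identical(simMatingTrials(pm), simMatingTrials(pm))
    pr <- profileModelFor("ST", nFlies = 5, seed = 5)
    expect_identical(simPeakTables(pr), simPeakTables(pr))
    mm <- MortalityModel(6.4, n0 = 50, seed = 5)
    expect_identical(simDesiccation(mm), simDesiccation(mm))
    # distinct seeds give distinct draws
    expect_false(identical(
        matingCounts(simMatingTrials(PreferenceModel(s = 0.3, nTrials = 200, seed = 6))),
        matingCounts(simMatingTrials(pm))))
    # generators leave the caller's RNG stream alone
    set.seed(42); before <- .Random.seed
    invisible(simMatingTrials(pm)); invisible(simPeakTables(pr))
    expect_identical(.Random.seed, before)
})

test_that("random mating (s = 0) yields a near-zero isolation index", {
    tab <- simMatingTrials(PreferenceModel(s = 0, pNoMating = 0,
                                           nTrials = 10000, seed = 19))
    expect_equal(nReplicates(tab), 10000L)
    expect_equal(nNoMating(tab), 0L)
    # 3 Monte-Carlo SEs: SD(ipsi) ~ 1/sqrt(T)
    expect_lt(abs(ipsi(tab)), 3 / sqrt(10000))
})

test_that("extreme homotypic advantage gives a nearly diagonal table", {
    tab <- simMatingTrials(PreferenceModel(s = 1 - 1e-6, nTrials = 2000,
                                           seed = 23))
    off <- matingCounts(tab)[1, 2] + matingCounts(tab)[2, 1]
    expect_lte(off, 1)
    expect_gt(ipsi(tab), 0.99)
})

test_that("the estimator recovers the generating isolation parameter", {
    # multiple-choice homotypic advantage: E[ipsi] = s analytically
    means <- sapply(c(0, 0.2, 0.4, 0.6), function(s)
        mean(sapply(1:200, function(i)
            ipsi(simMatingTrials(PreferenceModel(s = s, nTrials = 500,
                                                 seed = 3000 + 200 * s * 10 + i))))))
    expect_lt(abs(means[1] - 0), 0.05)
    expect_lt(abs(means[3] - 0.4), 0.05)
    # monotone in s with perfect rank agreement across the grid
    expect_identical(order(means), 1:4)
})

test_that("choice designs keep the designed margins balanced", {
    tab <- simMatingTrials(PreferenceModel(s = 0.4, design = "male_choice",
                                           pNoMating = 0, nTrials = 400,
                                           seed = 31))
    # the tested male's strain alternates, so column sums are exactly n/2
    expect_equal(unname(colSums(matingCounts(tab))), c(200, 200))
    tabF <- simMatingTrials(PreferenceModel(s = 0.4, design = "female_choice",
                                            pNoMating = 0, nTrials = 400,
                                            seed = 31))
    expect_equal(unname(rowSums(matingCounts(tabF))), c(200, 200))
    # non-mating trials are tallied, not lost
    tabN <- simMatingTrials(PreferenceModel(s = 0, pNoMating = 0.2,
                                            nTrials = 1000, seed = 7))
    expect_equal(sum(matingCounts(tabN)) + nNoMating(tabN), 1000)
    expect_gt(nNoMating(tabN), 100)
})

test_that("PSI deviations from 1 shrink as 1/sqrt(T)", {
    dev <- sapply(c(100, 10000), function(n) {
        mean(sapply(1:30, function(i) {
            tab <- simMatingTrials(PreferenceModel(s = 0, pNoMating = 0,
                                                   nTrials = n, seed = 500 + i))
            mean(abs(psiCoefficients(tab) - 1))
        }))
    })
    # T grows 100-fold, deviation should drop ~10-fold
    expect_gt(dev[1] / dev[2], 5)
    expect_lt(dev[1] / dev[2], 20)
})

test_that("a huge Dirichlet concentration collapses to the mean composition", {
    pm <- ProfileModel(panel = paste0("hc", 1:5),
                       meanProportions = c(0.4, 0.3, 0.15, 0.1, 0.05),
                       concentration = 1e8, totalMeanNg = 1000,
                       totalCV = 0.1, nFlies = 5, seed = 3)
    p <- hcProportions(quantifyHC(simPeakTables(pm)))
    expect_lt(max(abs(p - c(0.4, 0.3, 0.15, 0.1, 0.05))), 1e-3)
})

test_that("calibrated profile models reproduce the group summaries they target", {
    # Eg males: mean total over many flies within 2 SEM of the 1577 ng target
    pm <- profileModelFor("Eg", nFlies = 500, seed = 11)
    tot <- totalHC(quantifyHC(simPeakTables(pm)))
    sem <- sd(tot) / sqrt(length(tot))
    expect_lt(abs(mean(tot) - 1577), 2 * sem + 1)   # +1 ng numerical slack
    # the 7-T/7-P phenotype separates simulated Eg from Cam in >= 99% of groups
    ratios <- function(strain, seeds) sapply(seeds, function(s) {
        prof <- quantifyHC(simPeakTables(profileModelFor(strain, nFlies = 10,
                                                         seed = s)))
        mean(phenoRatio(prof))
    })
    rEg <- ratios("Eg", 1:100); rCam <- ratios("Cam", 101:200)
    expect_gte(mean(rEg > 1), 0.99)
    expect_gte(mean(rCam < 1), 0.99)
})

test_that("death-time generator matches its stated median and scales", {
    # binning preserves the Weibull median on average
    est <- sapply(1:100, function(i)
        msdHours(msd(simDesiccation(MortalityModel(6.4, n0 = 100, seed = i)))))
    expect_lt(abs(mean(est) - 6.4), 0.5)
    # empirical survival at the median is about one half
    rec <- simDesiccation(MortalityModel(6.4, n0 = 10000, seed = 9))
    sc <- survivalCurve(rec)
    expect_lt(abs(sc$survival[which.min(abs(sc$time_h - 6.4))] - 0.5), 0.05)
    # scale equivariance: doubling the median doubles the estimate
    est2 <- sapply(1:50, function(i)
        msdHours(msd(simDesiccation(MortalityModel(12.8, n0 = 100, seed = i)))))
    expect_lt(abs(mean(est2) / mean(est[1:50]) - 2), 0.1)
    # a near-degenerate shape puts every death at the median's interval
    sharp <- simDesiccation(MortalityModel(6.4, shape = 1e3, n0 = 100, seed = 4))
    expect_equal(sum(sharp@deaths > 0), 1)
    expect_equal(which(sharp@deaths > 0) * 0.5, 6.5)
})
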