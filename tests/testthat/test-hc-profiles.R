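makePT <- function(areas, std = 200, stdMass = 500) {
    n <- ncol(areas)
    PeakTable(areas,
              data.frame(sex = rep("male", n), strain = rep("X", n),
                         temperature_C = rep(25, n),
                         std_area = rep(std, n)),
              stdMassNg = stdMass)
}

test_that("internal-standard quantification follows the area ratio rule", {
    one <- makePT(matrix(100, 1, 1, dimnames = list("hcA", "f1")),
                  std = 100)
    prof <- quantifyHC(one)
    expect_equal(as.numeric(hcAmounts(prof)), 500)
    expect_equal(as.numeric(hcProportions(prof)), 1)

    two <- makePT(matrix(c(300, 100), 2, 1,
                         dimnames = list(c("hcA", "hcB"), "f1")))
    prof2 <- quantifyHC(two)
    expect_equal(as.numeric(hcAmounts(prof2)), c(750, 250))
    expect_equal(as.numeric(hcProportions(prof2)), c(0.75, 0.25))
    expect_equal(unname(totalHC(prof2)), 1000)
})

test_that("quantification is homogeneous in the peak areas", {
    set.seed(8)
    areas <- matrix(rexp(5 * 4, 1 / 100), 5, 4,
                    dimnames = list(paste0("hc", 1:5), paste0("f", 1:4)))
    base <- quantifyHC(makePT(areas))
    # scaling everything (standard included) changes nothing
    allScaled <- quantifyHC(makePT(areas * 3, std = 600))
    expect_equal(hcAmounts(allScaled), hcAmounts(base))
    expect_equal(hcProportions(allScaled), hcProportions(base))
    # scaling only the hydrocarbons scales ng, leaves proportions alone
    hcScaled <- quantifyHC(makePT(areas * 3))
    expect_equal(hcAmounts(hcScaled), hcAmounts(base) * 3)
    expect_equal(hcProportions(hcScaled), hcProportions(base))
})

test_that("invalid peak tables are rejected with informative errors", {
    expect_error(PeakTable(matrix(1, 1, 1, dimnames = list("mystery", "f1")),
                           data.frame(sex = "male", strain = "X",
                                      temperature_C = 25, std_area = 1),
                           panel = data.frame(name = "hcA", class = NA)),
                 "not in the declared panel")
    expect_error(makePT(matrix(c(1, 1), 1, 2,
                               dimnames = list("hcA", c("f1", "f2"))),
                        std = 0),
                 "must be positive")
})

test_that("log-contrasts match closed forms and invert exactly", {
    p <- c(a = 0.5, b = 0.25, c = 0.25)
    lc <- logContrast(p, denominator = "c")
    expect_equal(unname(lc), c(log10(2), 0))
    expect_equal(names(lc), c("a", "b"))
    expect_equal(unname(logContrast(c(a = 1, b = 1, c = 1) / 3, "b")), c(0, 0))
    # Eg-male worked value: log10(52.01 / 2.08)
    m <- hcStrainMeans("male")
    lcEg <- logContrast(m$mean[, "Eg"] / 100, denominator = "(Z)-5-C23:1")
    expect_equal(unname(lcEg["(Z)-7-C23:1"]), 1.398, tolerance = 5e-4)
    # round trip: exponentiation recovers proportion ratios to 1e-12
    set.seed(13)
    q <- rgamma(8, 2); q <- setNames(q / sum(q), paste0("hc", 1:8))
    back <- 10^logContrast(q, "hc8")
    expect_equal(back, (q / q[["hc8"]])[names(back)], tolerance = 1e-12)
})

test_that("denominator choice only shifts log-contrasts", {
    set.seed(14)
    q <- rgamma(6, 2); q <- setNames(q / sum(q), paste0("hc", 1:6))
    # differences between two hydrocarbons are denominator-invariant
    ref <- logContrast(q, "hc1")[["hc2"]] - logContrast(q, "hc1")[["hc3"]]
    for (den in paste0("hc", 4:6)) {
        lc <- logContrast(q, den)
        expect_equal(lc[["hc2"]] - lc[["hc3"]], ref)
    }
})

test_that("compositional zeros follow the declared policy", {
    p <- c(a = 0.5, b = 0.5, c = 0)
    expect_error(logContrast(p, "a"), "compositional zero\\(s\\) in: c")
    lc <- logContrast(p, "a", zeroPolicy = "replace")
    expect_true(is.finite(lc[["c"]]))
    expect_error(logContrast(p, "zz"), "not in the panel")
})

test_that("arcsine-square-root transform is the textbook map", {
    expect_equal(arcsineSqrt(c(0, 0.5, 1)), c(0, pi / 4, pi / 2))
    expect_equal(arcsineSqrt(0.2001), 0.46377, tolerance = 1e-4)
    expect_error(arcsineSqrt(1.2), "\\[0, 1\\]")
    # monotone
    p <- seq(0, 1, by = 0.05)
    expect_true(all(diff(arcsineSqrt(p)) > 0))
})

test_that("per-HC ANOVA flags only truly shifted hydrocarbons", {
    # the unit-sum constraint couples raw proportions, so a clean
    # single-component shift is constructed in log-contrast space: per fly,
    # log10 ratios to a reference peak are normal, and one group's "hit"
    # ratio is displaced by 5 x its SD
    set.seed(31)
    n <- 10
    mk <- function(shift) {
        lcHit <- rnorm(n, 0.3 + shift, 0.04)   # shift in log10 units
        lcNull <- rnorm(n, -0.2, 0.04)
        areas <- rbind(hit = 10^lcHit, null1 = 10^lcNull, den = 1) * 100
        areas
    }
    a1 <- mk(0); a2 <- mk(5 * 0.04)
    colnames(a1) <- paste0("g1_", 1:n); colnames(a2) <- paste0("g2_", 1:n)
    pt <- PeakTable(cbind(a1, a2),
                    data.frame(sex = "male",
                               strain = rep(c("g1", "g2"), each = n),
                               temperature_C = 25, std_area = 1))
    prof <- quantifyHC(pt)
    res <- comparisonResults(compareGroups(prof, transform = "log_contrast",
                                           denominator = "den"))
    expect_lt(res$p[res$hc == "hit"], 0.001)
    expect_gt(res$p[res$hc == "null1"], 0.001)
    expect_equal(res$stars[res$hc == "hit"], "***")
    # the permutation oracle agrees on the shifted log-contrast
    lc <- logContrast(prof, "den")
    g <- flyData(prof)$strain
    expect_lt(permutationP(lc["hit", ], g), 0.01)
    expect_gt(permutationP(lc["null1", ], g), 0.001)
})

test_that("identical flies give F = 0 and p = 1 for every hydrocarbon", {
    a <- matrix(rep(c(10, 20, 70), 12), 3, 12,
                dimnames = list(c("x", "y", "z"), paste0("f", 1:12)))
    pt <- PeakTable(a, data.frame(sex = "male",
                                  strain = rep(c("a", "b", "c"), each = 4),
                                  temperature_C = 25, std_area = 1))
    res <- comparisonResults(compareGroups(quantifyHC(pt)))
    expect_true(all(res$F == 0))
    expect_true(all(res$p == 1))
    # under-replicated groups are refused
    tiny <- PeakTable(a[, 1:5], data.frame(sex = "male",
                                           strain = c("a", "a", "a", "b", "b"),
                                           temperature_C = 25, std_area = 1))
    expect_error(compareGroups(quantifyHC(tiny)), "insufficient replication")
})

test_that("phenotype ratios and percent differences match hand arithmetic", {
    m <- hcStrainMeans("male")
    expect_equal(phenoRatio(m$mean[, "ST"]), 0.591, tolerance = 1e-3)
    expect_equal(phenoRatio(m$mean[, "Eg"]), 12.75, tolerance = 1e-3)
    expect_equal(phenoRatio(c(`(Z)-7-C23:1` = 3, `(Z)-7-C25:1` = 3)), 1)
    expect_error(phenoRatio(c(`(Z)-7-C23:1` = 3)), "missing from the panel")
    # the 7-T/7-P cline: Eg > ST > Cam
    r <- sapply(m$strains, function(s) phenoRatio(m$mean[, s]))
    expect_true(r["Eg"] > r["ST"] && r["ST"] > r["Cam"])

    expect_equal(percentDifference(1577, 1128), 28.5, tolerance = 1e-2)
    expect_equal(percentDifference(10, 10), 0)
    expect_equal(percentDifference(2141, 3044), -42.2, tolerance = 1e-2)
    expect_error(percentDifference(0, 5), "positive")
})

test_that("arcsine and raw-proportion ANOVA agree on exactly null data", {
    set.seed(77)
    rejA <- rejR <- logical(400)
    for (i in seq_len(400)) {
        p <- matrix(rbeta(30, 5, 15), 1, 30,
                    dimnames = list("hc", NULL))
        g <- factor(rep(c("a", "b", "c"), each = 10))
        rejA[i] <- oneway.test(asin(sqrt(p[1, ])) ~ g, var.equal = TRUE)$p.value < 0.05
        rejR[i] <- oneway.test(p[1, ] ~ g, var.equal = TRUE)$p.value < 0.05
    }
    expect_lt(abs(mean(rejA) - 0.05), 0.03)
    expect_lt(abs(mean(rejR) - 0.05), 0.03)
})
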