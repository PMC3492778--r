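## Independent oracles, written from first principles and kept free of the
## package's internal code paths.

# Joint isolation index computed step by step with explicit loops: build the
# expectation from the margins, take observed/expected ratios, contrast
# homotypic vs heterotypic.
oracleIpsi <- function(counts) {
    o <- matrix(counts, 2, 2, byrow = TRUE)
    total <- 0
    for (i in 1:2) for (j in 1:2) total <- total + o[i, j]
    r <- c(o[1, 1] + o[1, 2], o[2, 1] + o[2, 2])
    cc <- c(o[1, 1] + o[2, 1], o[1, 2] + o[2, 2])
    psi <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) psi[i, j] <- o[i, j] / (r[i] * cc[j] / total)
    num <- psi[1, 1] + psi[2, 2] - psi[1, 2] - psi[2, 1]
    den <- psi[1, 1] + psi[1, 2] + psi[2, 1] + psi[2, 2]
    num / den
}

# All 2x2 count tables with total exactly T and strictly positive margins,
# as rows (AA, AB, BA, BB).
allTables <- function(total) {
    g <- expand.grid(a = 0:total, b = 0:total, c = 0:total)
    g <- g[g$a + g$b + g$c <= total, ]
    g$d <- total - g$a - g$b - g$c
    ok <- (g$a + g$b) > 0 & (g$c + g$d) > 0 & (g$a + g$c) > 0 & (g$b + g$d) > 0
    as.matrix(g[ok, c("a", "b", "c", "d")])
}

# Permutation p-value for a location difference across groups, using the
# between-group sum of squared mean deviations as the statistic.
permutationP <- function(y, g, nPerm = 499, seed = 99) {
    stat <- function(y) {
        m <- tapply(y, g, mean)
        n <- tapply(y, g, length)
        sum(n * (m - mean(y))^2)
    }
    obs <- stat(y)
    set.seed(seed)
    perm <- replicate(nPerm, stat(sample(y)))
    (1 + sum(perm >= obs)) / (nPerm + 1)
}

# A quick MatingTable builder.
mt <- function(counts, design = "multiple_choice", strains = c("A", "B"),
               nReplicates = 0L) {
    MatingTable(counts, design = design, strains = strains,
                nReplicates = nReplicates)
}
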