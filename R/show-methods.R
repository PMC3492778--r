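## Compact show() methods.

setMethod("show", "MatingTable", function(object) {
    cat(sprintf("MatingTable (%s), strains %s (female first)\n",
                object@design, paste(rownames(object@counts), collapse = "/")))
    print(object@counts)
    cat(sprintf("matings: %d  replicates: %d  no-mating: %d\n",
                sum(object@counts), object@nReplicates, object@nNoMating))
})

setMethod("show", "IsolationResult", function(object) {
    cat(sprintf("IsolationResult: %s, %s (%s expectation)\n",
                paste(object@strains, collapse = "/"), object@design,
                object@expectedModel))
    cat(sprintf("  I_PSI = %.3f", object@ipsi))
    if (!is.na(object@ipsiSD))
        cat(sprintf(" +/- %.3f (bootstrap SD, n = %d), p = %.4g",
                    object@ipsiSD, object@nBoot, object@pValue))
    cat("\n  PSI:\n")
    print(round(object@psi, 3))
})

setMethod("show", "LatencyComparison", function(object) {
    cat(sprintf("Kruskal-Wallis H = %.2f, df = %d, p = %.4g\n",
                object@statistic, object@df, object@pValue))
    cat("letters (alpha =", object@alpha,
        "; groups sharing no letter differ):\n")
    print(object@letters)
})

setMethod("show", "GroupComparison", function(object) {
    cat(sprintf("GroupComparison (%s) across %s\n", object@transformation,
                paste(object@groups, collapse = ", ")))
    print(object@results, digits = 3)
})

setMethod("show", "SurvivalRecord", function(object) {
    cat(sprintf("SurvivalRecord '%s': n0 = %d, %d intervals of %g h, %d deaths\n",
                object@group, object@n0, length(object@deaths),
                object@intervalH, sum(object@deaths)))
})

setMethod("show", "MsdEstimate", function(object) {
    cat(sprintf("MSD (%s): %.2f h", object@group, object@msdH))
    if (!is.na(object@ciLowH))
        cat(sprintf(" [%.2f, %.2f] (%d%% percentile bootstrap, n = %d)",
                    object@ciLowH, object@ciHighH, round(100 * object@level),
                    object@nBoot))
    cat("\n")
})
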