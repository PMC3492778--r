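## Cuticular-hydrocarbon quantification and compositional statistics.

#' Accessors for PeakTable and HCProfileSet
#'
#' @param x a \linkS4class{PeakTable} or \linkS4class{HCProfileSet}.
#' @return \code{peakAreas}: hydrocarbon x fly area matrix; \code{flyData}:
#'   per-fly covariates; \code{hcPanel}: the declared panel data.frame;
#'   \code{stdMassNg}: internal-standard mass; \code{hcAmounts} /
#'   \code{hcProportions}: ng and fraction matrices; \code{totalHC}: summed
#'   hydrocarbon load per fly (ng).
#' @name hc-accessors
#' @aliases peakAreas flyData hcPanel stdMassNg hcAmounts hcProportions totalHC
#' @export
peakAreas <- function(x) SummarizedExperiment::assay(x, "area")

#' @rdname hc-accessors
#' @export
flyData <- function(x) SummarizedExperiment::colData(x)

#' @rdname hc-accessors
#' @export
hcPanel <- function(x) S4Vectors::metadata(x)$panel

#' @rdname hc-accessors
#' @export
stdMassNg <- function(x) S4Vectors::metadata(x)$stdMassNg

#' @rdname hc-accessors
#' @export
hcAmounts <- function(x) SummarizedExperiment::assay(x, "ng")

#' @rdname hc-accessors
#' @export
hcProportions <- function(x) SummarizedExperiment::assay(x, "proportion")

#' @rdname hc-accessors
#' @export
totalHC <- function(x) SummarizedExperiment::colData(x)$total_ng

#' Quantify hydrocarbon profiles against the internal standard
#'
#' Converts raw peak areas to absolute amounts by the internal-standard
#' rule \eqn{ng_n = (area_n / area_{std}) \times mass_{std}}, sums them into
#' the per-fly total load, and computes relative proportions as each peak's
#' share of the summed hydrocarbon area.  The internal standard itself is
#' excluded from both.  The transformation is homogeneous: rescaling all
#' areas (hydrocarbons and standard alike) leaves the profile unchanged.
#'
#' @param x a \linkS4class{PeakTable}.
#' @param ... unused.
#' @return an \linkS4class{HCProfileSet}.
#' @examples
#' pt <- PeakTable(matrix(c(300, 100), 2, 1, dimnames = list(c("a", "b"), "f1")),
#'                 data.frame(sex = "male", strain = "X", temperature_C = 25,
#'                            std_area = 200))
#' hcAmounts(quantifyHC(pt))     # 750 and 250 ng
#' @export
setMethod("quantifyHC", "PeakTable", function(x, ...) {
    a <- peakAreas(x)
    std <- flyData(x)$std_area
    ng <- sweep(a, 2L, std, "/") * stdMassNg(x)
    tot <- colSums(ng)
    p <- sweep(a, 2L, colSums(a), "/")
    cd <- flyData(x)
    cd$total_ng <- tot
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(ng = ng, proportion = p), colData = cd)
    S4Vectors::metadata(se) <- S4Vectors::metadata(x)
    new("HCProfileSet", se)
})

#' Arcsine-square-root transform
#'
#' Variance-stabilising transform for proportions, \eqn{t = \arcsin\sqrt p}
#' in radians: monotone on [0, 1] with \eqn{t(0)=0}, \eqn{t(1)=\pi/2}.
#'
#' @param p proportions in [0, 1] (vector or matrix).
#' @return transformed values, same shape.
#' @examples
#' arcsineSqrt(c(0, 0.5, 1))    # 0, pi/4, pi/2
#' @export
arcsineSqrt <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("proportions must lie in [0, 1]")
    asin(sqrt(p))
}

## Zero handling for compositions: hard error, or multiplicative replacement
## by half the smallest observed nonzero proportion (renormalised).
.handleZeros <- function(p, zeroPolicy) {
    if (!any(p == 0)) return(p)
    if (zeroPolicy == "error") {
        bad <- if (is.matrix(p)) rownames(p)[rowSums(p == 0) > 0] else
            names(p)[p == 0]
        stop("compositional zero(s) in: ", paste(bad, collapse = ", "),
             " (use zeroPolicy = \"replace\" to impute)")
    }
    eps <- min(p[p > 0]) / 2
    p[p == 0] <- eps
    if (is.matrix(p)) sweep(p, 2L, colSums(p), "/") else p / sum(p)
}

.logContrastCore <- function(p, denominator, zeroPolicy) {
    nm <- if (is.matrix(p)) rownames(p) else names(p)
    if (!denominator %in% nm)
        stop("denominator '", denominator, "' is not in the panel")
    p <- .handleZeros(p, zeroPolicy)
    if (is.matrix(p)) {
        lc <- log10(sweep(p, 2L, p[denominator, ], "/"))
        lc[setdiff(nm, denominator), , drop = FALSE]
    } else {
        lc <- log10(p / p[[denominator]])
        lc[setdiff(nm, denominator)]
    }
}

#' Compositional log-contrasts
#'
#' For each hydrocarbon other than the denominator, returns
#' \eqn{\log_{10}(p_n / p_{denom})}.  This removes the unit-sum constraint of
#' proportional data and reduces the number of traits by one; differences of
#' log-contrasts between two hydrocarbons do not depend on the denominator
#' chosen.
#'
#' @param x a named proportion vector, or an \linkS4class{HCProfileSet}
#'   (applied per fly).
#' @param denominator name of the reference hydrocarbon.
#' @param zeroPolicy \code{"error"} rejects zero proportions;
#'   \code{"replace"} imputes half the smallest nonzero proportion.
#' @param ... unused.
#' @return named vector (or matrix, flies in columns) of panel-size - 1
#'   log-contrasts.
#' @examples
#' logContrast(c(a = 0.5, b = 0.25, c = 0.25), denominator = "c")
#' @export
setMethod("logContrast", "numeric", function(x, denominator, zeroPolicy, ...) {
    zeroPolicy <- match.arg(zeroPolicy, c("error", "replace"))
    .logContrastCore(x, denominator, zeroPolicy)
})

#' @rdname logContrast-numeric-method
#' @export
setMethod("logContrast", "HCProfileSet", function(x, denominator, zeroPolicy, ...) {
    zeroPolicy <- match.arg(zeroPolicy, c("error", "replace"))
    .logContrastCore(hcProportions(x), denominator, zeroPolicy)
})

.starCode <- function(p) {
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Per-hydrocarbon group comparison (one-way ANOVA + Tukey HSD)
#'
#' For every hydrocarbon (or log-contrast), runs a one-way ANOVA on the
#' transformed per-fly values across groups, followed by Tukey's HSD for all
#' group pairs.  Under \code{"arcsine_sqrt"} the per-fly proportions are
#' arcsine-square-root transformed; under \code{"log_contrast"} each of the
#' panel-size - 1 log-contrasts is analysed separately.
#'
#' @param x an \linkS4class{HCProfileSet} covering all groups.
#' @param group name of the grouping column in \code{flyData(x)}
#'   (default \code{"strain"}).
#' @param transform \code{"arcsine_sqrt"} or \code{"log_contrast"}.
#' @param denominator reference hydrocarbon (log-contrast only).
#' @param zeroPolicy passed to \code{\link{logContrast}}.
#' @return a \linkS4class{GroupComparison}; \code{comparisonResults} extracts
#'   the per-hydrocarbon table (F, overall p, Tukey-adjusted p per pair,
#'   star code at the 0.05/0.01/0.001 levels).
#' @export
compareGroups <- function(x, group = "strain",
                          transform = c("arcsine_sqrt", "log_contrast"),
                          denominator = NULL, zeroPolicy = "error") {
    transform <- match.arg(transform)
    g <- factor(flyData(x)[[group]])
    if (nlevels(g) < 2L) stop("need at least two groups")
    sz <- table(g)
    if (any(sz < 3L))
        stop("insufficient replication (< 3 flies) in group(s): ",
             paste(names(sz)[sz < 3L], collapse = ", "))
    vals <- switch(transform,
        arcsine_sqrt = arcsineSqrt(hcProportions(x)),
        log_contrast = {
            if (is.null(denominator))
                stop("log_contrast requires a denominator hydrocarbon")
            logContrast(x, denominator, zeroPolicy)
        })
    pairs <- utils::combn(levels(g), 2L)
    pairNames <- paste0("p_", pairs[1L, ], ".", pairs[2L, ])
    rows <- lapply(rownames(vals), function(hc) {
        y <- vals[hc, ]
        if (stats::var(y) == 0) {        # identical flies: no variation at all
            pw <- stats::setNames(rep(1, ncol(pairs)), pairNames)
            return(c(list(hc = hc, F = 0, p = 1), as.list(pw)))
        }
        fit <- stats::aov(y ~ g)
        an <- summary(fit)[[1L]]
        tk <- stats::TukeyHSD(fit)$g
        key <- paste0(pairs[2L, ], "-", pairs[1L, ])
        pw <- stats::setNames(tk[key, "p adj"], pairNames)
        c(list(hc = hc, F = an$`F value`[1L], p = an$`Pr(>F)`[1L]), as.list(pw))
    })
    res <- do.call(rbind, lapply(rows, as.data.frame))
    res$stars <- .starCode(res$p)
    new("GroupComparison", results = res, transformation = transform,
        groups = levels(g),
        denominator = if (is.null(denominator)) NA_character_ else denominator)
}

#' @rdname compareGroups
#' @export
comparisonResults <- function(x) x@results

#' Pheromonal phenotype ratio (7-T / 7-P)
#'
#' Ratio of the 7-tricosene to the 7-pentacosene proportion, the scalar that
#' places a strain on the 7-T-rich vs 7-P-rich phenotype axis.
#'
#' @param x named proportion (or percentage) vector, or an
#'   \linkS4class{HCProfileSet} (one ratio per fly).
#' @param numeratorHC,denominatorHC panel names of the two monoenes.
#' @return the ratio (numeric; per-fly vector for a profile set).
#' @examples
#' phenoRatio(c(`(Z)-7-C23:1` = 20.42, `(Z)-7-C25:1` = 34.55))  # 0.59
#' @export
setMethod("phenoRatio", "numeric", function(x, numeratorHC, denominatorHC) {
    miss <- setdiff(c(numeratorHC, denominatorHC), names(x))
    if (length(miss))
        stop("hydrocarbon(s) missing from the panel: ",
             paste(miss, collapse = ", "))
    if (x[[denominatorHC]] <= 0) stop("denominator proportion must be positive")
    unname(x[[numeratorHC]] / x[[denominatorHC]])
})

#' @rdname phenoRatio-numeric-method
#' @export
setMethod("phenoRatio", "HCProfileSet", function(x, numeratorHC, denominatorHC) {
    p <- hcProportions(x)
    miss <- setdiff(c(numeratorHC, denominatorHC), rownames(p))
    if (length(miss))
        stop("hydrocarbon(s) missing from the panel: ",
             paste(miss, collapse = ", "))
    as.numeric(p[numeratorHC, ] / p[denominatorHC, ])
})

#' Percent difference relative to a reference
#'
#' \eqn{100 (reference - other) / reference}: positive when the other group
#' is lower than the reference, negative when it is higher.
#'
#' @param reference,other totals (or any positive quantities) to compare.
#' @return percent difference.
#' @examples
#' percentDifference(1577, 1128)   # Cam males carry ~28% less HC than Eg
#' @export
percentDifference <- function(reference, other) {
    if (any(reference <= 0)) stop("reference must be positive")
    100 * (reference - other) / reference
}
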