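## Central S4 classes for the three analysis stages and their generators.

.DESIGNS <- c("no_choice", "male_choice", "female_choice", "multiple_choice")
.EXPECTED_MODELS <- c("marginal_product", "uniform")

#' MatingTable: a 2x2 mate-choice contingency table
#'
#' Counts of copulations by (female strain, male strain) for a pairwise
#' mate-choice experiment, with the design and replicate metadata.  Rows index
#' the female strain and columns the male strain; the female is always listed
#' first, so cell \code{[i, j]} counts copulations between strain-\code{i}
#' females and strain-\code{j} males.
#'
#' @slot design one of \code{"no_choice"}, \code{"male_choice"},
#'   \code{"female_choice"}, \code{"multiple_choice"}.
#' @slot counts 2x2 integer matrix of copulation counts, dimnames = strains.
#' @slot nReplicates number of trials run (0 if unknown).
#' @slot nNoMating number of trials in which no copulation occurred.
#'
#' @export
setClass("MatingTable",
    representation(design = "character", counts = "matrix",
                   nReplicates = "integer", nNoMating = "integer"))

setValidity("MatingTable", function(object) {
    msg <- character()
    if (length(object@design) != 1L || !object@design %in% .DESIGNS)
        msg <- c(msg, sprintf("design must be one of: %s",
                              paste(.DESIGNS, collapse = ", ")))
    cnt <- object@counts
    if (!is.numeric(cnt) || !identical(dim(cnt), c(2L, 2L)))
        msg <- c(msg, "counts must be a 2x2 numeric matrix")
    else {
        if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(cnt != round(cnt)))
            msg <- c(msg, "counts must be whole numbers (no fractional counts)")
        if (is.null(rownames(cnt)) || is.null(colnames(cnt)))
            msg <- c(msg, "counts must carry strain dimnames")
        else if (!identical(rownames(cnt), colnames(cnt)))
            msg <- c(msg, "row (female) and column (male) strain labels must match")
    }
    if (object@nReplicates < 0L || object@nNoMating < 0L)
        msg <- c(msg, "nReplicates and nNoMating must be non-negative")
    if (is.numeric(cnt) && identical(dim(cnt), c(2L, 2L)) &&
        object@nReplicates > 0L &&
        sum(cnt) + object@nNoMating > object@nReplicates)
        msg <- c(msg, "matings + non-mating trials exceed nReplicates (each trial yields at most one copulation)")
    if (length(msg)) msg else TRUE
})

#' @rdname MatingTable-class
#' @param counts 2x2 matrix (or length-4 vector in row-major female-first
#'   order AA, AB, BA, BB) of copulation counts.
#' @param design experimental design.
#' @param strains character(2) strain labels (female = row = first).
#' @param nReplicates,nNoMating trial metadata; \code{nNoMating} defaults to
#'   \code{nReplicates - sum(counts)} when replicates are given.
#' @return a \code{MatingTable}.
#' @examples
#' MatingTable(c(17, 23, 33, 27), design = "male_choice",
#'             strains = c("Eg", "Cam"), nReplicates = 108)
#' @export
MatingTable <- function(counts, design = "multiple_choice",
                        strains = c("A", "B"), nReplicates = 0L,
                        nNoMating = NULL) {
    if (!is.matrix(counts)) {
        stopifnot(length(counts) == 4L)
        counts <- matrix(counts, 2L, 2L, byrow = TRUE)
    }
    dimnames(counts) <- list(female = strains, male = strains)
    nReplicates <- as.integer(nReplicates)
    if (is.null(nNoMating))
        nNoMating <- if (nReplicates > 0L)
            max(0L, nReplicates - as.integer(sum(counts))) else 0L
    new("MatingTable", design = design, counts = counts,
        nReplicates = nReplicates, nNoMating = as.integer(nNoMating))
}

#' IsolationResult: isolation/selection estimates for one mating table
#'
#' Holds the pair sexual isolation (PSI) and pair total (PTI) coefficient
#' matrices, the joint isolation index \eqn{I_{PSI}} with its bootstrap
#' standard deviation and two-tailed p-value, and full provenance (expected
#' model, bootstrap size, seed).
#'
#' @slot psi,pti 2x2 matrices of coefficients (female strain x male strain).
#' @slot ipsi point estimate in [-1, 1].
#' @slot ipsiSD bootstrap standard deviation (NA before bootstrapping).
#' @slot pValue two-tailed bootstrap p-value (NA before bootstrapping).
#' @slot nBoot,seed bootstrap provenance (0/NA before bootstrapping).
#' @slot expectedModel \code{"marginal_product"} or \code{"uniform"}.
#' @slot design,strains copied from the source table.
#' @export
setClass("IsolationResult",
    representation(psi = "matrix", pti = "matrix", ipsi = "numeric",
                   ipsiSD = "numeric", pValue = "numeric", nBoot = "integer",
                   seed = "integer", expectedModel = "character",
                   design = "character", strains = "character"))

setValidity("IsolationResult", function(object) {
    msg <- character()
    if (!is.na(object@ipsi) && abs(object@ipsi) > 1 + 1e-12)
        msg <- c(msg, "ipsi must lie in [-1, 1]")
    if (any(object@psi < 0) || any(object@pti < 0))
        msg <- c(msg, "PSI and PTI coefficients must be non-negative")
    if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
        msg <- c(msg, "pValue must lie in [0, 1]")
    if (!is.na(object@ipsiSD) && object@ipsiSD < 0)
        msg <- c(msg, "ipsiSD must be non-negative")
    if (!object@expectedModel %in% .EXPECTED_MODELS)
        msg <- c(msg, "unknown expected model")
    if (length(msg)) msg else TRUE
})

#' LatencyComparison: Kruskal-Wallis test with rank-mean post hoc
#'
#' Result of comparing courtship or copulation latencies across pair types:
#' the tie-corrected Kruskal-Wallis H statistic, its chi-square p-value, and
#' pairwise decisions by the rank-mean-difference criterion with a Bonferroni
#' correction over all pairs, summarised as a compact letter display.
#'
#' @slot statistic Kruskal-Wallis H (tie-corrected).
#' @slot df degrees of freedom (k - 1).
#' @slot pValue chi-square p-value.
#' @slot rankMeans named mean ranks per group.
#' @slot pairwise data.frame of pairwise |rank-mean difference|, critical
#'   value and significance flag.
#' @slot letters named letter codes; groups sharing no letter differ at alpha.
#' @slot alpha family significance level.
#' @export
setClass("LatencyComparison",
    representation(statistic = "numeric", df = "integer", pValue = "numeric",
                   rankMeans = "numeric", pairwise = "data.frame",
                   letters = "character", alpha = "numeric"))

#' PeakTable: per-fly GC peak areas with an internal standard
#'
#' A \linkS4class{SummarizedExperiment} whose single \code{"area"} assay holds
#' raw gas-chromatography peak areas (rows = hydrocarbons of the declared
#' panel, columns = individual flies).  \code{colData} carries \code{sex},
#' \code{strain}, \code{temperature_C} and the internal-standard peak area
#' \code{std_area}; the standard's injected mass (ng) and the panel table live
#' in \code{metadata}.
#'
#' @export
setClass("PeakTable", contains = "SummarizedExperiment")

setValidity("PeakTable", function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    need <- c("sex", "strain", "temperature_C", "std_area")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, sprintf("colData must contain: %s", paste(miss, collapse = ", ")))
    if (!"area" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'area' is required")
    else {
        a <- SummarizedExperiment::assay(object, "area")
        if (any(a < 0)) msg <- c(msg, "peak areas must be non-negative")
        if (ncol(a) > 0 && any(colSums(a) <= 0))
            msg <- c(msg, "every fly needs at least one positive hydrocarbon peak")
    }
    if ("std_area" %in% colnames(cd) && any(cd$std_area <= 0))
        msg <- c(msg, "internal-standard area must be positive for every fly")
    md <- S4Vectors::metadata(object)
    if (is.null(md$stdMassNg) || md$stdMassNg <= 0)
        msg <- c(msg, "metadata$stdMassNg (internal-standard mass) must be positive")
    if (length(msg)) msg else TRUE
})

#' @rdname PeakTable-class
#' @param areas numeric matrix of peak areas, rows = hydrocarbons (named),
#'   columns = flies.
#' @param flyData data.frame with one row per fly: \code{sex}, \code{strain},
#'   \code{temperature_C}, \code{std_area}.
#' @param panel optional data.frame with columns \code{name}, \code{class}
#'   declaring the hydrocarbon panel; defaults to the row names with class
#'   \code{NA}.  Areas for hydrocarbons outside the panel are rejected.
#' @param stdMassNg mass (ng) of internal standard co-injected per fly.
#' @export
PeakTable <- function(areas, flyData, panel = NULL, stdMassNg = 500) {
    areas <- as.matrix(areas)
    if (is.null(panel))
        panel <- data.frame(name = rownames(areas), class = NA_character_)
    unknown <- setdiff(rownames(areas), panel$name)
    if (length(unknown))
        stop("peak(s) not in the declared panel: ", paste(unknown, collapse = ", "))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(area = areas),
        colData = S4Vectors::DataFrame(flyData))
    S4Vectors::metadata(se)$stdMassNg <- stdMassNg
    S4Vectors::metadata(se)$panel <- panel
    new("PeakTable", se)
}

#' HCProfileSet: absolute and relative hydrocarbon profiles
#'
#' A \linkS4class{SummarizedExperiment} with assays \code{"ng"} (absolute
#' amounts, ng/fly) and \code{"proportion"} (fractions summing to 1 per fly),
#' produced by \code{\link{quantifyHC}}.  \code{colData} keeps the fly
#' covariates plus \code{total_ng}, the summed hydrocarbon load per fly.
#'
#' @export
setClass("HCProfileSet", contains = "SummarizedExperiment")

setValidity("HCProfileSet", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("ng", "proportion") %in% an))
        msg <- c(msg, "assays 'ng' and 'proportion' are required")
    else {
        p <- SummarizedExperiment::assay(object, "proportion")
        ng <- SummarizedExperiment::assay(object, "ng")
        tot <- SummarizedExperiment::colData(object)$total_ng
        if (is.null(tot)) msg <- c(msg, "colData$total_ng is required")
        else if (ncol(p) > 0) {
            if (max(abs(colSums(p) - 1)) > 1e-9)
                msg <- c(msg, "proportions must sum to 1 per fly")
            if (max(abs(sweep(p, 2, tot, "*") - ng)) > 1e-6)
                msg <- c(msg, "ng must equal proportion * total_ng")
        }
    }
    if (length(msg)) msg else TRUE
})

#' GroupComparison: per-hydrocarbon ANOVA across groups
#'
#' Per-hydrocarbon one-way ANOVA on transformed profile values, with Tukey
#' HSD pairwise adjusted p-values for every group pair.
#'
#' @slot results data.frame: one row per hydrocarbon with \code{F},
#'   \code{p}, one \code{p_<g1>.<g2>} column per group pair, and a star code.
#' @slot transformation \code{"arcsine_sqrt"} or \code{"log_contrast"}.
#' @slot groups the group labels compared.
#' @slot denominator log-contrast denominator (NA for arcsine).
#' @export
setClass("GroupComparison",
    representation(results = "data.frame", transformation = "character",
                   groups = "character", denominator = "character"))

#' SurvivalRecord: deaths on a fixed inspection grid
#'
#' Mortality counts for one group of flies inspected at a fixed interval
#' (typically every 0.5 h) under desiccation stress.  A death recorded at
#' inspection k occurred within the half-open interval ((k-1)h, kh].
#'
#' @slot group group label.
#' @slot n0 initial number of flies.
#' @slot intervalH inspection interval, hours.
#' @slot deaths integer deaths per interval.
#' @export
setClass("SurvivalRecord",
    representation(group = "character", n0 = "integer", intervalH = "numeric",
                   deaths = "integer"))

setValidity("SurvivalRecord", function(object) {
    msg <- character()
    if (object@n0 <= 0L) msg <- c(msg, "n0 must be positive")
    if (object@intervalH <= 0) msg <- c(msg, "inspection interval must be positive")
    if (any(object@deaths < 0)) msg <- c(msg, "deaths must be non-negative")
    if (sum(object@deaths) > object@n0)
        msg <- c(msg, "total deaths exceed the initial count n0")
    if (length(msg)) msg else TRUE
})

#' @rdname SurvivalRecord-class
#' @param deaths integer vector of deaths per inspection interval.
#' @param n0 initial group size.
#' @param intervalH inspection interval in hours.
#' @param group label.
#' @export
SurvivalRecord <- function(deaths, n0 = 100L, intervalH = 0.5, group = "group") {
    new("SurvivalRecord", group = group, n0 = as.integer(n0),
        intervalH = intervalH, deaths = as.integer(deaths))
}

#' MsdEstimate: median survival duration with confidence interval
#'
#' @slot group group label.
#' @slot msdH median survival duration, decimal hours.
#' @slot ciLowH,ciHighH bootstrap percentile confidence bounds (NA for a
#'   point-only estimate).
#' @slot level confidence level.
#' @slot nBoot,seed bootstrap provenance.
#' @export
setClass("MsdEstimate",
    representation(group = "character", msdH = "numeric", ciLowH = "numeric",
                   ciHighH = "numeric", level = "numeric", nBoot = "integer",
                   seed = "integer"))

setValidity("MsdEstimate", function(object) {
    if (!is.na(object@ciLowH) && !is.na(object@ciHighH) &&
        !(object@ciLowH <= object@msdH + 1e-12 &&
          object@msdH <= object@ciHighH + 1e-12))
        "confidence interval must bracket the point estimate" else TRUE
})

#' PreferenceModel: generative model for mate-choice trials
#'
#' Relative mating propensities \code{weights[i, j]} for female strain i with
#' male strain j.  The homotypic-advantage parameterisation sets
#' \code{w = 1 + s} for same-strain and \code{1 - s} for cross-strain pairs,
#' so that under the multiple-choice design the expected isolation index
#' equals \code{s}.
#'
#' @slot design mate-choice design simulated.
#' @slot strains strain labels (female first in pair order).
#' @slot weights 2x2 positive propensity matrix.
#' @slot pNoMating probability a trial ends without copulation.
#' @slot nTrials number of trials.
#' @slot seed RNG seed.
#' @export
setClass("PreferenceModel",
    representation(design = "character", strains = "character",
                   weights = "matrix", pNoMating = "numeric",
                   nTrials = "integer", seed = "integer"))

setValidity("PreferenceModel", function(object) {
    msg <- character()
    if (!object@design %in% .DESIGNS) msg <- c(msg, "unknown design")
    if (any(object@weights <= 0)) msg <- c(msg, "weights must be positive")
    if (object@pNoMating < 0 || object@pNoMating >= 1)
        msg <- c(msg, "pNoMating must lie in [0, 1)")
    if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @rdname PreferenceModel-class
#' @param s homotypic advantage in (-1, 1); ignored if \code{weights} given.
#' @param weights optional explicit 2x2 propensity matrix.
#' @param design,strains,pNoMating,nTrials,seed see slots.
#' @export
PreferenceModel <- function(s = 0, design = "multiple_choice",
                            strains = c("A", "B"), weights = NULL,
                            pNoMating = 0, nTrials = 100L, seed = 1L) {
    if (is.null(weights)) {
        stopifnot(abs(s) < 1)
        weights <- matrix(1 - s, 2L, 2L)
        diag(weights) <- 1 + s
    }
    dimnames(weights) <- list(female = strains, male = strains)
    new("PreferenceModel", design = design, strains = strains,
        weights = weights, pNoMating = pNoMating,
        nTrials = as.integer(nTrials), seed = as.integer(seed))
}

#' ProfileModel: generative model for hydrocarbon peak tables
#'
#' Per-fly compositions are Dirichlet with mean \code{meanProportions} and
#' spread set by \code{concentration}; per-fly totals are lognormal with mean
#' \code{totalMeanNg} and coefficient of variation \code{totalCV}.  Peak
#' areas are back-computed against a unit internal-standard area.
#'
#' @slot panel hydrocarbon names (simplex order).
#' @slot meanProportions mean composition, sums to 1.
#' @slot concentration Dirichlet concentration (larger = tighter).
#' @slot totalMeanNg,totalCV lognormal total hydrocarbon load parameters.
#' @slot nFlies,seed generation parameters.
#' @slot sex,strain labels stamped onto generated flies.
#' @export
setClass("ProfileModel",
    representation(panel = "character", meanProportions = "numeric",
                   concentration = "numeric", totalMeanNg = "numeric",
                   totalCV = "numeric", nFlies = "integer", seed = "integer",
                   sex = "character", strain = "character"))

setValidity("ProfileModel", function(object) {
    msg <- character()
    if (abs(sum(object@meanProportions) - 1) > 1e-8)
        msg <- c(msg, "meanProportions must sum to 1")
    if (any(object@meanProportions <= 0))
        msg <- c(msg, "meanProportions must be positive")
    if (object@concentration <= 0) msg <- c(msg, "concentration must be positive")
    if (object@totalMeanNg <= 0 || object@totalCV <= 0)
        msg <- c(msg, "total mean and CV must be positive")
    if (length(object@panel) != length(object@meanProportions))
        msg <- c(msg, "panel and meanProportions lengths differ")
    if (length(msg)) msg else TRUE
})

#' @rdname ProfileModel-class
#' @param panel,meanProportions,concentration,totalMeanNg,totalCV,nFlies,seed
#'   see slots; \code{meanProportions} is renormalised to sum exactly to 1.
#' @param sex,strain labels for the generated flies.
#' @export
ProfileModel <- function(panel, meanProportions, concentration = 200,
                         totalMeanNg = 1500, totalCV = 0.15, nFlies = 10L,
                         seed = 1L, sex = "male", strain = "synthetic") {
    meanProportions <- meanProportions / sum(meanProportions)
    names(meanProportions) <- panel
    new("ProfileModel", panel = panel, meanProportions = meanProportions,
        concentration = concentration, totalMeanNg = totalMeanNg,
        totalCV = totalCV, nFlies = as.integer(nFlies),
        seed = as.integer(seed), sex = sex, strain = strain)
}

#' MortalityModel: generative model for desiccation death records
#'
#' Death times are Weibull with the stated median and shape, observed on a
#' fixed inspection grid.
#'
#' @slot group label.
#' @slot medianH median death time, hours.
#' @slot shape Weibull shape (steepness of the die-off).
#' @slot n0 initial number of flies.
#' @slot intervalH inspection interval, hours.
#' @slot seed RNG seed.
#' @export
setClass("MortalityModel",
    representation(group = "character", medianH = "numeric", shape = "numeric",
                   n0 = "integer", intervalH = "numeric", seed = "integer"))

setValidity("MortalityModel", function(object) {
    msg <- character()
    if (object@medianH <= 0) msg <- c(msg, "medianH must be positive")
    if (object@shape <= 0) msg <- c(msg, "shape must be positive")
    if (object@n0 <= 0L) msg <- c(msg, "n0 must be positive")
    if (object@intervalH <= 0) msg <- c(msg, "intervalH must be positive")
    if (length(msg)) msg else TRUE
})

#' @rdname MortalityModel-class
#' @param medianH,shape,n0,intervalH,seed,group see slots.
#' @export
MortalityModel <- function(medianH, shape = 6, n0 = 100L, intervalH = 0.5,
                           seed = 1L, group = "group") {
    new("MortalityModel", group = group, medianH = medianH, shape = shape,
        n0 = as.integer(n0), intervalH = intervalH, seed = as.integer(seed))
}
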