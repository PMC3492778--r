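## Bundled example data: mate-choice counts and hydrocarbon group summaries
## for three African D. simulans strains -- Eg (Egypt, 7-T rich), ST
## (Sao Tome, intermediate) and Cam (Cameroon, 7-P rich).

.extfile <- function(...) {
    f <- system.file("extdata", ..., package = "isopair", mustWork = TRUE)
    f
}

#' Bundled mate-choice contingency tables
#'
#' Observed pair-mating counts for the three strain pairs (Eg/Cam, Eg/ST,
#' ST/Cam) under the male-choice, female-choice and multiple-choice designs,
#' with replicate counts.  The female strain is listed first throughout.
#'
#' @return named list of \linkS4class{MatingTable}, names
#'   \code{"<F>_<M>_<design>"}.
#' @examples
#' tabs <- matingChoiceTables()
#' ipsi(tabs$Eg_Cam_female_choice)
#' @export
matingChoiceTables <- function() {
    files <- list.files(system.file("extdata", package = "isopair"),
                        pattern = "^mating_.*\\.csv$", full.names = TRUE)
    tabs <- lapply(files, readMatingCSV)
    names(tabs) <- sub("^mating_(.*)\\.csv$", "\\1", basename(files))
    tabs
}

#' Bundled hydrocarbon group summaries
#'
#' Per-strain mean +/- SEM (n = 10 flies) of the total hydrocarbon load
#' (ng/fly) and the relative abundance (percent) of each panel hydrocarbon,
#' for males or females at 25 degrees C.
#'
#' @param sex \code{"male"} or \code{"female"}.
#' @return list with elements \code{strains}; \code{total_mean} and
#'   \code{total_sem} (named, ng/fly); \code{mean} and \code{sem}
#'   (hydrocarbon x strain percent matrices); \code{n} (group size).
#' @examples
#' m <- hcStrainMeans("male")
#' phenoRatio(m$mean[, "ST"])     # ~0.59
#' @export
hcStrainMeans <- function(sex = c("male", "female")) {
    sex <- match.arg(sex)
    d <- utils::read.csv(.extfile(paste0("hc_means_", sex, ".csv")),
                         check.names = FALSE)
    strains <- sub("_mean$", "", grep("_mean$", names(d), value = TRUE))
    tot <- d[d$hc == "total_ng", ]
    hcs <- d[d$hc != "total_ng", ]
    mk <- function(rows, suffix) {
        m <- as.matrix(rows[, paste0(strains, suffix)])
        dimnames(m) <- list(rows$hc, strains)
        m
    }
    list(strains = strains,
         total_mean = stats::setNames(as.numeric(tot[, paste0(strains, "_mean")]),
                                      strains),
         total_sem = stats::setNames(as.numeric(tot[, paste0(strains, "_sem")]),
                                     strains),
         mean = mk(hcs, "_mean"), sem = mk(hcs, "_sem"), n = 10L)
}

#' Bundled male hydrocarbon panel
#'
#' The 13-hydrocarbon male panel (chain lengths 23-29) with each compound's
#' structural class.
#'
#' @return data.frame with columns \code{name}, \code{class}.
#' @export
defaultMalePanel <- function() readPanelYAML(.extfile("panel_male.yaml"))

#' Profile model calibrated to a bundled strain summary
#'
#' Builds a \linkS4class{ProfileModel} whose Dirichlet mean equals the
#' strain's mean composition, whose concentration is calibrated from the
#' printed SEMs (\code{\link{calibrateConcentration}}), and whose lognormal
#' total matches the printed total mean with CV = SEM * sqrt(n) / mean.
#'
#' @param strain one of the bundled strain labels.
#' @param sex \code{"male"} or \code{"female"}.
#' @param nFlies,seed generation parameters.
#' @return a \linkS4class{ProfileModel}.
#' @examples
#' pm <- profileModelFor("Eg", nFlies = 10, seed = 2)
#' totalHC(quantifyHC(simPeakTables(pm)))
#' @export
profileModelFor <- function(strain, sex = "male", nFlies = 10L, seed = 1L) {
    s <- hcStrainMeans(sex)
    if (!strain %in% s$strains)
        stop("unknown strain '", strain, "'; bundled: ",
             paste(s$strains, collapse = ", "))
    p <- s$mean[, strain] / 100
    sem <- s$sem[, strain] / 100
    conc <- calibrateConcentration(p / sum(p), sem, n = s$n)
    cv <- s$total_sem[strain] * sqrt(s$n) / s$total_mean[strain]
    ProfileModel(panel = rownames(s$mean), meanProportions = p,
                 concentration = conc, totalMeanNg = s$total_mean[[strain]],
                 totalCV = unname(cv), nFlies = nFlies, seed = seed,
                 sex = sex, strain = strain)
}
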