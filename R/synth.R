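## Seed-reproducible generators for mate-choice trials, hydrocarbon peak
## tables and desiccation death records.

## Evaluate expr under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    force(expr)
}

#' Simulate mate-choice trials
#'
#' Runs \code{nTrials} trials of the model's design.  With probability
#' \code{pNoMating} a trial ends without copulation; otherwise one pair
#' copulates, chosen with probability proportional to its propensity
#' \code{weights[i, j]} among the pairs available under the design:
#' \describe{
#'   \item{multiple_choice}{all four pairs compete (two flies of each sex).}
#'   \item{male_choice}{one male with two females; the male's strain
#'     alternates between trials, the female is chosen within his column.}
#'   \item{female_choice}{one female with two males; symmetric.}
#'   \item{no_choice}{a single fixed pair per trial, cycling through the
#'     four combinations.}
#' }
#' Under the homotypic-advantage parameterisation with the multiple-choice
#' design the expected isolation index of the generated table equals
#' \code{s} exactly.
#'
#' @param model a \linkS4class{PreferenceModel}.
#' @param ... unused.
#' @return a \linkS4class{MatingTable} with \code{nReplicates = nTrials} and
#'   the non-mating trials tallied.
#' @examples
#' tab <- simMatingTrials(PreferenceModel(s = 0.4, nTrials = 500, seed = 11))
#' ipsi(tab)
#' @export
setMethod("simMatingTrials", "PreferenceModel", function(model, ...) {
    w <- model@weights
    n <- model@nTrials
    .withSeed(model@seed, {
        mates <- stats::runif(n) >= model@pNoMating
        cell <- integer(n)           # 1..4 in column-major (AA, BA, AB, BB)
        for (t in seq_len(n)) {
            if (!mates[t]) next
            probs <- switch(model@design,
                multiple_choice = as.vector(w),
                male_choice = {      # male strain fixed per trial, alternating
                    j <- (t - 1L) %% 2L + 1L
                    p <- numeric(4L); p[(j - 1L) * 2L + 1:2] <- w[, j]; p
                },
                female_choice = {    # female strain fixed per trial
                    i <- (t - 1L) %% 2L + 1L
                    p <- numeric(4L); p[c(i, i + 2L)] <- w[i, ]; p
                },
                no_choice = {        # one fixed pair, cycling AA, BA, AB, BB
                    p <- numeric(4L); p[(t - 1L) %% 4L + 1L] <- 1; p
                })
            cell[t] <- sample.int(4L, 1L, prob = probs)
        }
        cnt <- matrix(tabulate(cell[cell > 0L], 4L), 2L, 2L)
        dimnames(cnt) <- dimnames(w)
        new("MatingTable", design = model@design, counts = cnt,
            nReplicates = n, nNoMating = sum(cell == 0L))
    })
})

#' Simulate per-fly hydrocarbon peak tables
#'
#' Per fly, a composition is drawn from
#' Dirichlet(\code{concentration} x \code{meanProportions}) and a total
#' hydrocarbon load from a lognormal with the model's mean and coefficient
#' of variation.  Peak areas are then back-computed against a unit
#' internal-standard area, so that \code{\link{quantifyHC}} recovers the
#' intended absolute amounts.
#'
#' @param model a \linkS4class{ProfileModel}.
#' @param stdMassNg internal-standard mass used for back-computation
#'   (default 500 ng).
#' @param ... unused.
#' @return a \linkS4class{PeakTable}.
#' @export
setMethod("simPeakTables", "ProfileModel", function(model, stdMassNg = 500, ...) {
    k <- length(model@panel)
    n <- model@nFlies
    .withSeed(model@seed, {
        alpha <- model@concentration * model@meanProportions
        g <- matrix(stats::rgamma(k * n, shape = alpha), k, n)
        p <- sweep(g, 2L, colSums(g), "/")
        sdlog <- sqrt(log(1 + model@totalCV^2))
        tot <- stats::rlnorm(n, log(model@totalMeanNg) - sdlog^2 / 2, sdlog)
        ng <- sweep(p, 2L, tot, "*")
        areas <- ng / stdMassNg      # unit internal-standard area
        dimnames(areas) <- list(model@panel,
                                paste0(model@strain, "_", seq_len(n)))
        PeakTable(areas,
                  data.frame(sex = rep(model@sex, n),
                             strain = rep(model@strain, n),
                             temperature_C = rep(25, n),
                             std_area = rep(1, n),
                             row.names = colnames(areas)),
                  stdMassNg = stdMassNg)
    })
})

#' Simulate a gridded desiccation death record
#'
#' Death times are Weibull with the model's median and shape (scale
#' \eqn{\lambda = median / (\ln 2)^{1/shape}}), binned to the inspection
#' grid: a death in \eqn{(t_{k-1}, t_k]} is recorded at inspection k.
#'
#' @param model a \linkS4class{MortalityModel}.
#' @param ... unused.
#' @return a \linkS4class{SurvivalRecord} covering all deaths.
#' @examples
#' rec <- simDesiccation(MortalityModel(medianH = 6.4, n0 = 100, seed = 3))
#' msdHours(msd(rec))
#' @export
setMethod("simDesiccation", "MortalityModel", function(model, ...) {
    scale <- model@medianH / log(2)^(1 / model@shape)
    .withSeed(model@seed, {
        times <- stats::rweibull(model@n0, shape = model@shape, scale = scale)
        k <- ceiling(times / model@intervalH)
        k[k < 1L] <- 1L
        new("SurvivalRecord", group = model@group, n0 = model@n0,
            intervalH = model@intervalH, deaths = tabulate(k, max(k)))
    })
})

#' Simulate no-choice latency data
#'
#' Exponential latencies with a per-pair-type mean, for exercising
#' \code{\link{compareLatencies}}.  Purely synthetic: real courtship
#' latencies need not be exponential.
#'
#' @param meansMin named vector of mean latencies (minutes) per pair type.
#' @param n trials per pair type.
#' @param seed integer RNG seed.
#' @return data.frame with \code{pair_type} and \code{latency_min}.
#' @export
simLatencies <- function(meansMin, n = 30L, seed = 1L) {
    .withSeed(seed, data.frame(
        pair_type = rep(names(meansMin), each = n),
        latency_min = stats::rexp(n * length(meansMin),
                                  rate = rep(1 / meansMin, each = n))))
}

#' Calibrate a Dirichlet concentration from group means and SEMs
#'
#' Given per-component mean proportions and their standard errors over n
#' individuals, returns the Dirichlet concentration whose marginal SDs,
#' \eqn{\sqrt{p(1-p)/(c+1)}}, best match (median over components of
#' \eqn{p(1-p)/SD^2 - 1}).
#'
#' @param meanProportions,sems proportion means and SEMs (fractions, same
#'   length).
#' @param n group size behind the SEMs.
#' @return the concentration parameter (a single positive number).
#' @export
calibrateConcentration <- function(meanProportions, sems, n = 10L) {
    sd <- sems * sqrt(n)
    ok <- sd > 0 & meanProportions > 0 & meanProportions < 1
    stats::median(meanProportions[ok] * (1 - meanProportions[ok]) / sd[ok]^2 - 1)
}
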