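## Sexual-isolation and sexual-selection statistics on 2x2 mate-choice tables.

#' Accessors for MatingTable and IsolationResult
#'
#' @param x a \linkS4class{MatingTable} or \linkS4class{IsolationResult}.
#' @return \code{matingCounts}: the 2x2 count matrix; \code{designType} and
#'   \code{strainLabels}: metadata; \code{nReplicates}/\code{nNoMating}:
#'   trial counts; \code{isolationIndex}, \code{isolationSD},
#'   \code{isolationP}: components of an \code{IsolationResult}.
#' @name mating-accessors
#' @aliases matingCounts designType strainLabels nReplicates nNoMating
#'   isolationIndex isolationSD isolationP
#' @export
matingCounts <- function(x) x@counts

#' @rdname mating-accessors
#' @export
designType <- function(x) x@design

#' @rdname mating-accessors
#' @export
strainLabels <- function(x) if (is(x, "MatingTable")) rownames(x@counts) else x@strains

#' @rdname mating-accessors
#' @export
nReplicates <- function(x) x@nReplicates

#' @rdname mating-accessors
#' @export
nNoMating <- function(x) x@nNoMating

#' @rdname mating-accessors
#' @export
isolationIndex <- function(x) x@ipsi

#' @rdname mating-accessors
#' @export
isolationSD <- function(x) x@ipsiSD

#' @rdname mating-accessors
#' @export
isolationP <- function(x) x@pValue

## Expected counts for a bare 2x2 matrix; the workhorse behind all the
## estimators and the bootstrap (which operates on raw matrices for speed).
.expectedCounts <- function(cnt, model) {
    tot <- sum(cnt)
    if (tot < 1) stop("at least one mating is required for estimation")
    if (model == "uniform") {
        e <- matrix(tot / 4, 2L, 2L, dimnames = dimnames(cnt))
        return(e)
    }
    r <- rowSums(cnt); cs <- colSums(cnt)
    if (any(r == 0) || any(cs == 0)) {
        bad <- c(
            if (any(r == 0)) paste0("female margin '", rownames(cnt)[r == 0], "'"),
            if (any(cs == 0)) paste0("male margin '", colnames(cnt)[cs == 0], "'"))
        stop("degenerate table: empty ", paste(bad, collapse = " and "),
             " under the marginal-product model")
    }
    e <- outer(r, cs) / tot
    dimnames(e) <- dimnames(cnt)
    e
}

#' Expected mating counts under a null model
#'
#' Computes the cell counts expected if mating between strains were random.
#' Under \code{"marginal_product"} the expectation preserves the observed
#' margins, \eqn{e_{ij} = r_i c_j / T}; under \code{"uniform"} every cell is
#' \eqn{T/4}.  Both conserve the total \eqn{T}.
#'
#' @param x a \linkS4class{MatingTable}.
#' @param model expected-frequency model.
#' @return 2x2 numeric matrix of expected counts.
#' @examples
#' tab <- MatingTable(c(17, 23, 33, 27), "male_choice", c("Eg", "Cam"))
#' expectedCounts(tab)                      # 20 20 / 30 30
#' @export
setMethod("expectedCounts", "MatingTable", function(x, model) {
    model <- match.arg(model, .EXPECTED_MODELS)
    .expectedCounts(x@counts, model)
})

#' Pair sexual isolation (PSI) coefficients
#'
#' The PSI coefficient of a pair type is the ratio of its observed to its
#' expected mating count, \eqn{\psi_{ij} = o_{ij} / e_{ij}}.  The
#' expectation-weighted mean of the coefficients is 1 by construction.
#'
#' @inheritParams expectedCounts
#' @return 2x2 matrix of PSI coefficients.
#' @export
setMethod("psiCoefficients", "MatingTable", function(x, model) {
    model <- match.arg(model, .EXPECTED_MODELS)
    e <- .expectedCounts(x@counts, model)
    if (any(e <= 0)) stop("expected counts must be strictly positive")
    x@counts / e
})

#' Pair total (PTI) coefficients
#'
#' The PTI coefficient is the ratio of the observed to the expected mating
#' *frequency*, \eqn{(o_{ij}/T)/(e_{ij}/T)}; it combines sexual selection and
#' sexual isolation and equals 1 for every pair under random mating with
#' equal propensities.  Numerically it coincides with PSI for a single 2x2
#' table, but is reported separately because it answers a different question
#' (total deviation, not isolation alone).
#'
#' @inheritParams expectedCounts
#' @return 2x2 matrix of PTI coefficients.
#' @examples
#' tab <- MatingTable(c(6, 44, 4, 46), "female_choice", c("ST", "Cam"))
#' ptiCoefficients(tab, model = "uniform")  # 0.24 1.76 / 0.16 1.84
#' @export
setMethod("ptiCoefficients", "MatingTable", function(x, model) {
    model <- match.arg(model, .EXPECTED_MODELS)
    tot <- sum(x@counts)
    (x@counts / tot) / (.expectedCounts(x@counts, model) / tot)
})

## ipsi on a bare matrix; fallback to the uniform expectation on degenerate
## margins is used only where explicitly requested (bootstrap replicates).
.ipsi <- function(cnt, model, degenerateUniform = FALSE) {
    e <- if (degenerateUniform &&
             (any(rowSums(cnt) == 0) || any(colSums(cnt) == 0)))
        matrix(sum(cnt) / 4, 2L, 2L)
    else .expectedCounts(cnt, model)
    psi <- cnt / e
    s <- sum(psi)
    if (s == 0) stop("isolation index undefined: all PSI coefficients are zero")
    (psi[1L, 1L] + psi[2L, 2L] - psi[1L, 2L] - psi[2L, 1L]) / s
}

#' Joint isolation index I_PSI
#'
#' Normalised contrast of homotypic versus heterotypic PSI coefficients,
#' \deqn{I_{PSI} = \frac{\psi_{AA} + \psi_{BB} - \psi_{AB} - \psi_{BA}}
#'                      {\psi_{AA} + \psi_{BB} + \psi_{AB} + \psi_{BA}},}
#' ranging from -1 (complete disassortative mating) through 0 (random
#' mating) to +1 (complete assortative mating / full sexual isolation).
#'
#' @inheritParams expectedCounts
#' @return a single number in [-1, 1].
#' @examples
#' ipsi(MatingTable(c(36, 19, 15, 43), "female_choice", c("Eg", "Cam")))
#' ipsi(MatingTable(c(10, 0, 0, 10)))      # 1: complete assortative mating
#' @export
setMethod("ipsi", "MatingTable", function(x, model) {
    model <- match.arg(model, .EXPECTED_MODELS)
    .ipsi(x@counts, model)
})

## Vectorised ipsi over columns of a 4 x n matrix of counts in the order
## (AA, BA, AB, BB) -- i.e. as.vector() of the 2x2 matrix.  Degenerate
## replicates (an empty margin) fall back to the uniform expectation so that
## every replicate contributes and nBoot stays exact.
.ipsiVec <- function(m, model) {
    tot <- colSums(m)
    if (model == "marginal_product") {
        r1 <- m[1L, ] + m[3L, ]; r2 <- m[2L, ] + m[4L, ]
        c1 <- m[1L, ] + m[2L, ]; c2 <- m[3L, ] + m[4L, ]
        e <- rbind(r1 * c1, r2 * c1, r1 * c2, r2 * c2) / rep(tot, each = 4L)
        bad <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
        if (any(bad)) e[, bad] <- rep(tot[bad] / 4, each = 4L)
    } else {
        e <- rep(tot / 4, each = 4L)
        dim(e) <- dim(m)
    }
    psi <- m / e
    (psi[1L, ] + psi[4L, ] - psi[2L, ] - psi[3L, ]) / colSums(psi)
}

#' Bootstrap inference for the isolation index
#'
#' Resamples the \eqn{T} observed copulations multinomially at the observed
#' pair frequencies, \code{nBoot} times, and recomputes \eqn{I_{PSI}} on each
#' replicate.  The standard deviation of the replicates is the bootstrap SD;
#' the p-value for deviation from random mating is the two-tailed
#' sign-crossing proportion \eqn{2\min(\Pr(I^* \le 0), \Pr(I^* \ge 0))},
#' capped at 1.  Replicates that draw an empty margin are recomputed under
#' the uniform expectation rather than dropped, so \code{nBoot} is exact.
#'
#' The full result is bit-reproducible given \code{seed}; the caller's RNG
#' state is left untouched.
#'
#' @inheritParams expectedCounts
#' @param nBoot number of bootstrap replicates (>= 100).
#' @param seed integer RNG seed, recorded in the result.
#' @return an \linkS4class{IsolationResult}.
#' @examples
#' tab <- MatingTable(c(36, 19, 15, 43), "female_choice", c("Eg", "Cam"),
#'                    nReplicates = 142)
#' bootstrapIsolation(tab, nBoot = 1000, seed = 7)
#' @export
setMethod("bootstrapIsolation", "MatingTable",
function(x, model, nBoot, seed) {
    model <- match.arg(model, .EXPECTED_MODELS)
    nBoot <- as.integer(nBoot)
    if (nBoot < 100L) stop("nBoot must be at least 100")
    cnt <- x@counts
    tot <- sum(cnt)
    if (tot < 4L) stop("too few matings for bootstrap inference (need T >= 4)")
    point <- .ipsi(cnt, model)
    psi <- psiCoefficients(x, model)
    pti <- ptiCoefficients(x, model)

    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    draws <- stats::rmultinom(nBoot, tot, as.vector(cnt) / tot)
    reps <- .ipsiVec(draws, model)

    p <- 2 * min(mean(reps <= 0), mean(reps >= 0))
    new("IsolationResult", psi = psi, pti = pti, ipsi = point,
        ipsiSD = stats::sd(reps), pValue = min(1, p), nBoot = nBoot,
        seed = as.integer(seed), expectedModel = model,
        design = x@design, strains = rownames(cnt))
})
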