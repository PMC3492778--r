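## Survival curves on a fixed inspection grid and median survival duration.

## Survival fractions at the grid times (t_0 = 0, t_k = k * interval).
.survFractions <- function(x) (x@n0 - cumsum(c(0L, x@deaths))) / x@n0

#' Survival curve from gridded mortality counts
#'
#' Step survival function from deaths recorded at fixed inspections:
#' \eqn{S(0) = 1} and \eqn{S(t_k)} = (survivors through interval k) / n0.
#' A death recorded at inspection k is taken to occur within
#' \eqn{(t_{k-1}, t_k]}, so the curve steps down at \eqn{t_k}.
#'
#' @param x a \linkS4class{SurvivalRecord}.
#' @param ... unused.
#' @return data.frame with columns \code{time_h} and \code{survival}
#'   (non-increasing, starting at 1).
#' @examples
#' survivalCurve(SurvivalRecord(c(0, 10), n0 = 10))
#' @export
setMethod("survivalCurve", "SurvivalRecord", function(x, ...) {
    data.frame(time_h = x@intervalH * seq(0L, length(x@deaths)),
               survival = .survFractions(x))
})

.msdPoint <- function(x, method) {
    s <- .survFractions(x)
    t <- x@intervalH * seq(0L, length(x@deaths))
    idx <- which(s <= 0.5)
    if (!length(idx))
        stop("median survival is censored: the curve never reaches 0.5 ",
             "(final survival ", signif(s[length(s)], 3), ")")
    k <- idx[1L]
    if (s[k] == 0.5 || method == "step") return(t[k])
    t[k - 1L] + x@intervalH * (s[k - 1L] - 0.5) / (s[k - 1L] - s[k])
}

#' Median survival duration (MSD)
#'
#' The time at which the survival curve crosses the horizontal 0.5 level, in
#' decimal hours.  By default the crossing is located by linear
#' interpolation between the last inspection with \eqn{S > 0.5} and the
#' first with \eqn{S \le 0.5}; if the curve hits exactly 0.5 at a grid time,
#' that time is returned.  \code{method = "step"} instead returns the first
#' grid time with \eqn{S \le 0.5}.  Records whose curve never reaches 0.5
#' raise a censored-median error rather than extrapolating.
#'
#' @param x a \linkS4class{SurvivalRecord}.
#' @param method \code{"interpolate"} (default) or \code{"step"}.
#' @return an \linkS4class{MsdEstimate} (point only; CI slots are NA).
#' @examples
#' rec <- SurvivalRecord(c(rep(0, 12), 6), n0 = 10)  # S: 1 ... then 0.4 at 6.5 h
#' msdHours(msd(rec))                                 # 6.417
#' @export
setMethod("msd", "SurvivalRecord", function(x, method) {
    method <- match.arg(method, c("interpolate", "step"))
    new("MsdEstimate", group = x@group, msdH = .msdPoint(x, method),
        ciLowH = NA_real_, ciHighH = NA_real_, level = NA_real_,
        nBoot = 0L, seed = NA_integer_)
})

#' Bootstrap confidence interval for the MSD
#'
#' Resamples the n0 individual death-interval assignments multinomially
#' (flies surviving past the last inspection form their own censored
#' category), recomputes the MSD on each replicate, and reports the
#' percentile interval at the requested level.  Replicates whose resampled
#' curve never reaches 0.5 are excluded from the percentiles; if more than
#' half are censored the estimate is deemed unstable and an error is raised.
#'
#' @param x a \linkS4class{SurvivalRecord}.
#' @param nBoot number of bootstrap replicates (>= 200).
#' @param seed integer RNG seed (caller's RNG state is preserved).
#' @param level confidence level (default 0.95).
#' @param method crossing rule, as in \code{\link{msd}}.
#' @return an \linkS4class{MsdEstimate} with CI bounds filled in.
#' @export
setMethod("msdCI", "SurvivalRecord", function(x, nBoot, seed, level, method) {
    method <- match.arg(method, c("interpolate", "step"))
    nBoot <- as.integer(nBoot)
    if (nBoot < 200L) stop("nBoot must be at least 200")
    point <- .msdPoint(x, method)

    nInt <- length(x@deaths)
    probs <- c(x@deaths, x@n0 - sum(x@deaths)) / x@n0
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    draws <- stats::rmultinom(nBoot, x@n0, probs)
    reps <- vapply(seq_len(nBoot), function(b) {
        rec <- new("SurvivalRecord", group = x@group, n0 = x@n0,
                   intervalH = x@intervalH,
                   deaths = draws[seq_len(nInt), b])
        tryCatch(.msdPoint(rec, method), error = function(e) NA_real_)
    }, numeric(1L))
    cens <- mean(is.na(reps))
    if (cens > 0.5)
        stop("unstable MSD estimate: ", round(100 * cens),
             "% of bootstrap resamples are censored")
    ci <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    new("MsdEstimate", group = x@group, msdH = point,
        ciLowH = min(ci[1L], point), ciHighH = max(ci[2L], point),
        level = level, nBoot = nBoot, seed = as.integer(seed))
})

#' Accessors for MsdEstimate
#'
#' @param x an \linkS4class{MsdEstimate}.
#' @return \code{msdHours}: the point estimate (decimal hours);
#'   \code{msdCIBounds}: c(low, high).
#' @name msd-accessors
#' @aliases msdHours msdCIBounds
#' @export
msdHours <- function(x) x@msdH

#' @rdname msd-accessors
#' @export
msdCIBounds <- function(x) c(x@ciLowH, x@ciHighH)
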