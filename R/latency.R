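## Courtship/copulation latency comparisons across pair types:
## Kruskal-Wallis with a rank-mean-difference post hoc and letter display.

## Compact letter display by insert-and-absorb: start from one letter shared
## by all groups; for each significant pair split every letter containing
## both; drop letters that are subsets of others.
.letterDisplay <- function(groups, sigPairs) {
    sets <- list(groups)
    for (k in seq_len(nrow(sigPairs))) {
        a <- sigPairs[k, 1L]; b <- sigPairs[k, 2L]
        out <- list()
        for (s in sets) {
            if (a %in% s && b %in% s)
                out <- c(out, list(setdiff(s, a), setdiff(s, b)))
            else out <- c(out, list(s))
        }
        out <- out[vapply(out, length, 1L) > 0L]
        keep <- rep(TRUE, length(out))
        for (i in seq_along(out)) for (j in seq_along(out))
            if (i != j && keep[j] && all(out[[i]] %in% out[[j]]) &&
                !(j < i && identical(out[[i]], out[[j]]))) keep[i] <- FALSE
        sets <- out[keep]
    }
    codes <- vapply(groups, function(g) paste(
        letters[which(vapply(sets, function(s) g %in% s, TRUE))],
        collapse = ""), "")
    names(codes) <- groups
    codes
}

#' Compare latencies across pair types
#'
#' Kruskal-Wallis test (tie-corrected H, via \code{\link[stats]{kruskal.test}})
#' across all pair-type groups, followed by pairwise comparisons using the
#' rank-mean-difference criterion: groups i and j differ when
#' \deqn{|\bar R_i - \bar R_j| \ge z_{1-\alpha/(k(k-1))}
#'       \sqrt{\frac{N(N+1)}{12}\left(\frac1{n_i}+\frac1{n_j}\right)},}
#' a Bonferroni-style correction over all \eqn{k(k-1)/2} pairs.  The result
#' includes a compact letter display: groups sharing no letter differ
#' significantly, as in the usual bar-plot annotation.
#'
#' @param data data.frame with one latency per row.
#' @param groupCol,valueCol column names for the pair-type label and the
#'   latency (minutes).
#' @param alpha family significance level.
#' @return a \linkS4class{LatencyComparison}.
#' @examples
#' d <- data.frame(pair_type = rep(c("EgxEg", "STxST", "CamxCam"), each = 5),
#'                 latency_min = c(6, 7, 5, 8, 6, 2, 3, 2, 3, 2, 4, 3, 4, 5, 4))
#' compareLatencies(d)
#' @export
compareLatencies <- function(data, groupCol = "pair_type",
                             valueCol = "latency_min", alpha = 0.05) {
    stopifnot(groupCol %in% names(data), valueCol %in% names(data))
    g <- factor(data[[groupCol]], levels = unique(data[[groupCol]]))
    y <- data[[valueCol]]
    if (any(y < 0)) stop("latencies must be non-negative")
    n <- table(g)
    if (nlevels(g) < 2L) stop("need at least two pair-type groups")
    if (any(n < 2L))
        stop("insufficient data in group(s): ",
             paste(names(n)[n < 2L], collapse = ", "))
    kw <- stats::kruskal.test(y, g)

    N <- length(y)
    rk <- rank(y)                           # midranks for ties
    rbar <- tapply(rk, g, mean)
    k <- nlevels(g)
    pairs <- utils::combn(levels(g), 2L)
    zcrit <- stats::qnorm(1 - alpha / (k * (k - 1)))
    diff <- abs(rbar[pairs[1L, ]] - rbar[pairs[2L, ]])
    crit <- zcrit * sqrt(N * (N + 1) / 12 *
                         (1 / n[pairs[1L, ]] + 1 / n[pairs[2L, ]]))
    sig <- diff >= crit
    pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                     rank_diff = as.numeric(diff),
                     critical = as.numeric(crit),
                     significant = as.logical(sig), row.names = NULL)
    codes <- .letterDisplay(levels(g),
                            cbind(pw$group1, pw$group2)[pw$significant, ,
                                                        drop = FALSE])
    new("LatencyComparison",
        statistic = unname(kw$statistic), df = as.integer(kw$parameter),
        pValue = kw$p.value, rankMeans = stats::setNames(as.numeric(rbar),
                                                         levels(g)),
        pairwise = pw, letters = codes, alpha = alpha)
}
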