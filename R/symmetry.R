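#' Inter-limb symmetry index
#'
#' SI = 100 * (dominant - nonDominant) / ((dominant + nonDominant) / 2),
#' in percent. Antisymmetric under limb swap and invariant under common
#' positive rescaling of both values; range (-200, 200) for positive
#' inputs, attaining +/-200 when one limb is zero.
#'
#' @param dominant,nonDominant per-muscle values (SUV in g/mL or AUV in
#'   g), both >= 0, not both zero.
#' @return SI in percent.
#' @examples
#' symmetryIndex(3, 1)   # +100
#' symmetryIndex(0, 2)   # -200
#' @export
symmetryIndex <- function(dominant, nonDominant) {
    if (any(dominant < 0) || any(nonDominant < 0))
        stop("limb values must be >= 0")
    s <- dominant + nonDominant
    if (any(s == 0))
        stop("symmetry index undefined when both limb values are zero")
    100 * (dominant - nonDominant) / (s / 2)
}

#' Absolute symmetry index
#'
#' ASI = |SI|; swap-invariant magnitude of the inter-limb asymmetry.
#'
#' @inheritParams symmetryIndex
#' @return ASI in percent, in [0, 200].
#' @export
absoluteSymmetryIndex <- function(dominant, nonDominant)
    abs(symmetryIndex(dominant, nonDominant))

#' Summarize per-subject absolute symmetry indices
#'
#' Median (midpoint of the two central order statistics for even n),
#' range, and the number of subjects whose ASI strictly exceeds the
#' threshold (default 25 percent).
#'
#' @param asi numeric vector of ASI values (percent), one per subject.
#' @param subjectIds optional identifiers, same length as \code{asi}.
#' @param threshold strict exceedance threshold in percent.
#' @return list with \code{median}, \code{min}, \code{max},
#'   \code{n_above_threshold}, \code{subject_ids_above}, \code{threshold}.
#' @export
summarizeAsymmetry <- function(asi, subjectIds = NULL, threshold = 25) {
    if (!length(asi)) stop("'asi' must be nonempty")
    if (is.null(subjectIds)) subjectIds <- seq_along(asi)
    stopifnot(length(subjectIds) == length(asi))
    above <- asi > threshold
    list(median = stats::median(asi), min = min(asi), max = max(asi),
         n_above_threshold = sum(above),
         subject_ids_above = subjectIds[above],
         threshold = threshold)
}

#' Exact paired signed-rank test
#'
#' Two-sided Wilcoxon matched-pair signed-rank test on paired differences.
#' Zero differences are dropped. For n <= \code{exactMax} (default 20) the
#' p-value is exact: the null distribution of the positive-rank sum is
#' enumerated over all 2^n equiprobable sign assignments, with midranks
#' for tied absolute differences, and the two-sided p is
#' \code{min(1, 2 * min(P(W <= w), P(W >= w)))}. Above that, a
#' tie-corrected normal approximation (no continuity correction) is used.
#'
#' @param diffs numeric vector of paired differences.
#' @param exactMax largest n for which the exact enumeration is used.
#' @return list with \code{statistic} (positive-rank sum W), \code{n}
#'   (pairs after zero removal), \code{p.value}, \code{method}, and
#'   \code{degenerate} (TRUE when all differences were zero, in which case
#'   p = 1).
#' @examples
#' pairedSignedRank(c(1, 2, 3, 4, 5))$p.value  # 0.0625 (= 2/32)
#' @export
pairedSignedRank <- function(diffs, exactMax = 20L) {
    if (!length(diffs)) stop("'diffs' must be nonempty")
    if (anyNA(diffs)) stop("'diffs' must not contain NA")
    d <- diffs[diffs != 0]
    n <- length(d)
    if (n == 0L)
        return(list(statistic = NA_real_, n = 0L, p.value = 1,
                    method = "degenerate", degenerate = TRUE))
    r <- rank(abs(d))                       # midranks for ties
    w <- sum(r[d > 0])
    if (n <= exactMax) {
        # Distribution of W over sign assignments by convolution; midranks
        # are half-integers so work on doubled ranks (exact integers).
        r2 <- as.integer(round(2 * r))
        total <- sum(r2)
        f <- numeric(total + 1L)            # f[s + 1] = #assignments with 2W = s
        f[1L] <- 1
        for (ri in r2) {
            g <- f
            g[(ri + 1L):(total + 1L)] <- g[(ri + 1L):(total + 1L)] +
                f[1L:(total + 1L - ri)]
            f <- g
        }
        f <- f / 2^n
        w2 <- round(2 * w)
        pLe <- sum(f[seq_len(w2 + 1L)])
        pGe <- sum(f[(w2 + 1L):(total + 1L)])
        p <- min(1, 2 * min(pLe, pGe))
        method <- "exact enumeration (midranks)"
    } else {
        mu <- n * (n + 1) / 4
        ties <- table(r)
        sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
            sum(ties^3 - ties) / 48
        z <- (w - mu) / sqrt(sig2)
        p <- min(1, 2 * stats::pnorm(-abs(z)))
        method <- "normal approximation (tie-corrected)"
    }
    list(statistic = w, n = n, p.value = p, method = method,
         degenerate = FALSE)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS statistic of the values against a normal distribution
#' with the sample mean and standard deviation, with the decision taken at
#' alpha = 0.05. Estimating the parameters from the same sample makes the
#' plain KS test anticonservative (the Lilliefors situation); it is kept
#' as the screening device because it is only used to choose downstream
#' non-parametric tests, not to report inference.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha decision level (default 0.05).
#' @return list with \code{statistic}, \code{p.value}, \code{reject}
#'   (TRUE when normality is rejected at \code{alpha}), \code{degenerate}
#'   (TRUE for constant input, which is flagged and rejected).
#' @export
normalityScreen <- function(values, alpha = 0.05) {
    if (length(values) < 3L) stop("need at least 3 values")
    if (anyNA(values)) stop("'values' must not contain NA")
    s <- stats::sd(values)
    if (s == 0)
        return(list(statistic = NA_real_, p.value = NA_real_,
                    reject = TRUE, degenerate = TRUE))
    kt <- suppressWarnings(
        stats::ks.test(values, "pnorm", mean(values), s))
    list(statistic = unname(kt$statistic), p.value = kt$p.value,
         reject = kt$p.value <= alpha, degenerate = FALSE)
}
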