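#' Sample skewness of a voxel value distribution
#'
#' Moment-based (population-style) skewness
#' \code{g1 = m3 / m2^(3/2)} with central moments
#' \code{mk = mean((x - mean(x))^k)}. Zero for symmetric distributions,
#' positive when the bulk of voxels sits at low uptake with a tail toward
#' high uptake. Invariant under positive affine rescaling, so it is the
#' same whether computed on Bq/mL or SUV values.
#'
#' @param values numeric vector, n >= 3, nonconstant.
#' @return dimensionless skewness.
#' @examples
#' sampleSkewness(c(1, 2, 3))        # 0
#' sampleSkewness(c(0, 0, 0, 1))     # 1.1547
#' @export
sampleSkewness <- function(values) {
    if (length(values) < 3L) stop("need at least 3 values")
    if (anyNA(values)) stop("'values' must not contain NA")
    c0 <- values - mean(values)
    m2 <- mean(c0^2)
    if (m2 == 0) stop("skewness undefined for constant input")
    mean(c0^3) / m2^1.5
}

#' Histogram of within-muscle uptake
#'
#' Equal-width bins spanning [min, max], left-closed with a right-closed
#' last bin, so every value is counted exactly once and counts sum to n.
#' When all values are identical, the full count lands in the first bin.
#'
#' @param values numeric vector, n >= 1.
#' @param nBins number of bins, >= 1 (default 50).
#' @return list with \code{breaks} (length nBins + 1), \code{counts}
#'   (length nBins), \code{n}.
#' @export
uptakeHistogram <- function(values, nBins = 50L) {
    if (!length(values)) stop("'values' must be nonempty")
    if (nBins < 1L) stop("'nBins' must be >= 1")
    nBins <- as.integer(nBins)
    lo <- min(values); hi <- max(values)
    breaks <- seq(lo, hi, length.out = nBins + 1L)
    if (hi == lo) {
        counts <- integer(nBins)
        counts[1L] <- length(values)
    } else {
        bin <- pmin(floor((values - lo) / (hi - lo) * nBins) + 1L, nBins)
        counts <- tabulate(bin, nbins = nBins)
    }
    list(breaks = breaks, counts = counts, n = length(values))
}
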