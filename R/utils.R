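# Internal helpers shared across modules.

# Half-up rounding (round(2.5) in base R rounds to even, which is not the
# convention used for the hot-voxel count).
halfUp <- function(x) floor(x + 0.5)

# Run code with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards so library functions never disturb user RNG.
withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        set.seed(as.integer(seed))
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
    }
    force(code)
}

# Sum of the six face-neighbor values of a logical/numeric 3D array, with
# zero padding outside the grid. The workhorse behind NHN counting and
# mask erosion.
faceNeighborSum <- function(a) {
    d <- dim(a)
    s <- array(0, d)
    if (d[1] > 1L) {
        s[-1, , ] <- s[-1, , ] + a[-d[1], , ]
        s[-d[1], , ] <- s[-d[1], , ] + a[-1, , ]
    }
    if (d[2] > 1L) {
        s[, -1, ] <- s[, -1, ] + a[, -d[2], ]
        s[, -d[2], ] <- s[, -d[2], ] + a[, -1, ]
    }
    if (d[3] > 1L) {
        s[, , -1] <- s[, , -1] + a[, , -d[3]]
        s[, , -d[3]] <- s[, , -d[3]] + a[, , -1]
    }
    s
}

#' Erode a binary region by whole voxels
#'
#' Removes, at each iteration, every voxel with fewer than six face
#' neighbors inside the region (grid borders count as outside). Used to
#' build interior-only ROIs where boundary/partial-volume effects of
#' smoothing are absent.
#'
#' @param region logical 3D array.
#' @param iterations number of one-voxel erosion passes.
#' @return logical 3D array.
#' @export
erodeMask <- function(region, iterations = 1L) {
    stopifnot(is.array(region), length(dim(region)) == 3L, iterations >= 0L)
    region <- region & TRUE
    for (i in seq_len(iterations))
        region <- region & (faceNeighborSum(region) == 6L)
    region
}

#' Box-plot statistics with the 1.5 IQR outlier rule
#'
#' Median and quartiles by linear interpolation, whiskers extending to the
#' most extreme points within \code{q1 - 1.5 (q3 - q1)} and
#' \code{q3 + 1.5 (q3 - q1)}, values beyond them flagged as outliers —
#' the convention the study-level figures use.
#'
#' @param x numeric vector.
#' @return list with \code{median}, \code{q1}, \code{q3},
#'   \code{whisker_low}, \code{whisker_high}, \code{outliers}, \code{n}.
#' @export
boxplotStats <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) stop("no finite values")
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[3] + 1.5 * iqr
    inside <- x >= lo & x <= hi
    list(median = q[2], q1 = q[1], q3 = q[3],
         whisker_low = min(x[inside]), whisker_high = max(x[inside]),
         outliers = sort(x[!inside]), n = length(x))
}
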