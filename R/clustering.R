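#' Classify ROI voxels as hot or cold
#'
#' The \code{m = max(1, round(fraction * N))} voxels with the highest
#' values (half-up rounding) are hot; the rest are cold. Ties at the
#' cutoff are broken deterministically by lexicographic voxel index
#' (lowest index first) and flagged. Classification depends only on value
#' ranks, so it is unchanged by any strictly increasing transform.
#'
#' @param values numeric vector of ROI voxel values in extraction order
#'   (see [extractRoiVoxels()]).
#' @param fraction target hot fraction in (0, 1); default 0.05.
#' @return list with \code{hot} (logical vector aligned with
#'   \code{values}), \code{m}, \code{n}, \code{fraction},
#'   \code{tiesBroken} (TRUE when the cutoff value was tied).
#' @examples
#' classifyHot(1:20)$m                 # 1 hot voxel
#' which(classifyHot(rep(1, 40))$hot)  # 1 2: tie-break by index
#' @export
classifyHot <- function(values, fraction = 0.05) {
    N <- length(values)
    if (!N) stop("empty ROI")
    if (length(fraction) != 1L || fraction <= 0 || fraction >= 1)
        stop("'fraction' must lie in (0, 1)")
    m <- max(1L, as.integer(halfUp(fraction * N)))
    m <- min(m, N)
    ord <- order(-values, seq_len(N), method = "radix")
    hot <- logical(N)
    hot[ord[seq_len(m)]] <- TRUE
    ties <- m < N && values[ord[m]] == values[ord[m + 1L]]
    list(hot = hot, m = m, n = N - m, fraction = fraction,
         tiesBroken = ties)
}

#' Count hot face-neighbors of every ROI voxel
#'
#' For each voxel inside the ROI, the number of its six face-adjacent
#' (6-connectivity) neighbors that are inside the ROI and hot. Neighbors
#' outside the ROI are never counted (they have no hot/cold status);
#' grid borders count as outside.
#'
#' @param hot logical 3D array, TRUE exactly at hot ROI voxels
#'   (\code{hot & !roi} must be all FALSE).
#' @param roi logical 3D array of the same shape marking the ROI.
#' @return integer 3D array of NHN values in [0, 6]; zero outside the ROI.
#' @export
countHotNeighbors <- function(hot, roi) {
    if (!identical(dim(hot), dim(roi)))
        stop("'hot' and 'roi' shapes differ")
    if (length(dim(roi)) != 3L) stop("expected 3D arrays")
    hot <- hot & TRUE; roi <- roi & TRUE
    if (any(hot & !roi)) stop("'hot' flags must lie inside the ROI")
    nhn <- faceNeighborSum(hot)
    nhn[!roi] <- 0
    storage.mode(nhn) <- "integer"
    nhn
}

#' Hot-voxel cluster index
#'
#' Mean NHN over hot voxels divided by the mean NHN over cold voxels
#' times the correction factor \code{(1 - fraction) / fraction} (= 19 at
#' the default 5 percent hot fraction, the cold-to-hot count ratio).
#' Under uniformly random placement of m hot voxels the expected index is
#' approximately \code{(m - 1) / (19 m)} (about 0.053), so values near
#' zero indicate homogeneous spread and values above one indicate strong
#' aggregation of the hot voxels; [permutationNull()] calibrates the
#' scale empirically.
#'
#' @param hot logical vector over ROI voxels (from [classifyHot()]).
#' @param nhn integer vector of NHN values over the same ROI voxels, in
#'   the same order.
#' @param fraction hot fraction used for the correction factor.
#' @return list with \code{meanNhnHot}, \code{meanNhnCold},
#'   \code{clusterIndex}, \code{correctionFactor}, \code{m}, \code{n},
#'   \code{flag} (\code{"ok"}, \code{"infinite"} when no cold voxel
#'   touches a hot one while hot voxels do cluster, or
#'   \code{"undefined"} when both means are zero).
#' @export
clusterIndex <- function(hot, nhn, fraction = 0.05) {
    if (length(hot) != length(nhn))
        stop("'hot' and 'nhn' lengths differ")
    m <- sum(hot); n <- sum(!hot)
    if (m < 1L || n < 1L)
        stop("need at least one hot and one cold voxel")
    corr <- (1 - fraction) / fraction
    # the factor is a count ratio (19 at 5%); snap float noise on it
    if (abs(corr - round(corr)) < 1e-9) corr <- round(corr)
    meanH <- mean(nhn[hot])
    meanC <- mean(nhn[!hot])
    if (meanC == 0) {
        flag <- if (meanH > 0) "infinite" else "undefined"
        idx <- if (meanH > 0) Inf else NaN
    } else {
        flag <- "ok"
        idx <- meanH / (meanC * corr)
    }
    list(meanNhnHot = meanH, meanNhnCold = meanC, clusterIndex = idx,
         correctionFactor = corr, m = m, n = n, flag = flag)
}

# Cluster index for one hot configuration given as ROI-voxel flags.
# roiIdx: linear indices of ROI voxels; dims: grid shape.
.indexFromFlags <- function(hotFlags, roiIdx, dims, roiArr, fraction) {
    hotArr <- array(FALSE, dims)
    hotArr[roiIdx[hotFlags]] <- TRUE
    nhn <- faceNeighborSum(hotArr)[roiIdx]
    m <- sum(hotFlags)
    corr <- (1 - fraction) / fraction
    meanH <- mean(nhn[hotFlags])
    meanC <- mean(nhn[!hotFlags])
    if (meanC == 0) return(if (meanH > 0) Inf else NaN)
    meanH / (meanC * corr)
}

#' Permutation null for the cluster index
#'
#' Shuffles the hot flags uniformly over the ROI voxels (keeping the hot
#' count m fixed) with a seeded generator, recomputes the cluster index
#' for each shuffle, and reports the empirical null mean/sd and the
#' empirical p-value \code{(1 + #(null >= observed)) / (nPermutations +
#' 1)} for the observed index.
#'
#' @param values numeric vector of ROI voxel values in extraction order.
#' @param roi logical 3D array marking the ROI (its \code{which()} order
#'   must match \code{values}).
#' @param fraction hot fraction (default 0.05).
#' @param nPermutations number of shuffles, >= 1.
#' @param seed integer RNG seed; same seed gives an identical null.
#' @return list with \code{observed}, \code{nullMean}, \code{nullSd},
#'   \code{p}, \code{nPermutations}, \code{m}.
#' @export
permutationNull <- function(values, roi, fraction = 0.05,
                            nPermutations = 200L, seed = NULL) {
    if (nPermutations < 1L) stop("'nPermutations' must be >= 1")
    roi <- roi & TRUE
    roiIdx <- which(roi)
    if (length(roiIdx) != length(values))
        stop("'values' length must equal the ROI voxel count")
    dims <- dim(roi)
    cls <- classifyHot(values, fraction)
    observed <- .indexFromFlags(cls$hot, roiIdx, dims, roi, fraction)
    N <- length(roiIdx)
    nulls <- withSeed(seed, {
        vapply(seq_len(nPermutations), function(i) {
            flags <- logical(N)
            flags[sample.int(N, cls$m)] <- TRUE
            .indexFromFlags(flags, roiIdx, dims, roi, fraction)
        }, numeric(1))
    })
    list(observed = observed, nullMean = mean(nulls), nullSd = stats::sd(nulls),
         p = (1 + sum(nulls >= observed)) / (nPermutations + 1),
         nPermutations = nPermutations, m = cls$m)
}

#' Full cluster analysis of one muscle ROI
#'
#' Convenience wrapper: extracts the ROI voxels, classifies hot/cold at
#' \code{fraction}, counts hot neighbors under 6-connectivity, computes
#' the cluster index, and (optionally) the permutation null.
#'
#' @param volume a [VolumeGrid-class].
#' @param mask an aligned [LabelMask-class].
#' @param label ROI label to analyze.
#' @param fraction hot fraction (default 0.05).
#' @param nPermutations permutations for the null; 0 to skip.
#' @param seed RNG seed for the null (required when
#'   \code{nPermutations > 0}).
#' @return list with \code{m}, \code{n}, \code{meanNhnHot},
#'   \code{meanNhnCold}, \code{clusterIndex}, \code{flag},
#'   \code{tiesBroken}, \code{hotIndex} (grid linear indices of hot
#'   voxels), and, when permutations were run, \code{nullMean},
#'   \code{nullSd}, \code{pPerm}.
#' @export
clusterAnalysis <- function(volume, mask, label, fraction = 0.05,
                            nPermutations = 0L, seed = NULL) {
    roiVox <- extractRoiVoxels(volume, mask, label)
    roiArr <- maskArray(mask) == as.integer(label)
    cls <- classifyHot(roiVox$values, fraction)
    hotArr <- array(FALSE, dim(mask))
    hotArr[roiVox$index[cls$hot]] <- TRUE
    nhnArr <- countHotNeighbors(hotArr, roiArr)
    ci <- clusterIndex(cls$hot, nhnArr[roiVox$index], fraction)
    out <- list(m = ci$m, n = ci$n, meanNhnHot = ci$meanNhnHot,
                meanNhnCold = ci$meanNhnCold,
                clusterIndex = ci$clusterIndex, flag = ci$flag,
                tiesBroken = cls$tiesBroken,
                hotIndex = roiVox$index[cls$hot])
    if (nPermutations > 0L) {
        if (is.null(seed))
            stop("'seed' is required when permutations are requested")
        pn <- permutationNull(roiVox$values, roiArr, fraction,
                              nPermutations, seed)
        out$nullMean <- pn$nullMean
        out$nullSd <- pn$nullSd
        out$pPerm <- pn$p
    }
    out
}

#' Export hot voxels as a NIfTI mask
#'
#' Writes a binary mask (1 = hot voxel) aligned to the source grid, for
#' 3D rendering of the clustered regions.
#'
#' @param hotIndex grid linear indices of hot voxels (e.g. from
#'   [clusterAnalysis()]).
#' @param reference a [VolumeGrid-class] or [LabelMask-class] providing
#'   the grid geometry.
#' @param path output NIfTI path.
#' @return \code{path}, invisibly.
#' @export
writeHotMask <- function(hotIndex, reference, path) {
    arr <- array(0L, dim(reference))
    arr[hotIndex] <- 1L
    writeLabelMask(labelMask(arr, spacing = spacing(reference),
                             origin = origin(reference)), path)
}
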