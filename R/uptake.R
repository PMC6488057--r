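#' Muscle volume from voxel occupancy
#'
#' @param voxelCount number of voxels in the ROI (>= 0).
#' @param spacing voxel spacing in mm, length 3.
#' @return volume in mL (\code{voxelCount * sx * sy * sz / 1000}).
#' @examples
#' muscleVolume(1000, c(1.6, 1.6, 2.0))  # 5.12 mL
#' @export
muscleVolume <- function(voxelCount, spacing) {
    if (any(voxelCount < 0)) stop("'voxelCount' must be >= 0")
    if (length(spacing) != 3L || any(spacing <= 0))
        stop("'spacing' must be 3 positive numbers (mm)")
    voxelCount * prod(spacing) / 1000
}

#' Standardized uptake value of a muscle
#'
#' SUV = (total activity / volume) / (injected activity at scan start /
#' body mass); units g/mL. The injected activity must already be decayed
#' to scan start (see [injectedAtScan()]).
#'
#' @param totalActivity measured total activity in the muscle (Bq).
#' @param volume muscle volume in mL, > 0.
#' @param injectedAtScan injected activity decayed to scan start (Bq), > 0.
#' @param bodyMass body mass in g, > 0.
#' @return SUV in g/mL.
#' @examples
#' computeSUV(1000, 10, 5e7, 70000)  # 0.14
#' @export
computeSUV <- function(totalActivity, volume, injectedAtScan, bodyMass) {
    if (any(volume <= 0)) stop("'volume' must be > 0")
    if (any(injectedAtScan <= 0)) stop("'injectedAtScan' must be > 0")
    if (any(bodyMass <= 0)) stop("'bodyMass' must be > 0")
    (totalActivity / volume) / (injectedAtScan / bodyMass)
}

#' Voxelwise SUV map
#'
#' Divides every voxel's activity concentration (Bq/mL) by injected
#' activity at scan start per gram of body mass, yielding an SUV (g/mL)
#' volume. The ROI mean of the result equals [computeSUV()] on the ROI's
#' mean-based total activity.
#'
#' @param volume a [VolumeGrid-class] in \code{"BQ_PER_ML"} units.
#' @param meta an [AcquisitionMeta-class].
#' @return a [VolumeGrid-class] with unit \code{"SUV"}.
#' @export
voxelwiseSUV <- function(volume, meta) {
    stopifnot(is(volume, "VolumeGrid"), is(meta, "AcquisitionMeta"))
    if (volume@unit != "BQ_PER_ML")
        stop("voxelwiseSUV expects a volume in Bq/mL")
    denom <- injectedAtScan(meta) / bodyMass(meta)
    volumeGrid(volume@values / denom, spacing = volume@spacing,
               origin = volume@origin, unit = "SUV")
}

#' Absolute uptake value
#'
#' AUV = mean SUV x muscle volume (g). Removes the per-volume
#' normalization of the SUV so inter-limb volume differences are carried
#' through.
#'
#' @param suvMean mean SUV of the muscle (g/mL).
#' @param volume muscle volume (mL), >= 0.
#' @return AUV in g.
#' @export
computeAUV <- function(suvMean, volume) {
    if (any(volume < 0)) stop("'volume' must be >= 0")
    suvMean * volume
}

#' Quantify all muscles of one limb volume
#'
#' Runs the per-muscle quantification chain for every label of a label
#' table on one limb's activity volume: ROI extraction, volume, mean SUV,
#' AUV, voxel distribution skewness, and the hot-voxel cluster analysis.
#'
#' @param volume a [VolumeGrid-class]; if in Bq/mL, \code{meta} is used to
#'   convert to SUV first.
#' @param mask an aligned [LabelMask-class].
#' @param labelTable data.frame as from [readLabelTable()] (rows for this
#'   limb).
#' @param meta an [AcquisitionMeta-class] (required when \code{volume} is
#'   in Bq/mL).
#' @param hotFraction hot-voxel fraction for the cluster index
#'   (default 0.05).
#' @param nPermutations permutations for the cluster-index null; 0 skips
#'   the permutation test.
#' @param seed RNG seed for the permutation null (required when
#'   \code{nPermutations > 0}).
#' @return data.frame with one row per muscle: \code{muscle}, \code{side},
#'   \code{segment}, \code{label}, \code{voxel_count}, \code{volume_ml},
#'   \code{suv_g_per_ml}, \code{auv_g}, \code{skewness}, \code{m_hot},
#'   \code{n_cold}, \code{mean_nhn_hot}, \code{mean_nhn_cold},
#'   \code{cluster_index}, \code{ties_flag}, and, when permutations are
#'   requested, \code{null_mean}, \code{null_sd}, \code{p_perm}.
#' @export
quantifyMuscles <- function(volume, mask, labelTable, meta = NULL,
                            hotFraction = 0.05, nPermutations = 0L,
                            seed = NULL) {
    stopifnot(is(volume, "VolumeGrid"), is(mask, "LabelMask"))
    checkAlignment(volume, mask)
    if (volume@unit == "BQ_PER_ML") {
        if (is.null(meta))
            stop("'meta' is required to convert a Bq/mL volume to SUV")
        volume <- voxelwiseSUV(volume, meta)
    }
    if (nPermutations > 0L && is.null(seed))
        stop("'seed' is required when permutations are requested")
    vv <- voxelVolumeMl(volume)
    rows <- lapply(seq_len(nrow(labelTable)), function(i) {
        lab <- labelTable$label[i]
        roi <- extractRoiVoxels(volume, mask, lab)
        volMl <- muscleVolume(roi$count, volume@spacing)
        suv <- mean(roi$values)
        ca <- clusterAnalysis(volume, mask, lab, fraction = hotFraction,
                              nPermutations = nPermutations,
                              seed = if (nPermutations > 0L)
                                  seed + labelTable$label[i] else NULL)
        out <- data.frame(
            muscle = labelTable$muscle_name[i],
            side = labelTable$side[i],
            segment = labelTable$segment[i],
            label = lab,
            voxel_count = roi$count,
            volume_ml = volMl,
            suv_g_per_ml = suv,
            auv_g = computeAUV(suv, volMl),
            skewness = if (roi$count >= 3L && stats::sd(roi$values) > 0)
                sampleSkewness(roi$values) else NA_real_,
            m_hot = ca$m,
            n_cold = ca$n,
            mean_nhn_hot = ca$meanNhnHot,
            mean_nhn_cold = ca$meanNhnCold,
            cluster_index = ca$clusterIndex,
            ties_flag = ca$tiesBroken,
            stringsAsFactors = FALSE)
        if (nPermutations > 0L) {
            out$null_mean <- ca$nullMean
            out$null_sd <- ca$nullSd
            out$p_perm <- ca$pPerm
        }
        out
    })
    do.call(rbind, rows)
}
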