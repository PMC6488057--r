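#' Convert a Gaussian FWHM to its standard deviation
#'
#' \code{sigma = fwhm / (2 * sqrt(2 * log(2)))}, i.e. fwhm / 2.35482.
#'
#' @param fwhm full width at half maximum (mm).
#' @return sigma in the same units.
#' @examples
#' fwhmToSigma(3)  # 1.2740 mm
#' @export
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

.gaussKernel1d <- function(sigmaVox) {
    if (sigmaVox <= 0) return(1)
    r <- max(1L, ceiling(4 * sigmaVox))
    k <- stats::dnorm(seq(-r, r), sd = sigmaVox)
    k / sum(k)
}

# Convolve a 3D array along one axis with a centered 1D kernel,
# zero-padded at the borders. Implemented as a band-matrix product on the
# unfolded array.
.convAxis <- function(arr, kern, axis) {
    if (length(kern) == 1L) return(arr * kern)
    d <- dim(arr)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    n <- d[axis]
    r <- (length(kern) - 1L) %/% 2L
    band <- matrix(0, n, n)
    for (off in -r:r) {
        i <- seq_len(n)
        j <- i + off
        ok <- j >= 1L & j <= n
        band[cbind(i[ok], j[ok])] <- kern[off + r + 1L]
    }
    band <- band / rowSums(band)   # renormalize truncated border rows
    out <- band %*% matrix(a, n, prod(d[perm[2:3]]))
    dim(out) <- d[perm]
    aperm(out, order(perm))
}

#' Separable 3D Gaussian smoothing by kernel FWHM
#'
#' Emulates scanner post-reconstruction filtering: a Gaussian kernel of
#' the given FWHM (mm) is applied along each axis, with the per-axis sigma
#' converted to voxel units by that axis's spacing, so anisotropic voxels
#' are handled correctly. The discrete kernel is truncated at 4 sigma and
#' renormalized to unit mass; at the grid borders the truncated kernel is
#' renormalized again, so constant fields pass through unchanged and the
#' total integral is preserved for signal supported away from the grid
#' edges. \code{fwhm = 0} is the identity.
#'
#' @param volume a [VolumeGrid-class].
#' @param fwhmMm kernel FWHM in mm, >= 0 (default 3).
#' @return smoothed [VolumeGrid-class] with unchanged geometry and unit.
#' @export
smoothFWHM <- function(volume, fwhmMm = 3) {
    stopifnot(is(volume, "VolumeGrid"))
    if (fwhmMm < 0) stop("'fwhmMm' must be >= 0")
    if (fwhmMm == 0) return(volume)
    sigmaMm <- fwhmToSigma(fwhmMm)
    arr <- volume@values
    for (axis in 1:3)
        arr <- .convAxis(arr, .gaussKernel1d(sigmaMm / volume@spacing[axis]),
                         axis)
    volumeGrid(arr, spacing = volume@spacing, origin = volume@origin,
               unit = volume@unit)
}

# Voxel-center world coordinates along each axis.
.axisCenters <- function(dims, spacing, origin)
    lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 0.5) * spacing[a])

# Linear indices of voxels whose centers lie inside the ellipsoid.
.ellipsoidIdx <- function(dims, spacing, origin, center, semiAxes) {
    ax <- .axisCenters(dims, spacing, origin)
    u <- (ax[[1]] - center[1]) / semiAxes[1]
    v <- (ax[[2]] - center[2]) / semiAxes[2]
    w <- (ax[[3]] - center[3]) / semiAxes[3]
    q <- outer(outer(u^2, v^2, `+`), w^2, `+`)
    which(q <= 1)
}

#' Ellipsoidal muscle ROI mask
#'
#' Labels every voxel whose center lies inside the axis-aligned ellipsoid;
#' a stand-in for anatomically segmented muscle ROIs. The ellipsoid must
#' fit entirely within the grid extent.
#'
#' @param dims grid dimensions (3 integers).
#' @param spacing voxel spacing in mm.
#' @param center ellipsoid center in world mm.
#' @param semiAxes ellipsoid semi-axes in mm, all > 0.
#' @param label label value to assign (default 1).
#' @param origin grid origin in mm.
#' @return a [LabelMask-class].
#' @export
ellipsoidMask <- function(dims, spacing = c(1.6, 1.6, 2.0), center,
                          semiAxes, label = 1L, origin = c(0, 0, 0)) {
    dims <- as.integer(dims)
    if (any(semiAxes <= 0)) stop("ellipsoid semi-axes must be > 0")
    lo <- center - semiAxes
    hi <- center + semiAxes
    if (any(lo < origin) || any(hi > origin + dims * spacing))
        stop("ellipsoid exceeds the grid bounds")
    arr <- array(0L, dims)
    arr[.ellipsoidIdx(dims, spacing, origin, center, semiAxes)] <-
        as.integer(label)
    labelMask(arr, spacing = spacing, origin = origin)
}

#' Mirror a mask or volume across the x axis
#'
#' Flips the array along the first (left-right) axis within the same grid,
#' emulating the mirrored geometry of the contralateral limb. Applying it
#' twice returns the original object.
#'
#' @param x a [LabelMask-class] or [VolumeGrid-class].
#' @return an object of the same class with the array reversed along x.
#' @export
mirrorMask <- function(x) {
    flip <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
    if (is(x, "LabelMask"))
        labelMask(flip(x@labels), spacing = x@spacing, origin = x@origin)
    else if (is(x, "VolumeGrid"))
        volumeGrid(flip(x@values), spacing = x@spacing, origin = x@origin,
                   unit = x@unit)
    else stop("'x' must be a LabelMask or VolumeGrid")
}

#' Gamma-distributed background uptake on an ROI
#'
#' Fills the ROI voxels with i.i.d. gamma(shape, scale) draws (zero
#' outside), realizing the right-skewed within-muscle uptake the analysis
#' expects: gamma skewness is \code{2 / sqrt(shape)} and its mean
#' \code{shape * scale}, so one parameter controls asymmetry and the
#' other the activity level.
#'
#' @param mask a [LabelMask-class]; all labels > 0 are filled unless
#'   \code{label} restricts to one ROI.
#' @param shape,scale gamma parameters, > 0.
#' @param seed integer seed, or NULL to draw from the current RNG state.
#' @param label optional single label to fill.
#' @return a [VolumeGrid-class] in Bq/mL.
#' @export
sampleBackground <- function(mask, shape, scale, seed = NULL,
                             label = NULL) {
    stopifnot(is(mask, "LabelMask"))
    if (shape <= 0 || scale <= 0) stop("'shape' and 'scale' must be > 0")
    idx <- if (is.null(label)) which(mask@labels > 0L)
           else which(mask@labels == as.integer(label))
    if (!length(idx)) stop("mask has no voxels to fill")
    arr <- array(0, dim(mask))
    arr[idx] <- withSeed(seed, stats::rgamma(length(idx), shape = shape,
                                             scale = scale))
    volumeGrid(arr, spacing = mask@spacing, origin = mask@origin,
               unit = "BQ_PER_ML")
}

#' Inject compact hot clusters into an ROI
#'
#' Multiplies voxels inside each spherical blob by \code{amplitude}. Blob
#' centers are drawn uniformly over the ROI voxels with a seeded
#' generator; blob membership is all ROI voxels within \code{radiusMm} of
#' the chosen center (world distance, so anisotropic spacing is
#' respected). The true blob voxel sets are returned for recovery tests.
#'
#' @param volume a [VolumeGrid-class].
#' @param mask an aligned [LabelMask-class].
#' @param label ROI label to inject into.
#' @param nClusters number of blobs, >= 0 (0 is the identity).
#' @param radiusMm blob radius in mm, > 0 and no larger than the ROI's
#'   largest half-extent.
#' @param amplitude multiplicative uptake factor, > 1.
#' @param seed integer seed, or NULL for the current RNG state.
#' @return list with \code{volume} (modified copy) and \code{blobs}
#'   (list of grid linear index vectors, one per cluster).
#' @export
injectHotClusters <- function(volume, mask, label, nClusters, radiusMm,
                              amplitude, seed = NULL) {
    checkAlignment(volume, mask)
    if (nClusters < 0L) stop("'nClusters' must be >= 0")
    if (nClusters == 0L) return(list(volume = volume, blobs = list()))
    if (radiusMm <= 0) stop("'radiusMm' must be > 0")
    if (amplitude <= 1) stop("'amplitude' must be > 1")
    idx <- which(mask@labels == as.integer(label))
    if (!length(idx)) stop("label ", label, " is absent from the mask")
    dims <- dim(mask)
    coord <- arrayInd(idx, dims)
    world <- sweep(coord - 0.5, 2, mask@spacing, `*`)
    world <- sweep(world, 2, mask@origin, `+`)
    halfExtent <- (apply(world, 2, max) - apply(world, 2, min)) / 2
    if (radiusMm > max(halfExtent))
        stop("'radiusMm' exceeds the ROI's largest half-extent")
    centersI <- withSeed(seed, sample.int(length(idx), nClusters,
                                          replace = TRUE))
    arr <- volume@values
    blobs <- lapply(centersI, function(ci) {
        d2 <- rowSums(sweep(world, 2, world[ci, ], `-`)^2)
        idx[d2 <= radiusMm^2]
    })
    for (b in blobs) arr[b] <- arr[b] * amplitude
    list(volume = volumeGrid(arr, spacing = volume@spacing,
                             origin = volume@origin, unit = volume@unit),
         blobs = blobs)
}

#' Build a PhantomSpec
#'
#' @param muscles data.frame with one row per muscle pair and columns
#'   \code{name}, \code{segment}, \code{label}, \code{cx}, \code{cy},
#'   \code{cz}, \code{ax}, \code{ay}, \code{az} (ellipsoid center and
#'   semi-axes, mm, in the dominant limb's half of the grid),
#'   \code{meanSUV} (target mean SUV of the dominant limb, g/mL),
#'   \code{gammaShape} (background gamma shape; skewness 2/sqrt(shape)),
#'   \code{targetSI} (inter-limb symmetry index, percent, in (-200, 200)),
#'   \code{nClusters}, \code{clusterRadiusMm}, \code{clusterAmplitude}.
#' @param gridDim,spacing,origin grid geometry (defaults 64 x 64 x 96 at
#'   1.6 x 1.6 x 2.0 mm).
#' @param fwhmMm post-smoothing FWHM in mm (default 3).
#' @param injectedActivity injected activity in Bq (default 53.6 MBq).
#' @param bodyMass body mass in g (default 70 kg).
#' @param uptakeMin injection-to-scan interval in minutes (default 60).
#' @param halfLife isotope half-life in minutes (default fluorine-18).
#' @param seed integer RNG seed.
#' @return a [PhantomSpec-class].
#' @seealso [defaultPhantomSpec()], [makePairedStudy()]
#' @export
phantomSpec <- function(muscles, gridDim = c(64L, 64L, 96L),
                        spacing = c(1.6, 1.6, 2.0), origin = c(0, 0, 0),
                        fwhmMm = 3, injectedActivity = 5.36e7,
                        bodyMass = 7e4, uptakeMin = 60,
                        halfLife = 109.77, seed = 42L) {
    new("PhantomSpec", gridDim = as.integer(gridDim),
        spacing = as.numeric(spacing), origin = as.numeric(origin),
        muscles = muscles, fwhmMm = as.numeric(fwhmMm),
        injectedActivity = as.numeric(injectedActivity),
        bodyMass = as.numeric(bodyMass), uptakeMin = as.numeric(uptakeMin),
        halfLife = as.numeric(halfLife), seed = as.integer(seed))
}

#' Default three-muscle paired-limb phantom
#'
#' One representative muscle per segment on the default 64 x 64 x 96 grid
#' (1.6 x 1.6 x 2.0 mm voxels): a gluteus-medius-like ellipsoid (pelvis,
#' moderate skew), a vastus-lateralis-like ellipsoid (thigh, mild skew)
#' and a gastrocnemius-medialis-like ellipsoid (lower leg, strong skew).
#' Mean SUVs follow typical walking-study magnitudes (0.6 - 1.5 g/mL);
#' each muscle carries two 6 mm hot clusters at amplitude 3, giving the
#' clustered hot-voxel structure the cluster index is designed to detect.
#'
#' @param targetSI length-3 numeric, target symmetry index (percent) for
#'   the pelvis, thigh and lower-leg muscle respectively.
#' @param seed integer RNG seed.
#' @param ... further arguments passed to [phantomSpec()] (e.g.
#'   \code{bodyMass}, \code{injectedActivity}, \code{fwhmMm}).
#' @return a [PhantomSpec-class].
#' @export
defaultPhantomSpec <- function(targetSI = c(15, -5, 42), seed = 42L, ...) {
    stopifnot(length(targetSI) == 3L)
    muscles <- data.frame(
        name = c("gluteus_medius", "vastus_lateralis",
                 "gastrocnemius_medialis"),
        segment = c("pelvis", "thigh", "lower_leg"),
        label = 1:3,
        cx = c(27, 27, 27), cy = c(51, 51, 51), cz = c(156, 96, 36),
        ax = c(16, 15, 13), ay = c(16, 15, 13), az = c(22, 26, 22),
        meanSUV = c(0.85, 0.64, 1.50),
        gammaShape = c(4, 16, 1),
        targetSI = as.numeric(targetSI),
        nClusters = 2L,
        clusterRadiusMm = 6,
        clusterAmplitude = 3,
        stringsAsFactors = FALSE)
    phantomSpec(muscles, seed = seed, ...)
}

#' Realize a synthetic paired-limb study
#'
#' Generates one subject's dominant and non-dominant limb volumes and
#' masks from a [PhantomSpec-class], with full ground truth. Per muscle:
#' an ellipsoidal ROI is filled with gamma background, hot clusters are
#' injected, and the non-dominant limb (the mirrored geometry, with its
#' own independent noise and clusters) is rescaled so that the analytic
#' symmetry index on pre-smoothing mean concentrations equals the
#' muscle's \code{targetSI} exactly. Both volumes are then smoothed with
#' the spec's FWHM. All randomness derives from the spec's seed; the same
#' spec yields a bit-identical study.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with \code{dominant} and \code{nonDominant} (each a list
#'   of \code{volume} and \code{mask}), \code{meta}
#'   ([AcquisitionMeta-class]), \code{labelTable} (both sides),
#'   \code{groundTruth} (per-muscle data.frame of realized pre-smoothing
#'   mean concentrations/SUVs and target SI, plus per-side blob voxel
#'   sets) and \code{spec}.
#' @export
makePairedStudy <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    m <- spec@muscles
    meta <- acquisitionMeta(spec@injectedActivity, 0, spec@uptakeMin,
                            halfLife = spec@halfLife,
                            bodyMass = spec@bodyMass)
    denom <- injectedAtScan(meta) / bodyMass(meta)   # Bq/mL per unit SUV

    buildMask <- function() {
        arr <- array(0L, spec@gridDim)
        for (i in seq_len(nrow(m))) {
            idx <- .ellipsoidIdx(spec@gridDim, spec@spacing, spec@origin,
                                 c(m$cx[i], m$cy[i], m$cz[i]),
                                 c(m$ax[i], m$ay[i], m$az[i]))
            if (any(arr[idx] != 0L)) stop("muscle ellipsoids overlap")
            lo <- c(m$cx[i], m$cy[i], m$cz[i]) -
                  c(m$ax[i], m$ay[i], m$az[i])
            hi <- c(m$cx[i], m$cy[i], m$cz[i]) +
                  c(m$ax[i], m$ay[i], m$az[i])
            if (any(lo < spec@origin) ||
                any(hi > spec@origin + spec@gridDim * spec@spacing))
                stop("muscle ellipsoid exceeds the grid bounds")
            arr[idx] <- m$label[i]
        }
        labelMask(arr, spacing = spec@spacing, origin = spec@origin)
    }

    withSeed(spec@seed, {
        maskDom <- buildMask()
        maskNd <- mirrorMask(maskDom)

        fillLimb <- function(mask) {
            vol <- volumeGrid(array(0, spec@gridDim),
                              spacing = spec@spacing, origin = spec@origin)
            blobs <- vector("list", nrow(m))
            for (i in seq_len(nrow(m))) {
                theta <- m$meanSUV[i] * denom / m$gammaShape[i]
                bg <- sampleBackground(mask, shape = m$gammaShape[i],
                                       scale = theta, label = m$label[i])
                inj <- injectHotClusters(bg, mask, m$label[i],
                                         nClusters = m$nClusters[i],
                                         radiusMm = m$clusterRadiusMm[i],
                                         amplitude = m$clusterAmplitude[i])
                vol@values <- vol@values + inj$volume@values
                blobs[[i]] <- inj$blobs
            }
            list(volume = vol, blobs = blobs)
        }

        dom <- fillLimb(maskDom)
        nd <- fillLimb(maskNd)

        truth <- data.frame(name = m$name, label = m$label,
                            segment = m$segment, targetSI = m$targetSI,
                            trueMeanConcDom = NA_real_,
                            trueMeanConcNonDom = NA_real_,
                            stringsAsFactors = FALSE)
        for (i in seq_len(nrow(m))) {
            idxD <- which(maskDom@labels == m$label[i])
            idxN <- which(maskNd@labels == m$label[i])
            muD <- mean(dom$volume@values[idxD])
            s <- m$targetSI[i]
            target <- muD * (200 - s) / (200 + s)
            nd$volume@values[idxN] <- nd$volume@values[idxN] *
                (target / mean(nd$volume@values[idxN]))
            truth$trueMeanConcDom[i] <- muD
            truth$trueMeanConcNonDom[i] <- target
        }
        truth$trueMeanSuvDom <- truth$trueMeanConcDom / denom
        truth$trueMeanSuvNonDom <- truth$trueMeanConcNonDom / denom

        volDom <- smoothFWHM(dom$volume, spec@fwhmMm)
        volNd <- smoothFWHM(nd$volume, spec@fwhmMm)

        labelTable <- rbind(
            data.frame(label = m$label, muscle_name = m$name,
                       side = "dominant", segment = m$segment,
                       stringsAsFactors = FALSE),
            data.frame(label = m$label, muscle_name = m$name,
                       side = "non_dominant", segment = m$segment,
                       stringsAsFactors = FALSE))

        list(dominant = list(volume = volDom, mask = maskDom),
             nonDominant = list(volume = volNd, mask = maskNd),
             meta = meta, labelTable = labelTable,
             groundTruth = list(perMuscle = truth,
                                blobs = list(dominant = dom$blobs,
                                             nonDominant = nd$blobs)),
             spec = spec)
    })
}
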