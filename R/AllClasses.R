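#' @import methods
NULL

#' VolumeGrid: a 3D scalar field with voxel geometry
#'
#' Container for a 3D image volume together with its voxel spacing (mm),
#' world origin (mm) and value unit. Arrays are indexed \code{[x, y, z]}
#' with x the fastest-varying (in-plane) axis and z the slice axis; world
#' coordinates of the center of voxel \code{(i, j, k)} (1-based) are
#' \code{origin + (c(i, j, k) - 0.5) * spacing}.
#'
#' @slot values double 3D array, activity concentration (Bq/mL) or SUV (g/mL).
#' @slot spacing numeric length-3, voxel spacing in mm, all > 0.
#' @slot origin numeric length-3, world coordinate (mm) of the grid corner.
#' @slot unit character, one of \code{"BQ_PER_ML"} or \code{"SUV"}.
#'
#' @seealso [volumeGrid()], [labelMask()]
#' @export
setClass("VolumeGrid",
    representation(
        values = "array",
        spacing = "numeric",
        origin = "numeric",
        unit = "character"
    )
)

setValidity("VolumeGrid", function(object) {
    msg <- NULL
    if (length(dim(object@values)) != 3L)
        msg <- c(msg, "'values' must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "'spacing' must be 3 positive finite numbers (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "'origin' must be 3 finite numbers (mm)")
    if (!object@unit %in% c("BQ_PER_ML", "SUV"))
        msg <- c(msg, "'unit' must be \"BQ_PER_ML\" or \"SUV\"")
    if (any(!is.finite(object@values)))
        msg <- c(msg, "'values' must be finite")
    if (is.null(msg)) TRUE else msg
})

#' LabelMask: a 3D integer label field aligned to a VolumeGrid
#'
#' Voxels labeled 0 are background; label k > 0 identifies muscle ROI k.
#' A mask is only usable with a [VolumeGrid-class] of identical shape,
#' spacing and origin (see [checkAlignment()]).
#'
#' @slot labels integer 3D array, all values >= 0.
#' @slot spacing numeric length-3, voxel spacing in mm.
#' @slot origin numeric length-3, world origin in mm.
#'
#' @export
setClass("LabelMask",
    representation(
        labels = "array",
        spacing = "numeric",
        origin = "numeric"
    )
)

setValidity("LabelMask", function(object) {
    msg <- NULL
    if (length(dim(object@labels)) != 3L)
        msg <- c(msg, "'labels' must be a 3D array")
    if (!is.integer(object@labels))
        msg <- c(msg, "'labels' must be integer storage mode")
    if (any(object@labels < 0L, na.rm = TRUE) || anyNA(object@labels))
        msg <- c(msg, "'labels' must be >= 0 and non-missing")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        msg <- c(msg, "'spacing' must be 3 positive numbers (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "'origin' must be 3 finite numbers (mm)")
    if (is.null(msg)) TRUE else msg
})

#' AcquisitionMeta: tracer and subject metadata for SUV computation
#'
#' Holds the injected activity, injection and scan-start times, isotope
#' half-life, subject body mass, and the DICOM rescale slope/intercept of
#' the stored pixel values. The default half-life is fluorine-18
#' (109.77 min).
#'
#' @slot injectedActivity numeric, injected activity at injection time (Bq).
#' @slot tInjection,tScanStart POSIXct timestamps; scan start must not
#'   precede injection.
#' @slot halfLife numeric, isotope half-life in minutes.
#' @slot bodyMass numeric, subject body mass in grams.
#' @slot rescaleSlope,rescaleIntercept numeric, affine map from stored
#'   pixel values to Bq/mL.
#'
#' @export
setClass("AcquisitionMeta",
    representation(
        injectedActivity = "numeric",
        tInjection = "POSIXct",
        tScanStart = "POSIXct",
        halfLife = "numeric",
        bodyMass = "numeric",
        rescaleSlope = "numeric",
        rescaleIntercept = "numeric"
    )
)

setValidity("AcquisitionMeta", function(object) {
    msg <- NULL
    if (length(object@injectedActivity) != 1L || object@injectedActivity <= 0)
        msg <- c(msg, "'injectedActivity' must be a single positive value (Bq)")
    if (length(object@bodyMass) != 1L || object@bodyMass <= 0)
        msg <- c(msg, "'bodyMass' must be a single positive value (g)")
    if (length(object@halfLife) != 1L || object@halfLife <= 0)
        msg <- c(msg, "'halfLife' must be a single positive value (min)")
    if (length(object@tInjection) != 1L || length(object@tScanStart) != 1L)
        msg <- c(msg, "times must be single timestamps")
    else if (as.numeric(object@tScanStart) < as.numeric(object@tInjection))
        msg <- c(msg, "'tScanStart' must not precede 'tInjection'")
    if (object@rescaleSlope == 0)
        msg <- c(msg, "'rescaleSlope' must be nonzero")
    if (is.null(msg)) TRUE else msg
})

#' PhantomSpec: full parameterization of a synthetic paired-limb study
#'
#' Describes one subject's synthetic study: the grid, the per-muscle
#' ellipsoidal ROIs with their uptake distribution (gamma background,
#' injected hot clusters), the inter-limb target symmetry index per muscle,
#' the post-reconstruction Gaussian smoothing, the acquisition metadata and
#' the RNG seed. [makePairedStudy()] realizes it into two limbs' volumes,
#' masks and recorded ground truth.
#'
#' @slot gridDim integer length-3, voxels per axis.
#' @slot spacing numeric length-3, voxel spacing in mm (default
#'   c(1.6, 1.6, 2.0), the scanner geometry the pipeline targets).
#' @slot origin numeric length-3, world origin in mm.
#' @slot muscles data.frame, one row per muscle pair; see [phantomSpec()].
#' @slot fwhmMm numeric, post-smoothing Gaussian kernel FWHM in mm.
#' @slot injectedActivity numeric, Bq at injection.
#' @slot bodyMass numeric, g.
#' @slot uptakeMin numeric, minutes between injection and scan start.
#' @slot halfLife numeric, isotope half-life in minutes.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("PhantomSpec",
    representation(
        gridDim = "integer",
        spacing = "numeric",
        origin = "numeric",
        muscles = "data.frame",
        fwhmMm = "numeric",
        injectedActivity = "numeric",
        bodyMass = "numeric",
        uptakeMin = "numeric",
        halfLife = "numeric",
        seed = "integer"
    )
)

.phantomMuscleCols <- c("name", "segment", "label",
    "cx", "cy", "cz", "ax", "ay", "az",
    "meanSUV", "gammaShape", "targetSI",
    "nClusters", "clusterRadiusMm", "clusterAmplitude")

setValidity("PhantomSpec", function(object) {
    msg <- NULL
    if (length(object@gridDim) != 3L || any(object@gridDim < 1L))
        msg <- c(msg, "'gridDim' must be 3 positive integers")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        msg <- c(msg, "'spacing' must be 3 positive numbers (mm)")
    miss <- setdiff(.phantomMuscleCols, names(object@muscles))
    if (length(miss))
        msg <- c(msg, paste0("'muscles' lacks columns: ",
            paste(miss, collapse = ", ")))
    else {
        m <- object@muscles
        if (nrow(m) < 1L) msg <- c(msg, "'muscles' must have >= 1 row")
        if (any(m$ax <= 0 | m$ay <= 0 | m$az <= 0))
            msg <- c(msg, "ellipsoid semi-axes must be > 0")
        if (any(m$gammaShape <= 0) || any(m$meanSUV <= 0))
            msg <- c(msg, "gammaShape and meanSUV must be > 0")
        if (any(abs(m$targetSI) >= 200))
            msg <- c(msg, "targetSI must lie strictly inside (-200, 200)")
        if (anyDuplicated(m$label))
            msg <- c(msg, "muscle labels must be unique")
    }
    if (object@fwhmMm < 0) msg <- c(msg, "'fwhmMm' must be >= 0")
    if (object@injectedActivity <= 0 || object@bodyMass <= 0 ||
        object@halfLife <= 0 || object@uptakeMin < 0)
        msg <- c(msg, "acquisition fields must be positive (uptakeMin >= 0)")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "VolumeGrid", function(object) {
    d <- dim(object@values)
    cat(sprintf("VolumeGrid %d x %d x %d [%s]\n", d[1], d[2], d[3],
        object@unit))
    cat(sprintf("  spacing: %.3g x %.3g x %.3g mm; origin: (%.3g, %.3g, %.3g) mm\n",
        object@spacing[1], object@spacing[2], object@spacing[3],
        object@origin[1], object@origin[2], object@origin[3]))
    cat(sprintf("  value range: [%.4g, %.4g]\n",
        min(object@values), max(object@values)))
})

setMethod("show", "LabelMask", function(object) {
    d <- dim(object@labels)
    labs <- sort(unique(object@labels[object@labels > 0L]))
    cat(sprintf("LabelMask %d x %d x %d; %d ROI label(s)\n",
        d[1], d[2], d[3], length(labs)))
    cat(sprintf("  spacing: %.3g x %.3g x %.3g mm; labeled voxels: %d\n",
        object@spacing[1], object@spacing[2], object@spacing[3],
        sum(object@labels > 0L)))
})

setMethod("show", "AcquisitionMeta", function(object) {
    cat(sprintf(
        "AcquisitionMeta: %.3g MBq injected, body mass %.3g kg, T1/2 %.4g min\n",
        object@injectedActivity / 1e6, object@bodyMass / 1e3, object@halfLife))
    cat(sprintf("  uptake interval %.4g min; rescale %g * x + %g\n",
        uptakeMinutes(object), object@rescaleSlope, object@rescaleIntercept))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec: %d muscle pair(s) on %d x %d x %d grid, seed %d\n",
        nrow(object@muscles), object@gridDim[1], object@gridDim[2],
        object@gridDim[3], object@seed))
    cat(sprintf("  smoothing FWHM %.3g mm; target SI: %s\n", object@fwhmMm,
        paste(sprintf("%s=%g%%", object@muscles$name, object@muscles$targetSI),
            collapse = ", ")))
})

#' Construct a VolumeGrid
#'
#' @param values numeric 3D array.
#' @param spacing voxel spacing in mm, length 3.
#' @param origin world origin in mm, length 3.
#' @param unit \code{"BQ_PER_ML"} (default) or \code{"SUV"}.
#' @return A [VolumeGrid-class].
#' @examples
#' vg <- volumeGrid(array(1, c(4, 4, 4)), spacing = c(1.6, 1.6, 2.0))
#' spacing(vg)
#' @export
volumeGrid <- function(values, spacing = c(1.6, 1.6, 2.0),
                       origin = c(0, 0, 0), unit = "BQ_PER_ML") {
    storage.mode(values) <- "double"
    new("VolumeGrid", values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin), unit = unit)
}

#' Construct a LabelMask
#'
#' @param labels integer 3D array (coerced), 0 = background.
#' @param spacing,origin grid geometry in mm, as in [volumeGrid()].
#' @return A [LabelMask-class].
#' @export
labelMask <- function(labels, spacing = c(1.6, 1.6, 2.0),
                      origin = c(0, 0, 0)) {
    storage.mode(labels) <- "integer"
    new("LabelMask", labels = labels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Construct AcquisitionMeta
#'
#' Times may be given as POSIXct, or numerically as minutes on a common
#' clock (converted internally); only their difference matters.
#'
#' @param injectedActivity injected activity in Bq (at injection time).
#' @param tInjection,tScanStart injection / scan-start times (POSIXct or
#'   minutes as numbers).
#' @param halfLife isotope half-life in minutes; default fluorine-18.
#' @param bodyMass subject body mass in grams.
#' @param rescaleSlope,rescaleIntercept stored-value rescale (DICOM header
#'   convention); defaults 1 and 0.
#' @return An [AcquisitionMeta-class].
#' @examples
#' meta <- acquisitionMeta(5.36e7, 0, 60, bodyMass = 70000)
#' injectedAtScan(meta)  # decayed over 60 min of F-18
#' @export
acquisitionMeta <- function(injectedActivity, tInjection, tScanStart,
                            halfLife = 109.77, bodyMass,
                            rescaleSlope = 1, rescaleIntercept = 0) {
    toTime <- function(t) {
        if (inherits(t, "POSIXct")) t
        else as.POSIXct(as.numeric(t) * 60, origin = "2000-01-01", tz = "UTC")
    }
    new("AcquisitionMeta",
        injectedActivity = as.numeric(injectedActivity),
        tInjection = toTime(tInjection), tScanStart = toTime(tScanStart),
        halfLife = as.numeric(halfLife), bodyMass = as.numeric(bodyMass),
        rescaleSlope = as.numeric(rescaleSlope),
        rescaleIntercept = as.numeric(rescaleIntercept))
}
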