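#' Read a 3D activity volume
#'
#' Reads a NIfTI-1 volume into a [VolumeGrid-class]. Voxel spacing is taken
#' from the header pixdim and the world origin from the sform/qform
#' translation. Values are returned in stored units; apply
#' [applyRescale()] if the source encodes an affine rescale
#' (slope/intercept) rather than physical Bq/mL.
#'
#' Only NIfTI input is supported; scanner DICOM series must be converted
#' to NIfTI upstream (any standard converter preserves the rescale
#' slope/intercept, which this package then applies explicitly).
#'
#' @param path file path to a .nii or .nii.gz volume.
#' @param format input format; currently only \code{"nifti"}.
#' @param unit unit tag for the stored values, \code{"BQ_PER_ML"} (default)
#'   or \code{"SUV"}.
#' @return A [VolumeGrid-class].
#' @seealso [writeVolume()], [readLabelMask()], [applyRescale()]
#' @export
readVolume <- function(path, format = c("nifti", "dicom"),
                       unit = "BQ_PER_ML") {
    format <- match.arg(format)
    if (format == "dicom")
        stop("DICOM series input is not supported; convert to NIfTI first")
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    geo <- .niftiGeometry(img)
    arr <- .bareArray(img)
    if (length(dim(arr)) != 3L) stop("expected a 3D volume: ", path)
    volumeGrid(arr, spacing = geo$spacing, origin = geo$origin, unit = unit)
}

#' Read a 3D label mask
#'
#' @param path file path to a .nii or .nii.gz integer label image
#'   (0 = background, k > 0 = ROI k).
#' @return A [LabelMask-class].
#' @export
readLabelMask <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    geo <- .niftiGeometry(img)
    arr <- .bareArray(img)
    if (length(dim(arr)) != 3L) stop("expected a 3D mask: ", path)
    if (max(abs(arr - round(arr))) > 0)
        stop("mask contains non-integer labels: ", path)
    labelMask(round(arr), spacing = geo$spacing, origin = geo$origin)
}

.niftiGeometry <- function(img) {
    pd <- RNifti::pixdim(img)[1:3]
    xf <- RNifti::xform(img)
    list(spacing = abs(as.numeric(pd)), origin = as.numeric(xf[1:3, 4]))
}

# Strip the niftiImage class/attributes down to a bare R array.
.bareArray <- function(img) {
    arr <- as.array(img)
    array(as.vector(arr), dim = dim(arr))
}

.niftiFrom <- function(arr, spacing, origin) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing
    m <- diag(c(spacing, 1))
    m[1:3, 4] <- origin
    RNifti::`sform<-`(img, structure(m, code = 2L))
}

#' Write a VolumeGrid or LabelMask to NIfTI
#'
#' Volumes are stored as float64 so values round-trip bit-exactly; masks as
#' int32. Spacing goes to pixdim and origin to an axis-aligned sform.
#'
#' @param x a [VolumeGrid-class] (\code{writeVolume}) or
#'   [LabelMask-class] (\code{writeLabelMask}).
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(x, path) {
    stopifnot(is(x, "VolumeGrid"))
    img <- .niftiFrom(x@values, x@spacing, x@origin)
    RNifti::writeNifti(img, path, datatype = "double")
    invisible(path)
}

#' @rdname writeVolume
#' @export
writeLabelMask <- function(x, path) {
    stopifnot(is(x, "LabelMask"))
    img <- .niftiFrom(x@labels, x@spacing, x@origin)
    RNifti::writeNifti(img, path, datatype = "int32")
    invisible(path)
}

#' Check that a mask is aligned to a volume
#'
#' A [LabelMask-class] may only be combined with a [VolumeGrid-class]
#' of identical shape and (to numerical tolerance) identical spacing and
#' origin.
#'
#' @param volume a VolumeGrid.
#' @param mask a LabelMask.
#' @return TRUE, invisibly; otherwise an error.
#' @export
checkAlignment <- function(volume, mask) {
    stopifnot(is(volume, "VolumeGrid"), is(mask, "LabelMask"))
    if (!identical(dim(volume@values), dim(mask@labels)))
        stop("mask shape does not match volume shape")
    if (max(abs(volume@spacing - mask@spacing)) > 1e-6)
        stop("mask spacing does not match volume spacing")
    if (max(abs(volume@origin - mask@origin)) > 1e-3)
        stop("mask origin does not match volume origin")
    invisible(TRUE)
}

#' Apply a stored-value rescale
#'
#' Maps stored pixel values to physical activity concentration via the
#' affine transform \code{stored * slope + intercept} (the DICOM
#' RescaleSlope/RescaleIntercept convention).
#'
#' @param stored numeric array or vector of stored values.
#' @param slope nonzero scale factor.
#' @param intercept additive offset.
#' @return numeric array of the same shape, in Bq/mL.
#' @examples
#' applyRescale(100, slope = 2, intercept = 5)  # 205
#' @export
applyRescale <- function(stored, slope, intercept = 0) {
    if (length(slope) != 1L || !is.finite(slope) || slope == 0)
        stop("'slope' must be a single nonzero finite number")
    stored * slope + intercept
}

#' Radioactive decay of an activity over elapsed time
#'
#' Returns the activity remaining after \code{elapsed} minutes:
#' \code{a0 * 2^(-elapsed / halfLife)}. Dividing the SUV denominator
#' (injected activity) by the decay over the injection-to-scan interval is
#' the decay correction applied before computing SUVs.
#'
#' @param a0 activity at time zero (Bq).
#' @param elapsed elapsed time in minutes, >= 0.
#' @param halfLife isotope half-life in minutes; default fluorine-18
#'   (109.77 min).
#' @return decayed activity in Bq.
#' @examples
#' decayCorrectActivity(100, 109.77, 109.77)  # one half-life: 50
#' @export
decayCorrectActivity <- function(a0, elapsed, halfLife = 109.77) {
    if (any(elapsed < 0)) stop("'elapsed' must be >= 0")
    if (length(halfLife) != 1L || halfLife <= 0)
        stop("'halfLife' must be a single positive number")
    a0 * 2^(-elapsed / halfLife)
}

#' Extract the voxel values of one ROI
#'
#' Returns the volume values at voxels whose mask label equals
#' \code{label}, in deterministic lexicographic index order (x fastest,
#' then y, then z — R's array linear order), together with the linear
#' indices and the occupancy count.
#'
#' @param volume a [VolumeGrid-class].
#' @param mask an aligned [LabelMask-class].
#' @param label positive integer label present in the mask.
#' @return list with \code{values} (numeric vector), \code{index}
#'   (integer linear indices into the grid) and \code{count}.
#' @export
extractRoiVoxels <- function(volume, mask, label) {
    checkAlignment(volume, mask)
    label <- as.integer(label)
    if (length(label) != 1L || is.na(label) || label <= 0L)
        stop("'label' must be a single positive integer")
    idx <- which(mask@labels == label)
    if (!length(idx)) stop("label ", label, " is absent from the mask")
    list(values = volume@values[idx], index = idx, count = length(idx))
}

#' Read a muscle label table
#'
#' CSV sidecar mapping mask labels to muscles, with columns
#' \code{label}, \code{muscle_name}, \code{side} (\code{dominant} /
#' \code{non_dominant}), \code{segment} (\code{pelvis} / \code{thigh} /
#' \code{lower_leg}) and optional \code{subject_id}.
#'
#' @param path CSV file path.
#' @return data.frame with validated columns.
#' @export
readLabelTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("label", "muscle_name", "side", "segment")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("label table lacks columns: ", paste(miss, collapse = ", "))
    if (!all(tab$side %in% c("dominant", "non_dominant")))
        stop("side must be 'dominant' or 'non_dominant'")
    if (!all(tab$segment %in% c("pelvis", "thigh", "lower_leg")))
        stop("segment must be 'pelvis', 'thigh' or 'lower_leg'")
    tab$label <- as.integer(tab$label)
    if (anyNA(tab$label) || any(tab$label <= 0L))
        stop("labels must be positive integers")
    tab
}
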