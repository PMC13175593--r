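#' CT volume container
#'
#' A 3-D scalar grid of Hounsfield-unit (HU) values with per-axis voxel
#' spacing in millimetres and the world position of the centre of voxel
#' `[1, 1, 1]`. Array axes follow the fixed convention
#' (sagittal, coronal, axial): axis 3 is axial. World coordinates use the
#' voxel-centre convention `world = origin + (index - 1) * spacing`.
#'
#' @param voxels 3-D numeric array of HU values; every dimension must be >= 2.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, world coordinate (mm) of voxel `[1,1,1]`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array, got ", length(dim(voxels)), " dimensions")
  if (any(dim(voxels) < 2L))
    stop("every volume axis must have length >= 2 (got ",
         paste(dim(voxels), collapse = "x"), ")")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing (", paste(signif(x$spacing, 4), collapse = ", "),
      ") mm\n  HU range [", round(min(x$voxels)), ", ",
      round(max(x$voxels)), "]\n", sep = "")
  invisible(x)
}

#' Binary voxel mask derived from a CT volume
#'
#' @param voxels 3-D logical array.
#' @param spacing,origin inherited from the source [ct_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.logical(voxels), length(dim(voxels)) == 3L)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, ", sum(x$voxels), " true\n", sep = "")
  invisible(x)
}

#' Load a CT volume from NIfTI or a DICOM series directory
#'
#' NIfTI voxel values are used as stored (assumed HU); DICOM stored values
#' are converted to HU with the rescale slope and intercept. Spacing is taken
#' from the file metadata and must be present and positive.
#'
#' @param path file path (`.nii`/`.nii.gz`) or a directory holding a single
#'   DICOM series.
#' @param format `"auto"` (directory implies DICOM), `"nifti"` or
#'   `"dicom_dir"`.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input path does not exist: ", path)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  if (format == "dicom_dir")
    return(read_dicom_series(path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume, got dimensions ",
         paste(dim(arr), collapse = "x"))
  if (any(dim(arr) < 2L))
    stop("volume has a degenerate axis (length < 2): ",
         paste(dim(arr), collapse = "x"))
  xf <- RNifti::xform(img)
  code <- attr(xf, "code")
  if (!is.null(code) && code > 0) {
    spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
    origin <- xf[1:3, 4]
  } else {
    spacing <- RNifti::pixdim(img)[1:3]
    origin <- c(0, 0, 0)
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing or invalid voxel spacing in NIfTI header (pixdim/sform)")
  ct_volume(arr, spacing = spacing, origin = origin)
}

#' Write a CT volume (or mask) as NIfTI
#'
#' Spacing and origin are stored in the sform (code 2).
#'
#' @param vol a [ct_volume()] or [binary_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- vol$voxels
  if (is.logical(arr)) arr <- array(as.integer(arr), dim = dim(arr))
  img <- RNifti::asNifti(arr)
  m <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Gaussian smoothing followed by HU thresholding
#'
#' The physical smoothing scale `sigma_mm` is converted per axis to voxel
#' units so anisotropic voxels are smoothed isotropically in world space.
#' With `sigma_mm = 0` this is pure thresholding.
#'
#' @param vol a [ct_volume()].
#' @param sigma_mm Gaussian sigma in mm (>= 0). Default 0.5 mm.
#' @param hu_threshold voxels with smoothed HU >= this are kept.
#'   Default 300 HU (lower bound of cortical bone).
#' @return A [binary_mask()].
#' @export
smooth_and_threshold <- function(vol, sigma_mm = 0.5, hu_threshold = 300) {
  stopifnot(inherits(vol, "ct_volume"))
  if (sigma_mm < 0) stop("sigma_mm must be >= 0")
  arr <- vol$voxels
  if (sigma_mm > 0) {
    arr <- .gaussian_blur3d_cpp(as.double(arr), dim(vol$voxels),
                                sigma_mm / vol$spacing)
  }
  binary_mask(array(arr >= hu_threshold, dim = dim(vol$voxels)),
              vol$spacing, vol$origin)
}

#' Keep only the largest connected component of a mask
#'
#' Size ties are broken in favour of the component containing the lowest
#' linear voxel index (components are labelled in raster-scan order, so the
#' smallest qualifying label wins).
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6, 18 or 26 (default) voxel connectivity.
#' @return A [binary_mask()] with a single connected component.
#' @export
largest_component <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  if (!any(mask$voxels))
    stop("empty segmentation: mask has no true voxels")
  lab <- .label_components_cpp(mask$voxels, dim(mask$voxels),
                               as.integer(connectivity))
  sizes <- tabulate(lab)
  keep <- which(sizes == max(sizes))[1]  # labels assigned in scan order
  binary_mask(array(lab == keep, dim = dim(mask$voxels)),
              mask$spacing, mask$origin)
}

#' Per-axial-slice morphological closing and hole filling
#'
#' Each axial slice (array axis 3) is processed independently in 2-D:
#' dilation by a disc of radius `dilate_r`, hole filling, then erosion by
#' `erode_r`. With `dilate_r = erode_r` the outer contour scale is
#' approximately preserved while gaps up to `2 * dilate_r` voxels are
#' bridged, yielding a solid head cross-section per slice.
#'
#' @param mask a [binary_mask()].
#' @param dilate_r,erode_r disc radii in voxels, `dilate_r >= erode_r >= 0`.
#' @return A [binary_mask()] of solid cross-sections.
#' @export
axial_close_and_fill <- function(mask, dilate_r = 3, erode_r = 3) {
  stopifnot(inherits(mask, "binary_mask"))
  if (erode_r < 0 || dilate_r < erode_r)
    stop("need dilate_r >= erode_r >= 0")
  vox <- mask$voxels
  kd <- if (dilate_r > 0) EBImage::makeBrush(2 * dilate_r + 1, "disc")
  ke <- if (erode_r > 0) EBImage::makeBrush(2 * erode_r + 1, "disc")
  out <- vox
  for (z in seq_len(dim(vox)[3])) {
    sl <- vox[, , z] * 1
    if (!any(sl > 0)) { out[, , z] <- FALSE; next }
    if (!is.null(kd)) sl <- EBImage::dilate(sl, kd)
    sl <- EBImage::fillHull(sl)
    if (!is.null(ke)) sl <- EBImage::erode(sl, ke)
    out[, , z] <- sl > 0.5
  }
  binary_mask(out, mask$spacing, mask$origin)
}

#' Surface point cloud of a solid mask
#'
#' Returns the world coordinates (voxel-centre convention) of true voxels
#' that have at least one false face-neighbour; voxels at the array border
#' count as boundary.
#'
#' @param solid a [binary_mask()] of a solid region.
#' @return An object of class `surface_points` with fields `points`
#'   (n x 3 matrix, mm) and `source_spacing`.
#' @export
extract_surface_points <- function(solid) {
  stopifnot(inherits(solid, "binary_mask"))
  if (!any(solid$voxels))
    stop("empty segmentation: cannot extract surface points")
  idx <- .boundary_voxels_cpp(solid$voxels, dim(solid$voxels))
  pts <- sweep(idx * rep(solid$spacing, each = nrow(idx)), 2,
               solid$origin, "+")
  colnames(pts) <- c("x", "y", "z")
  structure(list(points = pts, source_spacing = solid$spacing),
            class = "surface_points")
}

#' @export
print.surface_points <- function(x, ...) {
  cat("<surface_points> ", nrow(x$points), " points\n", sep = "")
  invisible(x)
}
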