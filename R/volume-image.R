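#' Volumetric scalar image
#'
#' A `volume_image` is a 3-D grid of real-valued intensities together with its
#' physical geometry: voxel spacing (mm per axis), the physical position of the
#' first voxel, and an axis-convention tag. It is the unit that all
#' normalization, filtering and feature extraction act on. 2-D inputs are
#' represented as single-slice volumes (third dimension of length 1).
#'
#' @param voxels A numeric 3-D array (a 2-D matrix is promoted to a
#'   single-slice volume). All values must be finite.
#' @param spacing Numeric length-3 vector of voxel sizes in mm, all `> 0`.
#' @param origin Numeric length-3 vector, physical coordinates of the first
#'   voxel centre.
#' @param axes Axis-convention tag (free-form; default `"RAS"`).
#'
#' @return An object of class `volume_image`.
#' @examples
#' img <- volume_image(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 3))
#' dim(img$voxels)
#' @export
volume_image <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         axes = "RAS") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (length(voxels) == 0L) stop("image grid must be non-empty", call. = FALSE)
  if (!all(is.finite(voxels))) stop("image intensities must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be three positive values (mm)", call. = FALSE)
  }
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin, axes = axes),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<volume_image> %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
    d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$voxels)

# replace voxel data, keeping geometry
with_voxels <- function(img, voxels) {
  img$voxels <- voxels
  img
}

#' Multi-label segmentation mask
#'
#' A `seg_mask` holds an integer label grid co-registered with its image plus a
#' dictionary mapping region-of-interest names to the label codes making up
#' each ROI. ROIs may be nested (e.g. the tumor lies inside the peripheral
#' zone, which lies inside the whole gland): an ROI is simply the union of its
#' codes.
#'
#' @param labels Integer 3-D array of non-negative label codes (0 = background).
#' @param roi_codes Named list mapping ROI name to an integer vector of codes.
#' @param spacing,origin Geometry, as for [volume_image()].
#'
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(labels, roi_codes, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.matrix(labels)) labels <- array(labels, c(dim(labels), 1L))
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("label codes must be non-negative", call. = FALSE)
  stopifnot(is.list(roi_codes), !is.null(names(roi_codes)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be three positive values (mm)", call. = FALSE)
  }
  structure(
    list(labels = labels, roi_codes = roi_codes,
         spacing = spacing, origin = as.numeric(origin)),
    class = "seg_mask"
  )
}

#' @export
print.seg_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<seg_mask> %d x %d x %d voxels, ROIs: %s\n",
              d[1], d[2], d[3], paste(names(x$roi_codes), collapse = ", ")))
  invisible(x)
}

#' @export
dim.seg_mask <- function(x) dim(x$labels)

check_same_grid <- function(img, mask) {
  if (!identical(dim(img$voxels), dim(mask$labels))) {
    stop("image and mask grids differ in shape", call. = FALSE)
  }
  if (max(abs(img$spacing - mask$spacing)) > 1e-9) {
    stop("image and mask voxel spacings differ", call. = FALSE)
  }
  invisible(TRUE)
}

#' Logical ROI selector
#'
#' @param mask A [seg_mask()].
#' @param roi ROI name present in the mask's `roi_codes` dictionary.
#' @return Logical array, `TRUE` inside the ROI.
#' @export
roi_indicator <- function(mask, roi) {
  codes <- mask$roi_codes[[roi]]
  if (is.null(codes)) {
    stop(sprintf("unknown ROI '%s' (available: %s)", roi,
                 paste(names(mask$roi_codes), collapse = ", ")), call. = FALSE)
  }
  array(mask$labels %in% codes, dim(mask$labels))
}

#' Image intensities inside an ROI
#'
#' @inheritParams roi_indicator
#' @param img A [volume_image()] on the same grid as `mask`.
#' @return Numeric vector of ROI voxel intensities.
#' @export
roi_values <- function(img, mask, roi) {
  check_same_grid(img, mask)
  v <- img$voxels[roi_indicator(mask, roi)]
  if (length(v) == 0L) {
    stop(sprintf("ROI '%s' is empty", roi), call. = FALSE)
  }
  v
}
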