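#' Intensity-normalization specification
#'
#' MR signal intensity is relative, so images are brought onto a common scale
#' before feature extraction. Two schemes are supported, both pure affine maps
#' of the voxel intensities:
#'
#' * `whole_image`: shift/scale so the whole image has mean 300 and SD 100
#'   (putting most intensities in 0-600 under an approximately normal
#'   histogram);
#' * `reference_region`: fit the affine map on a reference tissue ROI
#'   (a muscle region, assumed stable across subjects and timepoints) so that
#'   the ROI reaches mean 100 / SD 10, and apply that same map to every voxel.
#'
#' @param mode `"none"`, `"whole_image"` or `"reference_region"`.
#' @param target_mean,target_sd Targets of the affine map; defaults 300/100
#'   for `whole_image` and 100/10 for `reference_region`. `target_sd` must be
#'   positive.
#' @param reference_label ROI name of the reference region
#'   (`reference_region` mode only).
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(mode = c("none", "whole_image", "reference_region"),
                               target_mean = NULL, target_sd = NULL,
                               reference_label = "muscle_reference") {
  mode <- match.arg(mode)
  if (is.null(target_mean)) {
    target_mean <- switch(mode, whole_image = 300, reference_region = 100, 0)
  }
  if (is.null(target_sd)) {
    target_sd <- switch(mode, whole_image = 100, reference_region = 10, 1)
  }
  if (target_sd <= 0) stop("target_sd must be > 0", call. = FALSE)
  structure(
    list(mode = mode, target_mean = target_mean, target_sd = target_sd,
         reference_label = reference_label),
    class = "normalization_spec"
  )
}

# population (divide-by-N) standard deviation: image-level statistic
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Whole-image intensity normalization
#'
#' Applies the affine map `(x - mean) / sd * target_sd + target_mean` computed
#' over all voxels, so the output image has exactly the target mean and SD
#' (population convention). Geometry is unchanged.
#'
#' @param img A [volume_image()] with non-constant intensities.
#' @param spec A [normalization_spec()] (mode `whole_image`); defaults to the
#'   standard 300/100 targets.
#' @return The normalized [volume_image()].
#' @export
normalize_whole_image <- function(img, spec = normalization_spec("whole_image")) {
  stopifnot(inherits(img, "volume_image"))
  s <- pop_sd(img$voxels)
  if (s == 0) stop("constant image: whole-image normalization undefined",
                   call. = FALSE)
  a <- spec$target_sd / s
  b <- spec$target_mean - a * mean(img$voxels)
  with_voxels(img, a * img$voxels + b)
}

#' Reference-region intensity normalization
#'
#' Fits a single affine map on the reference-ROI voxels (so the ROI reaches
#' the target mean/SD) and applies that map to **all** voxels of the image.
#'
#' @param img A [volume_image()].
#' @param mask A [seg_mask()] on the same grid containing the reference ROI.
#' @param spec A [normalization_spec()] (mode `reference_region`); its
#'   `reference_label` names the ROI.
#' @return The normalized [volume_image()].
#' @export
normalize_reference_region <- function(img, mask,
                                       spec = normalization_spec("reference_region")) {
  stopifnot(inherits(img, "volume_image"), inherits(mask, "seg_mask"))
  ref <- roi_values(img, mask, spec$reference_label)
  s <- pop_sd(ref)
  if (s == 0) stop("constant reference ROI: normalization undefined",
                   call. = FALSE)
  a <- spec$target_sd / s
  b <- spec$target_mean - a * mean(ref)
  with_voxels(img, a * img$voxels + b)
}

#' Apply a normalization spec to an image
#'
#' Dispatch helper used by the extraction pipeline: `none` returns the image
#' unchanged, the other modes call the dedicated functions.
#'
#' @inheritParams normalize_reference_region
#' @return A [volume_image()].
#' @export
apply_normalization <- function(img, spec, mask = NULL) {
  switch(spec$mode,
    none = img,
    whole_image = normalize_whole_image(img, spec),
    reference_region = {
      if (is.null(mask)) stop("reference_region normalization needs a mask",
                              call. = FALSE)
      normalize_reference_region(img, mask, spec)
    }
  )
}
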