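#' Write an image or mask to disk
#'
#' Dispatches on file extension: `.nrrd` (default format, see [write_nrrd()])
#' or `.nii`/`.nii.gz` (NIfTI-1 via the RNifti package).
#'
#' @param x A [volume_image()] or [seg_mask()].
#' @param path Output path ending in `.nrrd`, `.nii` or `.nii.gz`.
#' @param ... Passed to the format writer (e.g. `encoding` for NRRD).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, ...) {
  if (grepl("\\.nrrd$", path)) {
    write_nrrd(x, path, ...)
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    voxels <- if (inherits(x, "seg_mask")) x$labels else x$voxels
    nii <- RNifti::asNifti(voxels)
    RNifti::pixdim(nii) <- x$spacing
    RNifti::writeNifti(nii, path)
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read an image or mask from disk
#'
#' @param path `.nrrd` or `.nii`/`.nii.gz` file.
#' @param as `"image"` or `"mask"`.
#' @param roi_codes ROI dictionary, required when `as = "mask"`.
#' @return A [volume_image()] or [seg_mask()].
#' @export
read_volume <- function(path, as = c("image", "mask"), roi_codes = NULL) {
  as <- match.arg(as)
  if (grepl("\\.nrrd$", path)) {
    return(read_nrrd(path, as = as, roi_codes = roi_codes))
  }
  if (grepl("\\.nii(\\.gz)?$", path)) {
    nii <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(nii)
    arr <- array(as.vector(nii), dim(nii))
    if (as == "mask") {
      if (is.null(roi_codes)) stop("roi_codes required for masks", call. = FALSE)
      return(seg_mask(array(as.integer(round(arr)), dim(arr)), roi_codes,
                      spacing = spacing[seq_len(3)]))
    }
    return(volume_image(arr, spacing = spacing[seq_len(3)]))
  }
  stop("unsupported image format: ", path, call. = FALSE)
}

#' Write a cohort to disk with a manifest
#'
#' Persists every image/mask of a generated cohort and writes a CSV manifest
#' with columns `subject_id`, `timepoint`, `image_path`, `mask_path`.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"nrrd"` (default) or `"nii"`.
#' @return Tibble manifest (also written to `dir/manifest.csv`), invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("nrrd", "nii")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "nrrd") ".nrrd" else ".nii"
  manifest <- purrr::pmap_dfr(cohort, function(subject_id, timepoint, image, mask) {
    stub <- sprintf("%s_%s", subject_id, timepoint)
    ip <- file.path(dir, paste0(stub, "_img", ext))
    mp <- file.path(dir, paste0(stub, "_msk", ext))
    write_volume(image, ip)
    write_volume(mask, mp)
    tibble::tibble(subject_id = subject_id, timepoint = timepoint,
                   image_path = ip, mask_path = mp)
  })
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort back from a manifest
#'
#' @param manifest_path Path to a manifest CSV written by [write_cohort()].
#' @param roi_codes ROI dictionary for the masks (default: the phantom
#'   dictionary used by [generate_cohort()]).
#' @return Cohort tibble with `subject_id`, `timepoint`, `image`, `mask`.
#' @export
read_cohort <- function(manifest_path, roi_codes = phantom_roi_codes()) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  tibble::tibble(
    subject_id = man$subject_id,
    timepoint = man$timepoint,
    image = purrr::map(resolve(man$image_path), read_volume),
    mask = purrr::map(resolve(man$mask_path), read_volume,
                      as = "mask", roi_codes = roi_codes)
  )
}
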