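#' Default feature roster and exclusion list
#'
#' The roster maps each feature class to the feature names emitted by
#' default. The exclusion list contains features that are never emitted
#' because they are deterministic functions of retained features
#' (`Compactness1`, `Compactness2` and `SphericalDisproportion` of
#' `Sphericity`; `SumAverage` of `JointAverage`; `Homogeneity1`/`Homogeneity2`
#' of `Idm`) or meaningless for single-slice ROIs (`Flatness`, `LeastAxis`).
#'
#' @return `default_roster()`: named list class -> character vector;
#'   `default_exclusions()`: character vector.
#' @export
default_roster <- function() {
  list(
    first_order = c("Mean", "Median", "10Percentile", "90Percentile",
                    "Energy", "Variance", "Skewness", "Kurtosis", "Entropy"),
    shape = c("Volume", "SurfaceArea", "Sphericity", "SurfaceVolumeRatio",
              "Maximum3DDiameter", "Maximum2DDiameterSlice",
              "MajorAxisLength", "Elongation"),
    glcm = c("JointEntropy", "JointEnergy", "Idm", "Correlation", "Contrast",
             "JointAverage", "ClusterProminence"),
    glrlm = c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
              "RunPercentage", "GrayLevelVariance"),
    glszm = c("SmallAreaEmphasis", "LargeAreaEmphasis",
              "GrayLevelNonUniformity", "ZonePercentage", "ZoneEntropy")
  )
}

#' @rdname default_roster
#' @export
default_exclusions <- function() {
  c("Compactness1", "Compactness2", "SphericalDisproportion", "Flatness",
    "LeastAxis", "SumAverage", "Homogeneity1", "Homogeneity2")
}

#' Extraction configuration (processing grid)
#'
#' Describes the full processing grid for one image type: normalization
#' modes x pre-filters x bin widths x texture dimensionality, applied to one
#' or more ROIs with a feature roster. [extract_features()] iterates every
#' cell of the grid; each emitted record carries the cell's fingerprint
#' `normalization|filter|bin_width|dim`.
#'
#' @param image_type Tag recorded in the output (`"T2w"`, `"ADC"`,
#'   `"synthetic"`, ...).
#' @param rois Character vector of ROI names to extract from.
#' @param normalizations List of [normalization_spec()]s or mode strings.
#' @param filters List of [filter_spec()]s or filter label strings.
#' @param bin_widths Numeric vector of discretization bin widths.
#' @param dims Texture dimensionalities, subset of `c("2D", "3D")`.
#' @param roster Feature roster (see [default_roster()]).
#' @param exclusions Feature names never emitted.
#' @param aligned_bins Use edge-aligned discretization (see [discretize()]).
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(image_type = "synthetic",
                              rois = "tumor",
                              normalizations = list("none", "whole_image"),
                              filters = enumerate_filters(),
                              bin_widths = c(10, 15, 20, 40),
                              dims = c("2D", "3D"),
                              roster = default_roster(),
                              exclusions = default_exclusions(),
                              aligned_bins = FALSE) {
  normalizations <- lapply(normalizations, function(n) {
    if (is.character(n)) normalization_spec(n) else n
  })
  filters <- lapply(filters, function(f) {
    if (is.character(f)) parse_filter_spec(f) else f
  })
  stopifnot(length(roster) > 0, all(dims %in% c("2D", "3D")),
            all(bin_widths > 0))
  roster <- lapply(roster, setdiff, y = exclusions)
  structure(
    list(image_type = image_type, rois = rois,
         normalizations = normalizations, filters = filters,
         bin_widths = bin_widths, dims = dims, roster = roster,
         exclusions = exclusions, aligned_bins = aligned_bins),
    class = "extraction_config"
  )
}

#' @export
print.extraction_config <- function(x, ...) {
  cat(sprintf(
    "<extraction_config> %s: %d ROI(s) x %d normalization(s) x %d filter(s) x %d bin width(s) x %d dim(s)\n",
    x$image_type, length(x$rois), length(x$normalizations),
    length(x$filters), length(x$bin_widths), length(x$dims)))
  invisible(x)
}

feature_class_values <- function(class, vals_filtered, mask, roi, levels_arr,
                                 roi_ind, dim, bin_width, shape_cache) {
  switch(class,
    first_order = first_order_features(vals_filtered, bin_width = bin_width),
    shape = shape_cache,
    glcm = glcm_features(normalize_texture_matrix(
      build_glcm(levels_arr, roi_ind, dim = dim))),
    glrlm = glrlm_features(build_glrlm(levels_arr, roi_ind, dim = dim)),
    glszm = glszm_features(build_glszm(levels_arr, roi_ind, dim = dim))
  )
}

#' Extract the full feature grid from one image/mask pair
#'
#' Runs the pipeline normalization -> filter -> discretization -> texture
#' matrices -> features for every cell of the processing grid. Shape features
#' depend only on the mask and are computed once per ROI (their values repeat
#' identically across filter/normalization cells, carrying the full
#' fingerprint like every other record). A feature whose computation fails on
#' a degenerate input is emitted with a missing value, never dropped.
#'
#' @param img A [volume_image()].
#' @param mask A [seg_mask()] on the same grid.
#' @param config An [extraction_config()].
#' @param subject_id,timepoint Identifiers stamped on every record.
#' @return A tibble of feature records with columns `subject_id`, `timepoint`,
#'   `image_type`, `roi`, `normalization`, `filter`, `bin_width`, `dim`,
#'   `class`, `feature`, `value`.
#' @export
extract_features <- function(img, mask, config, subject_id = NA_character_,
                             timepoint = NA_character_) {
  stopifnot(inherits(config, "extraction_config"))
  check_same_grid(img, mask)
  shape_cache <- lapply(stats::setNames(config$rois, config$rois),
                        function(r) shape_features(mask, r))
  roi_inds <- lapply(stats::setNames(config$rois, config$rois),
                     function(r) roi_indicator(mask, r))
  out <- list()
  for (nspec in config$normalizations) {
    nimg <- apply_normalization(img, nspec, mask = mask)
    for (fspec in config$filters) {
      fimg <- apply_filter(nimg, fspec)
      flab <- filter_label(fspec)
      for (roi in config$rois) {
        ind <- roi_inds[[roi]]
        vals <- fimg$voxels[ind]
        for (w in config$bin_widths) {
          disc <- discretize(vals, w, aligned = config$aligned_bins)
          levels_arr <- array(0L, dim(ind))
          levels_arr[ind] <- disc$levels
          for (dm in config$dims) {
            for (class in names(config$roster)) {
              wanted <- config$roster[[class]]
              if (length(wanted) == 0L) next
              feats <- tryCatch(
                feature_class_values(class, vals, mask, roi, levels_arr, ind,
                                     dm, w, shape_cache[[roi]]),
                error = function(e) {
                  stats::setNames(as.list(rep(NA_real_, length(wanted))), wanted)
                }
              )
              vv <- vapply(wanted, function(f) {
                v <- feats[[f]]
                if (is.null(v)) NA_real_ else as.numeric(v)
              }, numeric(1))
              out[[length(out) + 1L]] <- tibble::tibble(
                subject_id = subject_id, timepoint = timepoint,
                image_type = config$image_type, roi = roi,
                normalization = nspec$mode, filter = flab,
                bin_width = w, dim = dm, class = class,
                feature = wanted, value = unname(vv)
              )
            }
          }
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Extract features for a whole cohort
#'
#' @param cohort Cohort tibble from [generate_cohort()] or [read_cohort()].
#' @param config An [extraction_config()].
#' @param progress Print per-record progress to stderr.
#' @return Long feature table: one row per (subject, timepoint, ROI, grid
#'   cell, feature).
#' @export
extract_cohort <- function(cohort, config, progress = FALSE) {
  stopifnot(all(c("subject_id", "timepoint", "image", "mask") %in%
                  names(cohort)))
  tabs <- purrr::pmap(cohort, function(subject_id, timepoint, image, mask, ...) {
    if (progress) {
      message(sprintf("extracting %s/%s", subject_id, timepoint))
    }
    extract_features(image, mask, config, subject_id = subject_id,
                     timepoint = timepoint)
  })
  dplyr::bind_rows(tabs)
}

#' Fingerprint of a processing-grid cell
#'
#' @param tab Feature table (or any tibble with the four grid columns).
#' @return The table with a `fingerprint` column
#'   `normalization|filter|bin_width|dim` prepended to the feature key.
#' @export
add_fingerprint <- function(tab) {
  dplyr::mutate(tab, fingerprint = paste(.data$normalization, .data$filter,
                                         .data$bin_width, .data$dim,
                                         sep = "|"))
}
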