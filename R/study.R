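# Study-level summaries over an ICC table, mirroring the reporting structure
# of a repeatability study: a Volume-ICC reference threshold, bin-width
# sensitivity (ranges and rank histograms), per-class top features, filter
# frequency above the reference, and deltas between normalization modes.

#' Volume-reference ICC
#'
#' The repeatability of the segmentation-driven `Volume` feature serves as
#' the within-study reference: a feature is called "repeatable" when its ICC
#' exceeds the Volume ICC of the same ROI/image type. Volume is a shape
#' feature, so its ICC is identical across all filter/bin-width fingerprints;
#' the single value is returned.
#'
#' @param icc_results ICC table from [icc_table()].
#' @param roi,image_type Key of the reference.
#' @return The reference ICC (scalar).
#' @export
volume_reference <- function(icc_results, roi, image_type) {
  rows <- dplyr::filter(icc_results, .data$feature == "Volume",
                        .data$roi == !!roi, .data$image_type == !!image_type)
  vals <- unique(stats::na.omit(rows$icc))
  if (nrow(rows) == 0L || length(vals) == 0L) {
    stop(sprintf("no usable Volume ICC for roi '%s', image type '%s'",
                 roi, image_type), call. = FALSE)
  }
  if (length(vals) > 1L) {
    warning("Volume ICC differs across fingerprints; using the first")
  }
  vals[1]
}

range_key_cols <- c("roi", "image_type", "normalization", "filter", "dim",
                    "class", "feature")

#' ICC range across bin widths
#'
#' For every (feature, filter) key, the spread `max - min` of the ICC across
#' the discretization bin widths: a direct measure of how sensitive a
#' feature's apparent repeatability is to the binning choice. Keys observed
#' at fewer than two bin widths are skipped with a warning.
#'
#' @param icc_results ICC table from [icc_table()].
#' @return Tibble with the key columns plus `n_widths` and `icc_range`.
#' @export
icc_range_over_binwidths <- function(icc_results) {
  res <- icc_results |>
    dplyr::filter(is.finite(.data$icc)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(range_key_cols))) |>
    dplyr::summarise(n_widths = dplyr::n_distinct(.data$bin_width),
                     icc_range = max(.data$icc) - min(.data$icc),
                     .groups = "drop")
  few <- res$n_widths < 2L
  if (any(few)) {
    warning(sprintf("%d key(s) observed at a single bin width were skipped",
                    sum(few)))
    res <- res[!few, ]
  }
  res
}

#' Rank histogram of bin widths
#'
#' Per key (feature x filter x the remaining grid columns), the bin widths
#' are ranked by ICC in descending order (rank 1 = highest ICC; ties share
#' the better, i.e. minimum, rank), and the ranks are tallied per bin width.
#' Each bin width's counts sum to the number of keys.
#'
#' @param icc_results ICC table from [icc_table()]; only keys with every bin
#'   width present (and finite) are used.
#' @return Tibble with `bin_width`, `rank`, `count`.
#' @export
rank_histogram_over_binwidths <- function(icc_results) {
  widths <- sort(unique(icc_results$bin_width))
  complete <- icc_results |>
    dplyr::filter(is.finite(.data$icc)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(range_key_cols))) |>
    dplyr::filter(dplyr::n_distinct(.data$bin_width) == length(widths)) |>
    dplyr::mutate(rank = dplyr::min_rank(dplyr::desc(.data$icc))) |>
    dplyr::ungroup()
  complete |>
    dplyr::count(.data$bin_width, .data$rank, name = "count") |>
    tidyr::complete(bin_width = widths,
                    rank = seq_along(widths),
                    fill = list(count = 0L))
}

#' Top-k most repeatable features per class
#'
#' Ranks features within each feature class by their best-configuration ICC —
#' the maximum ICC over the filter grid at the study's reporting bin width —
#' and keeps the top `k` (all, when the class is smaller). Ties are broken
#' lexicographically by feature name for determinism. The ICC spread across
#' filters (`icc_min`, `icc_max`) is reported alongside.
#'
#' @param icc_results ICC table from [icc_table()].
#' @param k Number of features per class (default 3).
#' @param bin_width Reporting bin width at which configurations are compared
#'   (default 15); shape features, which carry all bin widths identically,
#'   are filtered the same way.
#' @return Tibble with `roi`, `image_type`, `normalization`, `class`,
#'   `feature`, `best_icc`, `best_filter`, `icc_min`, `icc_max`, `rank`.
#' @export
top_k_per_class <- function(icc_results, k = 3, bin_width = 15) {
  pool <- dplyr::filter(icc_results, .data$bin_width == !!bin_width,
                        is.finite(.data$icc))
  pool |>
    dplyr::group_by(.data$roi, .data$image_type, .data$normalization,
                    .data$class, .data$feature) |>
    dplyr::summarise(best_icc = max(.data$icc),
                     best_filter = .data$filter[order(-.data$icc,
                                                      .data$filter)][1],
                     icc_min = min(.data$icc), icc_max = max(.data$icc),
                     .groups = "drop_last") |>
    dplyr::arrange(dplyr::desc(.data$best_icc), .data$feature,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Filter frequency above the Volume reference
#'
#' Counts, per pre-filter, how many distinct features reach an ICC above the
#' Volume reference under that filter (a feature exceeding the reference
#' under several filters contributes to each of them), plus the total number
#' of distinct features above the reference under at least one filter.
#'
#' @param icc_results ICC table (typically pre-filtered to one ROI, image
#'   type, normalization and bin width).
#' @param reference The reference ICC (see [volume_reference()]).
#' @return List with `by_filter` (tibble `filter`, `n_features`) and
#'   `n_total` (distinct features above the reference).
#' @export
filter_frequency_above_reference <- function(icc_results, reference) {
  above <- icc_results |>
    dplyr::filter(is.finite(.data$icc), .data$icc > reference,
                  .data$class != "shape") |>
    dplyr::distinct(.data$filter, .data$class, .data$feature)
  by_filter <- icc_results |>
    dplyr::distinct(.data$filter) |>
    dplyr::left_join(dplyr::count(above, .data$filter, name = "n_features"),
                     by = "filter") |>
    dplyr::mutate(n_features = dplyr::coalesce(.data$n_features, 0L)) |>
    dplyr::arrange(.data$filter)
  list(by_filter = by_filter,
       n_total = nrow(dplyr::distinct(above, .data$class, .data$feature)))
}

#' ICC change between two normalization modes
#'
#' Pairs the ICC tables of two normalization modes on their shared keys and
#' reports the per-feature change `icc_b - icc_a`, together with the union of
#' both modes' top-k feature sets per class (hence up to `2k` features per
#' class), which is the set usually plotted.
#'
#' @param icc_results_a,icc_results_b ICC tables of the two modes.
#' @param k Top-k per class entering the union set (default 3).
#' @param bin_width Reporting bin width for the top-k selection.
#' @return List with `deltas` (tibble: shared key columns, `icc_a`, `icc_b`,
#'   `delta`) and `top_union` (tibble of the selected features with both
#'   modes' best ICCs).
#' @export
normalization_delta <- function(icc_results_a, icc_results_b, k = 3,
                                bin_width = 15) {
  keys <- setdiff(icc_key_cols, "normalization")
  a <- dplyr::select(icc_results_a, dplyr::all_of(keys), icc_a = "icc")
  b <- dplyr::select(icc_results_b, dplyr::all_of(keys), icc_b = "icc")
  deltas <- dplyr::inner_join(a, b, by = keys) |>
    dplyr::mutate(delta = .data$icc_b - .data$icc_a)
  dropped <- nrow(a) - nrow(deltas)
  if (dropped > 0) {
    warning(sprintf("%d unmatched key(s) dropped", dropped))
  }
  top_a <- top_k_per_class(icc_results_a, k = k, bin_width = bin_width)
  top_b <- top_k_per_class(icc_results_b, k = k, bin_width = bin_width)
  sel_cols <- c("roi", "image_type", "class", "feature")
  union_set <- dplyr::distinct(dplyr::bind_rows(
    dplyr::select(top_a, dplyr::all_of(sel_cols)),
    dplyr::select(top_b, dplyr::all_of(sel_cols))
  ))
  top_union <- union_set |>
    dplyr::left_join(dplyr::select(top_a, dplyr::all_of(sel_cols),
                                   best_icc_a = "best_icc"), by = sel_cols) |>
    dplyr::left_join(dplyr::select(top_b, dplyr::all_of(sel_cols),
                                   best_icc_b = "best_icc"), by = sel_cols) |>
    dplyr::arrange(.data$roi, .data$image_type, .data$class, .data$feature)
  list(deltas = deltas, top_union = top_union)
}

#' Study configuration
#'
#' Bundles everything [run_study()] needs: the phantom cohort spec, the
#' extraction grid, the CI level and the reporting conventions.
#'
#' @param phantom A [phantom_spec()].
#' @param extraction An [extraction_config()].
#' @param alpha CI level for [icc_table()] (default 0.1: 90% intervals).
#' @param reporting_bin_width Bin width used for top-k selection and filter
#'   frequency (default 15; falls back to the first configured width if 15 is
#'   not in the grid).
#' @param top_k Features per class in the top listings.
#' @return An object of class `study_config`.
#' @export
study_config <- function(phantom = phantom_spec(),
                         extraction = extraction_config(),
                         alpha = 0.1, reporting_bin_width = 15, top_k = 3) {
  if (!reporting_bin_width %in% extraction$bin_widths) {
    reporting_bin_width <- extraction$bin_widths[1]
  }
  structure(
    list(phantom = phantom, extraction = extraction, alpha = alpha,
         reporting_bin_width = reporting_bin_width, top_k = top_k),
    class = "study_config"
  )
}

#' Reduced demonstration configuration
#'
#' A small end-to-end configuration (5 subjects, 3 filters, 2 bin widths,
#' tumor + whole gland, 2D textures) that exercises every pipeline stage in a
#' few minutes on one CPU.
#'
#' @param seed Master seed.
#' @param ... Overrides passed to [phantom_spec()].
#' @return A [study_config()].
#' @export
demo_study_config <- function(seed = 1L, ...) {
  study_config(
    phantom = phantom_spec(n_subjects = 5, seed = seed, ...),
    extraction = extraction_config(
      image_type = "synthetic",
      rois = c("tumor", "whole_gland"),
      normalizations = list("none", "whole_image"),
      filters = list("original", "log:sigma=2.0", "square"),
      bin_widths = c(15, 40),
      dims = "2D"
    ),
    reporting_bin_width = 15
  )
}

#' Run the full repeatability study
#'
#' Executes simulate -> extract -> ICC -> report. The result is fully
#' deterministic given the phantom seed; when `out` is given, all
#' intermediates (features, ICC table, report tables) are persisted as CSV.
#'
#' @param config A [study_config()].
#' @param out Optional output directory for the CSV artifacts.
#' @param progress Forwarded to [extract_cohort()].
#' @return A `study_report`: list with `cohort` (tibble), `features`,
#'   `icc`, and the summary tables (see [build_report()]).
#' @export
run_study <- function(config = study_config(), out = NULL, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cohort <- generate_cohort(config$phantom)
  features <- extract_cohort(cohort, config$extraction, progress = progress)
  icc <- icc_table(features, alpha = config$alpha)
  report <- build_report(icc, reporting_bin_width = config$reporting_bin_width,
                         top_k = config$top_k)
  report$cohort <- cohort
  report$features <- features
  report$config <- config
  if (!is.null(out)) write_report(report, out)
  report
}

#' Build the study report from an ICC table
#'
#' Pure function of the ICC table (so a report can be reproduced exactly from
#' a persisted `icc.csv`): computes the Volume references, bin-width ranges,
#' rank histograms, top-k listings, filter frequencies, and — when exactly
#' two normalization modes are present — the per-feature normalization
#' deltas.
#'
#' @param icc ICC table from [icc_table()].
#' @param reporting_bin_width,top_k Reporting conventions (see
#'   [study_config()]).
#' @return An object of class `study_report` (a named list of tibbles).
#' @export
build_report <- function(icc, reporting_bin_width = 15, top_k = 3) {
  combos <- dplyr::distinct(icc, .data$roi, .data$image_type)
  refs <- combos |>
    dplyr::mutate(reference_icc = purrr::map2_dbl(
      .data$roi, .data$image_type,
      function(r, it) tryCatch(volume_reference(icc, r, it),
                               error = function(e) NA_real_)))
  ranges <- suppressWarnings(icc_range_over_binwidths(icc))
  rank_hist <- rank_histogram_over_binwidths(icc)
  top <- top_k_per_class(icc, k = top_k, bin_width = reporting_bin_width)
  freq <- purrr::pmap_dfr(refs, function(roi, image_type, reference_icc) {
    if (!is.finite(reference_icc)) return(tibble::tibble())
    sub <- dplyr::filter(icc, .data$roi == !!roi,
                         .data$image_type == !!image_type,
                         .data$bin_width == reporting_bin_width)
    ff <- filter_frequency_above_reference(sub, reference_icc)
    dplyr::mutate(ff$by_filter, roi = roi, image_type = image_type,
                  n_total = ff$n_total)
  })
  report <- list(volume_reference = refs, icc = icc, binwidth_range = ranges,
                 rank_histogram = rank_hist, top_features = top,
                 filter_frequency = freq,
                 reporting_bin_width = reporting_bin_width, top_k = top_k)
  norms <- sort(unique(icc$normalization))
  if (length(norms) == 2L) {
    nd <- suppressWarnings(normalization_delta(
      dplyr::filter(icc, .data$normalization == norms[1]),
      dplyr::filter(icc, .data$normalization == norms[2]),
      k = top_k, bin_width = reporting_bin_width))
    report$normalization_delta <- nd$deltas
    report$normalization_top_union <- nd$top_union
  }
  structure(report, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  ICC rows: %d (reporting bin width %s, top-%d)\n",
              nrow(x$icc), x$reporting_bin_width, x$top_k))
  cat("  Volume reference ICCs:\n")
  for (i in seq_len(nrow(x$volume_reference))) {
    cat(sprintf("    %s / %s: %.3f\n", x$volume_reference$roi[i],
                x$volume_reference$image_type[i],
                x$volume_reference$reference_icc[i]))
  }
  invisible(x)
}

report_tables <- c("volume_reference", "icc", "binwidth_range",
                   "rank_histogram", "top_features", "filter_frequency",
                   "normalization_delta", "normalization_top_union")

#' Persist a study report as CSV artifacts
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$features)) {
    utils::write.csv(report$features, file.path(dir, "features.csv"),
                     row.names = FALSE)
  }
  for (nm in report_tables) {
    if (!is.null(report[[nm]]) && is.data.frame(report[[nm]])) {
      utils::write.csv(report[[nm]],
                       file.path(dir, paste0(sub("^icc$", "icc", nm), ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a study configuration from YAML
#'
#' The YAML mirrors the constructors: blocks `cohort` (fields of
#' [phantom_spec()]), `extraction` (`image_type`, `rois`, `normalization`,
#' `filters`, `bin_widths`, `dim`), and scalars `alpha`,
#' `reporting_bin_width`, `top_k`, `seed` (overrides the cohort seed).
#'
#' @param path YAML file path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  if (!is.null(y$seed)) cohort_args$seed <- y$seed
  if (!is.null(cohort_args$shape)) cohort_args$shape <- unlist(cohort_args$shape)
  if (!is.null(cohort_args$spacing)) {
    cohort_args$spacing <- unlist(cohort_args$spacing)
  }
  if (!is.null(cohort_args$tissue)) cohort_args$tissue <- unlist(cohort_args$tissue)
  phantom <- do.call(phantom_spec, cohort_args)
  ex <- y$extraction %||% list()
  extraction <- extraction_config(
    image_type = ex$image_type %||% "synthetic",
    rois = unlist(ex$rois %||% "tumor"),
    normalizations = as.list(unlist(ex$normalization %||%
                                      c("none", "whole_image"))),
    filters = if (is.null(ex$filters)) enumerate_filters() else
      as.list(unlist(ex$filters)),
    bin_widths = unlist(ex$bin_widths %||% c(10, 15, 20, 40)),
    dims = unlist(ex$dim %||% c("2D", "3D"))
  )
  study_config(phantom = phantom, extraction = extraction,
               alpha = y$alpha %||% 0.1,
               reporting_bin_width = y$reporting_bin_width %||% 15,
               top_k = y$top_k %||% 3)
}
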