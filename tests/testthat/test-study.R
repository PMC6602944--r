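# small hand-built ICC tables for the summary operations
toy_icc <- function(df) {
  defaults <- tibble::tibble(
    roi = "tumor", image_type = "synthetic", normalization = "none",
    filter = "original", bin_width = 15, dim = "2D", class = "glcm",
    feature = "Contrast", n = 15L, icc = 0.5, ci_low = 0.3, ci_high = 0.7,
    bms = 1, wms = 0.3)
  out <- dplyr::bind_rows(lapply(seq_len(nrow(df)), function(i) {
    row <- defaults
    for (nm in names(df)) row[[nm]] <- df[[nm]][i]
    row
  }))
  out
}

test_that("volume_reference looks up the shape-invariant Volume ICC", {
  tab <- toy_icc(data.frame(class = c("shape", "glcm"),
                            feature = c("Volume", "Contrast"),
                            icc = c(0.7, 0.9)))
  expect_equal(volume_reference(tab, "tumor", "synthetic"), 0.7)
  expect_error(volume_reference(tab, "whole_gland", "synthetic"), "Volume")
  missing_vol <- toy_icc(data.frame(class = "shape", feature = "Volume",
                                    icc = NA_real_))
  expect_error(volume_reference(missing_vol, "tumor", "synthetic"), "Volume")
})

test_that("bin-width ICC ranges equal a brute-force max-min scan", {
  tab <- toy_icc(data.frame(bin_width = c(10, 15, 20, 40),
                            icc = c(0.5, 0.6, 0.7, 0.8)))
  r <- icc_range_over_binwidths(tab)
  expect_equal(r$icc_range, 0.3)
  tied <- toy_icc(data.frame(bin_width = c(10, 15, 20, 40), icc = 0.6))
  expect_equal(icc_range_over_binwidths(tied)$icc_range, 0)
  # random tables against an explicit scan
  set.seed(20)
  rand <- toy_icc(data.frame(
    feature = rep(sprintf("F%d", 1:6), each = 4),
    bin_width = rep(c(10, 15, 20, 40), 6),
    icc = stats::runif(24, -0.2, 1)))
  got <- icc_range_over_binwidths(rand)
  for (f in unique(rand$feature)) {
    v <- rand$icc[rand$feature == f]
    expect_equal(got$icc_range[got$feature == f], max(v) - min(v))
  }
  single <- toy_icc(data.frame(bin_width = 15, icc = 0.5))
  expect_warning(out <- icc_range_over_binwidths(single), "single bin width")
  expect_equal(nrow(out), 0)
})

test_that("rank histograms use min-rank ties and conserve key counts", {
  tab <- toy_icc(data.frame(bin_width = c(10, 15, 20, 40),
                            icc = c(0.5, 0.6, 0.7, 0.8)))
  h <- rank_histogram_over_binwidths(tab)
  expect_equal(h$count[h$bin_width == 40 & h$rank == 1], 1L)
  expect_equal(h$count[h$bin_width == 10 & h$rank == 4], 1L)
  tied <- toy_icc(data.frame(bin_width = c(10, 15, 20, 40), icc = 0.7))
  ht <- rank_histogram_over_binwidths(tied)
  expect_true(all(ht$count[ht$rank == 1] == 1L))  # all widths share rank 1
  # conservation on random tables: each width's counts sum to the key count
  set.seed(21)
  rand <- toy_icc(data.frame(
    feature = rep(sprintf("F%d", 1:7), each = 4),
    bin_width = rep(c(10, 15, 20, 40), 7),
    icc = stats::runif(28)))
  hr <- rank_histogram_over_binwidths(rand)
  sums <- tapply(hr$count, hr$bin_width, sum)
  expect_true(all(sums == 7))
})

test_that("top-k per class sorts by best-configuration ICC with ties by name", {
  tab <- toy_icc(data.frame(
    feature = c("A", "B", "C", "D"),
    icc = c(0.9, 0.8, 0.7, 0.6)))
  top <- top_k_per_class(tab, k = 3)
  expect_equal(top$feature, c("A", "B", "C"))
  expect_equal(top$rank, 1:3)
  all4 <- top_k_per_class(tab, k = 10)
  expect_equal(nrow(all4), 4)  # k larger than the class returns everything
  # brute-force agreement on a random table with several filters
  set.seed(22)
  rand <- toy_icc(tidyr::expand_grid(
    feature = sprintf("F%d", 1:5),
    filter = c("original", "square", "log:sigma=1.0")))
  rand$icc <- stats::runif(nrow(rand))
  top2 <- top_k_per_class(rand, k = 2)
  best <- tapply(rand$icc, rand$feature, max)
  expect_equal(top2$feature, names(sort(best, decreasing = TRUE))[1:2])
  expect_equal(top2$best_icc, as.numeric(sort(best, decreasing = TRUE))[1:2])
})

test_that("filter frequency counts every filter a feature exceeds under", {
  tab <- toy_icc(tidyr::expand_grid(
    feature = c("F1", "F2"),
    filter = c("original", "square", "wavelet:HHH")))
  tab$icc <- c(0.9, 0.9, 0.9, 0.2, 0.2, 0.2)  # F1 beats under all 3 filters
  ff <- filter_frequency_above_reference(tab, reference = 0.7)
  expect_equal(sort(ff$by_filter$n_features), c(1L, 1L, 1L))
  expect_equal(ff$n_total, 1L)
  none <- filter_frequency_above_reference(tab, reference = 0.95)
  expect_true(all(none$by_filter$n_features == 0))
  expect_equal(none$n_total, 0L)
  # brute-force threshold scan on a random table
  set.seed(23)
  rand <- toy_icc(tidyr::expand_grid(
    feature = sprintf("F%d", 1:6),
    filter = c("original", "square")))
  rand$icc <- stats::runif(nrow(rand))
  got <- filter_frequency_above_reference(rand, 0.5)
  for (fl in c("original", "square")) {
    manual <- length(unique(rand$feature[rand$filter == fl & rand$icc > 0.5]))
    expect_equal(got$by_filter$n_features[got$by_filter$filter == fl], manual)
  }
})

test_that("normalization deltas subtract element-wise and antisymmetrize", {
  a <- toy_icc(data.frame(feature = c("A", "B"), icc = c(0.5, 0.9)))
  b <- dplyr::mutate(toy_icc(data.frame(feature = c("A", "B"),
                                        icc = c(0.7, 0.4))),
                     normalization = "reference_region")
  nd <- normalization_delta(a, b)
  expect_equal(nd$deltas$delta[nd$deltas$feature == "A"], 0.2)
  expect_equal(nd$deltas$delta[nd$deltas$feature == "B"], -0.5)
  nd_rev <- normalization_delta(b, a)
  expect_equal(nd_rev$deltas$delta, -nd$deltas$delta)
  same <- normalization_delta(a, dplyr::mutate(a, normalization = "x"))
  expect_true(all(same$deltas$delta == 0))
  # unmatched keys are dropped with a warning
  expect_warning(normalization_delta(a, b[1, ]), "unmatched")
})

test_that("the demo study runs end-to-end and its report is self-consistent", {
  rep <- demo_report()
  expect_s3_class(rep, "study_report")
  expect_equal(nrow(rep$cohort), 10)  # 5 subjects x 2 timepoints
  # grid completeness: records = subjects x 2 x cells x roster
  cfg <- rep$config$extraction
  n_cells <- length(cfg$rois) * length(cfg$normalizations) *
    length(cfg$filters) * length(cfg$bin_widths) * length(cfg$dims)
  expect_equal(nrow(rep$features),
               10 * n_cells * sum(lengths(cfg$roster)))
  expect_equal(nrow(rep$icc) * 10, nrow(rep$features))
  # every summary row traces back to ICC rows
  expect_true(all(rep$top_features$feature %in% rep$icc$feature))
  sums <- tapply(rep$rank_histogram$count, rep$rank_histogram$bin_width, sum)
  expect_true(length(unique(sums)) == 1)  # conservation across widths
})

test_that("rebuilding the report from the persisted ICC CSV is idempotent", {
  rep <- demo_report()
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  icc_back <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "icc.csv"), stringsAsFactors = FALSE))
  icc_back$dim <- as.character(icc_back$dim)
  rebuilt <- build_report(icc_back,
                          reporting_bin_width = rep$reporting_bin_width,
                          top_k = rep$top_k)
  expect_equal(rebuilt$volume_reference, rep$volume_reference)
  expect_equal(rebuilt$binwidth_range, rep$binwidth_range,
               tolerance = 1e-12)
  expect_equal(rebuilt$top_features, rep$top_features, tolerance = 1e-12)
})

test_that("YAML study configs round-trip into the constructors", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 5",
    "cohort:",
    "  n_subjects: 3",
    "  sigma_w: 7.5",
    "extraction:",
    "  rois: [tumor]",
    "  normalization: [none, whole_image]",
    "  filters: [original, \"log:sigma=2.0\"]",
    "  bin_widths: [15, 40]",
    "  dim: [2D]",
    "alpha: 0.05"), yml)
  cfg <- read_study_config(yml)
  expect_equal(cfg$phantom$n_subjects, 3L)
  expect_equal(cfg$phantom$sigma_w, 7.5)
  expect_equal(cfg$phantom$seed, 5L)
  expect_equal(length(cfg$extraction$filters), 2)
  expect_equal(cfg$alpha, 0.05)
  expect_equal(cfg$reporting_bin_width, 15)
})

test_that("report plots build without error", {
  rep <- demo_report()
  expect_s3_class(autoplot(rep, "ranges"), "ggplot")
  expect_s3_class(autoplot(rep, "ranks"), "ggplot")
  expect_s3_class(autoplot(rep, "filters"), "ggplot")
  expect_s3_class(plot_icc_panel(head(rep$icc, 20), reference = 0.5), "ggplot")
})
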