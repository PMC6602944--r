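test_that("first-order features reproduce hand arithmetic", {
  f <- first_order_features(c(1, 2, 3, 4), bin_width = 1)
  expect_equal(f$Mean, 2.5)
  expect_equal(f$Energy, 30)          # sum of squares
  expect_equal(f$Median, 2.5)
  expect_equal(f$Variance, 1.25)      # population convention
  expect_equal(f$Skewness, 0)         # symmetric values
  # four singleton bins -> 2 bits
  expect_equal(f$Entropy, 2)
  # {1,2,3,7} at width 2 -> levels 1,1,2,4 -> p = (.5,.25,.25)
  g <- first_order_features(c(1, 2, 3, 7), bin_width = 2)
  expect_equal(g$Entropy, 1.5)
})

test_that("degenerate first-order cases are flagged, not propagated", {
  f <- first_order_features(rep(7, 20), bin_width = 10)
  expect_equal(f$Variance, 0)
  expect_equal(f$Entropy, 0)
  expect_true(is.na(f$Skewness))
  expect_true(is.na(f$Kurtosis))
  expect_error(first_order_features(numeric(0)), "empty")
})

test_that("mean/median/variance transform correctly under affine maps", {
  set.seed(13)
  v <- stats::rnorm(200, 50, 8)
  a <- 2.5; b <- -30
  f0 <- first_order_features(v)
  f1 <- first_order_features(a * v + b)
  expect_equal(f1$Mean, a * f0$Mean + b, tolerance = 1e-12)
  expect_equal(f1$Median, a * f0$Median + b, tolerance = 1e-12)
  expect_equal(f1$Variance, a^2 * f0$Variance, tolerance = 1e-12)
  expect_equal(f1$Skewness, f0$Skewness, tolerance = 1e-9)
  expect_equal(f1$Kurtosis, f0$Kurtosis, tolerance = 1e-9)
})

test_that("shape features match closed forms on the cube fixture", {
  cube <- worked_fixture("cube10")
  sf <- shape_features(cube$mask, "roi")
  expect_equal(sf$Volume, 1000)
  expect_equal(sf$SurfaceArea, 600)
  expect_equal(sf$Sphericity, pi^(1 / 3) * 6000^(2 / 3) / 600)
  expect_equal(sf$SurfaceVolumeRatio, 0.6)
  expect_equal(sf$Maximum3DDiameter, sqrt(3 * 81))  # opposite corner centres
  expect_equal(sf$Maximum2DDiameterSlice, sqrt(2 * 81))
  expect_equal(sf$Elongation, 1)  # isotropic cube
})

test_that("a single voxel has unit volume at unit spacing", {
  labels <- array(0L, c(3, 3, 3)); labels[2, 2, 2] <- 1L
  sf <- shape_features(seg_mask(labels, list(roi = 1L)), "roi")
  expect_equal(sf$Volume, 1)
  expect_equal(sf$SurfaceArea, 6)
  expect_equal(sf$Maximum3DDiameter, 0)
})

test_that("flatness-type descriptors are excluded from the roster", {
  roster <- default_roster()
  expect_false(any(c("Flatness", "LeastAxis") %in% roster$shape))
  expect_false("SumAverage" %in% roster$glcm)
  expect_true(all(default_exclusions() %in%
                    c("Compactness1", "Compactness2", "SphericalDisproportion",
                      "Flatness", "LeastAxis", "SumAverage", "Homogeneity1",
                      "Homogeneity2")))
})

test_that("GLCM features evaluate the textbook formulas", {
  m <- structure(
    list(kind = "GLCM", counts = matrix(c(0, .5, .5, 0), 2, 2), ng = 2L,
         dim = "2D", n_voxels = 4L, n_directions = 1L,
         aggregation = "merged", normalized = TRUE),
    class = "texture_matrix")
  f <- glcm_features(m)
  expect_equal(f$Contrast, 1)
  expect_equal(f$JointEntropy, 1)      # two cells at 1/2
  expect_equal(f$JointEnergy, 0.5)
  expect_equal(f$Idm, 0.5)
  expect_equal(f$Correlation, -1)      # perfectly anti-correlated pairs
  expect_equal(f$JointAverage, 1.5)
  # constant ROI: all mass at (1,1)
  lv <- array(1L, c(3, 3, 1))
  fc <- glcm_features(normalize_texture_matrix(build_glcm(lv, dim = "2D")))
  expect_equal(fc$Contrast, 0)
  expect_equal(fc$JointEntropy, 0)
  expect_true(is.na(fc$Correlation))   # zero marginal variance
  expect_error(glcm_features(build_glcm(lv, dim = "2D")), "normalized")
})

test_that("SumAverage equals twice JointAverage on random symmetric GLCMs", {
  set.seed(14)
  for (i in 1:30) {
    g <- random_level_grid(max_side = 5, ng = sample(2:5, 1))
    f <- glcm_features(normalize_texture_matrix(build_glcm(g$levels, g$roi)))
    expect_equal(f$SumAverage, 2 * f$JointAverage, tolerance = 1e-12)
  }
})

test_that("GLRLM features reproduce hand evaluation", {
  counts <- matrix(0, 2, 3)
  counts[1, 2] <- 1; counts[2, 3] <- 1  # runs {(1,2):1, (2,3):1}
  m <- structure(list(kind = "GLRLM", counts = counts, ng = 2L, dim = "2D",
                      n_voxels = 5L, n_directions = 1L,
                      aggregation = "merged", normalized = FALSE),
                 class = "texture_matrix")
  f <- glrlm_features(m)
  expect_equal(f$ShortRunEmphasis, (1 / 4 + 1 / 9) / 2)
  expect_equal(f$LongRunEmphasis, (4 + 9) / 2)
  expect_equal(f$GrayLevelNonUniformity, 1)
  expect_equal(f$RunPercentage, 2 / 5)
  expect_equal(f$GrayLevelVariance, 0.25)
  # single run of length l: ShortRunEmphasis = 1/l^2
  single <- build_glrlm(array(1L, c(4, 1, 1)),
                        directions = list(c(1L, 0L, 0L)))
  expect_equal(glrlm_features(single)$ShortRunEmphasis, 1 / 16)
})

test_that("GLSZM features reproduce hand evaluation", {
  counts <- matrix(0, 2, 3)
  counts[1, 3] <- 1; counts[2, 1] <- 1  # zones {(1,3):1, (2,1):1}
  m <- structure(list(kind = "GLSZM", counts = counts, ng = 2L, dim = "2D",
                      n_voxels = 4L, n_directions = NA_integer_,
                      aggregation = "merged", normalized = FALSE),
                 class = "texture_matrix")
  f <- glszm_features(m)
  expect_equal(f$SmallAreaEmphasis, (1 / 9 + 1) / 2)
  expect_equal(f$LargeAreaEmphasis, (9 + 1) / 2)
  expect_equal(f$ZoneEntropy, 1)
  # single zone of size z: ZonePercentage = 1/z
  single <- build_glszm(array(1L, c(2, 3, 1)), dim = "2D")
  expect_equal(glszm_features(single)$ZonePercentage, 1 / 6)
})

test_that("extraction emits a complete, exclusion-free record grid", {
  fx <- small_image_and_mask(15)
  config <- extraction_config(
    image_type = "synthetic", rois = "roi",
    normalizations = list("none", "whole_image"),
    filters = list("original", "square", "log:sigma=1.0"),
    bin_widths = c(10, 25), dims = "3D")
  tab <- extract_features(fx$image, fx$mask, config,
                          subject_id = "S01", timepoint = "test")
  n_cells <- 2 * 3 * 2 * 1
  roster_size <- sum(lengths(config$roster))
  expect_equal(nrow(tab), n_cells * roster_size)
  expect_equal(nrow(dplyr::distinct(add_fingerprint(tab), fingerprint)),
               n_cells)
  expect_false(any(tab$feature %in% default_exclusions()))
  expect_true(all(is.finite(tab$value) | is.na(tab$value)))
})

test_that("shape features are identical under every pre-filter", {
  fx <- small_image_and_mask(16)
  config <- extraction_config(
    rois = "roi", normalizations = list("none"),
    filters = enumerate_filters(log_sigmas_mm = c(1, 2)),
    bin_widths = 20, dims = "3D")
  tab <- extract_features(fx$image, fx$mask, config)
  shp <- dplyr::filter(tab, class == "shape")
  per_feature <- dplyr::summarise(
    dplyr::group_by(shp, feature),
    n_distinct_values = dplyr::n_distinct(value), .groups = "drop")
  expect_true(all(per_feature$n_distinct_values == 1))
})
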