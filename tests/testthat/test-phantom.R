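test_that("a cohort has two timepoints per subject with all ROIs present", {
  spec <- phantom_spec(n_subjects = 3, seed = 4)
  cohort <- generate_cohort(spec)
  expect_equal(nrow(cohort), 6)
  expect_equal(as.integer(table(cohort$subject_id)), rep(2L, 3))
  expect_setequal(cohort$timepoint, c("test", "retest"))
  for (roi in names(phantom_roi_codes())) {
    expect_gt(length(roi_values(cohort$image[[1]], cohort$mask[[1]], roi)), 0)
  }
})

test_that("the cohort is a pure function of the spec (same seed, same bits)", {
  spec <- phantom_spec(n_subjects = 2, shape = c(16, 16, 8),
                       radius_mean = 2.5, radius_sd = 0.2, seed = 99)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$image[[3]]$voxels, b$image[[3]]$voxels)
  expect_identical(a$mask[[2]]$labels, b$mask[[2]]$labels)
  # byte-for-byte stable through the image writer
  p1 <- withr::local_tempfile(fileext = ".nrrd")
  p2 <- withr::local_tempfile(fileext = ".nrrd")
  write_nrrd(a$image[[1]], p1)
  write_nrrd(b$image[[1]], p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("first subjects are stable when the cohort grows", {
  small <- generate_cohort(phantom_spec(n_subjects = 2, seed = 7))
  large <- generate_cohort(phantom_spec(n_subjects = 4, seed = 7))
  expect_identical(small$image[[1]]$voxels, large$image[[1]]$voxels)
  expect_identical(small$image[[4]]$voxels, large$image[[4]]$voxels)
})

test_that("without within-subject variation, test equals retest exactly", {
  spec <- phantom_spec(n_subjects = 3, sigma_w = 0, gain_sd = 0,
                       offset_sd = 0, boundary_jitter = 0, seed = 12)
  cohort <- generate_cohort(spec)
  for (s in unique(cohort$subject_id)) {
    rows <- which(cohort$subject_id == s)
    expect_identical(cohort$image[[rows[1]]]$voxels,
                     cohort$image[[rows[2]]]$voxels)
    expect_identical(cohort$mask[[rows[1]]]$labels,
                     cohort$mask[[rows[2]]]$labels)
  }
})

test_that("an oversized lesion triggers a geometry error", {
  spec <- phantom_spec(n_subjects = 2, shape = c(12, 12, 6),
                       radius_mean = 30, radius_sd = 0, seed = 1)
  expect_error(generate_cohort(spec), "does not fit")
})

test_that("contour jitter never empties the tumor ROI", {
  spec <- phantom_spec(n_subjects = 8, shape = c(14, 14, 8),
                       spacing = c(1, 1, 1), radius_mean = 1.6,
                       radius_sd = 0, boundary_jitter = 1, seed = 21)
  cohort <- generate_cohort(spec)
  for (m in cohort$mask) expect_gt(sum(m$labels == 1L), 0)
})

test_that("closed-form ROI-mean ICC follows the variance-ratio identity", {
  spec <- restricted_spec(0.7)
  # sigma_b^2 = 3 * sigma_w_eff^2  =>  ICC = 0.75
  anat_n <- sum(
    radstab:::lesion_mask(radstab:::phantom_anatomy(spec),
                          radstab:::nominal_lesion_center(radstab:::phantom_anatomy(spec)),
                          spec$radius_mean, spec))
  spec75 <- spec
  spec75$sigma_b <- sqrt(3 * spec$sigma_w^2 / anat_n)
  expect_equal(theoretical_icc_roi_mean(spec75), 0.75)
  spec1 <- spec; spec1$sigma_w <- 0
  expect_equal(theoretical_icc_roi_mean(spec1), 1.0)
  spec0 <- spec; spec0$sigma_b <- 0
  expect_equal(theoretical_icc_roi_mean(spec0), 0.0)
  spec_na <- spec; spec_na$sigma_b <- 0; spec_na$sigma_w <- 0
  expect_true(is.na(theoretical_icc_roi_mean(spec_na)))
  bad <- spec; bad$gain_sd <- 0.1
  expect_error(theoretical_icc_roi_mean(bad), "gain")
})

test_that("empirical variance structure matches the generative model", {
  spec <- restricted_spec(0.5, seed = 31)
  spec$n_subjects <- 220L
  cohort <- generate_cohort(spec)
  m <- cohort_roi_means(cohort)
  x1 <- m[cohort$timepoint == "test"]
  x2 <- m[cohort$timepoint == "retest"]
  anat <- radstab:::phantom_anatomy(spec)
  n_vox <- sum(radstab:::lesion_mask(anat,
                                     radstab:::nominal_lesion_center(anat),
                                     spec$radius_mean, spec))
  sw_eff2 <- spec$sigma_w^2 / n_vox
  total_var <- spec$sigma_b^2 + sw_eff2
  n <- spec$n_subjects
  # per-scan subject means: variance sigma_b^2 + sigma_w_eff^2, within 3 SE
  v_hat <- stats::var(c(x1, x2))
  se_v <- total_var * sqrt(2 / (2 * n - 1))
  expect_lt(abs(v_hat - total_var), 3 * se_v)
  # test-retest differences: variance 2 sigma_w_eff^2, within 3 SE
  d_var <- stats::var(x1 - x2)
  se_d <- 2 * sw_eff2 * sqrt(2 / (n - 1))
  expect_lt(abs(d_var - 2 * sw_eff2), 3 * se_d)
})

test_that("worked fixtures are the documented tiny objects", {
  cube <- worked_fixture("cube10")
  expect_equal(dim(cube$image), c(10L, 10L, 10L))
  expect_true(all(cube$mask$labels == 1L))
  chk <- worked_fixture("checker2x2")
  expect_equal(chk$image$voxels[, , 1], matrix(c(1, 1, 2, 2), 2, 2))
  expect_equal(length(unique(as.vector(worked_fixture("constant")$image$voxels))), 1L)
  expect_error(worked_fixture("nope"), "unknown fixture")
})
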