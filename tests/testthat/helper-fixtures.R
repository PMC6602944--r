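# Shared fixtures. The demo study is expensive enough to build once and
# reuse across test files (lazily, cached in this environment).

.fixture_env <- new.env(parent = emptyenv())

demo_report <- function() {
  if (is.null(.fixture_env$demo)) {
    .fixture_env$demo <- run_study(demo_study_config(seed = 11))
  }
  .fixture_env$demo
}

# small non-constant image with a full-grid ROI plus a reference blob
small_image_and_mask <- function(seed = 42, dims = c(8, 8, 4)) {
  set.seed(seed)
  img <- volume_image(array(stats::rnorm(prod(dims), 100, 25), dims),
                      spacing = c(1, 1, 2))
  labels <- array(1L, dims)
  labels[1:3, 1:3, ] <- 2L
  mask <- seg_mask(labels, list(roi = c(1L, 2L), blob = 2L,
                                muscle_reference = 2L),
                   spacing = c(1, 1, 2))
  list(image = img, mask = mask)
}

# restricted phantom spec with a closed-form ROI-mean ICC
restricted_spec <- function(icc = 0.7, seed = 1) {
  spec <- phantom_spec(n_subjects = 15, shape = c(16, 16, 8),
                       spacing = c(1, 1, 1), radius_mean = 3, radius_sd = 0,
                       center_jitter = 0, texture_sd = 0,
                       muscle_texture_sd = 0, gain_sd = 0, offset_sd = 0,
                       boundary_jitter = 0, gland_scale_sd = 0,
                       sigma_w = 40, seed = seed)
  calibrate_phantom_icc(spec, icc)
}

cohort_roi_means <- function(cohort, roi = "tumor") {
  vapply(seq_len(nrow(cohort)), function(r) {
    mean(roi_values(cohort$image[[r]], cohort$mask[[r]], roi))
  }, numeric(1))
}
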