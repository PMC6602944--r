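#' Specification of a synthetic test-retest phantom cohort
#'
#' Defines the generative model for a cohort of prostate-like phantom volumes
#' imaged at two timepoints ("test" and "retest"). The anatomy is a bright
#' gland ellipsoid containing a posterior peripheral-zone band and a darker
#' spherical lesion, plus a homogeneous low-intensity muscle-reference
#' cylinder. The variance structure is explicit:
#'
#' * **between-subject**: a per-subject additive shift of the prostate tissue
#'   intensities with SD `sigma_b`, a per-subject lesion radius and centre,
#'   and a per-subject Gaussian-random-field texture (shared by both scans);
#' * **within-subject**: per-scan i.i.d. voxel noise with SD `sigma_w`,
#'   per-scan global gain/offset drift, and per-scan single-voxel
#'   dilation/erosion jitter of the tumor contour.
#'
#' @param n_subjects Number of subjects (each scanned twice). Must be >= 2.
#' @param shape Grid size (voxels per axis).
#' @param spacing Voxel size in mm per axis.
#' @param radius_mean,radius_sd Lesion radius distribution (mm); per-subject.
#' @param center_jitter SD (mm) of the per-subject lesion centre displacement.
#' @param sigma_b Between-subject SD of the prostate tissue mean intensity.
#' @param sigma_w Within-subject (scan-to-scan) per-voxel noise SD.
#' @param texture_sd Amplitude (SD) of the per-subject prostate texture field.
#' @param texture_corr_mm Correlation length (Gaussian smoothing sigma, mm) of
#'   the texture field.
#' @param muscle_texture_sd Texture SD of the muscle reference region (kept
#'   small: the reference region is meant to be homogeneous).
#' @param gain_sd SD of the per-scan multiplicative gain (mean 1).
#' @param offset_sd SD of the per-scan additive offset (mean 0).
#' @param boundary_jitter Probability that a scan's tumor contour is perturbed
#'   by one voxel (random in-plane dilation or erosion, mimicking slice-wise
#'   re-contouring inconsistency).
#' @param gland_scale_sd SD of the per-subject log-scale of the gland
#'   ellipsoid axes (between-subject anatomical size variation).
#' @param tissue Named intensities for `background`, `gland`, `pz`, `tumor`,
#'   `muscle`.
#' @param seed Master seed; the full cohort is a pure function of the spec.
#'
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(n_subjects = 3, seed = 7)
#' cohort <- generate_cohort(spec)
#' nrow(cohort)  # 6: two timepoints per subject
#' @export
phantom_spec <- function(n_subjects = 15,
                         shape = c(40, 40, 16),
                         spacing = c(1, 1, 3),
                         radius_mean = 5, radius_sd = 1,
                         center_jitter = 1,
                         sigma_b = 20, sigma_w = 10,
                         texture_sd = 15, texture_corr_mm = 2,
                         muscle_texture_sd = 2,
                         gain_sd = 0.05, offset_sd = 10,
                         boundary_jitter = 0.15,
                         gland_scale_sd = 0.08,
                         tissue = c(background = 50, gland = 200, pz = 240,
                                    tumor = 150, muscle = 80),
                         seed = 1L) {
  stopifnot(n_subjects >= 2, sigma_b >= 0, sigma_w >= 0, texture_sd >= 0,
            radius_mean > 0, radius_sd >= 0, boundary_jitter >= 0,
            boundary_jitter <= 1, length(shape) == 3, length(spacing) == 3,
            all(shape >= 4), all(spacing > 0))
  structure(
    list(n_subjects = as.integer(n_subjects), shape = as.integer(shape),
         spacing = as.numeric(spacing), radius_mean = radius_mean,
         radius_sd = radius_sd, center_jitter = center_jitter,
         sigma_b = sigma_b, sigma_w = sigma_w, texture_sd = texture_sd,
         texture_corr_mm = texture_corr_mm,
         muscle_texture_sd = muscle_texture_sd,
         gain_sd = gain_sd, offset_sd = offset_sd,
         boundary_jitter = boundary_jitter,
         gland_scale_sd = gland_scale_sd, tissue = tissue,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' ROI label dictionary of the phantom
#'
#' Labels are hierarchical: tumor voxels carry code 1, the rest of the
#' peripheral zone code 2, the rest of the gland code 3 and the muscle
#' reference code 4; an ROI is the union of codes.
#' @return Named list mapping ROI name to label codes.
#' @export
phantom_roi_codes <- function() {
  list(tumor = 1L, peripheral_zone = c(1L, 2L),
       whole_gland = c(1L, 2L, 3L), muscle_reference = 4L)
}

# physical voxel-centre coordinate grids
coord_grids <- function(shape, spacing) {
  list(
    x = array(rep((seq_len(shape[1]) - 0.5) * spacing[1], times = shape[2] * shape[3]), shape),
    y = array(rep(rep((seq_len(shape[2]) - 0.5) * spacing[2], each = shape[1]), times = shape[3]), shape),
    z = array(rep((seq_len(shape[3]) - 0.5) * spacing[3], each = shape[1] * shape[2]), shape)
  )
}

# deterministic anatomy scaffold: grid geometry, nominal gland axes, muscle
# cylinder; the gland/PZ masks are realized per subject via gland_masks()
phantom_anatomy <- function(spec) {
  g <- coord_grids(spec$shape, spec$spacing)
  ext <- spec$shape * spec$spacing
  ctr <- ext / 2
  semi <- pmin(c(0.35, 0.3, 0.35) * ext, c(16, 14, 18))
  mctr <- 0.15 * ext[1:2]
  mrad <- min(3.5, 0.12 * min(ext[1:2]))
  muscle <- ((g$x - mctr[1])^2 + (g$y - mctr[2])^2 <= mrad^2) &
    (g$z >= 0.25 * ext[3]) & (g$z <= 0.75 * ext[3])
  list(grids = g, ext = ext, ctr = ctr, semi = semi, muscle = muscle)
}

# gland ellipsoid and posterior peripheral-zone band at a subject's scale
gland_masks <- function(anat, scale = 1) {
  g <- anat$grids
  ctr <- anat$ctr
  semi <- anat$semi * scale
  gland <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2 <= 1
  pz <- gland & (g$y >= ctr[2] + 0.25 * semi[2])
  list(gland = gland, pz = pz)
}

# voxel mask of a sphere; errors if it pokes out of the grid
lesion_mask <- function(anat, center, radius, spec) {
  if (any(center - radius < 0) || any(center + radius > anat$ext)) {
    stop("lesion does not fit in the image grid", call. = FALSE)
  }
  g <- anat$grids
  (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2 <= radius^2
}

# nominal tumor centre: in the posterior gland, inside the PZ band
nominal_lesion_center <- function(anat) {
  c(anat$ctr[1], anat$ctr[2] + 0.5 * anat$semi[2], anat$ctr[3])
}

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# 6-connected binary dilation/erosion restricted to one voxel layer
shift3 <- function(arr, d) {
  dm <- dim(arr)
  idx <- lapply(1:3, function(a) {
    i <- seq_len(dm[a]) - d[a]
    i[i < 1L | i > dm[a]] <- NA_integer_
    i
  })
  out <- array(FALSE, dm)
  ok <- lapply(idx, function(i) !is.na(i))
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    arr[idx[[1]][ok[[1]]], idx[[2]][ok[[2]]], idx[[3]][ok[[3]]]]
  out
}

neighbor_offsets6 <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

binary_dilate <- function(arr, in_plane = FALSE) {
  offs <- if (in_plane) neighbor_offsets6[1:4] else neighbor_offsets6
  out <- arr
  for (d in offs) out <- out | shift3(arr, d)
  out
}

binary_erode <- function(arr, in_plane = FALSE) {
  offs <- if (in_plane) neighbor_offsets6[1:4] else neighbor_offsets6
  out <- arr
  for (d in offs) out <- out & shift3(arr, d)
  out
}

#' Generate a test-retest phantom cohort
#'
#' Realizes the generative model of a [phantom_spec()]: per-subject quantities
#' (tissue shift, lesion geometry, texture field) are drawn once and shared by
#' both timepoints; per-scan quantities (voxel noise, gain/offset, contour
#' jitter) are drawn independently per timepoint. Each subject uses a seed
#' sub-stream derived from the master seed, so the first `k` subjects of a
#' cohort do not change when `n_subjects` grows.
#'
#' @param spec A [phantom_spec()].
#' @return A tibble with columns `subject_id`, `timepoint` (`"test"` /
#'   `"retest"`), `image` (list of [volume_image()]) and `mask` (list of
#'   [seg_mask()]); exactly two rows per subject.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  anat <- phantom_anatomy(spec)
  subject_seeds <- derive_seeds(spec$seed, spec$n_subjects)
  rows <- purrr::map(seq_len(spec$n_subjects), function(i) {
    generate_subject(spec, anat, sprintf("S%02d", i), subject_seeds[i])
  })
  dplyr::bind_rows(rows)
}

generate_subject <- function(spec, anat, subject_id, subject_seed) {
  set.seed(subject_seed)
  shift_b <- stats::rnorm(1, 0, spec$sigma_b)
  radius <- max(1.5, stats::rnorm(1, spec$radius_mean, spec$radius_sd))
  center <- nominal_lesion_center(anat) +
    stats::rnorm(3, 0, spec$center_jitter)
  gscale <- if (spec$gland_scale_sd > 0) {
    exp(stats::rnorm(1, 0, spec$gland_scale_sd))
  } else 1
  scan_seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  gp <- gland_masks(anat, gscale)

  tumor0 <- lesion_mask(anat, center, radius, spec)
  texture <- array(0, spec$shape)
  if (spec$texture_sd > 0) {
    field <- gaussian_smooth(array(stats::rnorm(prod(spec$shape)), spec$shape),
                             spec$texture_corr_mm, spec$spacing)
    texture <- field / stats::sd(field) * spec$texture_sd
  }
  muscle_texture <- array(0, spec$shape)
  if (spec$muscle_texture_sd > 0) {
    muscle_texture <- array(stats::rnorm(prod(spec$shape), 0,
                                         spec$muscle_texture_sd), spec$shape)
  }

  tis <- spec$tissue
  base <- array(tis[["background"]], spec$shape)
  base[gp$gland] <- tis[["gland"]] + shift_b
  base[gp$pz] <- tis[["pz"]] + shift_b
  base[tumor0] <- tis[["tumor"]] + shift_b
  prostate <- gp$gland | tumor0
  base[prostate] <- base[prostate] + texture[prostate]
  # the reference muscle lies outside the prostate by construction
  muscle <- anat$muscle & !prostate
  base[muscle] <- tis[["muscle"]] + muscle_texture[muscle]

  purrr::map_dfr(c("test", "retest"), function(tp) {
    set.seed(scan_seeds[if (tp == "test") 1L else 2L])
    gain <- if (spec$gain_sd > 0) stats::rnorm(1, 1, spec$gain_sd) else 1
    offset <- if (spec$offset_sd > 0) stats::rnorm(1, 0, spec$offset_sd) else 0
    noise <- if (spec$sigma_w > 0) {
      array(stats::rnorm(prod(spec$shape), 0, spec$sigma_w), spec$shape)
    } else 0
    vox <- gain * base + offset + noise

    tumor <- tumor0
    if (spec$boundary_jitter > 0 && stats::runif(1) < spec$boundary_jitter) {
      if (stats::runif(1) < 0.5) {
        tumor <- binary_dilate(tumor0, in_plane = TRUE)
      } else {
        eroded <- binary_erode(tumor0, in_plane = TRUE)
        if (any(eroded)) tumor <- eroded  # jitter must never empty the tumor
      }
    }
    labels <- array(0L, spec$shape)
    labels[gp$gland] <- 3L
    labels[gp$pz] <- 2L
    labels[muscle] <- 4L
    labels[tumor] <- 1L

    tibble::tibble(
      subject_id = subject_id, timepoint = tp,
      image = list(volume_image(vox, spacing = spec$spacing)),
      mask = list(seg_mask(labels, phantom_roi_codes(),
                           spacing = spec$spacing))
    )
  })
}

#' Closed-form ICC of the tumor ROI-mean feature
#'
#' For a restricted phantom spec the one-way random-effects ICC of the
#' "mean intensity over the tumor ROI" feature has the closed form
#' \deqn{ICC = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2 / N),}
#' where \eqn{N} is the voxel count of the nominal lesion: averaging the
#' i.i.d. scan noise over the ROI reduces its variance by \eqn{N}. The closed
#' form requires that the ROI mean have no other variance source, i.e. gain
#' fixed at 1, offset fixed at 0, zero texture amplitude, no contour jitter
#' and a fixed lesion geometry (`radius_sd = 0`, `center_jitter = 0`).
#'
#' @param spec A [phantom_spec()] satisfying the restrictions above.
#' @return The theoretical ICC in `[0, 1]`; `NA` when both variance
#'   components are zero (the ICC is then undefined).
#' @export
theoretical_icc_roi_mean <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$gain_sd != 0 || spec$offset_sd != 0) {
    stop("closed form requires fixed gain (gain_sd = 0) and offset (offset_sd = 0)",
         call. = FALSE)
  }
  if (spec$texture_sd != 0 || spec$boundary_jitter != 0 ||
      spec$radius_sd != 0 || spec$center_jitter != 0) {
    stop(paste("closed form requires texture_sd = 0, boundary_jitter = 0,",
               "radius_sd = 0 and center_jitter = 0"), call. = FALSE)
  }
  anat <- phantom_anatomy(spec)
  n_vox <- sum(lesion_mask(anat, nominal_lesion_center(anat),
                           spec$radius_mean, spec))
  sigma_w_eff2 <- spec$sigma_w^2 / n_vox
  if (spec$sigma_b == 0 && sigma_w_eff2 == 0) return(NA_real_)
  spec$sigma_b^2 / (spec$sigma_b^2 + sigma_w_eff2)
}

#' Choose phantom variances for a target ROI-mean ICC
#'
#' Convenience inverse of [theoretical_icc_roi_mean()]: given a restricted
#' spec and a target ICC, returns the spec with `sigma_b` set so that the
#' closed-form ICC equals the target (holding `sigma_w` fixed).
#'
#' @param spec A restricted [phantom_spec()] (see [theoretical_icc_roi_mean()]).
#' @param icc Target ICC in `(0, 1)`.
#' @return The modified spec.
#' @export
calibrate_phantom_icc <- function(spec, icc) {
  stopifnot(icc > 0, icc < 1, spec$sigma_w > 0)
  anat <- phantom_anatomy(spec)
  n_vox <- sum(lesion_mask(anat, nominal_lesion_center(anat),
                           spec$radius_mean, spec))
  sigma_w_eff2 <- spec$sigma_w^2 / n_vox
  spec$sigma_b <- sqrt(icc / (1 - icc) * sigma_w_eff2)
  spec
}

#' Tiny deterministic worked fixtures
#'
#' A registry of hand-sized image/mask pairs used throughout the package's
#' worked examples and oracle tests.
#'
#' * `"cube10"`: 10x10x10 volume, intensities 1..1000, all-foreground mask,
#'   1 mm spacing.
#' * `"checker2x2"`: one 2x2 slice with columns of 1s and 2s.
#' * `"constant"`: uniform-intensity 8x8x3 volume.
#'
#' @param name Fixture name.
#' @return A list with elements `image` ([volume_image()]) and `mask`
#'   ([seg_mask()]) whose single ROI is called `"roi"`.
#' @export
worked_fixture <- function(name) {
  roi <- list(roi = 1L)
  switch(name,
    cube10 = {
      arr <- array(as.numeric(seq_len(1000)), c(10, 10, 10))
      list(image = volume_image(arr),
           mask = seg_mask(array(1L, c(10, 10, 10)), roi))
    },
    checker2x2 = {
      arr <- array(c(1, 1, 2, 2), c(2, 2, 1))  # column-major: [[1,2],[1,2]]
      list(image = volume_image(arr),
           mask = seg_mask(array(1L, c(2, 2, 1)), roi))
    },
    constant = {
      arr <- array(5, c(8, 8, 3))
      list(image = volume_image(arr),
           mask = seg_mask(array(1L, c(8, 8, 3)), roi))
    },
    stop(sprintf("unknown fixture '%s'", name), call. = FALSE)
  )
}
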