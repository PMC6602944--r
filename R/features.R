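# Feature definitions: first-order intensity statistics, geometric shape
# descriptors, and statistics over the GLCM/GLRLM/GLSZM texture matrices.
# Formulas follow the image-biomarker consensus definitions. Moments use the
# population (divide-by-N) convention; percentiles interpolate linearly
# between order statistics; Kurtosis is reported non-excess (a normal
# distribution scores 3); entropies use log base 2 with 0*log(0) = 0.

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' First-order intensity features
#'
#' Computes the first-order roster over the raw ROI intensities: `Mean`,
#' `Median`, `10Percentile`, `90Percentile`, `Energy` (sum of squares),
#' `Variance` (population), `Skewness`, `Kurtosis` (non-excess) and
#' `Entropy`. Entropy is the Shannon entropy (base 2) of the fixed-bin-width
#' discretized intensities, so it needs a `bin_width`; without one it is
#' flagged missing.
#'
#' @param values Numeric vector of ROI intensities (non-empty).
#' @param bin_width Bin width for the Entropy discretization (`NULL` to skip).
#' @return Named list of feature values; degenerate features are `NA`.
#' @examples
#' first_order_features(c(1, 2, 3, 4), bin_width = 1)
#' @export
first_order_features <- function(values, bin_width = NULL) {
  if (length(values) == 0L) stop("empty ROI", call. = FALSE)
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  skew <- if (m2 > 0) mean((values - mu)^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean((values - mu)^4) / m2^2 else NA_real_
  entropy <- NA_real_
  if (!is.null(bin_width)) {
    lv <- discretize(values, bin_width)$levels
    p <- tabulate(lv) / n
    entropy <- -sum(xlog2(p))
  }
  q <- unname(stats::quantile(values, c(0.1, 0.5, 0.9), type = 7))
  list(
    Mean = mu,
    Median = q[2],
    `10Percentile` = q[1],
    `90Percentile` = q[3],
    Energy = sum(values^2),
    Variance = m2,
    Skewness = skew,
    Kurtosis = kurt,
    Entropy = entropy
  )
}

# surface voxels: ROI voxels with at least one 6-neighbor outside the ROI
surface_voxels <- function(roi) {
  interior <- binary_erode(roi)
  roi & !interior
}

max_pairwise_distance <- function(coords) {
  n <- nrow(coords)
  if (n == 1L) return(0)
  # distances from the two extreme points along each axis bound the search;
  # exact answer via full pairwise distances on the (small) surface set
  d2 <- 0
  block <- 512L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    a <- coords[s:e, , drop = FALSE]
    cross <- outer(rowSums(a^2), rowSums(coords^2), "+") -
      2 * a %*% t(coords)
    d2 <- max(d2, max(cross))
  }
  sqrt(max(d2, 0))
}

#' Shape features of an ROI
#'
#' Geometry-only descriptors, independent of intensity (and therefore of any
#' intensity pre-filtering): `Volume` (voxel count x voxel volume),
#' `SurfaceArea` (sum of exposed voxel faces), `Sphericity`
#' (`pi^(1/3) (6V)^(2/3) / A`), `SurfaceVolumeRatio`, `Maximum3DDiameter`
#' and `Maximum2DDiameterSlice` (largest distances between voxel centres,
#' in 3-D and within any single slice), `MajorAxisLength` (4 sqrt of the
#' largest eigenvalue of the voxel-coordinate covariance) and `Elongation`
#' (sqrt of the second-largest over largest eigenvalue). Descriptors that are
#' meaningless for single-slice ROIs (flatness, least axis) are not part of
#' the roster.
#'
#' @param mask A [seg_mask()].
#' @param roi ROI name.
#' @return Named list of feature values (mm-based units).
#' @export
shape_features <- function(mask, roi) {
  ind <- roi_indicator(mask, roi)
  n <- sum(ind)
  if (n == 0L) stop(sprintf("ROI '%s' is empty", roi), call. = FALSE)
  sp <- mask$spacing
  voxvol <- prod(sp)
  volume <- n * voxvol

  # exposed-face counting per axis
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  area <- 0
  for (a in 1:3) {
    d <- c(0L, 0L, 0L); d[a] <- 1L
    nb_fwd <- shift_fill(ind, d, FALSE)
    nb_bwd <- shift_fill(ind, -d, FALSE)
    area <- area + face_area[a] * (sum(ind & !nb_fwd) + sum(ind & !nb_bwd))
  }
  sphericity <- pi^(1 / 3) * (6 * volume)^(2 / 3) / area

  which_idx <- which(ind, arr.ind = TRUE)
  coords <- sweep(which_idx, 2, sp, `*`)
  surf <- surface_voxels(ind)
  surf_idx <- which(surf, arr.ind = TRUE)
  surf_coords <- sweep(surf_idx, 2, sp, `*`)
  max3d <- max_pairwise_distance(surf_coords)
  max2d <- max(vapply(unique(surf_idx[, 3]), function(z) {
    max_pairwise_distance(surf_coords[surf_idx[, 3] == z, 1:2, drop = FALSE])
  }, numeric(1)))

  if (n > 1L) {
    cv <- stats::cov(coords) * (n - 1) / n  # population covariance
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0
    major <- 4 * sqrt(ev[1])
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_
  } else {
    major <- 0
    elong <- NA_real_
  }

  list(
    Volume = volume,
    SurfaceArea = area,
    Sphericity = sphericity,
    SurfaceVolumeRatio = area / volume,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = max2d,
    MajorAxisLength = major,
    Elongation = elong
  )
}

require_normalized <- function(m, kind) {
  stopifnot(inherits(m, "texture_matrix"))
  if (m$kind != kind) stop(sprintf("expected a %s matrix", kind), call. = FALSE)
  if (kind == "GLCM" && !m$normalized) {
    stop("GLCM features require a normalized matrix; see normalize_texture_matrix()",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' GLCM features
#'
#' Statistics over a normalized symmetric co-occurrence matrix `p(i, j)`:
#' `JointEntropy`, `JointEnergy`, `Idm` (inverse difference moment),
#' `Correlation`, `Contrast`, `JointAverage`, `ClusterProminence`, and
#' `SumAverage` (which equals `2 * JointAverage` for symmetric matrices and
#' is excluded from the default roster for that reason). `Correlation` of a
#' degenerate single-level matrix is flagged missing.
#'
#' @param m A normalized GLCM `texture_matrix`.
#' @return Named list of feature values.
#' @export
glcm_features <- function(m) {
  require_normalized(m, "GLCM")
  p <- m$counts
  ng <- m$ng
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(seq_len(ng) * px)
  muy <- sum(seq_len(ng) * py)
  sdx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  corr <- if (sdx > 0 && sdy > 0) {
    (sum(i * j * p) - mux * muy) / (sdx * sdy)
  } else NA_real_
  list(
    JointEntropy = -sum(xlog2(p)),
    JointEnergy = sum(p^2),
    Idm = sum(p / (1 + (i - j)^2)),
    Correlation = corr,
    Contrast = sum(p * (i - j)^2),
    JointAverage = sum(i * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    SumAverage = sum((i + j) * p)
  )
}

#' GLRLM features
#'
#' Statistics over the run-length matrix `r(i, l)` with `Nr = sum(r)` runs:
#' `ShortRunEmphasis`, `LongRunEmphasis`, `GrayLevelNonUniformity`,
#' `RunPercentage` and `GrayLevelVariance`. Under merged-direction
#' accumulation `RunPercentage` is `Nr / (n_voxels * n_directions)`, keeping
#' it in (0, 1].
#'
#' @param m A GLRLM `texture_matrix`.
#' @return Named list of feature values.
#' @export
glrlm_features <- function(m) {
  require_normalized(m, "GLRLM")
  r <- m$counts
  nr <- sum(r)
  if (nr == 0) stop("empty GLRLM", call. = FALSE)
  l <- matrix(seq_len(ncol(r)), nrow(r), ncol(r), byrow = TRUE)
  i <- matrix(seq_len(nrow(r)), nrow(r), ncol(r))
  p <- r / nr
  mu <- sum(i * p)
  list(
    ShortRunEmphasis = sum(r / l^2) / nr,
    LongRunEmphasis = sum(r * l^2) / nr,
    GrayLevelNonUniformity = sum(rowSums(r)^2) / nr,
    RunPercentage = nr / (m$n_voxels * m$n_directions),
    GrayLevelVariance = sum(p * (i - mu)^2)
  )
}

#' GLSZM features
#'
#' Statistics over the size-zone matrix `s(i, z)` with `Ns = sum(s)` zones:
#' `SmallAreaEmphasis`, `LargeAreaEmphasis`, `GrayLevelNonUniformity`,
#' `ZonePercentage` (`Ns / n_voxels`) and `ZoneEntropy`.
#'
#' @param m A GLSZM `texture_matrix`.
#' @return Named list of feature values.
#' @export
glszm_features <- function(m) {
  require_normalized(m, "GLSZM")
  s <- m$counts
  ns <- sum(s)
  if (ns == 0) stop("empty GLSZM", call. = FALSE)
  z <- matrix(seq_len(ncol(s)), nrow(s), ncol(s), byrow = TRUE)
  p <- s / ns
  list(
    SmallAreaEmphasis = sum(s / z^2) / ns,
    LargeAreaEmphasis = sum(s * z^2) / ns,
    GrayLevelNonUniformity = sum(rowSums(s)^2) / ns,
    ZonePercentage = ns / m$n_voxels,
    ZoneEntropy = -sum(xlog2(p))
  )
}
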