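# Image filter bank: identity, Laplacian-of-Gaussian at mm-scale sigmas,
# single-level undecimated wavelet sub-bands, and four single-voxel intensity
# transforms with range restoration.

# Decomposition filter banks. Coefficients are the standard published
# Coiflet-1 and Haar analysis filters.
wavelet_filters <- function(family = c("coif1", "haar")) {
  family <- match.arg(family)
  if (family == "haar") {
    lo <- c(1, 1) / sqrt(2)
    hi <- c(-1, 1) / sqrt(2)
  } else {
    lo <- c(-0.0156557281357920, -0.0727326195125265, 0.3848648468648578,
            0.8525720202116004, 0.3378976624574818, -0.0727326195125265)
    hi <- c(0.0727326195125265, 0.3378976624574818, -0.8525720202116004,
            0.3848648468648578, 0.0727326195125265, -0.0156557281357920)
  }
  list(L = lo, H = hi)
}

#' Filter specification
#'
#' One element of the pre-filter grid applied to the (normalized) image before
#' feature extraction.
#'
#' @param kind One of `"original"`, `"log"` (Laplacian of Gaussian),
#'   `"wavelet"`, `"square"`, `"squareroot"`, `"logarithm"`, `"exponential"`.
#' @param sigma_mm LoG scale in millimetres (`log` only); the study grid is
#'   1-5 mm.
#' @param subband Per-axis `"L"`/`"H"` string (`wavelet` only), e.g. `"HLH"`;
#'   its length must equal the image dimensionality (3 for volumes, 2 for
#'   single-slice images).
#' @param family Wavelet family: `"coif1"` (default) or `"haar"`.
#' @return An object of class `filter_spec`.
#' @examples
#' filter_spec("log", sigma_mm = 3)
#' filter_spec("wavelet", subband = "HLH")
#' @export
filter_spec <- function(kind = c("original", "log", "wavelet", "square",
                                 "squareroot", "logarithm", "exponential"),
                        sigma_mm = NULL, subband = NULL, family = "coif1") {
  kind <- match.arg(kind)
  if (kind == "log") {
    if (is.null(sigma_mm) || sigma_mm <= 0) {
      stop("LoG filter needs sigma_mm > 0", call. = FALSE)
    }
  }
  if (kind == "wavelet") {
    if (is.null(subband) || !grepl("^[LH]+$", subband)) {
      stop("wavelet filter needs a subband string over {L,H}", call. = FALSE)
    }
  }
  structure(
    list(kind = kind, sigma_mm = sigma_mm, subband = subband, family = family),
    class = "filter_spec"
  )
}

#' Serialize / parse filter specs
#'
#' Filter specs travel through configs and feature keys as compact strings:
#' `"original"`, `"log:sigma=3.0"`, `"wavelet:HLH"`, `"square"`, ...
#'
#' @param spec A [filter_spec()].
#' @return `filter_label()`: a string; `parse_filter_spec()`: a
#'   [filter_spec()].
#' @export
filter_label <- function(spec) {
  switch(spec$kind,
    log = sprintf("log:sigma=%.1f", spec$sigma_mm),
    wavelet = sprintf("wavelet:%s", spec$subband),
    spec$kind
  )
}

#' @rdname filter_label
#' @param label A filter label string.
#' @export
parse_filter_spec <- function(label) {
  if (grepl("^log:sigma=", label)) {
    return(filter_spec("log", sigma_mm = as.numeric(sub("^log:sigma=", "", label))))
  }
  if (grepl("^wavelet:", label)) {
    return(filter_spec("wavelet", subband = sub("^wavelet:", "", label)))
  }
  filter_spec(label)
}

# is the third axis degenerate (single slice)?
is_single_slice <- function(img) dim(img$voxels)[3] == 1L

log_filter <- function(img, sigma_mm) {
  sd_vox <- sigma_mm / img$spacing
  smooth_k <- lapply(sd_vox, gaussian_kernel)
  out <- array(0, dim(img$voxels))
  axes <- if (is_single_slice(img)) 1:2 else 1:3
  for (a in axes) {
    kernels <- smooth_k
    kernels[[a]] <- gaussian_d2_kernel(sd_vox[a])
    if (is_single_slice(img)) kernels[3] <- list(NULL)
    # second derivative w.r.t. physical distance: 1/spacing^2
    out <- out + conv_separable(img$voxels, kernels) / img$spacing[a]^2
  }
  out
}

wavelet_filter <- function(img, subband, family) {
  bands <- strsplit(subband, "")[[1]]
  ndim <- if (is_single_slice(img)) 2L else 3L
  if (length(bands) != ndim) {
    stop(sprintf("subband '%s' has length %d but the image is %d-D",
                 subband, length(bands), ndim), call. = FALSE)
  }
  fb <- wavelet_filters(family)
  kernels <- vector("list", 3)
  for (a in seq_len(ndim)) kernels[[a]] <- fb[[bands[a]]]
  conv_separable(img$voxels, kernels)
}

# square / squareroot / logarithm / exponential with range restoration:
# transformed magnitudes are rescaled so the maximum |value| equals the
# pre-transform maximum |value|, and the original sign is restored.
intensity_transform <- function(img, kind) {
  x <- img$voxels
  m <- max(abs(x))
  if (m == 0) return(x)
  t <- switch(kind,
    square = x^2,
    squareroot = sqrt(abs(x)),
    logarithm = log(abs(x) + 1),
    # exp(x) rescaled by its max == exp(x - max(x)); overflow-proof
    exponential = exp(x - max(x))
  )
  tm <- max(abs(t))
  if (tm == 0) return(array(0, dim(x)))
  sign(x) * abs(t) * (m / tm)
}

#' Apply one filter to an image
#'
#' All filters preserve grid geometry (shape, spacing, origin). `original`
#' returns the input unchanged. `log` convolves with a Laplacian-of-Gaussian
#' whose sigma is interpreted in millimetres: the per-axis Gaussian SD in
#' voxels is `sigma_mm / spacing`, so anisotropic spacing is honoured.
#' `wavelet` returns one sub-band of a single-level undecimated (stationary)
#' wavelet transform with symmetric boundary padding. The four intensity
#' transforms compute `x^2`, `sqrt(|x|)`, `log(|x|+1)` and `exp(x)` per voxel,
#' rescale the transformed magnitudes back to the original image's maximum
#' absolute intensity and restore the original sign. Single-slice images are
#' filtered in-plane (the out-of-plane axis is skipped for `log`/`wavelet`).
#'
#' @param img A [volume_image()].
#' @param spec A [filter_spec()] or its string label.
#' @return The filtered [volume_image()].
#' @export
apply_filter <- function(img, spec) {
  stopifnot(inherits(img, "volume_image"))
  if (is.character(spec)) spec <- parse_filter_spec(spec)
  out <- switch(spec$kind,
    original = img$voxels,
    log = log_filter(img, spec$sigma_mm),
    wavelet = wavelet_filter(img, spec$subband, spec$family),
    intensity_transform(img, spec$kind)
  )
  with_voxels(img, out)
}

#' Enumerate the filter grid
#'
#' Builds the ordered default filter set: the original image, LoG at each
#' sigma (ascending), every wavelet sub-band (all L/H combinations per axis,
#' first axis varying fastest: LLL, HLL, ..., HHH), then the four intensity
#' transforms. For 3-D images the default grid has 18 entries
#' (1 + 5 + 8 + 4).
#'
#' @param kinds Filter kinds to include (default: all).
#' @param log_sigmas_mm LoG sigmas in mm, default `1:5`.
#' @param ndim Image dimensionality (3 default; 2 gives 4 wavelet sub-bands).
#' @param family Wavelet family.
#' @return List of [filter_spec()]s in deterministic order.
#' @export
enumerate_filters <- function(kinds = c("original", "log", "wavelet", "square",
                                        "squareroot", "logarithm", "exponential"),
                              log_sigmas_mm = c(1, 2, 3, 4, 5),
                              ndim = 3, family = "coif1") {
  specs <- list()
  if ("original" %in% kinds) specs <- c(specs, list(filter_spec("original")))
  if ("log" %in% kinds) {
    for (s in sort(log_sigmas_mm)) {
      specs <- c(specs, list(filter_spec("log", sigma_mm = s)))
    }
  }
  if ("wavelet" %in% kinds) {
    combos <- do.call(expand.grid, rep(list(c("L", "H")), ndim))
    subbands <- apply(as.matrix(combos), 1, paste0, collapse = "")
    for (sb in subbands) {
      specs <- c(specs, list(filter_spec("wavelet", subband = sb,
                                         family = family)))
    }
  }
  for (k in c("square", "squareroot", "logarithm", "exponential")) {
    if (k %in% kinds) specs <- c(specs, list(filter_spec(k)))
  }
  specs
}
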