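# Fixed-bin-width discretization and grey-level texture matrices (GLCM,
# GLRLM, GLSZM) in 2D and 3D. Matrices are accumulated over the full unique
# direction set (13 offsets in 3D; 4 in-plane offsets, hence all slices, in
# 2D) and merged by summation before normalization.

#' Fixed-bin-width discretization of ROI intensities
#'
#' Maps intensities to integer grey levels with bins of constant width `w`.
#' The default anchors bins at the ROI minimum (the IBSI fixed-bin-size
#' form): `level(x) = floor((x - min) / w) + 1`. The alternative `aligned`
#' mode aligns bin edges to multiples of `w` instead:
#' `level(x) = floor(x / w) - floor(min / w) + 1`. Binning is always based
#' only on the intensities within the region of interest.
#'
#' @param values Numeric vector of ROI intensities (non-empty).
#' @param bin_width Bin width `w > 0`; the study grid is 10, 15, 20, 40.
#' @param aligned Use edge-aligned bins instead of min-anchored bins.
#' @return List with `levels` (integers in `1..n_levels`) and `n_levels`.
#' @examples
#' discretize(c(1, 2, 3, 7), 2)  # levels 1 1 2 4
#' @export
discretize <- function(values, bin_width, aligned = FALSE) {
  if (length(values) == 0L) stop("empty ROI: nothing to discretize", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  lv <- if (aligned) {
    as.integer(floor(values / bin_width) - floor(min(values) / bin_width)) + 1L
  } else {
    as.integer(floor((values - min(values)) / bin_width)) + 1L
  }
  list(levels = lv, n_levels = max(lv))
}

# unique direction sets (half-space representatives)
texture_directions <- function(dim = c("3D", "2D")) {
  dim <- match.arg(dim)
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) |
    (g$dz == 0 & g$dy == 0 & g$dx > 0)
  g <- g[keep, ]
  if (dim == "2D") g <- g[g$dz == 0, ]
  lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
}

# shift a 3-D array by integer offset d, filling exposed planes
shift_fill <- function(arr, d, fill) {
  dm <- dim(arr)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (d[a] >= 0) {
      dst[[a]] <- seq_len(dm[a] - d[a]) + d[a]
      src[[a]] <- seq_len(dm[a] - d[a])
    } else {
      dst[[a]] <- seq_len(dm[a] + d[a])
      src[[a]] <- seq_len(dm[a] + d[a]) - d[a]
    }
    if (length(src[[a]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

new_texture_matrix <- function(kind, counts, ng, dim, n_voxels, n_directions,
                               normalized = FALSE) {
  structure(
    list(kind = kind, counts = counts, ng = ng, dim = dim,
         n_voxels = n_voxels, n_directions = n_directions,
         aggregation = "merged", normalized = normalized),
    class = "texture_matrix"
  )
}

#' @export
print.texture_matrix <- function(x, ...) {
  cat(sprintf("<%s %s, %d grey levels, %s, %s>\n", x$kind, x$dim, x$ng,
              x$aggregation,
              if (x$normalized) "normalized" else "counts"))
  print(x$counts)
  invisible(x)
}

check_levels <- function(levels, roi) {
  lv <- levels[roi]
  if (length(lv) == 0L) stop("empty ROI", call. = FALSE)
  if (any(lv < 1L)) stop("levels must be >= 1 inside the ROI", call. = FALSE)
  lv
}

#' Grey-level co-occurrence matrix
#'
#' Counts co-occurring grey-level pairs at a fixed voxel offset, accumulated
#' over the unique direction set (13 directions in 3D, the 4 in-plane
#' directions in 2D, which merges all slices) with both voxels inside the
#' ROI. Matrices from all directions are merged by summation. With
#' `symmetric = TRUE` (default) each pair is counted in both orders, making
#' the matrix symmetric.
#'
#' @param levels Integer 3-D array of grey levels (values inside the ROI must
#'   be in `1..ng`). A matrix is treated as a single slice.
#' @param roi Logical array marking the ROI (default: everything).
#' @param dim `"3D"` or `"2D"` neighborhood.
#' @param distance Offset length in voxels (default 1).
#' @param symmetric Symmetric accumulation flag.
#' @param directions Optional list of integer offsets `c(dx, dy, dz)`
#'   overriding the standard direction set (e.g. a single direction for a
#'   worked example).
#' @return A `texture_matrix` of raw counts (normalize with
#'   [normalize_texture_matrix()]).
#' @export
build_glcm <- function(levels, roi = NULL, dim = c("3D", "2D"), distance = 1L,
                       symmetric = TRUE, directions = NULL) {
  dim <- match.arg(dim)
  if (is.matrix(levels)) levels <- array(levels, c(base::dim(levels), 1L))
  if (is.null(roi)) roi <- array(TRUE, base::dim(levels))
  if (is.matrix(roi)) roi <- array(roi, c(base::dim(roi), 1L))
  lv_in <- check_levels(levels, roi)
  ng <- max(lv_in)
  dirs <- if (is.null(directions)) texture_directions(dim) else directions
  m <- matrix(0, ng, ng)
  lv_na <- ifelse(roi, levels, NA_integer_)
  for (d in dirs) {
    nb <- shift_fill(lv_na, as.integer(d * distance), NA_integer_)
    sel <- !is.na(lv_na) & !is.na(nb)
    if (!any(sel)) next
    i <- lv_na[sel]; j <- nb[sel]
    cnt <- matrix(tabulate((i - 1L) * ng + j, nbins = ng * ng), ng, ng,
                  byrow = TRUE)
    m <- m + if (symmetric) cnt + t(cnt) else cnt
  }
  new_texture_matrix("GLCM", m, ng, dim, n_voxels = length(lv_in),
                     n_directions = length(dirs))
}

#' Normalize a texture matrix to probabilities
#'
#' @param m A `texture_matrix` of counts.
#' @return The matrix with entries summing to 1 and `normalized = TRUE`.
#' @export
normalize_texture_matrix <- function(m) {
  stopifnot(inherits(m, "texture_matrix"))
  tot <- sum(m$counts)
  if (tot == 0) stop("empty texture matrix", call. = FALSE)
  m$counts <- m$counts / tot
  m$normalized <- TRUE
  m
}

#' Grey-level run-length matrix
#'
#' Counts maximal runs of identical grey level along each direction of the
#' unique direction set; entry `(i, l)` is the number of runs of level `i`
#' and length `l`, merged over directions (and slices in 2D). Voxels outside
#' the ROI break runs. The run-length-weighted total satisfies
#' `sum(r * l) == n_voxels * n_directions`.
#'
#' @inheritParams build_glcm
#' @return A `texture_matrix` of run counts (`ng` rows, max run length cols).
#' @export
build_glrlm <- function(levels, roi = NULL, dim = c("3D", "2D"),
                        directions = NULL) {
  dim <- match.arg(dim)
  if (is.matrix(levels)) levels <- array(levels, c(base::dim(levels), 1L))
  if (is.null(roi)) roi <- array(TRUE, base::dim(levels))
  if (is.matrix(roi)) roi <- array(roi, c(base::dim(roi), 1L))
  lv_in <- check_levels(levels, roi)
  ng <- max(lv_in)
  dm <- base::dim(levels)
  dirs <- if (is.null(directions)) texture_directions(dim) else directions
  maxlen <- max(dm)
  counts <- matrix(0, ng, maxlen)
  ix <- as.vector(slice.index(levels, 1))
  iy <- as.vector(slice.index(levels, 2))
  iz <- as.vector(slice.index(levels, 3))
  lv0 <- as.vector(ifelse(roi, levels, 0L))
  for (d in dirs) {
    ax <- which(d != 0)[1]
    t_pos <- switch(ax, ix, iy, iz) * sign(d[ax])
    # line identifier: starting point of the line through each voxel
    k1 <- ix - t_pos * d[1]
    k2 <- iy - t_pos * d[2]
    k3 <- iz - t_pos * d[3]
    ord <- order(k1, k2, k3, t_pos)
    key <- (k1[ord] + 2L * maxlen) * (16L * maxlen * maxlen) +
      (k2[ord] + 2L * maxlen) * (4L * maxlen) + (k3[ord] + 2L * maxlen)
    grp <- cumsum(c(TRUE, diff(key) != 0))
    v <- grp * (ng + 1) + lv0[ord]  # distinct across group or level change
    r <- rle(v)
    lev <- r$values %% (ng + 1)
    keep <- lev > 0
    if (!any(keep)) next
    inc <- table(factor(lev[keep], levels = seq_len(ng)),
                 factor(r$lengths[keep], levels = seq_len(maxlen)))
    counts <- counts + unclass(inc)
  }
  used <- which(colSums(counts) > 0)
  counts <- counts[, seq_len(max(used)), drop = FALSE]
  dimnames(counts) <- NULL
  new_texture_matrix("GLRLM", counts, ng, dim, n_voxels = length(lv_in),
                     n_directions = length(dirs))
}

# connected-component labelling by iterative minimum-label propagation
connected_zones <- function(levels, roi, dim) {
  dm <- dim(levels)
  offs <- texture_directions(dim)          # half set; propagate both ways
  offs <- c(offs, lapply(offs, function(d) -d))
  lab <- array(NA_real_, dm)
  lab[roi] <- seq_len(sum(roi))
  idx <- array(NA_real_, dm)
  idx[roi] <- lab[roi]
  lv <- ifelse(roi, levels, NA_integer_)
  repeat {
    changed <- FALSE
    for (d in offs) {
      nb_lab <- shift_fill(lab, as.integer(d), NA_real_)
      nb_lv <- shift_fill(lv, as.integer(d), NA_integer_)
      upd <- !is.na(lab) & !is.na(nb_lab) & nb_lv == lv & nb_lab < lab
      upd[is.na(upd)] <- FALSE
      if (any(upd)) {
        lab[upd] <- nb_lab[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # resolve chains: labels point to ROI enumeration indices; compress
  flat_lab <- lab[roi]
  tibble::tibble(zone = match(flat_lab, sort(unique(flat_lab))),
                 level = levels[roi])
}

#' Grey-level size-zone matrix
#'
#' Counts connected components ("zones") of identical grey level; entry
#' `(i, z)` is the number of zones of level `i` and size `z` voxels.
#' Connectivity is 26-neighborhood in 3D and 8-neighborhood in-plane in 2D
#' (slices merged). The zone-size-weighted total satisfies
#' `sum(s * z) == n_voxels`.
#'
#' @inheritParams build_glcm
#' @return A `texture_matrix` of zone counts (`ng` rows, max zone size cols).
#' @export
build_glszm <- function(levels, roi = NULL, dim = c("3D", "2D")) {
  dim <- match.arg(dim)
  if (is.matrix(levels)) levels <- array(levels, c(base::dim(levels), 1L))
  if (is.null(roi)) roi <- array(TRUE, base::dim(levels))
  if (is.matrix(roi)) roi <- array(roi, c(base::dim(roi), 1L))
  lv_in <- check_levels(levels, roi)
  ng <- max(lv_in)
  zones <- connected_zones(levels, roi, dim)
  per_zone <- dplyr::summarise(dplyr::group_by(zones, .data$zone),
                               level = .data$level[1],
                               size = dplyr::n(), .groups = "drop")
  maxsize <- max(per_zone$size)
  counts <- matrix(0, ng, maxsize)
  for (r in seq_len(nrow(per_zone))) {
    counts[per_zone$level[r], per_zone$size[r]] <-
      counts[per_zone$level[r], per_zone$size[r]] + 1
  }
  new_texture_matrix("GLSZM", counts, ng, dim, n_voxels = length(lv_in),
                     n_directions = NA_integer_)
}
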