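# Independent brute-force oracles, written with plain loops and no use of
# the package's texture-matrix internals.

oracle_directions <- function(dim) {
  dirs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (!(dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))) next
    if (dim == "2D" && dz != 0) next
    dirs[[length(dirs) + 1]] <- c(dx, dy, dz)
  }
  dirs
}

in_bounds <- function(p, dm) all(p >= 1) && all(p <= dm)

# exhaustive pair enumeration
oracle_glcm <- function(levels, roi, dim, symmetric = TRUE) {
  dm <- dim(levels)
  ng <- max(levels[roi])
  m <- matrix(0, ng, ng)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (!roi[x, y, z]) next
    for (d in oracle_directions(dim)) {
      q <- c(x, y, z) + d
      if (!in_bounds(q, dm) || !roi[q[1], q[2], q[3]]) next
      i <- levels[x, y, z]; j <- levels[q[1], q[2], q[3]]
      m[i, j] <- m[i, j] + 1
      if (symmetric) m[j, i] <- m[j, i] + 1
    }
  }
  m
}

# maximal-run scanner
oracle_glrlm <- function(levels, roi, dim) {
  dm <- dim(levels)
  ng <- max(levels[roi])
  counts <- matrix(0, ng, max(dm))
  for (d in oracle_directions(dim)) {
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      p <- c(x, y, z)
      if (!roi[x, y, z]) next
      lv <- levels[x, y, z]
      prev <- p - d
      if (in_bounds(prev, dm) && roi[prev[1], prev[2], prev[3]] &&
          levels[prev[1], prev[2], prev[3]] == lv) next  # not a run start
      len <- 1
      q <- p + d
      while (in_bounds(q, dm) && roi[q[1], q[2], q[3]] &&
             levels[q[1], q[2], q[3]] == lv) {
        len <- len + 1
        q <- q + d
      }
      counts[lv, len] <- counts[lv, len] + 1
    }
  }
  counts[, seq_len(max(which(colSums(counts) > 0))), drop = FALSE]
}

# stack-based flood fill, 26/8-connectivity
oracle_glszm <- function(levels, roi, dim) {
  dm <- dim(levels)
  ng <- max(levels[roi])
  nbrs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dim == "2D" && dz != 0) next
    nbrs[[length(nbrs) + 1]] <- c(dx, dy, dz)
  }
  seen <- array(FALSE, dm)
  zones <- list()
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (!roi[x, y, z] || seen[x, y, z]) next
    lv <- levels[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (d in nbrs) {
        q <- p + d
        if (!in_bounds(q, dm)) next
        if (seen[q[1], q[2], q[3]] || !roi[q[1], q[2], q[3]]) next
        if (levels[q[1], q[2], q[3]] != lv) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(lv, size)
  }
  zm <- do.call(rbind, zones)
  counts <- matrix(0, ng, max(zm[, 2]))
  for (r in seq_len(nrow(zm))) {
    counts[zm[r, 1], zm[r, 2]] <- counts[zm[r, 1], zm[r, 2]] + 1
  }
  counts
}

# random small level grid with optional ragged ROI
random_level_grid <- function(max_side = 6, ng = 4, roi_prob = 1) {
  dm <- sample(2:max_side, 3, replace = TRUE)
  levels <- array(sample.int(ng, prod(dm), replace = TRUE), dm)
  roi <- array(stats::runif(prod(dm)) <= roi_prob, dm)
  if (!any(roi)) roi[1, 1, 1] <- TRUE
  # re-map levels so the ROI max equals the in-ROI level count
  list(levels = levels, roi = roi)
}

# direct sums-of-squares one-way ANOVA (k = 2) oracle
oracle_icc <- function(x1, x2) {
  n <- length(x1)
  all_v <- c(x1, x2)
  grand <- mean(all_v)
  mi <- (x1 + x2) / 2
  ss_between <- 2 * sum((mi - grand)^2)
  ss_within <- sum((x1 - mi)^2) + sum((x2 - mi)^2)
  bms <- ss_between / (n - 1)
  wms <- ss_within / n
  list(bms = bms, wms = wms, icc = (bms - wms) / (bms + wms))
}

# trim trailing all-zero columns so matrices of different widths compare
trim_cols <- function(m) {
  keep <- max(which(colSums(m) > 0))
  m[, seq_len(keep), drop = FALSE]
}
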