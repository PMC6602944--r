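# Minimal NRRD reader/writer for scalar 3-D volumes.
# Supports the subset the pipeline emits: dimension-3 fields, ascii or raw
# little-endian encodings, space directions on the grid axes. NRRD stores the
# first ("fastest") axis first, which matches R's column-major arrays, so no
# axis permutation is needed.

nrrd_type_of <- function(voxels) {
  if (is.integer(voxels)) "int" else "double"
}

#' Write a volume or mask as NRRD
#'
#' Writes a detached-free single-file NRRD (header + data). `encoding =
#' "ascii"` produces a plain-text file (useful for small fixtures);
#' `"raw"` writes little-endian binary data.
#'
#' @param x A [volume_image()] or [seg_mask()].
#' @param path Output file path (conventionally `.nrrd`).
#' @param encoding `"ascii"` or `"raw"`.
#' @return `path`, invisibly.
#' @seealso [read_nrrd()], [write_volume()]
#' @export
write_nrrd <- function(x, path, encoding = c("ascii", "raw")) {
  encoding <- match.arg(encoding)
  voxels <- if (inherits(x, "seg_mask")) x$labels else x$voxels
  d <- dim(voxels)
  dirs <- sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                  x$spacing[1], x$spacing[2], x$spacing[3])
  header <- c(
    "NRRD0004",
    sprintf("type: %s", nrrd_type_of(voxels)),
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "space dimension: 3",
    sprintf("space directions: %s", dirs),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            x$origin[1], x$origin[2], x$origin[3]),
    if (!is.integer(voxels) || encoding == "raw") "endian: little",
    sprintf("encoding: %s", encoding),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(format(as.vector(voxels), digits = 17, trim = TRUE,
                      scientific = FALSE), con, sep = "\n")
  } else {
    writeBin(as.vector(voxels), con, endian = "little",
             size = if (is.integer(voxels)) 4L else 8L)
  }
  invisible(path)
}

parse_nrrd_vec <- function(s) {
  as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
}

#' Read a scalar 3-D NRRD file
#'
#' Parses the NRRD subset written by [write_nrrd()]: scalar 3-D data, ascii or
#' raw little-endian encoding, axis-aligned space directions.
#'
#' @param path NRRD file path.
#' @param as `"image"` (default) or `"mask"`; masks additionally need
#'   `roi_codes`.
#' @param roi_codes ROI dictionary when `as = "mask"`.
#' @return A [volume_image()] or [seg_mask()].
#' @export
read_nrrd <- function(path, as = c("image", "mask"), roi_codes = NULL) {
  as <- match.arg(as)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ": ", fixed = TRUE)[[1]]
    fields[[kv[1]]] <- kv[2]
  }
  if (as.integer(fields[["dimension"]]) != 3L) {
    stop("only 3-D NRRD supported", call. = FALSE)
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], " ")[[1]])
  n <- prod(sizes)
  type <- fields[["type"]]
  is_int <- type %in% c("int", "signed int", "int32", "int32_t", "short",
                        "unsigned char", "uchar", "uint8", "uint8_t")
  enc <- fields[["encoding"]]
  if (enc == "ascii" || enc == "text" || enc == "txt") {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
  } else if (enc == "raw") {
    vals <- readBin(con, what = if (is_int) integer() else double(), n = n,
                    size = if (is_int) 4L else 8L, endian = "little")
  } else {
    stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  }
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\([^)]*\\)", fields[["space directions"]]))[[1]]
    m <- vapply(dirs, parse_nrrd_vec, numeric(3))
    spacing <- sqrt(colSums(m^2))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], " ")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- parse_nrrd_vec(fields[["space origin"]])
  }
  arr <- array(vals, sizes)
  if (as == "mask") {
    if (is.null(roi_codes)) stop("roi_codes required for masks", call. = FALSE)
    seg_mask(array(as.integer(arr), sizes), roi_codes,
             spacing = spacing, origin = origin)
  } else {
    volume_image(arr, spacing = spacing, origin = origin)
  }
}
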