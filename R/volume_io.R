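#' Construct an image volume
#'
#' An `image_volume` holds a 3D grayscale grid of intensities stored as a
#' numeric array indexed `(z, y, x)`, 0-based in all user-facing coordinate
#' arguments. The y axis increases downward (raster image convention).
#' Intensities are kept as floating-point values throughout; quantisation to
#' 8 bits happens only on export, by round-half-up.
#'
#' @param voxels numeric array with `dim = c(depth, height, width)`, or a
#'   matrix (treated as a single slice), or a list of equal-sized slice
#'   matrices in ascending z order.
#' @return an object of class `image_volume` with fields `voxels`, `depth`,
#'   `height`, `width`, `intensity_range`.
#' @export
image_volume <- function(voxels) {
  if (is.list(voxels)) {
    dims <- unique(lapply(voxels, dim))
    if (length(dims) != 1L)
      stop("all slices must share the same (height, width)")
    arr <- array(0, dim = c(length(voxels), dims[[1L]][1L], dims[[1L]][2L]))
    for (z in seq_along(voxels)) arr[z, , ] <- voxels[[z]]
    voxels <- arr
  }
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(1L, dim(voxels)))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array indexed (z, y, x)")
  if (any(dim(voxels) < 1L)) stop("all dimensions must be >= 1")
  storage.mode(voxels) <- "double"
  structure(
    list(
      voxels = voxels,
      depth = dim(voxels)[1L],
      height = dim(voxels)[2L],
      width = dim(voxels)[3L],
      intensity_range = range(voxels)
    ),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf(
    "<image_volume> %d x %d x %d (z, y, x), intensities [%.4g, %.4g]\n",
    x$depth, x$height, x$width, x$intensity_range[1L], x$intensity_range[2L]
  ))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

# Extract slice z (0-based) as a height x width matrix.
#' Extract one z slice of a volume
#' @param volume an `image_volume`.
#' @param z 0-based slice index.
#' @return a `height x width` numeric matrix.
#' @export
volume_slice <- function(volume, z) {
  stopifnot(inherits(volume, "image_volume"))
  if (z < 0L || z >= volume$depth)
    stop(sprintf("slice index %d out of range [0, %d]", z, volume$depth - 1L))
  volume$voxels[z + 1L, , ]
}

quantize8 <- function(m) {
  # round-half-up quantisation to the 8-bit grid on [0, 1]
  m <- pmin(pmax(m, 0), 1)
  floor(m * 255 + 0.5) / 255
}

quantize16 <- function(m) {
  # round-half-up quantisation to the 16-bit grid on [0, 1]; the 8-bit grid
  # embeds exactly (65535 = 255 * 257), so PNG-grade data survives intact
  m <- pmin(pmax(m, 0), 1)
  floor(m * 65535 + 0.5) / 65535
}

slice_files <- function(path) {
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  if (length(files) == 0L)
    stop(sprintf("no PNG/TIFF slices found in '%s'", path))
  suffix <- sub("^.*_([0-9]+)\\.[A-Za-z]+$", "\\1", files)
  bad <- suffix == files
  if (any(bad))
    stop(sprintf(
      "slice file(s) without zero-padded numeric suffix '<stem>_<z>.<ext>': %s",
      paste(files[bad], collapse = ", ")
    ))
  files[order(as.integer(suffix))]
}

read_slice <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- switch(ext,
    png = png::readPNG(file),
    tif = ,
    tiff = tiff::readTIFF(file),
    stop(sprintf("unsupported image format: '%s'", file))
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel of RGB(A)
  img
}

#' Read a 3D grayscale volume
#'
#' Reads either a multi-page TIFF (`layout = "multipage"`) or a directory of
#' per-slice PNG/TIFF files named `<stem>_<zero-padded z>.<ext>`
#' (`layout = "slice_directory"`). Slices are ordered by ascending numeric
#' suffix and must share dimensions.
#'
#' @param path file (multipage) or directory (slice_directory).
#' @param layout `"multipage"` or `"slice_directory"`.
#' @return an [image_volume()].
#' @export
read_volume <- function(path, layout = c("multipage", "slice_directory")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop(sprintf("path does not exist: '%s'", path))
  if (layout == "multipage") {
    slices <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    slices <- lapply(slices, function(s) if (length(dim(s)) == 3L) s[, , 1L] else s)
    return(image_volume(slices))
  }
  if (!dir.exists(path)) stop(sprintf("not a directory: '%s'", path))
  files <- slice_files(path)
  slices <- vector("list", length(files))
  ref_dim <- NULL
  for (i in seq_along(files)) {
    f <- file.path(path, files[i])
    s <- tryCatch(read_slice(f), error = function(e)
      stop(sprintf("unreadable image file '%s': %s", files[i], conditionMessage(e))))
    if (is.null(ref_dim)) ref_dim <- dim(s)
    if (!identical(dim(s), ref_dim))
      stop(sprintf(
        "slice '%s' has dimensions %dx%d, expected %dx%d",
        files[i], dim(s)[1L], dim(s)[2L], ref_dim[1L], ref_dim[2L]
      ))
    slices[[i]] <- s
  }
  image_volume(slices)
}

#' Write a 3D grayscale volume
#'
#' TIFF output (multi-page or per-slice) stores 16-bit samples, so
#' `read_volume()` of the result reproduces the voxels exactly for any data
#' on the 16-bit grid — which includes everything previously read from 8- or
#' 16-bit files; other values are quantised by round-half-up. Slice
#' directories are written as `<stem>_<zero-padded z>.<ext>`; PNG slices are
#' 8-bit. Intensities must already lie in `[0, 1]`.
#'
#' @param volume an [image_volume()].
#' @param path destination file (multipage) or directory (slice_directory).
#' @param layout `"multipage"` or `"slice_directory"`.
#' @param format slice format for `slice_directory`: `"tiff"` (exact) or
#'   `"png"` (8-bit).
#' @param stem file-name stem for slice files.
#' @return `invisible(path)`.
#' @export
write_volume <- function(volume, path,
                         layout = c("multipage", "slice_directory"),
                         format = c("tiff", "png"), stem = "slice") {
  stopifnot(inherits(volume, "image_volume"))
  layout <- match.arg(layout)
  format <- match.arg(format)
  if (!nzchar(path)) stop("empty path")
  rng <- volume$intensity_range
  if (rng[1L] < 0 || rng[2L] > 1)
    stop("intensities must lie in [0, 1] before writing; see stretch_contrast()")
  slices <- lapply(seq_len(volume$depth) - 1L, function(z) volume_slice(volume, z))
  if (layout == "multipage") {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    tiff::writeTIFF(lapply(slices, quantize16), path, bits.per.sample = 16L)
    return(invisible(path))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop(sprintf("cannot create directory '%s'", path))
  nd <- max(4L, nchar(as.character(volume$depth - 1L)))
  for (z in seq_len(volume$depth) - 1L) {
    f <- file.path(path, sprintf("%s_%0*d.%s", stem, nd, z,
                                 if (format == "png") "png" else "tif"))
    if (format == "png") {
      png::writePNG(quantize8(slices[[z + 1L]]), f)
    } else {
      tiff::writeTIFF(quantize16(slices[[z + 1L]]), f, bits.per.sample = 16L)
    }
  }
  invisible(path)
}

#' Percentile contrast stretch
#'
#' Linearly rescales intensities so that the `low` / `high` input percentiles
#' map to 0 and 1; values beyond them are clipped. A constant volume maps to
#' all zeros (the output range minimum).
#'
#' @param volume an [image_volume()].
#' @param low,high percentile fractions, `0 <= low < high <= 1`.
#' @return a contrast-stretched [image_volume()] with intensities in `[0, 1]`.
#' @export
stretch_contrast <- function(volume, low = 0, high = 1) {
  stopifnot(inherits(volume, "image_volume"))
  if (!(low >= 0 && high <= 1 && low < high))
    stop("require 0 <= low < high <= 1")
  q <- stats::quantile(volume$voxels, probs = c(low, high), names = FALSE)
  if (q[2L] <= q[1L]) {
    out <- array(0, dim = dim(volume$voxels))
  } else {
    out <- (volume$voxels - q[1L]) / (q[2L] - q[1L])
    out <- pmin(pmax(out, 0), 1)
  }
  image_volume(out)
}

#' Block-mean binning
#'
#' Each output voxel is the mean of the corresponding `factor`-sized block;
#' trailing partial blocks are averaged over their actual size, so output
#' dimensions are `ceiling(dim / factor)` and the field of view is preserved.
#'
#' @param volume an [image_volume()].
#' @param factor integer binning factor per axis, length 1 (isotropic) or 3
#'   in `(z, y, x)` order.
#' @return the binned [image_volume()].
#' @export
bin_volume <- function(volume, factor) {
  stopifnot(inherits(volume, "image_volume"))
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  factor <- as.integer(factor)
  if (length(factor) != 3L || any(factor < 1L) || any(is.na(factor)))
    stop("factor must be positive integers, length 1 or 3 (z, y, x)")
  d <- dim(volume$voxels)
  gd <- as.integer(ceiling(d / factor))
  gz <- (seq_len(d[1L]) - 1L) %/% factor[1L]
  gy <- (seq_len(d[2L]) - 1L) %/% factor[2L]
  gx <- (seq_len(d[3L]) - 1L) %/% factor[3L]
  # linear group id per voxel, then group means
  gid <- as.vector(
    outer(outer(gz, gy * gd[1L], "+"), gx * (gd[1L] * gd[2L]), "+")
  ) + 1L
  sums <- rowsum(as.vector(volume$voxels), gid)
  counts <- rowsum(rep(1, length(gid)), gid)
  image_volume(array(sums / counts, dim = gd))
}
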