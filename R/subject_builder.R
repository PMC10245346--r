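#' Plan an overlapping tiling of an image plane
#'
#' Produces the geometric schema mapping padded-frame tiles back to the
#' original frame. With the default overlap fraction of 0.5, adjacent tiles
#' overlap by 50% of the tile width, the frame is padded on every side by the
#' overlap width, and every original pixel falls in at least two tiles so
#' that a feature on the edge or corner of one tile sits centrally in a
#' neighbour. The stride between tile origins is
#' `tile * (1 - overlap_fraction)` and must be a whole number of pixels.
#' The final origin per axis is clamped so the last tile flushes the padded
#' edge (duplicating coverage rather than truncating it).
#'
#' @param original_width,original_height original frame size in pixels.
#' @param tile_width,tile_height tile size in pixels (`>= 2`).
#' @param overlap_fraction fraction of the tile size shared by adjacent
#'   tiles, in `[0, 1)`; default 0.5.
#' @return a `tiling_schema`: list with `original_width`, `original_height`,
#'   `tile_width`, `tile_height`, `pad_x`, `pad_y`, `stride_x`, `stride_y`,
#'   `padded_width`, `padded_height` and `tiles`, a data frame of
#'   `tile_id`, `x0`, `y0` (0-based origins in the padded frame).
#' @export
plan_tiles <- function(original_width, original_height,
                       tile_width, tile_height = tile_width,
                       overlap_fraction = 0.5) {
  if (tile_width < 2L || tile_height < 2L) stop("tile dimensions must be >= 2")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  axis_plan <- function(orig, tile) {
    stride <- tile * (1 - overlap_fraction)
    if (abs(stride - round(stride)) > 1e-9)
      stop(sprintf("non-integral stride: tile %d with overlap %g", tile,
                   overlap_fraction))
    stride <- as.integer(round(stride))
    pad <- tile - stride                      # the overlap width
    padded <- orig + 2L * pad
    last <- padded - tile                     # final origin flushes the edge
    origins <- seq(0L, max(0L, last), by = stride)
    if (origins[length(origins)] != last) origins <- c(origins, last)
    list(stride = stride, pad = pad, padded = padded, origins = origins)
  }
  px <- axis_plan(original_width, tile_width)
  py <- axis_plan(original_height, tile_height)
  grid <- expand.grid(x0 = px$origins, y0 = py$origins,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$y0, grid$x0), , drop = FALSE]
  tiles <- data.frame(
    tile_id = sprintf("tile_x%03d_y%03d",
                      match(grid$x0, px$origins) - 1L,
                      match(grid$y0, py$origins) - 1L),
    x0 = grid$x0, y0 = grid$y0,
    stringsAsFactors = FALSE
  )
  rownames(tiles) <- NULL
  structure(
    list(
      original_width = original_width, original_height = original_height,
      tile_width = tile_width, tile_height = tile_height,
      overlap_fraction = overlap_fraction,
      pad_x = px$pad, pad_y = py$pad,
      stride_x = px$stride, stride_y = py$stride,
      padded_width = px$padded, padded_height = py$padded,
      tiles = tiles
    ),
    class = "tiling_schema"
  )
}

#' @export
print.tiling_schema <- function(x, ...) {
  cov <- tile_coverage(x)
  cat(sprintf(
    paste0("<tiling_schema> %dx%d original, %dx%d tiles, overlap %.0f%%\n",
           "  padded %dx%d (pad %d,%d), stride (%d,%d), %d tiles\n",
           "  per-pixel tile multiplicity: min %d, max %d\n"),
    x$original_width, x$original_height, x$tile_width, x$tile_height,
    100 * x$overlap_fraction, x$padded_width, x$padded_height,
    x$pad_x, x$pad_y, x$stride_x, x$stride_y, nrow(x$tiles),
    min(cov), max(cov)
  ))
  invisible(x)
}

#' Per-pixel tile multiplicity of a schema
#'
#' Counts, for every pixel of the original frame, how many tiles contain it.
#' Useful for adjusting the retirement limit when overlap multiplies
#' coverage (the operator decides; this only reports).
#'
#' @param schema a [plan_tiles()] schema.
#' @return integer matrix `original_height x original_width`.
#' @export
tile_coverage <- function(schema) {
  stopifnot(inherits(schema, "tiling_schema"))
  count_axis <- function(orig, pad, origins, tile) {
    cnt <- integer(orig)
    for (o in origins) {
      lo <- max(0L, o - pad)                  # original-frame coords
      hi <- min(orig - 1L, o + tile - 1L - pad)
      if (hi >= lo) cnt[(lo:hi) + 1L] <- cnt[(lo:hi) + 1L] + 1L
    }
    cnt
  }
  cx <- count_axis(schema$original_width, schema$pad_x,
                   unique(schema$tiles$x0), schema$tile_width)
  cy <- count_axis(schema$original_height, schema$pad_y,
                   unique(schema$tiles$y0), schema$tile_height)
  outer(cy, cx)
}

#' Tile-local to original-frame coordinates (and back)
#'
#' `(u, v)` are 0-based pixel coordinates inside the tile; the original-frame
#' coordinates are `(x0 + u - pad_x, y0 + v - pad_y)`, which may be negative
#' or beyond the frame for padding pixels.
#'
#' @param spec one row of `schema$tiles` (or a list with `x0`, `y0`).
#' @param schema the owning [plan_tiles()] schema.
#' @param u,v tile-local coordinates.
#' @param x,y original-frame coordinates.
#' @return a list with `x`, `y` (or `u`, `v`).
#' @export
tile_to_global <- function(spec, schema, u, v) {
  list(x = spec$x0 + u - schema$pad_x, y = spec$y0 + v - schema$pad_y)
}

#' @rdname tile_to_global
#' @export
global_to_tile <- function(spec, schema, x, y) {
  list(u = x + schema$pad_x - spec$x0, v = y + schema$pad_y - spec$y0)
}

#' Crop one tile from a volume slice
#'
#' Pixels of the padded frame that fall outside the original image are filled
#' with `pad_value`.
#'
#' @param volume an [image_volume()].
#' @param z 0-based slice index.
#' @param spec one row of `schema$tiles`.
#' @param schema the owning schema.
#' @param pad_value fill value for padding pixels (default 0, black).
#' @return a `tile_height x tile_width` matrix.
#' @export
crop_tile <- function(volume, z, spec, schema, pad_value = 0) {
  stopifnot(inherits(volume, "image_volume"), inherits(schema, "tiling_schema"))
  if (z < 0L || z >= volume$depth)
    stop(sprintf("slice index %d out of range [0, %d]", z, volume$depth - 1L))
  slice <- volume_slice(volume, z)
  out <- matrix(pad_value, nrow = schema$tile_height, ncol = schema$tile_width)
  # original-frame coordinates covered by this tile
  gx <- spec$x0 + seq_len(schema$tile_width) - 1L - schema$pad_x
  gy <- spec$y0 + seq_len(schema$tile_height) - 1L - schema$pad_y
  inx <- gx >= 0L & gx < schema$original_width
  iny <- gy >= 0L & gy < schema$original_height
  if (any(inx) && any(iny))
    out[iny, inx] <- slice[gy[iny] + 1L, gx[inx] + 1L]
  out
}

#' Build a flipbook subject
#'
#' A flipbook is a stack of `2 * context_half_width + 1` consecutive z
#' slices presented as one subject; volunteers annotate the central plane and
#' the outer slices provide 3D context. Centres too close to the stack ends
#' are refused (no clamping), because annotation quality degrades there.
#' The crop window is given in original-frame coordinates and may extend
#' into padding; out-of-frame pixels are filled with `pad_value`.
#'
#' @param volume an [image_volume()].
#' @param x0,y0 0-based original-frame coordinates of the window origin
#'   (may be negative for padded windows).
#' @param tile_width,tile_height window size in pixels.
#' @param z_center 0-based central slice.
#' @param context_half_width slices of context either side (default 2,
#'   giving 5-frame subjects).
#' @param pad_value fill for out-of-frame pixels.
#' @param subject_id optional id; autogenerated from the anchor if missing.
#' @param tile_id,z_stride provenance metadata carried into the manifest.
#' @return a `subject`: list with `subject_id`, `frames` (list of matrices)
#'   and `metadata` (always containing `x`, `y`, `z`).
#' @export
build_flipbook <- function(volume, x0, y0, tile_width, tile_height,
                           z_center, context_half_width = 2L,
                           pad_value = 0, subject_id = NULL,
                           tile_id = NA_character_, z_stride = 1L) {
  stopifnot(inherits(volume, "image_volume"))
  h <- as.integer(context_half_width)
  if (h < 0L) stop("context_half_width must be >= 0")
  if (z_center < h || z_center > volume$depth - 1L - h)
    stop(sprintf(
      "z_center %d too near the stack boundary for context_half_width %d (valid [%d, %d])",
      z_center, h, h, volume$depth - 1L - h
    ))
  if (is.null(subject_id))
    subject_id <- sprintf("s_x%d_y%d_z%d", x0, y0, z_center)
  frames <- lapply((z_center - h):(z_center + h), function(z) {
    slice <- volume_slice(volume, z)
    out <- matrix(pad_value, nrow = tile_height, ncol = tile_width)
    gx <- x0 + seq_len(tile_width) - 1L
    gy <- y0 + seq_len(tile_height) - 1L
    inx <- gx >= 0L & gx < volume$width
    iny <- gy >= 0L & gy < volume$height
    if (any(inx) && any(iny))
      out[iny, inx] <- slice[gy[iny] + 1L, gx[inx] + 1L]
    out
  })
  structure(
    list(
      subject_id = subject_id,
      frames = frames,
      metadata = list(
        x = as.integer(x0), y = as.integer(y0), z = as.integer(z_center),
        tile_id = tile_id,
        annotation_frame_index = h,
        z_stride = as.integer(z_stride)
      )
    ),
    class = "subject"
  )
}

#' @export
print.subject <- function(x, ...) {
  cat(sprintf(
    "<subject> %s: %d frame(s) %dx%d, anchor (x=%d, y=%d, z=%d), annotation frame %d\n",
    x$subject_id, length(x$frames), nrow(x$frames[[1L]]), ncol(x$frames[[1L]]),
    x$metadata$x, x$metadata$y, x$metadata$z, x$metadata$annotation_frame_index
  ))
  invisible(x)
}

#' Sample flipbook centres along z
#'
#' Returns the ordered central slices `h, h + z_stride, ...` that admit a
#' full flipbook. A stride above 1 skips slices; the stride is recorded in
#' the manifest so downstream analysis can undo the resulting z-scale
#' distortion.
#'
#' @param depth volume depth.
#' @param z_stride sampling stride (`>= 1`).
#' @param context_half_width flipbook context half-width.
#' @return integer vector of 0-based z centres (empty, with a warning, when
#'   the volume is too shallow for any flipbook).
#' @export
sample_z <- function(depth, z_stride = 1L, context_half_width = 2L) {
  if (z_stride < 1L) stop("z_stride must be >= 1")
  h <- as.integer(context_half_width)
  if (depth < 2L * h + 1L) {
    warning(sprintf("depth %d admits no flipbook of context half-width %d",
                    depth, h))
    return(integer(0))
  }
  seq(h, depth - 1L - h, by = z_stride)
}

#' Validate the encoded size of a subject
#'
#' Subject media should stay small to spare contributor bandwidth: sizes are
#' recommended below 600 KB and restricted to a hard maximum of 1 MB.
#'
#' @param encoded_size_bytes total encoded bytes of the subject's frames.
#' @param subject_id optional id carried into the report.
#' @param warn_limit_bytes recommended maximum (default `600 * 1024`).
#' @param max_limit_bytes hard maximum (default `1024 * 1024`).
#' @return a one-row data frame `subject_id`, `encoded_size_bytes`, `status`
#'   (`"ok"`, `"warn"` or `"error"`), `message`.
#' @export
validate_subject <- function(encoded_size_bytes, subject_id = NA_character_,
                             warn_limit_bytes = 600L * 1024L,
                             max_limit_bytes = 1024L * 1024L) {
  if (encoded_size_bytes < 0) stop("encoded_size_bytes must be >= 0")
  status <- if (encoded_size_bytes >= max_limit_bytes) "error"
            else if (encoded_size_bytes >= warn_limit_bytes) "warn"
            else "ok"
  msg <- switch(status,
    ok = "within limits",
    warn = sprintf("above recommended %d bytes", warn_limit_bytes),
    error = sprintf("exceeds hard maximum %d bytes", max_limit_bytes)
  )
  data.frame(subject_id = subject_id,
             encoded_size_bytes = as.numeric(encoded_size_bytes),
             status = status, message = msg, stringsAsFactors = FALSE)
}

#' Encode subject frames as PNG files
#'
#' Writes each frame as an 8-bit PNG named
#' `<subject_id>_f<frame index>.png` and returns the subject with
#' `frame_files` and per-frame byte sizes attached.
#'
#' @param subject a [build_flipbook()] subject.
#' @param dir output directory.
#' @return the subject, with `frame_files` (relative names) and
#'   `frame_bytes` added.
#' @export
encode_subject <- function(subject, dir) {
  stopifnot(inherits(subject, "subject"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_f%d.png", subject$subject_id,
                   seq_along(subject$frames) - 1L)
  for (i in seq_along(subject$frames))
    png::writePNG(quantize8(subject$frames[[i]]), file.path(dir, files[i]))
  subject$frame_files <- files
  subject$frame_bytes <- as.numeric(file.size(file.path(dir, files)))
  subject
}

manifest_cols_fixed <- c("subject_id", "x", "y", "z", "tile_id",
                         "annotation_frame_index", "z_stride")

#' Write / read a subject manifest
#'
#' The manifest is the CSV linking every subject to its `(x, y, z)` anchor in
#' the original volume, plus tile and flipbook provenance. Columns are
#' `subject_id`, `frame_0 ... frame_{n-1}`, `x`, `y`, `z`, `tile_id`,
#' `annotation_frame_index`, `z_stride`.
#'
#' @param subjects list of subjects (after [encode_subject()] if frame files
#'   should be referenced and checked).
#' @param path CSV destination.
#' @param frame_dir directory against which referenced frame files are
#'   checked at write time; `NULL` skips the check.
#' @return `invisible(path)`; `read_manifest()` returns the manifest data
#'   frame and errors on duplicate ids or missing/non-integral x, y, z.
#' @export
write_manifest <- function(subjects, path, frame_dir = NULL) {
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate subject_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  n_frames <- vapply(subjects, function(s) length(s$frames), integer(1))
  if (length(unique(n_frames)) > 1L)
    stop("all subjects in one manifest must have the same frame count")
  nf <- n_frames[1L]
  rows <- lapply(subjects, function(s) {
    files <- if (!is.null(s$frame_files)) s$frame_files
             else sprintf("%s_f%d.png", s$subject_id, seq_len(nf) - 1L)
    if (!is.null(frame_dir)) {
      missing <- files[!file.exists(file.path(frame_dir, files))]
      if (length(missing))
        stop(sprintf("frame file(s) missing for subject '%s': %s",
                     s$subject_id, paste(missing, collapse = ", ")))
    }
    row <- c(list(subject_id = s$subject_id),
             stats::setNames(as.list(files), sprintf("frame_%d", seq_len(nf) - 1L)),
             s$metadata[c("x", "y", "z", "tile_id",
                          "annotation_frame_index", "z_stride")])
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("subject_id", "x", "y", "z"))
    if (!col %in% names(df))
      stop(sprintf("manifest lacks required column '%s'", col))
  if (anyDuplicated(df$subject_id))
    stop(sprintf("duplicate subject_id in manifest: %s",
                 paste(unique(df$subject_id[duplicated(df$subject_id)]),
                       collapse = ", ")))
  for (col in c("x", "y", "z")) {
    v <- df[[col]]
    if (!is.numeric(v))
      stop(sprintf("manifest column '%s' is not numeric", col))
    bad <- which(is.na(v) | v != round(v))
    if (length(bad))
      stop(sprintf("manifest row %d ('%s'): column '%s' missing or non-integral",
                   bad[1L], df$subject_id[bad[1L]], col))
    df[[col]] <- as.integer(v)
  }
  df
}
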