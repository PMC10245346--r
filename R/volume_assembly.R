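#' Map subject-frame marks to original-volume coordinates
#'
#' The manifest anchor `(x, y, z)` gives the original-frame origin of the
#' subject window (possibly negative, inside padding) and its annotated
#' central slice; a mark at subject-frame `(u, v)` on flipbook frame `f`
#' maps to `(x + u, y + v, z + (f - annotation_frame_index) * z_stride)`.
#' Marks landing in padding (outside the original volume) are flagged so
#' assembly can exclude them.
#'
#' @param marks data frame with columns `x`, `y` and optionally
#'   `frame_index` (subject-frame pixel coordinates).
#' @param subject_row one manifest row ([read_manifest()]).
#' @param volume_dim `(depth, height, width)` of the original volume, used
#'   to flag out-of-volume marks (`NULL` skips the flag).
#' @return data frame `x`, `y`, `z` (global, numeric) plus `in_volume`.
#' @export
mark_to_global <- function(marks, subject_row, volume_dim = NULL) {
  if (is.null(subject_row) || nrow(subject_row) != 1L)
    stop("subject unlinked: exactly one manifest row required")
  fi <- if ("frame_index" %in% names(marks)) marks$frame_index else 0L
  afi <- subject_row$annotation_frame_index %||% 0L
  zs <- subject_row$z_stride %||% 1L
  gx <- subject_row$x + marks$x
  gy <- subject_row$y + marks$y
  gz <- subject_row$z + (fi - afi) * zs
  out <- data.frame(x = gx, y = gy, z = gz)
  if (!is.null(volume_dim)) {
    out$in_volume <- gx >= 0 & gx < volume_dim[3L] &
      gy >= 0 & gy < volume_dim[2L] &
      gz >= 0 & gz < volume_dim[1L]
  } else {
    out$in_volume <- NA
  }
  out
}

#' Merge duplicate detections from overlapping tiles
#'
#' Tiling with overlap finds the same physical object in several tiles.
#' Detections (already in global coordinates) are clustered with
#' `eps = merge_radius` and `min_samples = 1` (so nothing is noise); each
#' cluster collapses to one detection with a support-weighted mean centroid,
#' summed support, and the label chosen by support-weighted majority
#' (lexicographic tie-break).
#'
#' @param detections data frame `object_id`, `x`, `y`, `z`, `support` and
#'   optionally `label`.
#' @param merge_radius clustering radius in pixels (typically the `eps`
#'   used in point aggregation).
#' @param anisotropy z-distance scale factor, as in [aggregate_points()].
#' @return merged detections data frame.
#' @export
dedupe_detections <- function(detections, merge_radius, anisotropy = 1) {
  if (is.null(detections) || nrow(detections) == 0L) {
    out <- data.frame(object_id = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), support = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  pts <- cbind(detections$x, detections$y, anisotropy * detections$z)
  labels <- dbscan_cluster(pts, eps = merge_radius, min_samples = 1L)
  rows <- lapply(sort(unique(labels)), function(k) {
    m <- which(labels == k)
    w <- detections$support[m]
    lab <- NA_character_
    if ("label" %in% names(detections)) {
      votes <- detections$label[m]
      ok <- !is.na(votes)
      if (any(ok)) {
        tallies <- tapply(w[ok], votes[ok], sum)
        tallies <- tallies[order(names(tallies))]
        lab <- names(tallies)[which.max(tallies)]
      }
    }
    data.frame(
      object_id = NA_character_,
      x = sum(w * detections$x[m]) / sum(w),
      y = sum(w * detections$y[m]) / sum(w),
      z = sum(w * detections$z[m]) / sum(w),
      support = sum(w), label = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # deterministic ids by spatial order, independent of tile processing order
  ord <- order(out$z, out$y, out$x)
  out <- out[ord, , drop = FALSE]
  out$object_id <- sprintf("obj_%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Fuse per-subject consensus segmentations into the volume
#'
#' Each subject contributes its agreement raster on its annotated slice at
#' its manifest offset; overlapping tiles are fused per voxel by the mean of
#' the covering agreement fractions, thresholded at 0.5 — preserving the
#' "half or more" semantics across tiles. Pixels outside the original frame
#' (padding) are ignored; voxels covered by no tile stay unset.
#'
#' @param segmentations list of elements `list(consensus =
#'   consensus_segmentation, x = , y = , z = )` with `(x, y)` the
#'   original-frame origin of the subject window and `z` its annotated
#'   slice (manifest anchor).
#' @param volume_dim `(depth, height, width)` of the target volume.
#' @return a `volume_consensus`: list with `mask` (logical `(z, y, x)`
#'   array), `agreement` (mean agreement), `coverage` (tile count per
#'   voxel).
#' @export
fuse_masks <- function(segmentations, volume_dim) {
  d <- as.integer(volume_dim)
  stopifnot(length(d) == 3L)
  agree_sum <- array(0, dim = d)
  coverage <- array(0L, dim = d)
  for (s in segmentations) {
    cs <- s$consensus
    stopifnot(inherits(cs, "consensus_segmentation"))
    th <- nrow(cs$agreement); tw <- ncol(cs$agreement)
    if (s$z < 0L || s$z >= d[1L])
      stop(sprintf("subject slice z=%d outside the volume", s$z))
    if (s$x + tw <= 0L || s$x >= d[3L] || s$y + th <= 0L || s$y >= d[2L])
      stop("subject window entirely outside the volume")
    # clip the window to the original frame
    u <- seq_len(tw) - 1L; v <- seq_len(th) - 1L
    gx <- s$x + u; gy <- s$y + v
    inx <- gx >= 0L & gx < d[3L]
    iny <- gy >= 0L & gy < d[2L]
    zi <- s$z + 1L
    agree_sum[zi, gy[iny] + 1L, gx[inx] + 1L] <-
      agree_sum[zi, gy[iny] + 1L, gx[inx] + 1L] + cs$agreement[iny, inx]
    coverage[zi, gy[iny] + 1L, gx[inx] + 1L] <-
      coverage[zi, gy[iny] + 1L, gx[inx] + 1L] + 1L
  }
  agreement <- array(0, dim = d)
  covered <- coverage > 0L
  agreement[covered] <- agree_sum[covered] / coverage[covered]
  structure(
    list(mask = covered & agreement >= 0.5, agreement = agreement,
         coverage = coverage),
    class = "volume_consensus"
  )
}

#' @export
print.volume_consensus <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<volume_consensus> %d x %d x %d (z, y, x), %d voxels set, coverage up to %d\n",
    d[1L], d[2L], d[3L], sum(x$mask), max(x$coverage)))
  invisible(x)
}

#' Export a consensus mask volume
#'
#' Writes the binary mask as a multi-page TIFF aligned to the source volume.
#'
#' @param vc a [fuse_masks()] result.
#' @param path destination TIFF.
#' @return `invisible(path)`.
#' @export
export_mask_volume <- function(vc, path) {
  stopifnot(inherits(vc, "volume_consensus"))
  vol <- image_volume(array(as.numeric(vc$mask), dim = dim(vc$mask)))
  write_volume(vol, path, layout = "multipage")
}

#' Export paired image/mask training slices
#'
#' Writes one grayscale image PNG and one binary mask PNG per slice, plus a
#' CSV index (`z`, `image`, `mask`) — directly consumable as
#' segmentation-model training data.
#'
#' @param volume the source [image_volume()].
#' @param vc the matching [fuse_masks()] result.
#' @param dir output directory.
#' @return `invisible(dir)`.
#' @export
export_training_pairs <- function(volume, vc, dir) {
  stopifnot(inherits(volume, "image_volume"), inherits(vc, "volume_consensus"))
  if (!identical(dim(volume$voxels), dim(vc$mask)))
    stop("volume and consensus dimensions differ")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nd <- max(4L, nchar(as.character(volume$depth - 1L)))
  rows <- lapply(seq_len(volume$depth) - 1L, function(z) {
    img <- sprintf("image_%0*d.png", nd, z)
    msk <- sprintf("mask_%0*d.png", nd, z)
    png::writePNG(quantize8(volume_slice(volume, z)), file.path(dir, img))
    png::writePNG(matrix(as.numeric(vc$mask[z + 1L, , ]),
                         nrow = volume$height), file.path(dir, msk))
    data.frame(z = z, image = img, mask = msk, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "index.csv"),
                   row.names = FALSE)
  invisible(dir)
}
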