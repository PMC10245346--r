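# End-to-end orchestration: per-subject CRIA aggregation of a contour study
# and reassembly into the source volume. Used by the CLI presets and by the
# recovery checks.

#' Aggregate a contour study subject-by-subject
#'
#' For each subject: take the freehand strokes drawn on the annotation
#' frame, close them ([close_polyline()]; default tolerance 5% of the frame
#' diagonal), rasterize per-contributor interiors, optionally remove
#' outlier annotations by IoU against the provisional consensus, and form
#' the CRIA consensus.
#'
#' @param classifications list of classification records (parsed or
#'   simulated) whose annotations include [freehand_line()]s.
#' @param manifest data frame with columns `subject_id`, `x`, `y`, `z`,
#'   `annotation_frame_index`, `frame_width`, `frame_height`.
#' @param gap_tolerance endpoint-closure tolerance in pixels, or `NULL` for
#'   5% of the frame diagonal.
#' @param outlier_removal apply [remove_outlier_annotations()].
#' @param iou_cutoff outlier IoU cutoff.
#' @return list of `list(subject_id, consensus, x, y, z, n_rejected)`,
#'   ready for [fuse_masks()].
#' @export
aggregate_contour_study <- function(classifications, manifest,
                                    gap_tolerance = NULL,
                                    outlier_removal = FALSE,
                                    iou_cutoff = 0.3) {
  subj_ids <- vapply(classifications, function(cl) cl$subject_id, character(1))
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, , drop = FALSE]
    w <- row$frame_width; h <- row$frame_height
    tol <- if (is.null(gap_tolerance)) 0.05 * sqrt(w^2 + h^2) else gap_tolerance
    cls <- classifications[subj_ids == row$subject_id]
    loops <- list(); who <- character(0); n_rejected <- 0L
    for (cl in cls) {
      for (a in cl$annotations) {
        if (!inherits(a, "freehand_line")) next
        afi <- row$annotation_frame_index %||% 0L
        # only the annotation plane is aggregated; other frames are context
        if (!is.na(afi) && a$frame_index != afi) next
        lp <- close_polyline(a, tol)
        if (inherits(lp, "loop_reject")) { n_rejected <- n_rejected + 1L; next }
        loops[[length(loops) + 1L]] <- lp
        who <- c(who, cl$contributor_id)
      }
    }
    if (length(loops) == 0L) next
    masks <- contributor_masks(loops, who, w, h)
    cons <- if (outlier_removal && length(masks) >= 2L)
      remove_outlier_annotations(masks, iou_cutoff = iou_cutoff)
    else cria_consensus(masks)
    out[[length(out) + 1L]] <- list(
      subject_id = row$subject_id, consensus = cons,
      x = row$x, y = row$y, z = row$z, n_rejected = n_rejected)
  }
  out
}

#' Run a contour study end-to-end on a phantom
#'
#' Phantom -> flipbook subjects -> simulated volunteers -> per-subject CRIA
#' -> volume reassembly, returning the recovered volume consensus and its
#' IoU against the phantom's ground-truth mask.
#'
#' @param phantom a [make_phantom()] result.
#' @param model a [volunteer_model()].
#' @param outlier_removal forwarded to [aggregate_contour_study()].
#' @param seed base seed for the simulated crowd.
#' @return list with `volume_consensus`, `iou`, `study`, `segmentations`.
#' @export
run_contour_recovery <- function(phantom, model, outlier_removal = FALSE,
                                 seed = 1L) {
  study <- simulate_contour_study(phantom, model, seed = seed)
  segs <- aggregate_contour_study(study$classifications, study$manifest,
                                  outlier_removal = outlier_removal)
  vc <- fuse_masks(segs, dim(phantom$volume$voxels))
  truth <- phantom_truth_mask(phantom)
  list(volume_consensus = vc, iou = mask_iou(vc$mask, truth),
       study = study, segmentations = segs)
}

#' Run a point-marking study on a phantom
#'
#' Simulates every volunteer's marks ([simulate_marks()]), aggregates them
#' with [aggregate_points()], and matches detections to the phantom truth.
#'
#' @param phantom a [make_phantom()] result.
#' @param model a [volunteer_model()].
#' @param eps clustering radius; default half the minimum truth radius + 2.
#' @param min_samples cluster support threshold; default
#'   `ceiling(n_volunteers / 2)`.
#' @param anisotropy z-distance scale.
#' @param match_radius a detection within this distance of a truth centroid
#'   counts as recovering it (default 1.5 px).
#' @param seed base seed.
#' @return list with `detections`, `marks`, `recovered` (logical per truth
#'   object), `centroid_errors`, `n_spurious`.
#' @export
run_point_recovery <- function(phantom, model, eps = NULL, min_samples = NULL,
                               anisotropy = 1, match_radius = 1.5, seed = 1L) {
  marks <- do.call(rbind, lapply(seq_len(model$n_volunteers), function(v)
    simulate_marks(phantom, model, v, seed = seed)))
  if (is.null(eps))
    eps <- min(vapply(phantom$objects, `[[`, numeric(1), "radius")) / 2 + 2
  if (is.null(min_samples)) min_samples <- ceiling(model$n_volunteers / 2)
  det <- aggregate_points(marks, eps = eps, min_samples = min_samples,
                          anisotropy = anisotropy)
  truth <- do.call(rbind, lapply(phantom$objects, function(o)
    matrix(o$centroid, nrow = 1L)))
  recovered <- logical(length(phantom$objects))
  errors <- rep(NA_real_, length(phantom$objects))
  matched_det <- integer(0)
  for (k in seq_along(phantom$objects)) {
    if (nrow(det) == 0L) break
    dd <- sqrt((det$x - truth[k, 1L])^2 + (det$y - truth[k, 2L])^2 +
                 (det$z - truth[k, 3L])^2)
    j <- which.min(dd)
    if (dd[j] <= match_radius) {
      recovered[k] <- TRUE
      errors[k] <- dd[j]
      matched_det <- c(matched_det, j)
    }
  }
  list(detections = det, marks = marks, recovered = recovered,
       centroid_errors = errors,
       n_spurious = nrow(det) - length(unique(matched_det)))
}

#' Single-slice contour recovery experiment
#'
#' Generates a one-object cell-scale phantom, takes the slice through the
#' object centre, simulates the crowd's outlines of it, forms the CRIA
#' consensus (optionally with outlier removal) and returns the IoU against
#' the rasterized truth boundary. This is the unit experiment behind the
#' contour-recovery checks.
#'
#' @param seed phantom and crowd seed.
#' @param model a [volunteer_model()].
#' @param outlier_removal apply [remove_outlier_annotations()].
#' @param radius_range truth-structure radius range, pixels.
#' @param fov_margin window margin around the radius, pixels.
#' @return list with `iou`, `consensus`, `truth_mask`, `n_rejected`.
#' @export
contour_slice_recovery <- function(seed, model, outlier_removal = FALSE,
                                   radius_range = c(10, 14),
                                   fov_margin = 6) {
  ph <- make_phantom(depth = 36L, height = 96L, width = 96L, n_objects = 1L,
                     radius_range = radius_range, seed = seed)
  ob <- ph$objects[[1L]]
  zs <- as.integer(names(ob$slices))
  z <- zs[which.min(abs(zs + 0.5 - ob$centroid[["z"]]))]
  poly <- ob$slices[[as.character(z)]]
  half <- ceiling(ob$radius + fov_margin)
  w <- 2L * half
  x0 <- round(ob$centroid[["x"]]) - half
  y0 <- round(ob$centroid[["y"]]) - half
  tl <- cbind(x = poly[, 1L] - x0, y = poly[, 2L] - y0)
  truth <- rasterize_interior(close_polyline(rbind(tl, tl[1L, ]), 1e-6), w, w)
  tol <- 0.05 * sqrt(2) * w
  masks <- list(); n_rejected <- 0L
  for (v in seq_len(model$n_volunteers)) {
    fl <- simulate_contour(tl, model, v, w, w, seed = seed, tag = "slice")
    lp <- close_polyline(fl, tol)
    if (inherits(lp, "loop_reject")) { n_rejected <- n_rejected + 1L; next }
    masks[[sprintf("vol_%02d", v)]] <- rasterize_interior(lp, w, w)
  }
  cons <- if (outlier_removal && length(masks) >= 2L)
    remove_outlier_annotations(masks)
  else cria_consensus(masks)
  list(iou = mask_iou(cons$mask, truth), consensus = cons,
       truth_mask = truth, n_rejected = n_rejected)
}
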