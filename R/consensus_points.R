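#' Density-based spatial clustering (DBSCAN)
#'
#' Implemented directly from the density-reachability definition so it can
#' be audited against a brute-force oracle. A core point has at least
#' `min_samples` neighbours within `eps` (inclusive, counting itself);
#' clusters are the connected components of core points under eps-adjacency,
#' with border points attached to any core neighbour; everything else is
#' noise.
#'
#' @param points numeric matrix, one row per point, any dimension.
#' @param eps neighbourhood radius (`> 0`), Euclidean.
#' @param min_samples core-point threshold (`>= 1`).
#' @return integer vector of cluster labels (`1..k`; noise is `0`).
#' @export
dbscan_cluster <- function(points, eps, min_samples) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(n) || n == 0L) return(integer(0))
  if (eps <= 0) stop("eps must be > 0")
  if (min_samples < 1L) stop("min_samples must be >= 1")
  d <- as.matrix(stats::dist(points))
  nbr <- d <= eps                    # includes self (diagonal is 0)
  core <- rowSums(nbr) >= min_samples
  labels <- integer(n)
  next_label <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    next_label <- next_label + 1L
    # BFS over core points through eps-adjacency
    queue <- i
    labels[i] <- next_label
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      reach <- which(nbr[p, ] & labels == 0L)
      if (length(reach)) {
        labels[reach] <- next_label
        queue <- c(queue, reach[core[reach]])
      }
    }
  }
  # border points are grabbed by the first cluster whose core reaches them
  labels
}

#' Aggregate point/ellipse marks into object detections
#'
#' Marks from many volunteers are clustered in 3D (distance
#' `sqrt(dx^2 + dy^2 + (anisotropy * dz)^2)`, the anisotropy factor
#' correcting z-scale distortion from slice subsampling); noise points are
#' discarded as outliers — they typically reflect unique errors by single
#' contributors — and each surviving cluster becomes one detection whose
#' centroid is the arithmetic mean of its member positions. Support counts
#' distinct contributors, so one volunteer double-marking an object cannot
#' inflate it.
#'
#' @param marks data frame with columns `contributor_id`, `x`, `y`, `z`
#'   (original-volume coordinates) and optionally `source`, `rx`, `ry`.
#' @param eps clustering radius in pixels (operator-supplied; typically the
#'   expected object radius).
#' @param min_samples minimum cluster size; defaults to
#'   `ceiling(retirement_limit / 2)` in pipeline code, mirroring majority
#'   logic.
#' @param anisotropy scale factor applied to z distances (default 1;
#'   typically the manifest `z_stride`).
#' @return an `object_detections` data frame: `object_id`, `x`, `y`, `z`,
#'   `support`, `n_marks`, plus a list column `members` of member-mark row
#'   indices into `marks`.
#' @export
aggregate_points <- function(marks, eps, min_samples = 2L, anisotropy = 1) {
  empty <- data.frame(object_id = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), support = integer(0),
                      n_marks = integer(0), stringsAsFactors = FALSE)
  empty$members <- list()
  class(empty) <- c("object_detections", "data.frame")
  if (is.null(marks) || nrow(marks) == 0L) return(empty)
  stopifnot(all(c("contributor_id", "x", "y", "z") %in% names(marks)))
  pts <- cbind(marks$x, marks$y, anisotropy * marks$z)
  labels <- dbscan_cluster(pts, eps = eps, min_samples = min_samples)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(empty)
  rows <- lapply(seq_along(ids), function(k) {
    m <- which(labels == ids[k])
    df <- data.frame(
      object_id = sprintf("obj_%03d", k),
      x = mean(marks$x[m]), y = mean(marks$y[m]), z = mean(marks$z[m]),
      support = length(unique(marks$contributor_id[m])),
      n_marks = length(m), stringsAsFactors = FALSE)
    df$members <- list(m)
    df
  })
  out <- do.call(rbind, rows)
  class(out) <- c("object_detections", "data.frame")
  out
}

#' Attach consensus labels to detections
#'
#' Implements the two-workflow pattern: objects found by a location workflow
#' are labelled by majority vote over a follow-up classification workflow.
#' Objects whose winning choice equals `drop_choice` (e.g. "not an object")
#' are removed when `drop_rejected` is set — an automated cleaning pass.
#'
#' @param detections an [aggregate_points()] result.
#' @param label_votes data frame `object_id`, `choice`.
#' @param drop_choice rejection choice, or `NULL`.
#' @param drop_rejected drop objects winning the rejection choice.
#' @return detections with `label`, `label_agreement`, `label_votes` added;
#'   votes for unknown object ids are attached as attribute
#'   `"unknown_votes"`.
#' @export
vote_object_labels <- function(detections, label_votes, drop_choice = NULL,
                               drop_rejected = FALSE) {
  detections$label <- NA_character_
  detections$label_agreement <- NA_real_
  detections$label_votes <- 0L
  unknown <- label_votes[!label_votes$object_id %in% detections$object_id, ,
                         drop = FALSE]
  for (i in seq_len(nrow(detections))) {
    v <- label_votes$choice[label_votes$object_id == detections$object_id[i]]
    if (length(v) == 0L) next
    cons <- majority_vote(v)
    detections$label[i] <- cons$winning_choice
    detections$label_agreement[i] <- cons$agreement_fraction
    detections$label_votes[i] <- cons$n_votes
  }
  if (drop_rejected && !is.null(drop_choice)) {
    keep <- is.na(detections$label) | detections$label != drop_choice
    detections <- detections[keep, , drop = FALSE]
  }
  attr(detections, "unknown_votes") <- unknown
  detections
}

#' Write / read an object-detection table
#'
#' Simple CSV of 3D coordinates plus classification, importable by
#' volumetric viewers that accept point + class tables. Unlabelled
#' detections get an empty label cell.
#'
#' @param detections an [aggregate_points()] result.
#' @param path CSV destination.
#' @return `invisible(path)`; `read_objects()` returns the data frame.
#' @export
export_objects <- function(detections, path) {
  cols <- c("object_id", "x", "y", "z", "support")
  df <- as.data.frame(detections)[, cols, drop = FALSE]
  df$label <- if ("label" %in% names(detections)) detections$label
              else NA_character_
  df$label_agreement <- if ("label_agreement" %in% names(detections))
    detections$label_agreement else NA_real_
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname export_objects
#' @export
read_objects <- function(path) {
  if (!file.exists(path)) stop(sprintf("objects file not found: '%s'", path))
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                  colClasses = c(object_id = "character",
                                 label = "character"))
}
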