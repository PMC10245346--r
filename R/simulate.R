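# Synthetic phantoms and simulated volunteers. Stands in for real EM/X-ray
# volumes and crowds so the whole pipeline, and all recovery tests, run
# without external data. Everything is deterministic under `seed`, with one
# pseudo-random stream per (seed, volunteer, subject/object) so adding
# volunteers never perturbs existing ones.

# derive a 31-bit sub-seed from a base seed and a context tag
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "|")
  as.integer(fnv1a32(tag) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Volunteer behaviour model
#'
#' Parameters of the simulated crowd: contour vertices are jittered radially
#' with `contour_jitter_sigma` pixels, point marks with
#' `point_jitter_sigma`; a `spam_rate` fraction of annotations is replaced
#' by random strokes or spurious marks; objects are skipped with
#' `miss_rate`; question answers are correct with `answer_accuracy`.
#'
#' @param n_volunteers number of simulated contributors.
#' @param contour_jitter_sigma radial vertex noise, pixels (default 1).
#' @param point_jitter_sigma mark noise, pixels (default 1).
#' @param spam_rate,miss_rate fractions in `[0, 1]`.
#' @param answer_accuracy probability of the true label.
#' @return a `volunteer_model` object.
#' @export
volunteer_model <- function(n_volunteers = 5L, contour_jitter_sigma = 1,
                            point_jitter_sigma = 1, spam_rate = 0,
                            miss_rate = 0, answer_accuracy = 1) {
  stopifnot(n_volunteers >= 1L, contour_jitter_sigma >= 0,
            point_jitter_sigma >= 0,
            spam_rate >= 0, spam_rate <= 1,
            miss_rate >= 0, miss_rate <= 1,
            answer_accuracy >= 0, answer_accuracy <= 1)
  structure(
    list(n_volunteers = as.integer(n_volunteers),
         contour_jitter_sigma = contour_jitter_sigma,
         point_jitter_sigma = point_jitter_sigma,
         spam_rate = spam_rate, miss_rate = miss_rate,
         answer_accuracy = answer_accuracy),
    class = "volunteer_model"
  )
}

circle_polygon <- function(cx, cy, r, n_vertices = NULL) {
  # freehand strokes record a vertex every pixel or two; default density
  # follows the circumference, with a floor for tiny cross-sections
  if (is.null(n_vertices))
    n_vertices <- max(12L, as.integer(round(2 * pi * r / 1.5)))
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Generate a phantom volume with known objects
#'
#' Spherical bright blobs with smooth profiles on a noisy background;
#' objects are packed without touching each other or the volume boundary
#' (rejection sampling with bounded retries). Ground truth stores, per
#' object, the centroid, radius, a class label, and a per-slice boundary
#' polygon (a 24-gon of the sphere's cross-section circle) for every slice
#' the sphere crosses.
#'
#' @param depth,height,width volume dimensions.
#' @param n_objects number of blobs.
#' @param radius_range `c(min, max)` blob radius in pixels.
#' @param noise_sigma Gaussian background noise sd (intensities in `[0,1]`).
#' @param labels class labels sampled uniformly per object.
#' @param seed integer seed fixing everything.
#' @return a `phantom`: list with `volume` ([image_volume()]), `objects`
#'   (list of `object_id`, `centroid`, `radius`, `label`, `slices` —
#'   named-by-z list of boundary polygons) and `seed`.
#' @export
make_phantom <- function(depth = 24L, height = 96L, width = 96L,
                         n_objects = 3L, radius_range = c(6, 9),
                         noise_sigma = 0.03,
                         labels = c("dense", "empty"), seed = 1L) {
  with_seed(derive_seed(seed, "phantom"), {
    margin <- ceiling(max(radius_range)) + 2
    objects <- list()
    centres <- NULL
    tries <- 0L
    while (length(objects) < n_objects) {
      tries <- tries + 1L
      if (tries > 200L * max(1L, n_objects))
        stop("infeasible packing: could not place all objects")
      r <- stats::runif(1, radius_range[1L], radius_range[2L])
      if (2 * r + 4 >= min(height, width) || 2 * r + 4 >= depth)
        stop("radius_range too large for the volume")
      c_xyz <- c(
        stats::runif(1, margin, width - margin),
        stats::runif(1, margin, height - margin),
        stats::runif(1, margin, depth - margin)
      )
      if (!is.null(centres)) {
        dd <- sqrt(colSums((t(centres) - c_xyz)^2))
        if (any(dd < r + vapply(objects, `[[`, numeric(1), "radius") + 3)) next
      }
      k <- length(objects) + 1L
      slices <- list()
      for (z in 0:(depth - 1L)) {
        dz <- z + 0.5 - c_xyz[3L]   # slice plane through the voxel centre
        if (abs(dz) >= r) next
        rz <- sqrt(r^2 - dz^2)
        if (rz < 1.5) next    # too small to outline meaningfully
        slices[[as.character(z)]] <- circle_polygon(c_xyz[1L], c_xyz[2L], rz)
      }
      objects[[k]] <- list(
        object_id = sprintf("truth_%03d", k),
        centroid = c(x = c_xyz[1L], y = c_xyz[2L], z = c_xyz[3L]),
        radius = r,
        label = sample(labels, 1L),
        slices = slices
      )
      centres <- rbind(centres, c_xyz)
    }
    vox <- array(stats::rnorm(depth * height * width, mean = 0.2,
                              sd = noise_sigma),
                 dim = c(depth, height, width))
    # render smooth bright blobs: sigmoid fall-off at the sphere surface
    xs <- seq_len(width) - 0.5; ys <- seq_len(height) - 0.5
    for (ob in objects) {
      cc <- ob$centroid
      for (z in 0:(depth - 1L)) {
        dz <- z + 0.5 - cc[3L]
        if (abs(dz) > ob$radius + 3) next
        d2 <- outer((ys - cc[2L])^2, (xs - cc[1L])^2, "+") + dz^2
        prof <- 0.7 / (1 + exp((sqrt(d2) - ob$radius) / 0.8))
        vox[z + 1L, , ] <- vox[z + 1L, , ] + prof
      }
    }
    vox <- pmin(pmax(vox, 0), 1)
    structure(list(volume = image_volume(vox), objects = objects, seed = seed),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d x %d with %d object(s), seed %d\n",
              x$volume$depth, x$volume$height, x$volume$width,
              length(x$objects), x$seed))
  invisible(x)
}

#' Ground-truth binary mask volume of a phantom
#'
#' Voxel set when its centre lies inside some object sphere.
#'
#' @param phantom a [make_phantom()] result.
#' @return logical `(z, y, x)` array.
#' @export
phantom_truth_mask <- function(phantom) {
  d <- dim(phantom$volume$voxels)
  mask <- array(FALSE, dim = d)
  xs <- seq_len(d[3L]) - 0.5; ys <- seq_len(d[2L]) - 0.5
  for (ob in phantom$objects) {
    cc <- ob$centroid
    for (z in 0:(d[1L] - 1L)) {
      dz <- z + 0.5 - cc[3L]
      if (abs(dz) >= ob$radius) next
      rz2 <- ob$radius^2 - dz^2
      d2 <- outer((ys - cc[2L])^2, (xs - cc[1L])^2, "+")
      mask[z + 1L, , ] <- mask[z + 1L, , ] | (d2 < rz2)
    }
  }
  mask
}

# a random open scribble away from a bounding box; the stroke stays within
# 4 px of its centre, so a 6-px bbox margin keeps it fully disjoint. When
# the structure fills the frame and no such centre exists, fall back to the
# frame corner (still off-structure for convex outlines).
spam_stroke <- function(avoid_bbox, width, height) {
  cx <- cy <- NA_real_
  for (try in 1:200) {
    px <- stats::runif(1, 2, width - 2)
    py <- stats::runif(1, 2, height - 2)
    if (px < avoid_bbox[1L] - 6 || px > avoid_bbox[2L] + 6 ||
        py < avoid_bbox[3L] - 6 || py > avoid_bbox[4L] + 6) {
      cx <- px; cy <- py; break
    }
  }
  if (is.na(cx)) { cx <- 4; cy <- 4 }
  t <- seq(0, 1, length.out = 8L)
  cbind(x = cx + 3 * cos(6 * t) + t, y = cy + 3 * sin(5 * t))
}

#' Simulate one volunteer's contour for a truth polygon
#'
#' With probability `spam_rate` the volunteer draws a random open scribble
#' elsewhere in the frame; otherwise the truth boundary with per-vertex
#' radial Gaussian jitter, and with probability 0.5 a small endpoint gap is
#' left open (within closure tolerance) to exercise loop closing.
#'
#' @param truth_polygon two-column `(x, y)` boundary (open ring).
#' @param model a [volunteer_model()].
#' @param volunteer 1-based volunteer index.
#' @param frame_width,frame_height subject-frame size (for spam placement).
#' @param seed base seed; the draw uses the (seed, volunteer, polygon)
#'   stream.
#' @param tag extra stream-identification tag (e.g. subject id).
#' @return a [freehand_line()].
#' @export
simulate_contour <- function(truth_polygon, model, volunteer,
                             frame_width, frame_height, seed = 1L,
                             tag = "contour") {
  stopifnot(inherits(model, "volunteer_model"))
  with_seed(derive_seed(seed, "contour", tag, volunteer), {
    if (stats::runif(1) < model$spam_rate) {
      bbox <- c(range(truth_polygon[, 1L]), range(truth_polygon[, 2L]))
      return(freehand_line("T_draw",
                           spam_stroke(bbox, frame_width, frame_height)))
    }
    cx <- mean(truth_polygon[, 1L]); cy <- mean(truth_polygon[, 2L])
    dx <- truth_polygon[, 1L] - cx; dy <- truth_polygon[, 2L] - cy
    r <- sqrt(dx^2 + dy^2)
    jitter <- stats::rnorm(nrow(truth_polygon), 0, model$contour_jitter_sigma)
    scale <- (r + jitter) / pmax(r, 1e-9)
    v <- cbind(x = cx + dx * scale, y = cy + dy * scale)
    if (stats::runif(1) < 0.5) {
      v <- rbind(v, v[1L, ])               # closed stroke
    } else {
      gap <- stats::runif(1, 0.2, 1.5)     # small endpoint gap
      last <- v[1L, ] + gap * (v[nrow(v), ] - v[1L, ]) /
        max(sqrt(sum((v[nrow(v), ] - v[1L, ])^2)), 1e-9)
      v <- rbind(v, last)
    }
    freehand_line("T_draw", v)
  })
}

#' Simulate one volunteer's point marks for a phantom
#'
#' Each object is skipped with probability `miss_rate`, otherwise marked at
#' its centroid plus 3D Gaussian jitter (`point_jitter_sigma` in x and y,
#' half that in z). Spurious marks are added with a Poisson count of rate
#' `spam_rate * n_objects`, placed away from all true objects.
#'
#' @param phantom a [make_phantom()] result.
#' @param model a [volunteer_model()].
#' @param volunteer 1-based volunteer index.
#' @param seed base seed.
#' @return data frame `contributor_id`, `x`, `y`, `z`, `true_object`
#'   (`NA` for spurious marks), in volume coordinates.
#' @export
simulate_marks <- function(phantom, model, volunteer, seed = 1L) {
  stopifnot(inherits(model, "volunteer_model"))
  d <- dim(phantom$volume$voxels)
  with_seed(derive_seed(seed, "marks", volunteer), {
    rows <- list()
    for (ob in phantom$objects) {
      if (stats::runif(1) < model$miss_rate) next
      rows[[length(rows) + 1L]] <- data.frame(
        contributor_id = sprintf("vol_%02d", volunteer),
        x = ob$centroid[["x"]] + stats::rnorm(1, 0, model$point_jitter_sigma),
        y = ob$centroid[["y"]] + stats::rnorm(1, 0, model$point_jitter_sigma),
        z = ob$centroid[["z"]] + stats::rnorm(1, 0, model$point_jitter_sigma / 2),
        true_object = ob$object_id, stringsAsFactors = FALSE)
    }
    n_spur <- stats::rpois(1, model$spam_rate * length(phantom$objects))
    centres <- do.call(rbind, lapply(phantom$objects, function(o) o$centroid))
    max_r <- if (length(phantom$objects)) max(vapply(phantom$objects, `[[`,
                                                     numeric(1), "radius")) else 0
    for (i in seq_len(n_spur)) {
      repeat {
        p <- c(stats::runif(1, 1, d[3L] - 1), stats::runif(1, 1, d[2L] - 1),
               stats::runif(1, 1, d[1L] - 1))
        if (is.null(centres) ||
            all(sqrt(rowSums((centres - rep(p, each = nrow(centres)))^2)) >
                3 * max_r)) break
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contributor_id = sprintf("vol_%02d", volunteer),
        x = p[1L], y = p[2L], z = p[3L],
        true_object = NA_character_, stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
      return(data.frame(contributor_id = character(0), x = numeric(0),
                        y = numeric(0), z = numeric(0),
                        true_object = character(0), stringsAsFactors = FALSE))
    do.call(rbind, rows)
  })
}

#' Simulate one question answer
#'
#' The true label with probability `answer_accuracy`, otherwise uniform over
#' the wrong labels.
#'
#' @param true_label the correct choice.
#' @param labels all available choices.
#' @param model a [volunteer_model()].
#' @param volunteer,seed,tag stream identification.
#' @return an [answer()].
#' @export
simulate_answers <- function(true_label, labels, model, volunteer = 1L,
                             seed = 1L, tag = "answer") {
  stopifnot(inherits(model, "volunteer_model"), true_label %in% labels)
  with_seed(derive_seed(seed, "answer", tag, volunteer), {
    choice <- if (stats::runif(1) < model$answer_accuracy || length(labels) == 1L)
      true_label
    else
      sample(setdiff(labels, true_label), 1L)
    answer("T_question", choice)
  })
}

annotation_to_json_value <- function(a) {
  if (inherits(a, "answer")) return(a$choice)
  if (inherits(a, "point_mark"))
    return(list(x = a$x, y = a$y, frame = a$frame_index))
  if (inherits(a, "ellipse_mark"))
    return(list(x = a$x, y = a$y, rx = a$rx, ry = a$ry, angle = a$angle,
                frame = a$frame_index))
  if (inherits(a, "freehand_line"))
    return(list(points = lapply(seq_len(nrow(a$vertices)), function(i)
      list(x = a$vertices[i, 1L], y = a$vertices[i, 2L])),
      frame = a$frame_index))
  stop("unknown annotation class")
}

#' Write simulated classifications as a classification export
#'
#' Emits exactly the CSV + embedded-JSON dialect that
#' [parse_classifications()] reads, so `parse(write(x))` round-trips.
#'
#' @param classifications list of `classification`-like lists: fields
#'   `classification_id`, `user_name` (raw name; pseudonymised on parse),
#'   `subject_id`, `workflow_id`, `workflow_version`, `created_at`,
#'   `annotations`.
#' @param path CSV destination.
#' @return `invisible(path)`.
#' @export
write_export <- function(classifications, path) {
  rows <- lapply(classifications, function(cl) {
    data.frame(
      classification_id = cl$classification_id,
      user_name = cl$user_name %||% cl$contributor_id,
      workflow_id = cl$workflow_id,
      workflow_version = cl$workflow_version,
      created_at = cl$created_at,
      annotations = as.character(jsonlite::toJSON(
        lapply(cl$annotations, function(a)
          list(task = a$task_id, value = annotation_to_json_value(a))),
        auto_unbox = TRUE, digits = NA)),
      subject_data = as.character(jsonlite::toJSON(
        cl$subject_data %||% list(), auto_unbox = TRUE)),
      subject_ids = cl$subject_id,
      stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(
      as.data.frame(matrix(character(0), ncol = length(export_cols)),
                    stringsAsFactors = FALSE), export_cols)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Simulate a full contour-annotation study on a phantom
#'
#' Builds one flipbook subject per (object, annotatable slice), has every
#' volunteer outline the object on the central plane, and returns the
#' subjects, manifest rows and classification records — the inputs the
#' aggregation and assembly stages expect.
#'
#' @param phantom a [make_phantom()] result.
#' @param model a [volunteer_model()].
#' @param fov_margin window half-margin around the object radius, pixels.
#' @param context_half_width flipbook context (default 2).
#' @param seed base seed.
#' @return list with `subjects` (list), `manifest` (data frame) and
#'   `classifications` (list, in-memory; see [write_export()]).
#' @export
simulate_contour_study <- function(phantom, model, fov_margin = 6,
                                   context_half_width = 2L, seed = 1L) {
  vol <- phantom$volume
  subjects <- list(); manifest_rows <- list(); classifications <- list()
  cl_counter <- 0L
  for (ob in phantom$objects) {
    half <- ceiling(ob$radius + fov_margin)
    x0 <- round(ob$centroid[["x"]]) - half
    y0 <- round(ob$centroid[["y"]]) - half
    size <- 2L * half
    for (z_chr in names(ob$slices)) {
      z <- as.integer(z_chr)
      if (z < context_half_width || z > vol$depth - 1L - context_half_width)
        next
      sid <- sprintf("%s_z%03d", ob$object_id, z)
      subj <- build_flipbook(vol, x0, y0, size, size, z,
                             context_half_width = context_half_width,
                             subject_id = sid)
      subjects[[length(subjects) + 1L]] <- subj
      manifest_rows[[length(manifest_rows) + 1L]] <- data.frame(
        subject_id = sid, x = x0, y = y0, z = z, tile_id = NA_character_,
        annotation_frame_index = context_half_width, z_stride = 1L,
        frame_width = size, frame_height = size,
        stringsAsFactors = FALSE)
      truth_local <- cbind(x = ob$slices[[z_chr]][, 1L] - x0,
                           y = ob$slices[[z_chr]][, 2L] - y0)
      for (v in seq_len(model$n_volunteers)) {
        cl_counter <- cl_counter + 1L
        line <- simulate_contour(truth_local, model, v, size, size,
                                 seed = seed, tag = sid)
        line$frame_index <- as.integer(context_half_width)
        classifications[[length(classifications) + 1L]] <- list(
          classification_id = sprintf("cl_%06d", cl_counter),
          user_name = sprintf("vol_%02d", v),
          contributor_id = sprintf("vol_%02d", v),
          subject_id = sid, workflow_id = "wf_contours",
          workflow_version = "1.0",
          created_at = sprintf("2024-01-01T%02d:%02d:00Z",
                               cl_counter %/% 60 %% 24, cl_counter %% 60),
          annotations = list(line))
      }
    }
  }
  list(subjects = subjects, manifest = do.call(rbind, manifest_rows),
       classifications = classifications)
}
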