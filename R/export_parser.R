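# Annotation constructors -----------------------------------------------

#' Annotation records
#'
#' Typed volunteer annotations: a point mark, an ellipse mark (centre,
#' semi-axes in pixels, angle in degrees), a freehand polyline (>= 2
#' vertices) or a question answer. Coordinates are subject-frame pixels;
#' `frame_index` is the 0-based flipbook frame the mark was made on.
#'
#' @param task_id workflow task identifier.
#' @param x,y coordinates (pixels).
#' @param frame_index 0-based frame index.
#' @param rx,ry ellipse semi-axes (pixels, `> 0`).
#' @param angle ellipse rotation (degrees).
#' @param vertices two-column matrix (or data frame) of `(x, y)` vertices.
#' @param choice answer string.
#' @return an object of class `point_mark`, `ellipse_mark`, `freehand_line`
#'   or `answer` (all also class `annotation`).
#' @name annotations
NULL

#' @rdname annotations
#' @export
point_mark <- function(task_id, x, y, frame_index = 0L) {
  stopifnot(is.finite(x), is.finite(y))
  structure(list(task_id = task_id, x = x, y = y,
                 frame_index = as.integer(frame_index)),
            class = c("point_mark", "annotation"))
}

#' @rdname annotations
#' @export
ellipse_mark <- function(task_id, x, y, rx, ry, angle = 0, frame_index = 0L) {
  stopifnot(is.finite(x), is.finite(y), rx > 0, ry > 0)
  structure(list(task_id = task_id, x = x, y = y, rx = rx, ry = ry,
                 angle = angle, frame_index = as.integer(frame_index)),
            class = c("ellipse_mark", "annotation"))
}

#' @rdname annotations
#' @export
freehand_line <- function(task_id, vertices, frame_index = 0L) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L) stop("a freehand line needs >= 2 vertices")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  colnames(vertices) <- c("x", "y")
  structure(list(task_id = task_id, vertices = vertices,
                 frame_index = as.integer(frame_index)),
            class = c("freehand_line", "annotation"))
}

#' @rdname annotations
#' @export
answer <- function(task_id, choice) {
  structure(list(task_id = task_id, choice = as.character(choice)),
            class = c("answer", "annotation"))
}

# 32-bit FNV-1a over UTF-8 bytes; exact in double arithmetic
fnv1a32 <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(enc2utf8(s))) {
    h <- xor_double(h, b)
    # multiply mod 2^32 in 16-bit halves to stay exact in doubles
    h_lo <- h %% 65536; h_hi <- h %/% 65536
    h <- (h_lo * p + ((h_hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

xor_double <- function(a, b) {
  # bitwXor on values up to 2^32-1, done in two 16-bit halves
  a_lo <- a %% 65536; a_hi <- a %/% 65536
  b_lo <- b %% 65536; b_hi <- b %/% 65536
  bitwXor(as.integer(a_lo), as.integer(b_lo)) +
    65536 * bitwXor(as.integer(a_hi), as.integer(b_hi))
}

#' Pseudonymise a contributor name
#'
#' Stable salted 32-bit FNV-1a hash; raw names are never stored downstream.
#' Empty or missing names (not-logged-in contributors) are mapped to a
#' distinct pseudo-contributor per classification row.
#'
#' @param user_name raw name (may be `NA` or empty).
#' @param classification_id used for anonymous rows.
#' @param salt project salt.
#' @return a pseudonymous id string.
#' @export
pseudonymize <- function(user_name, classification_id, salt = "crowdvol") {
  if (is.na(user_name) || !nzchar(user_name))
    return(paste0("anon_", classification_id))
  h <- fnv1a32(paste0(salt, ":", user_name))
  sprintf("c%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

parse_annotation_value <- function(task, value) {
  if (is.character(value) && length(value) == 1L)
    return(answer(task, value))
  if (is.list(value) && !is.null(value$points)) {
    pts <- value$points
    verts <- cbind(
      x = vapply(pts, function(p) as.numeric(p$x), numeric(1)),
      y = vapply(pts, function(p) as.numeric(p$y), numeric(1))
    )
    return(freehand_line(task, verts,
                         frame_index = as.integer(value$frame %||% 0L)))
  }
  if (is.list(value) && !is.null(value$rx)) {
    return(ellipse_mark(task, as.numeric(value$x), as.numeric(value$y),
                        as.numeric(value$rx), as.numeric(value$ry),
                        angle = as.numeric(value$angle %||% 0),
                        frame_index = as.integer(value$frame %||% 0L)))
  }
  if (is.list(value) && !is.null(value$x) && !is.null(value$y)) {
    return(point_mark(task, as.numeric(value$x), as.numeric(value$y),
                      frame_index = as.integer(value$frame %||% 0L)))
  }
  stop("unrecognised annotation value shape")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

export_cols <- c("classification_id", "user_name", "workflow_id",
                 "workflow_version", "created_at", "annotations",
                 "subject_data", "subject_ids")

#' Parse a classification export
#'
#' Reads the classification-export CSV dialect: one row per volunteer
#' response, with columns `classification_id`, `user_name`, `workflow_id`,
#' `workflow_version`, `created_at`, `annotations` (a JSON array of
#' `{task, value}` objects), `subject_data` (JSON) and `subject_ids`.
#' Drawing values with `{x, y, frame}` become point marks,
#' `{x, y, rx, ry, angle, frame}` ellipse marks, `{points: [...], frame}`
#' freehand lines; scalar strings become answers. Malformed rows are never
#' silently dropped: they are collected in the rejected-row report.
#'
#' @param path export CSV.
#' @param salt pseudonymisation salt (see [pseudonymize()]).
#' @return a list with `classifications` (list of `classification` objects)
#'   and `rejected` (data frame `row`, `classification_id`, `reason`).
#' @export
parse_classifications <- function(path, salt = "crowdvol") {
  if (!file.exists(path)) stop(sprintf("export not found: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(export_cols, names(df))
  if (length(missing))
    stop(sprintf("export lacks mandatory column(s): %s",
                 paste(missing, collapse = ", ")))
  out <- vector("list", nrow(df))
  rejected <- list()
  for (i in seq_len(nrow(df))) {
    res <- tryCatch({
      ann_raw <- jsonlite::fromJSON(df$annotations[i], simplifyVector = FALSE)
      if (length(ann_raw) == 0L) stop("empty annotation array")
      anns <- lapply(ann_raw, function(a)
        parse_annotation_value(a$task, a$value))
      structure(
        list(
          classification_id = df$classification_id[i],
          contributor_id = pseudonymize(df$user_name[i],
                                        df$classification_id[i], salt),
          subject_id = df$subject_ids[i],
          workflow_id = df$workflow_id[i],
          workflow_version = df$workflow_version[i],
          created_at = df$created_at[i],
          annotations = anns
        ),
        class = "classification"
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        row = i, classification_id = df$classification_id[i],
        reason = conditionMessage(res), stringsAsFactors = FALSE)
      out[i] <- list(NULL)
    } else {
      out[[i]] <- res
    }
  }
  list(
    classifications = Filter(Negate(is.null), out),
    rejected = if (length(rejected)) do.call(rbind, rejected)
               else data.frame(row = integer(0),
                               classification_id = character(0),
                               reason = character(0), stringsAsFactors = FALSE)
  )
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification> %s by %s on subject %s (%d annotation(s))\n",
              x$classification_id, x$contributor_id, x$subject_id,
              length(x$annotations)))
  invisible(x)
}

# dotted version strings compared componentwise, numerically
compare_versions <- function(a, b) {
  pa <- suppressWarnings(as.numeric(strsplit(a, ".", fixed = TRUE)[[1L]]))
  pb <- suppressWarnings(as.numeric(strsplit(b, ".", fixed = TRUE)[[1L]]))
  if (anyNA(pa) || anyNA(pb)) stop(sprintf("unparsable version: '%s' / '%s'", a, b))
  n <- max(length(pa), length(pb))
  pa <- c(pa, rep(0, n - length(pa)))
  pb <- c(pb, rep(0, n - length(pb)))
  for (i in seq_len(n)) {
    if (pa[i] < pb[i]) return(-1L)
    if (pa[i] > pb[i]) return(1L)
  }
  0L
}

#' Filter classifications by workflow and version
#'
#' Keeps rows matching `workflow_id` with dotted version numerically `>=`
#' `min_version` (so `10.1 > 2.3`, unlike lexicographic order). Order is
#' preserved; rows with unparsable versions are reported, not kept.
#'
#' @param classifications list of `classification` objects.
#' @param workflow_id workflow to keep.
#' @param min_version minimum dotted version, or `NULL` for any.
#' @return list with `kept` and `rejected` (data frame with reasons).
#' @export
filter_workflow <- function(classifications, workflow_id, min_version = NULL) {
  kept <- list(); rejected <- list()
  for (cl in classifications) {
    if (!identical(cl$workflow_id, workflow_id)) next
    ok <- tryCatch(
      is.null(min_version) ||
        compare_versions(cl$workflow_version, min_version) >= 0L,
      error = function(e) e)
    if (inherits(ok, "error")) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        classification_id = cl$classification_id,
        reason = conditionMessage(ok), stringsAsFactors = FALSE)
    } else if (ok) {
      kept[[length(kept) + 1L]] <- cl
    }
  }
  list(kept = kept,
       rejected = if (length(rejected)) do.call(rbind, rejected)
                  else data.frame(classification_id = character(0),
                                  reason = character(0),
                                  stringsAsFactors = FALSE))
}

#' Link classifications to manifest provenance
#'
#' Inner join on `subject_id`; classifications whose subject is absent from
#' the manifest are returned separately, never silently dropped.
#'
#' @param classifications list of `classification` objects.
#' @param manifest data frame from [read_manifest()].
#' @return list with `linked` (each element `list(classification, subject)`,
#'   `subject` being the matching manifest row) and `unlinked`.
#' @export
link_subjects <- function(classifications, manifest) {
  if (anyDuplicated(manifest$subject_id))
    stop("duplicate subject_id in manifest")
  idx <- match(vapply(classifications, `[[`, character(1), "subject_id"),
               manifest$subject_id)
  linked <- list(); unlinked <- list()
  for (i in seq_along(classifications)) {
    if (is.na(idx[i])) {
      unlinked[[length(unlinked) + 1L]] <- classifications[[i]]
    } else {
      linked[[length(linked) + 1L]] <-
        list(classification = classifications[[i]],
             subject = manifest[idx[i], , drop = FALSE])
    }
  }
  list(linked = linked, unlinked = unlinked)
}

#' One vote per volunteer per subject
#'
#' For each `(contributor_id, subject_id, workflow_id)` keeps the earliest
#' `created_at`; exact timestamp ties are broken by the lowest
#' `classification_id`. Later duplicates are reported.
#'
#' @param classifications list of `classification` objects.
#' @return list with `kept` (original order) and `duplicates`.
#' @export
deduplicate_contributor <- function(classifications) {
  if (length(classifications) == 0L)
    return(list(kept = list(), duplicates = list()))
  key <- vapply(classifications, function(cl)
    paste(cl$contributor_id, cl$subject_id, cl$workflow_id, sep = "\r"),
    character(1))
  ts <- vapply(classifications, `[[`, character(1), "created_at")
  cid <- vapply(classifications, `[[`, character(1), "classification_id")
  keep <- logical(length(classifications))
  for (k in unique(key)) {
    idx <- which(key == k)
    ord <- idx[order(ts[idx], cid[idx])]
    keep[ord[1L]] <- TRUE
  }
  list(kept = classifications[keep], duplicates = classifications[!keep])
}
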