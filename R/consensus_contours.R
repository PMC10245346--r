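# CRIA — contour regression by interior averages: close each volunteer's
# freehand stroke into a loop, rasterize its interior, stack interiors into
# a per-pixel height map, and keep pixels covered by at least half the
# volunteers.

#' Close a freehand stroke into a loop
#'
#' Strokes whose endpoints coincide are taken as-is; endpoint gaps up to
#' `gap_tolerance` pixels are closed by appending the first vertex; wider
#' gaps and degenerate strokes (< 3 distinct vertices) are rejected with a
#' reason — rejected strokes are excluded and reported, never guessed at.
#'
#' @param line a [freehand_line()] or a two-column vertex matrix.
#' @param gap_tolerance maximum endpoint gap in pixels. The pipeline default
#'   is 5% of the frame diagonal.
#' @return a `closed_loop` (fields `vertices`, first row equal to last, and
#'   `contributor_id`), or a `loop_reject` with a `reason` field.
#' @export
close_polyline <- function(line, gap_tolerance) {
  v <- if (inherits(line, "freehand_line")) line$vertices else as.matrix(line)
  reject <- function(reason)
    structure(list(reason = reason), class = "loop_reject")
  if (nrow(v) < 2L) return(reject("fewer than 2 vertices"))
  n_distinct <- nrow(unique(round(v, 9)))
  if (n_distinct < 3L) return(reject("fewer than 3 distinct vertices"))
  gap <- sqrt(sum((v[1L, ] - v[nrow(v), ])^2))
  if (gap > 0) {
    if (gap > gap_tolerance)
      return(reject(sprintf("endpoint gap %.2f px exceeds tolerance %.2f px",
                            gap, gap_tolerance)))
    v <- rbind(v, v[1L, ])
  }
  if (nrow(v) < 4L) return(reject("closed loop needs >= 4 stored vertices"))
  colnames(v) <- c("x", "y")
  structure(list(vertices = v), class = "closed_loop")
}

#' Rasterize the interior of a closed loop
#'
#' Pixel `(i, j)` (0-based column, row) is set exactly when its centre
#' `(i + 0.5, j + 0.5)` lies inside the polygon under the even-odd rule, so
#' self-intersecting volunteer strokes are handled deterministically.
#' Implemented as a scanline: per pixel row, edge crossings with the
#' horizontal line through the pixel centres are accumulated and parity
#' decides membership.
#'
#' @param loop a [close_polyline()] result (or a closed vertex matrix).
#' @param width,height raster size (the subject frame).
#' @return logical `height x width` matrix (row = y, column = x).
#' @export
rasterize_interior <- function(loop, width, height) {
  v <- if (inherits(loop, "closed_loop")) loop$vertices else as.matrix(loop)
  mask <- matrix(FALSE, nrow = height, ncol = width)
  if (nrow(v) < 4L) return(mask)
  x1 <- v[-nrow(v), 1L]; y1 <- v[-nrow(v), 2L]
  x2 <- v[-1L, 1L];      y2 <- v[-1L, 2L]
  px <- seq_len(width) - 0.5
  for (j in seq_len(height)) {
    py <- j - 0.5
    # half-open edge rule: edge crosses the scanline when py is in
    # [min(y1,y2), max(y1,y2)) taken directionally, so shared vertices are
    # counted exactly once
    cross <- (y1 <= py & py < y2) | (y2 <= py & py < y1)
    if (!any(cross)) next
    xs <- x1[cross] + (py - y1[cross]) / (y2[cross] - y1[cross]) *
      (x2[cross] - x1[cross])
    cnt <- vapply(px, function(p) sum(xs < p), numeric(1))
    mask[j, ] <- cnt %% 2 == 1
  }
  mask
}

#' Stack interior masks into a height map
#'
#' Per-pixel count of contributor interiors covering each pixel. Supply one
#' mask per contributor: a contributor's multiple loops on one frame must be
#' OR-ed first (see [contributor_masks()]), so the count is of contributors,
#' not strokes.
#'
#' @param masks list of equal-sized logical matrices.
#' @return integer matrix with attribute `n` (number of contributors).
#' @export
height_map <- function(masks) {
  if (length(masks) == 0L) stop("height_map needs at least one mask")
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) stop("mask dimension mismatch")
  h <- Reduce(`+`, lapply(masks, function(m) {
    storage.mode(m) <- "integer"; m
  }))
  attr(h, "n") <- length(masks)
  h
}

#' CRIA consensus segmentation
#'
#' The consensus mask keeps every pixel where half or more of the volunteer
#' interiors agree: `2 * height >= N`, inclusive (with even `N` exact-half
#' pixels are kept; at `N = 2` this yields the union of both interiors —
#' a direct consequence of the inclusive threshold). The agreement raster is
#' `height / N`. The consensus may comprise multiple disjoint regions.
#'
#' @param masks list of per-contributor interior masks (`N >= 1`).
#' @param excluded ids of contributors removed beforehand (bookkeeping).
#' @return a `consensus_segmentation`: list with `mask` (logical),
#'   `agreement` (numeric in `[0, 1]`), `n` and `excluded`.
#' @export
cria_consensus <- function(masks, excluded = character(0)) {
  h <- height_map(masks)
  n <- attr(h, "n")
  structure(
    list(mask = 2L * h >= n, agreement = h / n, n = n, excluded = excluded),
    class = "consensus_segmentation"
  )
}

#' @export
print.consensus_segmentation <- function(x, ...) {
  cat(sprintf(
    "<consensus_segmentation> %dx%d, N=%d, %d px set, %d contributor(s) excluded\n",
    nrow(x$mask), ncol(x$mask), x$n, sum(x$mask), length(x$excluded)))
  invisible(x)
}

mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(1)          # empty vs empty: perfect agreement
  sum(a & b) / u
}

#' Remove outlier annotations before consensus
#'
#' Two-pass scheme: a provisional consensus over all masks (or an expert
#' mask, when one is available) serves as the reference; masks whose
#' intersection-over-union with the reference falls below `iou_cutoff` are
#' excluded as outliers, and the consensus is recomputed once on the
#' survivors. If every mask would be excluded, all are kept and the result
#' is flagged.
#'
#' @param masks named list of per-contributor interior masks (`N >= 2`);
#'   names are contributor ids.
#' @param iou_cutoff exclusion threshold (default 0.3).
#' @param expert optional expert mask used as the reference instead of the
#'   provisional consensus.
#' @return a `consensus_segmentation` with `excluded` filled in and a
#'   logical attribute `all_excluded`.
#' @export
remove_outlier_annotations <- function(masks, iou_cutoff = 0.3,
                                       expert = NULL) {
  if (length(masks) < 2L) stop("outlier removal needs N >= 2 masks")
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    names(masks) <- sprintf("contributor_%d", seq_along(masks))
  reference <- if (!is.null(expert)) expert else cria_consensus(masks)$mask
  iou <- vapply(masks, mask_iou, numeric(1), b = reference)
  keep <- iou >= iou_cutoff
  all_excluded <- !any(keep)
  if (all_excluded) keep[] <- TRUE
  out <- cria_consensus(masks[keep], excluded = names(masks)[!keep])
  attr(out, "all_excluded") <- all_excluded
  attr(out, "iou") <- iou
  out
}

#' Extract boundary loops of a consensus mask
#'
#' Traces the pixel-edge (crack) boundary of each 8-connected component,
#' holes included, as closed loops on the integer pixel-corner lattice. The
#' loops are exact: XOR-combining [rasterize_interior()] over all returned
#' loops reproduces the mask pixel-for-pixel (holes cancel by even-odd
#' parity).
#'
#' @param mask logical matrix.
#' @return list of `closed_loop` objects, each with a `component` field.
#' @export
extract_consensus_contours <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  if (sum(mask) == 0L) return(list())
  comp <- label_components(mask)
  at <- function(i, j) i >= 0L && i < w && j >= 0L && j < h && mask[j + 1L, i + 1L]
  # boundary edges on the corner lattice; each edge keyed by its corner
  # endpoints, annotated with the adjacent foreground pixel's component
  edges <- list()
  add_edge <- function(a, b, cmp) {
    edges[[length(edges) + 1L]] <<- list(a = a, b = b, comp = cmp)
  }
  for (j in seq_len(h) - 1L) for (i in seq_len(w) - 1L) {
    if (!mask[j + 1L, i + 1L]) next
    cmp <- comp[j + 1L, i + 1L]
    if (!at(i, j - 1L)) add_edge(c(i, j), c(i + 1L, j), cmp)          # top
    if (!at(i, j + 1L)) add_edge(c(i, j + 1L), c(i + 1L, j + 1L), cmp) # bottom
    if (!at(i - 1L, j)) add_edge(c(i, j), c(i, j + 1L), cmp)          # left
    if (!at(i + 1L, j)) add_edge(c(i + 1L, j), c(i + 1L, j + 1L), cmp) # right
  }
  # link edges into closed loops; at degree-4 corners any pairing preserves
  # the even-odd fill, so the first unused edge is taken
  key <- function(p) paste(p[1L], p[2L])
  incident <- new.env(parent = emptyenv())
  for (e in seq_along(edges)) {
    for (p in list(edges[[e]]$a, edges[[e]]$b)) {
      k <- key(p)
      incident[[k]] <- c(incident[[k]], e)
    }
  }
  used <- logical(length(edges))
  loops <- list()
  for (start in seq_along(edges)) {
    if (used[start]) next
    used[start] <- TRUE
    e <- edges[[start]]
    verts <- list(e$a, e$b)
    cur <- e$b
    while (!identical(cur, e$a)) {
      cand <- incident[[key(cur)]]
      nxt <- cand[!used[cand]][1L]
      used[nxt] <- TRUE
      nx <- edges[[nxt]]
      cur <- if (identical(nx$a, cur)) nx$b else nx$a
      verts[[length(verts) + 1L]] <- cur
    }
    v <- do.call(rbind, verts)
    colnames(v) <- c("x", "y")
    loops[[length(loops) + 1L]] <- structure(
      list(vertices = v, component = e$comp), class = "closed_loop")
  }
  loops
}

# label 8-connected components of a logical mask (BFS, base R)
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  comp <- matrix(0L, h, w)
  cur <- 0L
  for (j0 in seq_len(h)) for (i0 in seq_len(w)) {
    if (!mask[j0, i0] || comp[j0, i0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(j0, i0))
    comp[j0, i0] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dj in -1L:1L) for (di in -1L:1L) {
        j <- p[1L] + dj; i <- p[2L] + di
        if (j >= 1L && j <= h && i >= 1L && i <= w &&
            mask[j, i] && comp[j, i] == 0L) {
          comp[j, i] <- cur
          queue[[length(queue) + 1L]] <- c(j, i)
        }
      }
    }
  }
  comp
}

#' Re-rasterize a set of boundary loops
#'
#' Even-odd (XOR) combination of the individual loop interiors; the exact
#' inverse of [extract_consensus_contours()].
#'
#' @param loops list of `closed_loop` objects.
#' @param width,height raster size.
#' @return logical matrix.
#' @export
rasterize_loops <- function(loops, width, height) {
  out <- matrix(FALSE, nrow = height, ncol = width)
  for (lp in loops) out <- xor(out, rasterize_interior(lp, width, height))
  out
}

#' Compare a consensus mask with an expert mask
#'
#' @param consensus,expert equal-sized logical matrices.
#' @return list with `iou` (`|A∩B| / |A∪B|`, defined as 1 when both masks
#'   are empty), `dice` (`2|A∩B| / (|A|+|B|)`, likewise 1) and `agreement`
#'   (fraction of pixels on which the masks agree).
#' @export
compare_to_expert <- function(consensus, expert) {
  if (!identical(dim(consensus), dim(expert)))
    stop("mask dimension mismatch")
  inter <- sum(consensus & expert)
  sizes <- sum(consensus) + sum(expert)
  list(
    iou = mask_iou(consensus, expert),
    dice = if (sizes == 0L) 1 else 2 * inter / sizes,
    agreement = mean(consensus == expert)
  )
}

#' OR together one contributor's loops per frame
#'
#' Groups closed loops by contributor and ORs each contributor's interiors,
#' so the height map counts contributors rather than strokes.
#'
#' @param loops list of `closed_loop` objects.
#' @param contributor_ids character vector parallel to `loops`.
#' @param width,height raster size.
#' @return named list of logical masks, one per contributor.
#' @export
contributor_masks <- function(loops, contributor_ids, width, height) {
  stopifnot(length(loops) == length(contributor_ids))
  out <- list()
  for (id in unique(contributor_ids)) {
    ms <- lapply(loops[contributor_ids == id], rasterize_interior,
                 width = width, height = height)
    out[[id]] <- Reduce(`|`, ms)
  }
  out
}
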