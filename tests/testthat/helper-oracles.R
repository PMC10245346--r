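# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementations.

# point-in-polygon by the classical crossing-number (even-odd) test,
# one point at a time
oracle_point_in_polygon <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1L]; yi <- verts[i, 2L]
    xj <- verts[j, 1L]; yj <- verts[j, 2L]
    if ((yi > py) != (yj > py)) {
      x_at <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < x_at) inside <- !inside
    }
    j <- i
  }
  inside
}

# even-odd rasterization by looping over every pixel centre
oracle_rasterize <- function(loop_vertices, width, height) {
  v <- loop_vertices
  if (identical(v[1L, ], v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  m <- matrix(FALSE, nrow = height, ncol = width)
  for (j in seq_len(height)) for (i in seq_len(width))
    m[j, i] <- oracle_point_in_polygon(i - 0.5, j - 0.5, v)
  m
}

# DBSCAN by explicit density-reachability closure over the definition:
# cores have >= min_samples eps-neighbours (self included); clusters are
# transitive closures of core-core adjacency plus attached border points
oracle_dbscan <- function(points, eps, min_samples) {
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  d <- as.matrix(dist(points))
  nbr <- d <= eps
  core <- rowSums(nbr) >= min_samples
  # transitive closure of adjacency restricted to cores (Floyd-Warshall style)
  reach <- nbr & outer(core, core, `&`)
  diag(reach) <- core
  for (k in seq_len(n)) if (core[k])
    reach <- reach | (outer(reach[, k], reach[k, ], `&`))
  labels <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    lab <- lab + 1L
    labels[reach[i, ] & core] <- lab
    labels[i] <- lab
  }
  # border points: non-core with a core neighbour; attach to the cluster of
  # the first core neighbour (matches first-come assignment up to relabel)
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    cn <- which(nbr[i, ] & core)
    if (length(cn)) labels[i] <- labels[cn[1L]]
  }
  labels
}

# Compare two DBSCAN labelings up to cluster renaming. Core points must form
# identical partitions and noise must match exactly; border points (whose
# attachment is order-dependent by definition) must in both labelings carry
# the label of some eps-close core point.
same_clustering <- function(a, b, points, eps, min_samples) {
  if (length(a) != length(b)) return(FALSE)
  if (!all((a == 0L) == (b == 0L))) return(FALSE)
  n <- nrow(points)
  if (n == 0L) return(TRUE)
  d <- as.matrix(dist(points))
  nbr <- d <= eps
  core <- rowSums(nbr) >= min_samples
  ac <- a[core]; bc <- b[core]
  if (length(ac)) {
    pairs <- unique(paste(ac, bc))
    if (length(pairs) != length(unique(ac)) ||
        length(pairs) != length(unique(bc))) return(FALSE)
  }
  for (i in which(!core & a != 0L)) {
    cn <- which(nbr[i, ] & core)
    if (!(a[i] %in% a[cn]) || !(b[i] %in% b[cn])) return(FALSE)
  }
  TRUE
}

# brute-force majority consensus: per-pixel count >= n/2
oracle_cria <- function(masks) {
  n <- length(masks)
  h <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  h >= n / 2
}

# exhaustive check that k votes decide the outcome whatever the remaining
# votes are: enumerate every completion over the choice alphabet
oracle_outcome_decided <- function(votes, N, choices) {
  remaining <- N - length(votes)
  winner <- function(v) {
    counts <- sort(table(v), decreasing = TRUE)
    top <- names(counts)[counts == counts[1L]]
    sort(top)[1L]
  }
  base_winner <- winner(votes)
  if (remaining == 0L) return(TRUE)
  grids <- do.call(expand.grid, rep(list(choices), remaining))
  for (r in seq_len(nrow(grids))) {
    full <- c(votes, unlist(grids[r, ], use.names = FALSE))
    if (!identical(winner(full), base_winner)) return(FALSE)
  }
  TRUE
}

random_mask <- function(h, w, p = 0.4) matrix(runif(h * w) < p, h, w)
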