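square_loop <- function(x0, y0, s) {
  rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s),
        c(x0, y0))
}

test_that("stroke closing honours the gap tolerance", {
  closed <- close_polyline(square_loop(0, 0, 2), gap_tolerance = 5)
  expect_s3_class(closed, "closed_loop")
  expect_equal(closed$vertices[1, ], closed$vertices[nrow(closed$vertices), ])

  open_sq <- square_loop(0, 0, 4)[1:4, ]
  open_sq <- rbind(open_sq, c(0, 2))   # ends 2 px from the start
  got <- close_polyline(open_sq, gap_tolerance = 5)
  expect_s3_class(got, "closed_loop")
  expect_equal(got$vertices[nrow(got$vertices), ], got$vertices[1, ])

  far <- close_polyline(open_sq, gap_tolerance = 1)
  expect_s3_class(far, "loop_reject")
  expect_match(far$reason, "gap")

  expect_s3_class(close_polyline(rbind(c(0, 0), c(5, 5)), 10), "loop_reject")
})

test_that("interior rasterization matches the even-odd oracle", {
  # unit-checked square: exactly the four pixels with interior centres
  m <- rasterize_interior(square_loop(0, 0, 2), 4, 4)
  expect_equal(which(m), which(matrix(c(TRUE, TRUE, FALSE, FALSE,
                                        TRUE, TRUE, FALSE, FALSE,
                                        FALSE, FALSE, FALSE, FALSE,
                                        FALSE, FALSE, FALSE, FALSE), 4)))
  expect_equal(sum(m), 4L)

  # zero-area loop
  z <- rbind(c(1, 1), c(3, 1), c(1, 1), c(1, 1))
  expect_equal(sum(rasterize_interior(z, 6, 6)), 0L)

  # concave L-shape against the brute-force point-in-polygon oracle
  L <- rbind(c(0, 0), c(5, 0), c(5, 2), c(2, 2), c(2, 6), c(0, 6), c(0, 0))
  expect_equal(rasterize_interior(L, 8, 8), oracle_rasterize(L, 8, 8))

  # random (including self-intersecting) polygons
  set.seed(55)
  for (i in 1:20) {
    n <- sample(3:9, 1)
    v <- cbind(runif(n, 0, 12), runif(n, 0, 12))
    v <- rbind(v, v[1, ])
    expect_equal(rasterize_interior(v, 12, 12), oracle_rasterize(v, 12, 12),
                 info = paste("polygon", i))
  }
})

test_that("height maps count covering contributors per pixel", {
  m1 <- matrix(FALSE, 6, 6); m1[1:2, 1:2] <- TRUE
  m2 <- matrix(FALSE, 6, 6); m2[5:6, 5:6] <- TRUE
  h <- height_map(list(m1, m2))
  expect_setequal(unique(as.vector(h)), c(0L, 1L))

  nested <- lapply(c(6, 4, 2), function(s) {
    m <- matrix(FALSE, 8, 8); m[seq_len(s) + 1, seq_len(s) + 1] <- TRUE; m
  })
  hn <- height_map(nested)
  expect_setequal(unique(as.vector(hn)), 0:3)
  expect_equal(hn[2, 2], 3L)    # covered by all three nested squares

  same <- replicate(4, m1, simplify = FALSE)
  hs <- height_map(same)
  expect_equal(max(hs), 4L)
  expect_equal(sum(hs == 4L), sum(m1))

  expect_error(height_map(list(m1, matrix(FALSE, 3, 3))), "mismatch")
})

test_that("CRIA keeps pixels covered by half or more volunteers", {
  m1 <- matrix(FALSE, 6, 6); m1[2:4, 2:4] <- TRUE
  expect_equal(cria_consensus(list(m1))$mask, m1)   # N = 1: the interior

  # three 6x6 squares offset by 1 px: consensus where >= 2 agree
  offs <- lapply(0:2, function(o) {
    m <- matrix(FALSE, 12, 12); m[(1:6) + o, (1:6) + o] <- TRUE; m
  })
  cons <- cria_consensus(offs)
  h <- height_map(offs)
  expect_equal(cons$mask, h >= 2)
  expect_equal(cons$agreement, h / 3)

  # even N is inclusive at exactly half: two disjoint masks give their union
  m2 <- matrix(FALSE, 6, 6); m2[5:6, 5:6] <- TRUE
  expect_equal(cria_consensus(list(m1, m2))$mask, m1 | m2)
})

test_that("CRIA equals the per-pixel majority oracle on random mask sets", {
  set.seed(66)
  for (i in 1:100) {
    n <- sample(1:9, 1)
    h <- sample(4:32, 1); w <- sample(4:32, 1)
    masks <- replicate(n, random_mask(h, w), simplify = FALSE)
    cons <- cria_consensus(masks)
    expect_equal(cons$mask, oracle_cria(masks), info = paste("set", i))
    # permutation invariance over contributors
    cons2 <- cria_consensus(masks[sample(n)])
    expect_equal(cons$mask, cons2$mask)
  }
})

test_that("raising the inclusion threshold only shrinks the consensus", {
  set.seed(77)
  masks <- replicate(7, random_mask(16, 16), simplify = FALSE)
  h <- height_map(masks)
  prev <- height_map(masks) >= 0.5 * 7
  for (t in seq(0.5, 1, by = 0.1)) {
    cur <- h >= t * 7
    expect_true(all(prev | !cur))     # cur subset of prev
    prev <- cur
  }
})

test_that("outlier annotations are excluded by IoU against the consensus", {
  good <- replicate(4, {
    m <- matrix(FALSE, 10, 10); m[3:7, 3:7] <- TRUE; m
  }, simplify = FALSE)
  scribble <- matrix(FALSE, 10, 10); scribble[9, 9] <- TRUE
  masks <- c(good, list(scribble))
  names(masks) <- sprintf("u%d", 1:5)
  res <- remove_outlier_annotations(masks, iou_cutoff = 0.3)
  expect_equal(res$excluded, "u5")
  expect_equal(res$n, 4L)
  expect_equal(res$mask, good[[1]])

  same <- remove_outlier_annotations(good[1:3])
  expect_length(same$excluded, 0L)

  # expert mask replaces the provisional consensus as the reference: with an
  # expert matching only the scribble, the four concordant masks are the
  # outliers
  expert <- matrix(FALSE, 10, 10); expert[9, 9] <- TRUE
  res2 <- remove_outlier_annotations(masks, iou_cutoff = 0.3, expert = expert)
  expect_setequal(res2$excluded, sprintf("u%d", 1:4))
  expect_false(attr(res2, "all_excluded"))
  expect_equal(res2$mask, scribble)
})

test_that("boundary extraction is the exact inverse of rasterization", {
  m <- matrix(FALSE, 8, 8); m[3:6, 2:5] <- TRUE
  loops <- extract_consensus_contours(m)
  expect_length(loops, 1L)
  expect_equal(rasterize_loops(loops, 8, 8), m)

  expect_length(extract_consensus_contours(matrix(FALSE, 4, 4)), 0L)

  two <- matrix(FALSE, 10, 10); two[2:3, 2:3] <- TRUE; two[7:9, 6:9] <- TRUE
  loops2 <- extract_consensus_contours(two)
  expect_length(loops2, 2L)
  expect_equal(rasterize_loops(loops2, 10, 10), two)

  # masks with holes and random structure still round-trip exactly
  set.seed(88)
  for (i in 1:20) {
    mm <- random_mask(12, 12, p = 0.45)
    lps <- extract_consensus_contours(mm)
    expect_equal(rasterize_loops(lps, 12, 12), mm, info = paste("mask", i))
  }
})

test_that("expert comparison computes IoU and Dice", {
  a <- matrix(FALSE, 6, 6); a[1:2, 1:3] <- TRUE   # 2x3 rectangle
  b <- matrix(FALSE, 6, 6); b[1:2, 2:4] <- TRUE   # shifted, overlap 2x2
  cmp <- compare_to_expert(a, b)
  expect_equal(cmp$iou, 0.5)
  expect_equal(cmp$dice, 2 / 3)

  same <- compare_to_expert(a, a)
  expect_equal(same$iou, 1)
  expect_equal(same$dice, 1)

  disj <- compare_to_expert(a, matrix(FALSE, 6, 6) | rbind(
    matrix(FALSE, 4, 6), matrix(TRUE, 2, 6)))
  expect_equal(disj$iou, 0)
  expect_equal(disj$dice, 0)

  empty <- compare_to_expert(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3))
  expect_equal(empty$iou, 1)
  expect_equal(empty$dice, 1)

  expect_error(compare_to_expert(a, matrix(FALSE, 3, 3)), "mismatch")
})

test_that("consensus of simulated crowds recovers the truth outline", {
  # study conditions: 5 volunteers, radial jitter sigma = 1 px
  clean <- vapply(1:20, function(seed)
    contour_slice_recovery(seed, volunteer_model())$iou, numeric(1))
  expect_true(all(clean > 0.9), info = paste(round(clean, 3), collapse = " "))

  # one-in-five spam annotations with outlier removal on
  spam <- vapply(1:20, function(seed)
    contour_slice_recovery(seed, volunteer_model(spam_rate = 0.2),
                           outlier_removal = TRUE)$iou, numeric(1))
  expect_true(all(spam > 0.85), info = paste(round(spam, 3), collapse = " "))
})
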