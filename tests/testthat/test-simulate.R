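test_that("phantoms are deterministic and objects stay apart", {
  p1 <- make_phantom(seed = 7)
  p2 <- make_phantom(seed = 7)
  expect_identical(p1$volume$voxels, p2$volume$voxels)
  expect_identical(p1$objects, p2$objects)

  p0 <- make_phantom(n_objects = 0, seed = 1)
  expect_length(p0$objects, 0L)
  expect_equal(dim(p0$volume$voxels), c(24L, 96L, 96L))

  p3 <- make_phantom(n_objects = 3, seed = 2)
  expect_length(p3$objects, 3L)
  cents <- t(vapply(p3$objects, `[[`, numeric(3), "centroid"))
  radii <- vapply(p3$objects, `[[`, numeric(1), "radius")
  for (i in 1:2) for (j in (i + 1):3)
    expect_gt(sqrt(sum((cents[i, ] - cents[j, ])^2)), radii[i] + radii[j])
  # objects fully inside the volume
  expect_true(all(cents[, 3] - radii > 0 & cents[, 3] + radii < 24))
})

test_that("simulated contours reduce to the truth when noiseless", {
  poly <- cbind(x = 20 + 6 * cos(seq(0, 2 * pi, length.out = 25)[-25]),
                y = 20 + 6 * sin(seq(0, 2 * pi, length.out = 25)[-25]))
  quiet <- volunteer_model(contour_jitter_sigma = 0, spam_rate = 0)
  fl <- simulate_contour(poly, quiet, 1, 40, 40, seed = 3)
  v <- fl$vertices
  expect_equal(v[seq_len(nrow(poly)), ], poly, tolerance = 1e-9,
               ignore_attr = TRUE)
  # any appended closure/gap vertex stays within the closure tolerance
  expect_lt(sqrt(sum((v[nrow(v), ] - v[1, ])^2)), 2)

  spammy <- volunteer_model(spam_rate = 1)
  fs <- simulate_contour(poly, spammy, 1, 100, 100, seed = 3)
  bb <- c(range(poly[, 1]), range(poly[, 2]))
  expect_true(all(fs$vertices[, 1] < bb[1] - 2 | fs$vertices[, 1] > bb[2] + 2 |
                  fs$vertices[, 2] < bb[3] - 2 | fs$vertices[, 2] > bb[4] + 2))

  # replay determinism
  f1 <- simulate_contour(poly, volunteer_model(), 2, 40, 40, seed = 9)
  f2 <- simulate_contour(poly, volunteer_model(), 2, 40, 40, seed = 9)
  expect_identical(f1$vertices, f2$vertices)
  # adding a volunteer does not perturb another volunteer's stream
  f3 <- simulate_contour(poly, volunteer_model(n_volunteers = 50), 2, 40, 40,
                         seed = 9)
  expect_identical(f1$vertices, f3$vertices)
})

test_that("simulated marks honour miss, jitter and spurious-rate settings", {
  ph <- make_phantom(n_objects = 3, seed = 4)
  quiet <- volunteer_model(point_jitter_sigma = 0, spam_rate = 0)
  m <- simulate_marks(ph, quiet, 1, seed = 4)
  expect_equal(nrow(m), 3L)
  cents <- t(vapply(ph$objects, `[[`, numeric(3), "centroid"))
  expect_equal(as.matrix(m[, c("x", "y", "z")]), cents, tolerance = 1e-9,
               ignore_attr = TRUE)

  all_miss <- volunteer_model(miss_rate = 1)
  expect_equal(nrow(simulate_marks(ph, all_miss, 1, seed = 4)), 0L)

  # determinism of the Poisson spurious count under the same stream
  noisy <- volunteer_model(spam_rate = 0.5)
  m1 <- simulate_marks(ph, noisy, 2, seed = 5)
  m2 <- simulate_marks(ph, noisy, 2, seed = 5)
  expect_identical(m1, m2)
  # spurious marks stay away from every true object
  spur <- m1[is.na(m1$true_object), , drop = FALSE]
  if (nrow(spur)) {
    for (i in seq_len(nrow(spur)))
      expect_gt(min(sqrt(colSums((t(cents) - unlist(spur[i, c("x", "y", "z")]))^2))),
                max(vapply(ph$objects, `[[`, numeric(1), "radius")))
  }
})

test_that("answer accuracy is honoured exactly and in distribution", {
  model1 <- volunteer_model(answer_accuracy = 1)
  labs <- c("dense", "empty")
  expect_equal(simulate_answers("dense", labs, model1, seed = 1)$choice,
               "dense")
  model0 <- volunteer_model(answer_accuracy = 0)
  for (s in 1:10)
    expect_equal(simulate_answers("dense", labs, model0, 1, seed = s)$choice,
                 "empty")

  # binomial check: empirical accuracy within 3 standard errors
  model <- volunteer_model(answer_accuracy = 0.8)
  hits <- vapply(1:2000, function(s)
    simulate_answers("dense", labs, model, 1, seed = s)$choice == "dense",
    logical(1))
  se <- sqrt(0.8 * 0.2 / 2000)
  expect_lt(abs(mean(hits) - 0.8), 3 * se)
})

test_that("simulated exports round-trip through the parser", {
  cls <- list(
    list(classification_id = "c1", user_name = "u1", subject_id = "s1",
         workflow_id = "wf", workflow_version = "1.0",
         created_at = "2024-01-01T00:00:00Z",
         annotations = list(point_mark("T0", 3.5, 4.25, 1))),
    list(classification_id = "c2", user_name = "u2", subject_id = "s1",
         workflow_id = "wf", workflow_version = "1.0",
         created_at = "2024-01-01T00:01:00Z",
         annotations = list(ellipse_mark("T0", 10, 12, 3, 2, 30, 2))),
    list(classification_id = "c3", user_name = "u3", subject_id = "s2",
         workflow_id = "wf", workflow_version = "1.0",
         created_at = "2024-01-01T00:02:00Z",
         annotations = list(freehand_line("T1", rbind(c(0, 0), c(4, 0),
                                                      c(4, 4), c(0, 0)), 2))),
    list(classification_id = "c4", user_name = "u4", subject_id = "s2",
         workflow_id = "wf", workflow_version = "1.0",
         created_at = "2024-01-01T00:03:00Z",
         annotations = list(answer("T2", "capsid"))))
  p <- file.path(tempdir(), "sim_export.csv")
  write_export(cls, p)
  res <- parse_classifications(p)
  expect_length(res$classifications, 4L)
  expect_equal(nrow(res$rejected), 0L)
  # every annotation variant survives with its payload
  back <- res$classifications
  expect_s3_class(back[[1]]$annotations[[1]], "point_mark")
  expect_equal(back[[1]]$annotations[[1]]$x, 3.5)
  expect_s3_class(back[[2]]$annotations[[1]], "ellipse_mark")
  expect_equal(back[[2]]$annotations[[1]]$ry, 2)
  expect_equal(back[[2]]$annotations[[1]]$angle, 30)
  expect_s3_class(back[[3]]$annotations[[1]], "freehand_line")
  expect_equal(nrow(back[[3]]$annotations[[1]]$vertices), 4L)
  expect_equal(back[[3]]$annotations[[1]]$frame_index, 2L)
  expect_s3_class(back[[4]]$annotations[[1]], "answer")
  expect_equal(back[[4]]$annotations[[1]]$choice, "capsid")

  # header row survives an empty set
  p2 <- file.path(tempdir(), "sim_empty.csv")
  write_export(list(), p2)
  res2 <- parse_classifications(p2)
  expect_length(res2$classifications, 0L)
})
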