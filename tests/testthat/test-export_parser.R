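make_export_fixture <- function(path) {
  rows <- data.frame(
    classification_id = c("c1", "c2"),
    user_name = c("alice", "bob"),
    workflow_id = c("wf1", "wf1"),
    workflow_version = c("1.0", "1.0"),
    created_at = c("2024-01-01T10:00:00Z", "2024-01-01T10:05:00Z"),
    annotations = c(
      '[{"task":"T0","value":{"x":12.5,"y":30.25,"frame":2}}]',
      '[{"task":"T1","value":"capsid"}]'
    ),
    subject_data = c("{}", "{}"),
    subject_ids = c("s1", "s1"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

test_that("well-formed export rows become typed classifications", {
  p <- make_export_fixture(file.path(tempdir(), "exp1.csv"))
  res <- parse_classifications(p)
  expect_length(res$classifications, 2L)
  expect_equal(nrow(res$rejected), 0L)
  a1 <- res$classifications[[1]]$annotations[[1]]
  expect_s3_class(a1, "point_mark")
  expect_equal(c(a1$x, a1$y, a1$frame_index), c(12.5, 30.25, 2))
  a2 <- res$classifications[[2]]$annotations[[1]]
  expect_s3_class(a2, "answer")
  expect_equal(a2$choice, "capsid")
  # raw names are pseudonymised on ingest
  expect_false(any(grepl("alice|bob", vapply(res$classifications,
                                             `[[`, character(1),
                                             "contributor_id"))))
})

test_that("malformed rows are rejected with reasons, never dropped silently", {
  p <- file.path(tempdir(), "exp_bad.csv")
  rows <- utils::read.csv(make_export_fixture(p), stringsAsFactors = FALSE,
                          colClasses = "character")
  rows$annotations[2] <- '[{"task":"T1","value":'   # truncated JSON
  utils::write.csv(rows, p, row.names = FALSE)
  res <- parse_classifications(p)
  expect_length(res$classifications, 1L)
  expect_equal(nrow(res$rejected), 1L)
  expect_equal(res$rejected$classification_id, "c2")
  # lossless modulo rejects
  expect_equal(length(res$classifications) + nrow(res$rejected), 2L)

  # header-only file: empty sequence, empty report
  p2 <- file.path(tempdir(), "exp_empty.csv")
  utils::write.csv(utils::read.csv(make_export_fixture(p2))[0, ], p2,
                   row.names = FALSE)
  res2 <- parse_classifications(p2)
  expect_length(res2$classifications, 0L)
  expect_equal(nrow(res2$rejected), 0L)

  # missing mandatory column is a hard error
  p3 <- file.path(tempdir(), "exp_nocol.csv")
  broken <- utils::read.csv(make_export_fixture(p3),
                            stringsAsFactors = FALSE)
  broken$subject_ids <- NULL
  utils::write.csv(broken, p3, row.names = FALSE)
  expect_error(parse_classifications(p3), "subject_ids")
})

test_that("workflow filtering compares dotted versions numerically", {
  mk <- function(id, wf, ver) structure(
    list(classification_id = id, contributor_id = "c", subject_id = "s",
         workflow_id = wf, workflow_version = ver,
         created_at = "2024-01-01T00:00:00Z",
         annotations = list(answer("T1", "x"))), class = "classification")
  cls <- list(mk("a", "wf1", "1.1"), mk("b", "wf1", "2.3"),
              mk("c", "wf1", "10.1"), mk("d", "wf2", "9.9"))
  kept <- filter_workflow(cls, "wf1", "2.0")$kept
  expect_equal(vapply(kept, `[[`, character(1), "workflow_version"),
               c("2.3", "10.1"))
  # no minimum: identity on the workflow
  expect_length(filter_workflow(cls, "wf1")$kept, 3L)
  expect_length(filter_workflow(cls, "nope", "1.0")$kept, 0L)
  bad <- filter_workflow(list(mk("e", "wf1", "one.two")), "wf1", "1.0")
  expect_length(bad$kept, 0L)
  expect_equal(nrow(bad$rejected), 1L)
})

test_that("subject linking joins on the manifest and reports the unlinked", {
  mk <- function(id, subj) structure(
    list(classification_id = id, contributor_id = "c", subject_id = subj,
         workflow_id = "wf1", workflow_version = "1.0",
         created_at = "2024-01-01T00:00:00Z",
         annotations = list(answer("T1", "x"))), class = "classification")
  manifest <- data.frame(subject_id = c("s1", "s2"), x = c(0L, 8L),
                         y = c(0L, 0L), z = c(2L, 2L),
                         stringsAsFactors = FALSE)
  res <- link_subjects(list(mk("a", "s1"), mk("b", "s2"), mk("c", "s9")),
                       manifest)
  expect_length(res$linked, 2L)
  expect_length(res$unlinked, 1L)
  expect_equal(res$linked[[2]]$subject$x, 8L)
  expect_equal(res$unlinked[[1]]$subject_id, "s9")

  res2 <- link_subjects(list(mk("a", "s1")), manifest[0, ])
  expect_length(res2$linked, 0L)
  expect_length(res2$unlinked, 1L)

  expect_error(link_subjects(list(mk("a", "s1")),
                             manifest[c(1, 1), ]), "duplicate subject_id")
})

test_that("contributor deduplication keeps the earliest vote", {
  mk <- function(id, who, when) structure(
    list(classification_id = id, contributor_id = who, subject_id = "s1",
         workflow_id = "wf1", workflow_version = "1.0", created_at = when,
         annotations = list(answer("T1", "x"))), class = "classification")
  res <- deduplicate_contributor(list(
    mk("c2", "u1", "2024-01-01T11:00:00Z"),
    mk("c1", "u1", "2024-01-01T10:00:00Z"),
    mk("c3", "u2", "2024-01-01T12:00:00Z")))
  expect_length(res$kept, 2L)
  expect_setequal(vapply(res$kept, `[[`, character(1), "classification_id"),
                  c("c1", "c3"))
  expect_equal(res$duplicates[[1]]$classification_id, "c2")

  # identical timestamps: lowest classification_id wins
  res2 <- deduplicate_contributor(list(
    mk("c9", "u1", "2024-01-01T10:00:00Z"),
    mk("c2", "u1", "2024-01-01T10:00:00Z")))
  expect_equal(res2$kept[[1]]$classification_id, "c2")

  # all distinct: identity
  res3 <- deduplicate_contributor(list(
    mk("a", "u1", "t1"), mk("b", "u2", "t1")))
  expect_length(res3$kept, 2L)
})

test_that("pseudonyms are stable, salted, and distinct for anonymous rows", {
  expect_identical(pseudonymize("alice", "c1"), pseudonymize("alice", "c2"))
  expect_false(identical(pseudonymize("alice", "c1"),
                         pseudonymize("bob", "c1")))
  expect_false(identical(pseudonymize("alice", "c1", salt = "a"),
                         pseudonymize("alice", "c1", salt = "b")))
  expect_false(identical(pseudonymize("", "c1"), pseudonymize("", "c2")))
  expect_false(identical(pseudonymize(NA_character_, "c1"),
                         pseudonymize(NA_character_, "c2")))
})
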