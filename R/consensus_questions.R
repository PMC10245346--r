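#' Retirement rule
#'
#' The retirement limit `N` is the number of classifications collected per
#' subject before it is withdrawn. With `early_enabled`, a subject retires as
#' soon as the votes already cast determine the majority outcome no matter
#' how the remaining votes fall.
#'
#' @param retirement_limit positive integer `N`.
#' @param early_enabled allow early retirement.
#' @return a `retirement_rule` object.
#' @export
retirement_rule <- function(retirement_limit, early_enabled = TRUE) {
  N <- as.integer(retirement_limit)
  if (is.na(N) || N < 1L) stop("retirement_limit must be >= 1")
  structure(list(retirement_limit = N, early_enabled = isTRUE(early_enabled)),
            class = "retirement_rule")
}

#' Majority vote over question answers
#'
#' The winning choice is the modal answer; ties are broken by the
#' lexicographically smallest choice and flagged, so analysts can exclude
#' tied subjects.
#'
#' @param answers non-empty character vector of choices.
#' @return a `question_consensus`: list with `winning_choice`,
#'   `vote_counts` (named integer vector), `n_votes`,
#'   `agreement_fraction` and `tie`.
#' @export
majority_vote <- function(answers) {
  answers <- as.character(answers)
  if (length(answers) == 0L) stop("majority_vote needs at least one answer")
  counts <- table(answers)
  counts <- counts[order(names(counts))]      # lexicographic
  top <- max(counts)
  winners <- names(counts)[counts == top]
  structure(
    list(
      winning_choice = winners[1L],
      vote_counts = stats::setNames(as.integer(counts), names(counts)),
      n_votes = length(answers),
      agreement_fraction = top / length(answers),
      tie = length(winners) > 1L
    ),
    class = "question_consensus"
  )
}

#' @export
print.question_consensus <- function(x, ...) {
  cat(sprintf("<question_consensus> '%s' (%d/%d = %.2f%s)\n",
              x$winning_choice, max(x$vote_counts), x$n_votes,
              x$agreement_fraction, if (x$tie) ", tie" else ""))
  invisible(x)
}

#' Can a subject retire early?
#'
#' TRUE exactly when no completion of the remaining votes can change the
#' modal choice: the leader's margin over the runner-up must exceed the
#' number of votes still to be cast, `(top - second) > (N - cast)`. With a
#' retirement limit of five, three identical classifications suffice — the
#' final two cannot alter the outcome.
#'
#' @param votes_so_far character vector of choices cast so far.
#' @param rule a [retirement_rule()].
#' @return logical.
#' @export
can_retire_early <- function(votes_so_far, rule) {
  stopifnot(inherits(rule, "retirement_rule"))
  N <- rule$retirement_limit
  n <- length(votes_so_far)
  if (n > N) stop(sprintf("%d votes exceed the retirement limit %d", n, N))
  if (n == 0L) return(FALSE)
  counts <- sort(table(as.character(votes_so_far)), decreasing = TRUE)
  top <- counts[1L]
  second <- if (length(counts) > 1L) counts[2L] else 0L
  unname((top - second) > (N - n))
}

#' Fewest identical votes that guarantee early retirement
#'
#' Smallest `k` such that `k` identical opening votes already decide the
#' outcome under retirement limit `N`; for unanimous openings this is
#' `floor(N / 2) + 1` (e.g. 3 of 5).
#'
#' @param N retirement limit.
#' @param n_choices number of available choices (`>= 2`; the value does not
#'   affect the unanimous-opening bound but is validated for clarity).
#' @return integer `k`.
#' @export
earliest_guaranteed_retirement <- function(N, n_choices = 2L) {
  if (N < 1L) stop("N must be >= 1")
  if (n_choices < 2L) stop("n_choices must be >= 2")
  rule <- retirement_rule(N)
  for (k in seq_len(N)) {
    if (can_retire_early(rep("a", k), rule)) return(k)
  }
  N
}

#' Aggregate question answers per subject
#'
#' One consensus row per subject that has votes on `task_id`; subjects with
#' none are omitted. Classifications should be parsed and deduplicated
#' first. Votes are ordered by `created_at`; the first `N` count toward the
#' consensus, and `retired_early` records whether some proper prefix already
#' decided the outcome (in which case the remaining votes cannot change it).
#'
#' @param classifications list of `classification` objects.
#' @param task_id question task to aggregate.
#' @param rule a [retirement_rule()].
#' @return data frame with columns `subject_id`, `task_id`, `winning_choice`,
#'   `n_votes`, `agreement_fraction`, `tie`, `retired_early`, `retired_at`.
#' @export
aggregate_question_table <- function(classifications, task_id, rule) {
  stopifnot(inherits(rule, "retirement_rule"))
  rows <- list()
  subj <- vapply(classifications, `[[`, character(1), "subject_id")
  for (s in unique(subj)) {
    cls <- classifications[subj == s]
    ts <- vapply(cls, `[[`, character(1), "created_at")
    cls <- cls[order(ts)]
    votes <- character(0)
    for (cl in cls) {
      for (a in cl$annotations)
        if (inherits(a, "answer") && identical(a$task_id, task_id))
          votes <- c(votes, a$choice)
    }
    if (length(votes) == 0L) next
    used <- utils::head(votes, rule$retirement_limit)
    cons <- majority_vote(used)
    retired_at <- NA_integer_
    if (rule$early_enabled) {
      for (k in seq_along(used))
        if (can_retire_early(used[seq_len(k)], rule)) { retired_at <- k; break }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = s, task_id = task_id,
      winning_choice = cons$winning_choice, n_votes = cons$n_votes,
      agreement_fraction = cons$agreement_fraction, tie = cons$tie,
      retired_early = !is.na(retired_at) && retired_at < rule$retirement_limit,
      retired_at = retired_at, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(subject_id = character(0), task_id = character(0),
                      winning_choice = character(0), n_votes = integer(0),
                      agreement_fraction = numeric(0), tie = logical(0),
                      retired_early = logical(0), retired_at = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
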