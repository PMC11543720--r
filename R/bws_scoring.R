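#' Pairwise wins implied by one best-worst choice
#'
#' A best-worst judgment on a trial of k items implies 2k - 3 ordered pairs:
#' the best item beats every other item (k - 1 pairs) and every remaining
#' item beats the worst (k - 2 further pairs, the best-vs-worst pair counted
#' once). The unchosen middle items are never compared with each other.
#'
#' @param items character vector of the trial's items.
#' @param best,worst the chosen most-positive and most-negative item.
#' @return Two-column character matrix with columns `winner`, `loser`.
#' @export
implied_pairs <- function(items, best, worst) {
  if (best == worst) stop("best and worst must differ")
  if (!(best %in% items) || !(worst %in% items)) stop("best/worst not in trial items")
  others <- setdiff(items, best)
  middles <- setdiff(others, worst)
  cbind(winner = c(rep(best, length(others)), middles),
        loser = c(others, rep(worst, length(middles))))
}

#' Value-learning configuration
#'
#' Tuning constants of the Elo-style scorer: items start at `initial_value`;
#' each of `n_passes` passes visits all implied pairs in a fresh seeded
#' random order and applies the logistic update with learning rate decaying
#' linearly from `eta_start` to `eta_end`; the reported score is the mean
#' over the last `average_fraction` of passes.
#'
#' @param initial_value starting score for every item (0-1 scale).
#' @param n_passes number of passes over the implied pairs.
#' @param eta_start,eta_end linear learning-rate schedule endpoints.
#' @param scale Elo logistic scale `s` in `p = 1/(1 + 10^((v_l - v_w)/s))`.
#' @param average_fraction trailing fraction of passes averaged into the
#'   final score.
#' @return List of class `vl_config`.
#' @export
vl_config <- function(initial_value = 0.5, n_passes = 100L,
                      eta_start = 0.1, eta_end = 0.001, scale = 0.4,
                      average_fraction = 0.1) {
  stopifnot(n_passes >= 1L, eta_start > 0, eta_end > 0,
            average_fraction > 0, average_fraction <= 1)
  structure(list(initial_value = initial_value, n_passes = as.integer(n_passes),
                 eta_start = eta_start, eta_end = eta_end, scale = scale,
                 average_fraction = average_fraction),
            class = "vl_config")
}

#' Score best-worst choices by value learning
#'
#' Converts discrete best-worst judgments into continuous value scores with
#' an Elo-style iterative algorithm: every choice record contributes its
#' [implied_pairs()], and for each pass the pairs are visited in seeded
#' random order, moving the winner's score up and the loser's down by
#' `eta * (1 - p)` where `p` is the logistic expected-win probability. Catch
#' trials (real-word compliance checks) are excluded from scoring input.
#' Scores are on an arbitrary interval scale; downstream use is through
#' correlation and regression, which are unaffected by affine rescaling.
#'
#' @param records a choice data.frame (see [simulate_raters()] or
#'   [read_choices_tsv()]): columns `participant_id`, `trial_id`, `is_catch`,
#'   `item1..itemK`, `best`, `worst`.
#' @param config a [vl_config()].
#' @param seed integer seed controlling pair-visit order.
#' @return Object of class `value_scores`: data.frame with columns `item`,
#'   `score`, `n_best`, `n_worst`, `n_appearances`, plus the config as an
#'   attribute.
#' @export
value_learning <- function(records, config = vl_config(), seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(config, "vl_config"))
  recs <- records[!records$is_catch, , drop = FALSE]
  if (nrow(recs) == 0L) stop("no non-catch records to score")
  item_cols <- grep("^item[0-9]+$", names(recs), value = TRUE)
  pair_list <- lapply(seq_len(nrow(recs)), function(i) {
    implied_pairs(as.character(recs[i, item_cols]), recs$best[i], recs$worst[i])
  })
  pairs <- do.call(rbind, pair_list)
  items <- sort(unique(as.vector(as.matrix(recs[, item_cols]))))
  winner <- match(pairs[, "winner"], items)
  loser <- match(pairs[, "loser"], items)
  np <- length(winner)
  v <- rep(config$initial_value, length(items))
  etas <- seq(config$eta_start, config$eta_end, length.out = config$n_passes)
  n_avg <- max(1L, ceiling(config$average_fraction * config$n_passes))
  acc <- numeric(length(items))
  set.seed(seed)
  for (pass in seq_len(config$n_passes)) {
    ord <- sample.int(np)
    v <- cpp_value_learning_pass(v, winner, loser, ord, etas[pass], config$scale)
    if (pass > config$n_passes - n_avg) acc <- acc + v
  }
  score <- acc / n_avg
  app <- table(factor(as.vector(as.matrix(recs[, item_cols])), levels = items))
  out <- data.frame(item = items, score = score,
                    n_best = tabulate(match(recs$best, items), length(items)),
                    n_worst = tabulate(match(recs$worst, items), length(items)),
                    n_appearances = as.integer(app),
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  class(out) <- c("value_scores", "data.frame")
  out
}

#' @export
print.value_scores <- function(x, ...) {
  cat(sprintf("Value scores for %d items (range %.3f .. %.3f)\n",
              nrow(x), min(x$score), max(x$score)))
  invisible(x)
}

#' Exclude non-compliant participants by catch-trial errors
#'
#' A catch error is choosing a best different from the trial's designated
#' positive word, or a worst different from its designated negative word
#' (each miss counts separately). Participants with more than `max_errors`
#' errors are removed with all their records.
#'
#' @param records choice data.frame including catch records (`is_catch`).
#' @param catch_keys named list mapping catch `trial_id` to
#'   `list(positive=, negative=)`; defaults to the `catch_keys` attribute
#'   that [assign_sessions()] stores and [simulate_raters()] forwards.
#' @param max_errors tolerated error count (default 1: "more than once"
#'   excludes).
#' @return List with `records` (kept rows), `excluded` (participant ids) and
#'   `errors` (per-participant error counts).
#' @export
exclude_noncompliant <- function(records, catch_keys = attr(records, "catch_keys"),
                                 max_errors = 1L) {
  if (is.null(catch_keys) || length(catch_keys) == 0L)
    stop("catch_keys required (no catch design attached to records)")
  catch <- records[records$is_catch, , drop = FALSE]
  participants <- unique(records$participant_id)
  no_catch <- setdiff(participants, unique(catch$participant_id))
  if (length(no_catch))
    stop(sprintf("participants without catch records: %s",
                 paste(head(no_catch, 5L), collapse = ", ")))
  errs <- vapply(participants, function(p) {
    rows <- catch[catch$participant_id == p, , drop = FALSE]
    sum(vapply(seq_len(nrow(rows)), function(i) {
      key <- catch_keys[[rows$trial_id[i]]]
      if (is.null(key)) stop(sprintf("unknown catch trial id '%s'", rows$trial_id[i]))
      (rows$best[i] != key$positive) + (rows$worst[i] != key$negative)
    }, numeric(1)))
  }, numeric(1))
  excluded <- participants[errs > max_errors]
  kept <- records[!(records$participant_id %in% excluded), , drop = FALSE]
  attr(kept, "catch_keys") <- catch_keys
  list(records = kept, excluded = excluded,
       errors = setNames(errs, participants))
}

#' Split-half reliability of value-learning scores
#'
#' Randomly splits participants into two halves, scores each half separately
#' with [value_learning()], and returns the Pearson correlation of the two
#' score vectors over the items present in both halves.
#'
#' @inheritParams value_learning
#' @param records non-catch-contaminated choice records (catch rows are
#'   ignored by the scorer anyway).
#' @return List with `r`, `n_items` (shared items correlated), and the two
#'   `value_scores` objects.
#' @export
split_half_reliability <- function(records, config = vl_config(), seed) {
  if (missing(seed)) stop("seed is required")
  participants <- unique(records$participant_id)
  if (length(participants) < 2L) stop("need at least two participants")
  set.seed(seed)
  half1 <- sample(participants, floor(length(participants) / 2))
  r1 <- records[records$participant_id %in% half1, , drop = FALSE]
  r2 <- records[!(records$participant_id %in% half1), , drop = FALSE]
  s1 <- value_learning(r1, config, seed = seed + 1L)
  s2 <- value_learning(r2, config, seed = seed + 2L)
  shared <- intersect(s1$item, s2$item)
  dropped <- length(union(s1$item, s2$item)) - length(shared)
  if (dropped > 0L)
    message(sprintf("split_half_reliability: %d items present in only one half dropped", dropped))
  list(r = cor(s1$score[match(shared, s1$item)], s2$score[match(shared, s2$item)]),
       n_items = length(shared), scores1 = s1, scores2 = s2)
}

#' Read / write best-worst choice records as TSV
#'
#' Columns: `participant_id`, `trial_id`, `is_catch`, `item1..itemK`,
#' `best`, `worst`.
#'
#' @param records choice data.frame.
#' @param path file path.
#' @export
write_choices_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_choices_tsv
#' @export
read_choices_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write value scores as CSV
#'
#' @param scores a `value_scores` data.frame.
#' @param path file path.
#' @export
write_scores_csv <- function(scores, path) {
  write.table(scores, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
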