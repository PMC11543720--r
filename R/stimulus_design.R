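#' Filter pseudoword candidates
#'
#' Marks candidates that must not enter a stimulus pool: strings for which
#' the embedding table holds a dedicated whole-word vector (the model has
#' "seen" them, e.g. through corpus typos), duplicates after the first
#' occurrence, and any strings on a manual exclusion list.
#'
#' @param strings character vector of candidate pseudowords.
#' @param embeddings an [embedding_table()] used for the whole-word check;
#'   `NULL` skips that check.
#' @param manual_exclusions character vector of strings excluded by hand
#'   (unreadable items, pseudocompounds, ...).
#' @param require_composable also exclude strings none of whose 4-grams the
#'   table covers (pretrained tables have near-complete coverage; synthetic
#'   ones need not).
#' @return A data.frame of class `candidate_pool` with columns `string` and
#'   `excluded` (`NA` for eligible entries, otherwise one of
#'   `"whole_word_vector"`, `"duplicate"`, `"manual"`, `"not_composable"`).
#' @export
filter_candidates <- function(strings, embeddings = NULL,
                              manual_exclusions = character(0),
                              require_composable = !is.null(embeddings)) {
  excluded <- rep(NA_character_, length(strings))
  if (!is.null(embeddings)) {
    has_vec <- vapply(strings, has_whole_word_vector, logical(1), table = embeddings)
    excluded[has_vec] <- "whole_word_vector"
    if (require_composable) {
      composable <- vapply(strings, function(s) {
        any(vapply(extract_ngrams(s), function(g)
          !is.null(get0(g, envir = embeddings$ngram_vectors, inherits = FALSE)),
          logical(1)))
      }, logical(1))
      excluded[!composable & is.na(excluded)] <- "not_composable"
    }
  }
  dup <- duplicated(strings)
  excluded[dup & is.na(excluded)] <- "duplicate"
  excluded[strings %in% manual_exclusions & is.na(excluded)] <- "manual"
  out <- data.frame(string = strings, excluded = excluded, stringsAsFactors = FALSE)
  class(out) <- c("candidate_pool", "data.frame")
  out
}

#' @export
print.candidate_pool <- function(x, ...) {
  n_ok <- sum(is.na(x$excluded))
  cat(sprintf("Candidate pool: %d strings, %d eligible\n", nrow(x), n_ok))
  if (n_ok < nrow(x)) print(table(x$excluded))
  invisible(x)
}

#' Sample stimuli with uniform predicted-valence coverage
#'
#' Divides the predicted-valence range of the eligible pool into
#' `n_slices` equal-width intervals and draws items at random within each
#' slice so that the selected set covers the valence range as uniformly as
#' possible. When a slice holds fewer items than its quota the deficit is
#' topped up from the nearest slices that still have items.
#'
#' @param pool a [filter_candidates()] result, or a data.frame with columns
#'   `string` and (`excluded` optional).
#' @param predicted named numeric vector or a numeric vector aligned with
#'   `pool$string`: the predicted valence of each candidate.
#' @param n_target number of stimuli to select.
#' @param n_slices number of equal-width valence slices (default 25).
#' @param exclusion_list additional strings never sampled.
#' @param seed integer seed; the draw is fully reproducible.
#' @return Character vector of `n_target` selected strings, with a
#'   `slice_counts` attribute giving per-slice selection counts.
#' @export
stratified_uniform_sample <- function(pool, predicted, n_target,
                                      n_slices = 25L,
                                      exclusion_list = character(0), seed) {
  if (missing(seed)) stop("seed is required")
  strings <- pool$string
  if (length(predicted) != length(strings)) stop("predicted misaligned with pool")
  elig <- (if ("excluded" %in% names(pool)) is.na(pool$excluded) else TRUE) &
    !(strings %in% exclusion_list)
  strings <- strings[elig]
  pv <- as.numeric(predicted)[elig]
  if (n_target > length(strings))
    stop(sprintf("n_target (%d) exceeds eligible pool (%d)", n_target, length(strings)))
  if (length(unique(pv)) < 2L) stop("pool spans a single predicted valence")
  if (n_target == length(strings)) {
    out <- strings
    attr(out, "slice_counts") <- table(slice_of(pv, pv, n_slices))
    return(out)
  }
  slice <- slice_of(pv, pv, n_slices)
  quota <- rep(n_target %/% n_slices, n_slices)
  extra <- n_target %% n_slices
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  avail <- tabulate(slice, nbins = n_slices)
  # Shift quota that exhausted slices cannot meet onto the nearest slices
  # with spare capacity (the top-up rule).
  take <- pmin(quota, avail)
  deficit <- sum(quota) - sum(take)
  while (deficit > 0L) {
    spare <- avail - take
    short <- which(quota > take)
    donor_order <- order(vapply(seq_len(n_slices), function(s)
      if (spare[s] > 0L) min(abs(s - short)) else Inf, numeric(1)))
    d <- donor_order[1L]
    take[d] <- take[d] + 1L  # one at a time keeps the top-up spread flat
    deficit <- deficit - 1L
  }
  set.seed(seed)
  picked <- unlist(lapply(seq_len(n_slices), function(s) {
    in_s <- which(slice == s)
    if (take[s] == 0L || length(in_s) == 0L) return(character(0))
    strings[resample(in_s, take[s])]
  }), use.names = FALSE)
  attr(picked, "slice_counts") <- as.table(setNames(take, seq_len(n_slices)))
  picked
}

# sample() misbehaves on length-1 x; this is the standard guard.
resample <- function(x, size) x[sample.int(length(x), size)]

slice_of <- function(x, ref, n_slices) {
  rng <- range(ref)
  breaks <- seq(rng[1L], rng[2L], length.out = n_slices + 1L)
  pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_slices)
}

#' Build a balanced best-worst trial set
#'
#' Assigns items to trials so that every item appears exactly `appearances`
#' times and no trial contains the same item twice. The construction runs
#' `appearances` rounds: each round is a seeded random permutation of the
#' items chunked into trials, followed by a repair pass that swaps members
#' across trials until no trial holds duplicates. This satisfies the design
#' constraints of the classic balanced best-worst ("Latin-square style")
#' layouts used for large rating studies.
#'
#' @param items character vector of distinct item strings.
#' @param appearances times each item must appear (default 30).
#' @param trial_size items per trial (default 6).
#' @param seed integer seed.
#' @return Object of class `trial_set`: list with `trials` (character matrix,
#'   one row per trial), `appearances`, `trial_size`.
#' @export
build_trial_set <- function(items, appearances = 30L, trial_size = 6L, seed) {
  if (missing(seed)) stop("seed is required")
  items <- as.character(items)
  n <- length(items)
  if (anyDuplicated(items)) stop("items must be distinct")
  if (n < trial_size) stop("fewer items than the trial size")
  total <- n * appearances
  if (total %% trial_size != 0L) {
    k <- appearances
    while ((n * k) %% trial_size != 0L) k <- k + 1L
    stop(sprintf("items x appearances (%d) not divisible by trial size %d; smallest compatible appearances is %d",
                 total, trial_size, k))
  }
  n_trials <- total %/% trial_size
  set.seed(seed)
  seq_items <- unlist(lapply(seq_len(appearances), function(i) sample.int(n)),
                      use.names = FALSE)
  trials <- matrix(seq_items, nrow = n_trials, ncol = trial_size, byrow = TRUE)
  trials <- repair_trial_duplicates(trials)
  trials_chr <- matrix(items[trials], nrow = n_trials)
  structure(list(trials = trials_chr, appearances = as.integer(appearances),
                 trial_size = as.integer(trial_size)),
            class = "trial_set")
}

# Swap duplicated members with entries of other trials, never breaking the
# exact appearance counts (swaps permute positions only).
repair_trial_duplicates <- function(trials) {
  n_trials <- nrow(trials)
  has_dup <- function(row) anyDuplicated(row) > 0L
  for (pass in 1:100) {
    bad <- which(apply(trials, 1L, has_dup))
    if (length(bad) == 0L) return(trials)
    for (t in bad) {
      row <- trials[t, ]
      dup_pos <- which(duplicated(row))
      for (j in dup_pos) {
        candidates <- sample.int(n_trials)
        done <- FALSE
        for (o in candidates) {
          if (o == t) next
          for (jj in seq_len(ncol(trials))) {
            a <- trials[t, j]; b <- trials[o, jj]
            if (b %in% trials[t, ]) next
            if (a %in% trials[o, -jj]) next
            trials[t, j] <- b; trials[o, jj] <- a
            done <- TRUE
            break
          }
          if (done) break
        }
      }
    }
  }
  if (any(apply(trials, 1L, has_dup)))
    stop("could not repair within-trial duplicates; trial size may be too close to item count")
  trials
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Trial set: %d trials of %d items, %d appearances per item (%d items)\n",
              nrow(x$trials), x$trial_size, x$appearances, length(unique(as.vector(x$trials)))))
  invisible(x)
}

#' Build a catch trial
#'
#' A known-answer trial: one clearly positive word, one clearly negative
#' word, and neutral fillers. Raters who miss the designated best/worst too
#' often are excluded as non-compliant.
#'
#' @param positive,negative the designated best / worst real words.
#' @param fillers neutral filler words (`trial_size - 2` of them).
#' @return Object of class `catch_trial` with `items`, `positive`, `negative`.
#' @export
catch_trial <- function(positive, negative, fillers) {
  items <- c(positive, fillers, negative)
  if (anyDuplicated(items)) stop("catch trial items must be distinct")
  structure(list(items = items, positive = positive, negative = negative),
            class = "catch_trial")
}

#' Partition trials into rater sessions
#'
#' Splits the experimental trials of a [build_trial_set()] result into
#' disjoint sessions of `trials_per_participant` trials, appends every catch
#' trial to every session, and randomizes within-session presentation order.
#' When the trial count is not a multiple of the session length the final
#' session is short (rather than padding with repeated trials).
#'
#' @param trial_set a `trial_set`.
#' @param trials_per_participant experimental trials per session.
#' @param catch list of [catch_trial()] objects shown to every participant.
#' @param seed integer seed.
#' @return List of class `session_set`; each element is a data.frame with
#'   columns `trial_id`, `is_catch`, and `item1..itemK`.
#' @export
assign_sessions <- function(trial_set, trials_per_participant, catch = list(),
                            seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(trial_set, "trial_set"))
  trials <- trial_set$trials
  n_trials <- nrow(trials)
  n_sessions <- ceiling(n_trials / trials_per_participant)
  set.seed(seed)
  ord <- sample.int(n_trials)
  sizes <- rep(trials_per_participant, n_sessions)
  if (n_trials %% trials_per_participant != 0L)
    sizes[n_sessions] <- n_trials %% trials_per_participant
  starts <- cumsum(c(0L, sizes[-n_sessions]))
  k <- trial_set$trial_size
  for (ct in catch) if (length(ct$items) != k)
    stop("catch trial size differs from experimental trial size")
  sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    idx <- ord[(starts[s] + 1L):(starts[s] + sizes[s])]
    exp_rows <- data.frame(trial_id = paste0("t", idx), is_catch = FALSE,
                           stringsAsFactors = FALSE)
    exp_items <- trials[idx, , drop = FALSE]
    catch_rows <- NULL
    if (length(catch)) {
      catch_rows <- data.frame(trial_id = paste0("catch", seq_along(catch)),
                               is_catch = TRUE, stringsAsFactors = FALSE)
      catch_items <- do.call(rbind, lapply(catch, function(ct) ct$items))
      exp_items <- rbind(exp_items, catch_items)
      exp_rows <- rbind(exp_rows, catch_rows)
    }
    colnames(exp_items) <- paste0("item", seq_len(k))
    df <- cbind(exp_rows, as.data.frame(exp_items, stringsAsFactors = FALSE))
    sessions[[s]] <- df[sample.int(nrow(df)), , drop = FALSE]
    rownames(sessions[[s]]) <- NULL
  }
  names(sessions) <- paste0("p", seq_len(n_sessions))
  catch_keys <- list()
  if (length(catch))
    catch_keys <- setNames(lapply(catch, function(ct)
      list(positive = ct$positive, negative = ct$negative)),
      paste0("catch", seq_along(catch)))
  structure(sessions, class = "session_set", catch_keys = catch_keys)
}

#' @export
print.session_set <- function(x, ...) {
  n_catch <- sum(x[[1L]]$is_catch)
  cat(sprintf("Session set: %d sessions, %d trials each (incl. %d catch trials)\n",
              length(x), nrow(x[[1L]]), n_catch))
  invisible(x)
}

#' Write trials or sessions as TSV
#'
#' One row per trial: `session_id`, `trial_index`, `is_catch`,
#' `item1..itemK`.
#'
#' @param sessions a `session_set`.
#' @param path output file.
#' @export
write_sessions_tsv <- function(sessions, path) {
  rows <- lapply(names(sessions), function(sid) {
    df <- sessions[[sid]]
    cbind(data.frame(session_id = sid, trial_index = seq_len(nrow(df))), df)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
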