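#' Simulation configuration for the synthetic pipeline
#'
#' Bundles every constant of the synthetic-data generators: lexicon size and
#' word shape, the planted letter-level and embedding-dimension effects on
#' valence, rating noise, the rater noise model and the compliance rate. All
#' generators are pure functions of this config (the seed is mandatory), so
#' identical configs reproduce byte-identical data.
#'
#' @param n_words lexicon size.
#' @param word_length integer range (min, max) of word lengths.
#' @param letter_effect_sd SD of the per-letter valence effects (rating
#'   points per occurrence); 0 plants no letter signal.
#' @param dimension_effect_sd SD of the embedding-dimension contribution to
#'   valence (rating points); 0 plants no semantic signal.
#' @param n_dims embedding dimensionality.
#' @param noise_sd SD of the residual rating noise (rating points).
#' @param valence_anchor scale midpoint the effects are added to.
#' @param rater_noise Gumbel scale of the simulated raters' utility noise,
#'   in latent-valence units; `NULL` defers to 0.5 x SD of the latent values
#'   at simulation time.
#' @param compliance_rate probability that a simulated participant performs
#'   the task rather than answering uniformly at random.
#' @param letter_freqs optional length-26 sampling weights for letters
#'   (default uniform).
#' @param seed integer seed (mandatory; there is no silent entropy).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_words = 5000L, word_length = c(3L, 8L),
                       letter_effect_sd = 0.4, dimension_effect_sd = 0,
                       n_dims = 300L, noise_sd = 0.5, valence_anchor = 5,
                       rater_noise = NULL, compliance_rate = 0.86,
                       letter_freqs = NULL, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_words >= 1L, letter_effect_sd >= 0, dimension_effect_sd >= 0,
            noise_sd >= 0, compliance_rate >= 0, compliance_rate <= 1,
            length(word_length) == 2L, word_length[1L] >= 1L)
  structure(list(n_words = as.integer(n_words),
                 word_length = as.integer(word_length),
                 letter_effect_sd = letter_effect_sd,
                 dimension_effect_sd = dimension_effect_sd,
                 n_dims = as.integer(n_dims), noise_sd = noise_sd,
                 valence_anchor = valence_anchor, rater_noise = rater_noise,
                 compliance_rate = compliance_rate,
                 letter_freqs = letter_freqs, seed = as.integer(seed)),
            class = "sim_config")
}

rgumbel <- function(n, scale) {
  if (scale == 0) return(numeric(n))
  -scale * log(-log(runif(n)))
}

random_words <- function(n, len_range, freqs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freqs)) freqs <- rep(1, 26)
  words <- character(0)
  while (length(words) < n) {
    lens <- sample(seq(len_range[1L], len_range[2L]), n, replace = TRUE)
    new <- vapply(lens, function(L)
      paste(sample(ALPHABET, L, replace = TRUE, prob = freqs), collapse = ""),
      character(1))
    words <- unique(c(words, new))
  }
  words[seq_len(n)]
}

#' Generate a synthetic lexicon with planted valence structure
#'
#' Draws random letter strings and assigns each a latent valence
#' `anchor + sum(letter effects x letter counts) + dimension term + noise`,
#' clipped to the 1-9 rating scale. The letter effects are Gaussian with SD
#' `letter_effect_sd`; when `dimension_effect_sd > 0` an embedding table is
#' generated over the lexicon's 4-grams and a planted weight vector makes
#' the words' composed-vector projections carry valence signal of that SD.
#' All planted quantities are returned so recovery can be tested.
#'
#' @param config a [sim_config()].
#' @return List with `lexicon` (a [clean_lexicon()]), `letter_effects`
#'   (named length-26 vector), `latent` (per-word latent valence before
#'   clipping), `embeddings` (an [embedding_table()] or `NULL`),
#'   `dim_weights` (planted projection weights or `NULL`).
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  words <- random_words(config$n_words, config$word_length, config$letter_freqs)
  letter_effects <- setNames(rnorm(26, 0, config$letter_effect_sd), ALPHABET)
  counts <- t(vapply(words, letter_counts, integer(26)))
  letter_term <- drop(counts %*% letter_effects)
  embeddings <- NULL
  dim_weights <- NULL
  dim_term <- 0
  if (config$dimension_effect_sd > 0 && config$n_dims > 0) {
    emb <- build_synthetic_embeddings(words, config$n_dims)
    embeddings <- emb$table
    dim_weights <- rnorm(config$n_dims)
    dim_weights <- dim_weights / sqrt(sum(dim_weights^2))
    proj <- drop(emb$word_matrix %*% dim_weights)
    dim_term <- config$dimension_effect_sd * (proj - mean(proj)) / sd(proj)
  }
  latent <- config$valence_anchor + letter_term + dim_term +
    rnorm(length(words), 0, config$noise_sd)
  valence <- pmin(pmax(latent, 1), 9)
  lex <- data.frame(word = words, valence = valence, stringsAsFactors = FALSE)
  class(lex) <- c("clean_lexicon", "data.frame")
  list(lexicon = lex, letter_effects = letter_effects, latent = latent,
       embeddings = embeddings, dim_weights = dim_weights)
}

# Independent Gaussian vectors for every 4-gram occurring in `words`;
# whole-word vectors are the exact 4-gram sums, so subword composition
# reproduces them by construction.
build_synthetic_embeddings <- function(words, n_dims) {
  grams <- unique(unlist(lapply(words, extract_ngrams), use.names = FALSE))
  G <- matrix(rnorm(length(grams) * n_dims), nrow = length(grams),
              dimnames = list(grams, NULL))
  word_matrix <- t(vapply(words, function(w) {
    colSums(G[extract_ngrams(w), , drop = FALSE])
  }, numeric(n_dims)))
  rownames(word_matrix) <- words
  list(table = embedding_table(ngrams = G, words = word_matrix),
       word_matrix = word_matrix)
}

#' Generate a synthetic n-gram embedding table
#'
#' Standalone version of the embedding generator used by
#' [generate_lexicon()]: independent Gaussian 4-gram vectors over the given
#' words' n-grams, whole-word vectors as exact 4-gram sums, and a planted
#' unit weight vector whose word projections can carry valence signal.
#'
#' @param config a [sim_config()] (uses `n_dims` and `seed`).
#' @param words character vector of words whose 4-grams populate the table.
#' @return List with `table` (an [embedding_table()]), `word_matrix` and
#'   `dim_weights`.
#' @export
generate_embedding_table <- function(config, words) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  emb <- build_synthetic_embeddings(words, config$n_dims)
  w <- rnorm(config$n_dims)
  c(emb, list(dim_weights = w / sqrt(sum(w^2))))
}

#' Generate pseudoword candidates from a lexicon
#'
#' A deliberately simple candidate generator standing in for phonotactic
#' pseudoword engines: each candidate either splices the first half of one
#' random lexicon word onto the second half of another, or substitutes one
#' random letter of a lexicon word. Strings equal to lexicon words are
#' rejected; duplicates among candidates are retained (downstream filtering
#' handles them).
#'
#' @param lexicon a [clean_lexicon()].
#' @param n number of candidates.
#' @param seed integer seed.
#' @param p_splice probability of the splice move (vs. substitution).
#' @return Character vector of `n` candidate strings.
#' @export
generate_candidates <- function(lexicon, n, seed, p_splice = 0.5) {
  if (missing(seed)) stop("seed is required")
  words <- lexicon$word
  in_lex <- new.env(parent = emptyenv())
  for (w in words) assign(w, TRUE, envir = in_lex)
  set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need), function(i) {
      if (runif(1) < p_splice) {
        w1 <- words[sample.int(length(words), 1L)]
        w2 <- words[sample.int(length(words), 1L)]
        paste0(substr(w1, 1L, ceiling(nchar(w1) / 2)),
               substr(w2, ceiling(nchar(w2) / 2) + 1L, nchar(w2)))
      } else {
        w <- words[sample.int(length(words), 1L)]
        pos <- sample.int(nchar(w), 1L)
        paste0(substr(w, 1L, pos - 1L), sample(ALPHABET, 1L),
               substr(w, pos + 1L, nchar(w)))
      }
    }, character(1))
    cand <- cand[nzchar(cand) &
                   !vapply(cand, function(x) isTRUE(get0(x, envir = in_lex)), logical(1))]
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

#' Simulate best-worst raters over a session set
#'
#' Each simulated participant draws, per trial, a noisy utility
#' `latent + Gumbel(0, rater_noise)` for every item and picks the argmax as
#' best and the argmin of the remaining items as worst (a multinomial-logit
#' choice model). With probability `1 - compliance_rate` a participant is
#' non-compliant and answers uniformly at random on every trial, catch
#' trials included, so compliance screening can be exercised.
#'
#' @param sessions a [assign_sessions()] result (or a [build_trial_set()]
#'   `trial_set`, in which case each trial becomes its own participant and
#'   there are no catch trials).
#' @param latent named numeric vector of latent valences covering every item
#'   (catch-trial words included).
#' @param config a [sim_config()] supplying `rater_noise`,
#'   `compliance_rate` and `seed`; a `NULL` `rater_noise` defaults to
#'   0.5 x SD of `latent`.
#' @return Choice data.frame (`participant_id`, `trial_id`, `is_catch`,
#'   `item1..itemK`, `best`, `worst`), with the sessions' `catch_keys`
#'   attribute forwarded.
#' @export
simulate_raters <- function(sessions, latent, config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(sessions, "trial_set")) {
    k <- sessions$trial_size
    sess_list <- lapply(seq_len(nrow(sessions$trials)), function(i) {
      df <- data.frame(trial_id = paste0("t", i), is_catch = FALSE,
                       stringsAsFactors = FALSE)
      items <- matrix(sessions$trials[i, ], nrow = 1L,
                      dimnames = list(NULL, paste0("item", seq_len(k))))
      cbind(df, as.data.frame(items, stringsAsFactors = FALSE))
    })
    names(sess_list) <- paste0("p", seq_along(sess_list))
    catch_keys <- list()
  } else {
    sess_list <- unclass(sessions)
    catch_keys <- attr(sessions, "catch_keys")
  }
  noise <- config$rater_noise
  if (is.null(noise)) noise <- 0.5 * sd(latent)
  set.seed(config$seed + 2L)
  all_items <- unique(unlist(lapply(sess_list, function(df)
    unlist(df[grep("^item", names(df))], use.names = FALSE))))
  missing_latent <- setdiff(all_items, names(latent))
  if (length(missing_latent))
    stop(sprintf("no latent value for item(s): %s",
                 paste(head(missing_latent, 5L), collapse = ", ")))
  recs <- lapply(names(sess_list), function(pid) {
    df <- sess_list[[pid]]
    item_cols <- grep("^item", names(df))
    compliant <- runif(1) < config$compliance_rate
    best <- character(nrow(df)); worst <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
      items <- as.character(df[i, item_cols])
      if (compliant) {
        u <- latent[items] + rgumbel(length(items), noise)
        best[i] <- items[which.max(u)]
        rest <- which(items != best[i])
        worst[i] <- items[rest[which.min(u[rest])]]
      } else {
        pick <- sample(items, 2L)
        best[i] <- pick[1L]; worst[i] <- pick[2L]
      }
    }
    cbind(data.frame(participant_id = pid, stringsAsFactors = FALSE),
          df, best = best, worst = worst)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "catch_keys") <- catch_keys
  out
}

#' Default catch trials for synthetic sessions
#'
#' Builds `n` catch trials from synthetic "real word" tokens with planted
#' extreme valences, returning both the trials and the latent values of
#' their words so simulated raters can answer them.
#'
#' @param trial_size items per trial.
#' @param n number of catch trials (default 4).
#' @return List with `trials` (list of [catch_trial()]) and `latent` (named
#'   vector: positives 8.5, negatives 1.5, fillers 5).
#' @export
make_catch_trials <- function(trial_size = 6L, n = 4L) {
  trials <- vector("list", n)
  latent <- numeric(0)
  for (i in seq_len(n)) {
    pos <- sprintf("goodword%d", i)
    neg <- sprintf("badword%d", i)
    fill <- sprintf("neutral%d%s", i, letters[seq_len(trial_size - 2L)])
    trials[[i]] <- catch_trial(pos, neg, fill)
    latent <- c(latent, setNames(c(8.5, 1.5, rep(5, length(fill))),
                                 c(pos, neg, fill)))
  }
  list(trials = trials, latent = latent)
}
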