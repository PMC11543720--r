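# Independent oracles used across test files. All are deliberately naive
# re-implementations kept separate from the package's own code paths.

# Left-to-right enumeration of edit sequences (match/substitute, delete,
# insert, adjacent transposition) with the optimal-string-alignment rule
# that a transposed pair is consumed whole and never re-edited. Plain
# exponential recursion; usable for short strings only.
osa_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    na <- length(av) - i + 1L
    nb <- length(bv) - j + 1L
    if (na == 0L) return(nb)
    if (nb == 0L) return(na)
    best <- rec(i + 1L, j + 1L) + (av[i] != bv[j])  # match / substitute
    best <- min(best, rec(i + 1L, j) + 1L)          # delete from a
    best <- min(best, rec(i, j + 1L) + 1L)          # insert into a
    if (na >= 2L && nb >= 2L && av[i] == bv[j + 1L] && av[i + 1L] == bv[j])
      best <- min(best, rec(i + 2L, j + 2L) + 1L)   # transpose, consume both
    best
  }
  rec(1L, 1L)
}

# All strings over `alphabet` with lengths 0..max_len.
all_strings <- function(alphabet, max_len) {
  out <- ""
  cur <- ""
  for (len in seq_len(max_len)) {
    cur <- as.vector(outer(cur, alphabet, paste0))
    out <- c(out, cur)
  }
  out
}

# Brute-force subword composition: look every 4-gram up in a plain named
# list and sum with an explicit loop.
compose_oracle <- function(string, vec_list, n = 4L) {
  wrapped <- paste0("<", string, ">")
  L <- nchar(wrapped)
  if (L < n) return(NULL)
  acc <- NULL
  for (s in 1:(L - n + 1)) {
    g <- substr(wrapped, s, s + n - 1)
    v <- vec_list[[g]]
    if (!is.null(v)) acc <- if (is.null(acc)) v else acc + v
  }
  acc
}

# Counting-based best-worst score: (#best - #worst) / #appearances. A crude
# but fully independent scaler used as a sanity oracle for value learning.
count_scores_oracle <- function(records) {
  recs <- records[!records$is_catch, , drop = FALSE]
  item_cols <- grep("^item[0-9]+$", names(recs), value = TRUE)
  items <- sort(unique(unlist(recs[item_cols], use.names = FALSE)))
  app <- table(factor(unlist(recs[item_cols], use.names = FALSE), levels = items))
  nb <- table(factor(recs$best, levels = items))
  nw <- table(factor(recs$worst, levels = items))
  setNames(as.numeric(nb - nw) / pmax(as.numeric(app), 1), items)
}

# Small deterministic choice-record builder: one participant, explicit picks.
make_records <- function(trials, best, worst, participant = "p1",
                         is_catch = FALSE) {
  k <- ncol(trials)
  df <- as.data.frame(trials, stringsAsFactors = FALSE)
  names(df) <- paste0("item", seq_len(k))
  cbind(data.frame(participant_id = participant,
                   trial_id = paste0("t", seq_len(nrow(trials))),
                   is_catch = is_catch, stringsAsFactors = FALSE),
        df, best = best, worst = worst)
}

# Standard small synthetic world shared by several tests.
small_world <- function(seed = 42, n_words = 600) {
  generate_lexicon(sim_config(n_words = n_words, letter_effect_sd = 0.4,
                              noise_sd = 0.5, seed = seed))
}
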