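test_that("candidate filtering marks whole-word vectors, duplicates and manual exclusions", {
  tab <- embedding_table(list("<gr" = rnorm(2), vacation = rnorm(2)))
  pool <- filter_candidates(c("grawp", "grawp", "vacation"), tab,
                            require_composable = FALSE)
  expect_equal(pool$string[is.na(pool$excluded)], "grawp")
  expect_equal(sort(pool$excluded[!is.na(pool$excluded)]),
               c("duplicate", "whole_word_vector"))
  # no exclusions apply -> pool unchanged
  pool2 <- filter_candidates(c("a", "b"), tab, require_composable = FALSE)
  expect_true(all(is.na(pool2$excluded)))
  pool3 <- filter_candidates(c("a", "b"), manual_exclusions = "b")
  expect_equal(pool3$excluded[2], "manual")
  # strings the table cannot compose at all are flagged when required
  tab4 <- embedding_table(list("<bus" = rnorm(2), "bus>" = rnorm(2)))
  pool4 <- filter_candidates(c("bus", "zzzzz"), tab4)
  expect_true(is.na(pool4$excluded[1]))
  expect_equal(pool4$excluded[2], "not_composable")
})

test_that("uniform sampling hits quotas, respects exclusions and is seed-deterministic", {
  set.seed(1)
  pv <- runif(4000, 2, 9)
  pool <- filter_candidates(sprintf("w%04da", seq_along(pv)))
  s1 <- stratified_uniform_sample(pool, pv, n_target = 1500, seed = 99)
  s2 <- stratified_uniform_sample(pool, pv, n_target = 1500, seed = 99)
  expect_identical(s1, s2)
  expect_equal(length(s1), 1500)
  expect_equal(anyDuplicated(s1), 0)
  counts <- attr(s1, "slice_counts")
  expect_equal(sum(counts), 1500)
  # per-slice counts stay inside the band floor(n/25)-10 .. ceil(n/25)+10,
  # the analogue of the 50-61 items-per-slice regime of a flat design
  expect_true(all(counts >= floor(1500 / 25) - 10))
  expect_true(all(counts <= ceiling(1500 / 25) + 10))
  # exclusion list is never sampled
  s3 <- stratified_uniform_sample(pool, pv, n_target = 100,
                                  exclusion_list = pool$string[1:2000], seed = 5)
  expect_false(any(s3 %in% pool$string[1:2000]))
  expect_error(stratified_uniform_sample(pool, pv, n_target = 5000, seed = 1),
               "exceeds eligible pool")
})

test_that("sampling everything returns the whole pool and uniformization beats random sampling", {
  pv <- c(1, 3, 5, 7, 9)
  pool <- filter_candidates(letters[1:5])
  out <- stratified_uniform_sample(pool, pv, n_target = 5, seed = 1)
  expect_setequal(out, letters[1:5])
  # coefficient of variation of per-slice counts: stratified < simple random
  set.seed(2)
  pv2 <- rbeta(3000, 1.3, 5) * 8 + 1
  pool2 <- filter_candidates(sprintf("c%04db", 1:3000))
  strat <- stratified_uniform_sample(pool2, pv2, n_target = 600, seed = 3)
  srs <- sample(pool2$string, 600)
  bins <- seq(min(pv2), max(pv2), length.out = 26)
  hist_of <- function(sel) {
    v <- pv2[match(sel, pool2$string)]
    as.numeric(table(cut(v, bins, include.lowest = TRUE)))
  }
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(hist_of(strat)), cv(hist_of(srs)))
})

test_that("trial sets satisfy exact appearance counts with no within-trial repeats", {
  ts <- build_trial_set(letters[1:6], appearances = 1, trial_size = 6, seed = 1)
  expect_equal(nrow(ts$trials), 1)
  expect_setequal(as.vector(ts$trials), letters[1:6])

  ts2 <- build_trial_set(sprintf("i%02d", 1:12), appearances = 3, trial_size = 6,
                         seed = 2)
  expect_equal(nrow(ts2$trials), 6)
  expect_true(all(table(as.vector(ts2$trials)) == 3))
  expect_true(all(apply(ts2$trials, 1, anyDuplicated) == 0))

  # invariants hold across seeds, including the non-divisible-rounds case
  for (seed in 1:5) {
    ts3 <- build_trial_set(sprintf("x%02d", 1:9), appearances = 2, trial_size = 6,
                           seed = seed)
    expect_equal(nrow(ts3$trials), 3)
    expect_true(all(table(as.vector(ts3$trials)) == 2))
    expect_true(all(apply(ts3$trials, 1, anyDuplicated) == 0))
  }
  expect_error(build_trial_set(letters[1:7], appearances = 1, trial_size = 6,
                               seed = 1),
               "smallest compatible appearances is 6")
})

test_that("sessions partition experimental trials and all carry the catch trials", {
  items <- sprintf("i%02d", 1:24)
  ts <- build_trial_set(items, appearances = 3, trial_size = 6, seed = 4)
  catch <- make_catch_trials(trial_size = 6, n = 4)
  sess <- assign_sessions(ts, trials_per_participant = 3, catch = catch$trials,
                          seed = 5)
  expect_length(sess, 4)
  exp_ids <- unname(unlist(lapply(sess, function(df) df$trial_id[!df$is_catch])))
  expect_equal(sort(exp_ids), sort(paste0("t", 1:12)))  # disjoint + complete
  for (df in sess) {
    expect_equal(sort(df$trial_id[df$is_catch]), paste0("catch", 1:4))
  }
  # short final session when counts do not divide
  sess2 <- assign_sessions(ts, trials_per_participant = 5, catch = list(), seed = 6)
  expect_length(sess2, 3)
  expect_equal(vapply(sess2, nrow, integer(1), USE.NAMES = FALSE), c(5L, 5L, 2L))
})

test_that("session TSV export is readable and complete", {
  ts <- build_trial_set(sprintf("i%02d", 1:12), appearances = 1, trial_size = 6,
                        seed = 3)
  sess <- assign_sessions(ts, 1, make_catch_trials(6, 1)$trials, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sessions_tsv(sess, path)
  back <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(back), 2 * 2)  # 2 sessions x (1 experimental + 1 catch)
  expect_true(all(c("session_id", "trial_index", "is_catch", "item1") %in% names(back)))
})
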