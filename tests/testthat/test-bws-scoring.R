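test_that("implied pairs follow the best-beats-all / all-beat-worst rule", {
  p6 <- implied_pairs(letters[1:6], best = "a", worst = "f")
  expect_equal(nrow(p6), 9)  # 5 + 4
  expect_equal(sum(p6[, "winner"] == "a"), 5)
  expect_equal(sum(p6[, "loser"] == "f"), 5)
  # middle items are never paired with each other
  middles <- c("b", "c", "d", "e")
  mm <- p6[p6[, "winner"] %in% middles & p6[, "loser"] %in% middles, , drop = FALSE]
  expect_equal(nrow(mm), 0)
  expect_equal(nrow(implied_pairs(c("x", "y"), "x", "y")), 1)
  expect_error(implied_pairs(letters[1:6], "a", "a"), "must differ")
  expect_error(implied_pairs(letters[1:6], "a", "q"), "not in trial")
})

test_that("a dominant winner and loser land at the extremes of the score range", {
  trials <- rbind(c("a", "b", "c", "d"),
                  c("a", "c", "d", "b"),
                  c("b", "a", "d", "c"),
                  c("c", "d", "a", "b"))
  recs <- make_records(trials, best = rep("a", 4), worst = rep("b", 4))
  sc <- value_learning(recs, vl_config(n_passes = 50), seed = 1)
  expect_equal(sc$item[which.max(sc$score)], "a")
  expect_equal(sc$item[which.min(sc$score)], "b")
  expect_equal(sc$n_best[sc$item == "a"], 4)
  expect_equal(sc$n_worst[sc$item == "b"], 4)
})

test_that("latent orderings are recovered from simulated choices", {
  latent <- c(i1 = 0.2, i2 = 0.5, i3 = 0.8)
  ts <- build_trial_set(names(latent), appearances = 200, trial_size = 3, seed = 2)
  cfg <- sim_config(n_words = 10, rater_noise = 0.15, compliance_rate = 1, seed = 3)
  recs <- simulate_raters(ts, latent, cfg)
  sc <- value_learning(recs, seed = 4)
  expect_equal(sc$item[order(sc$score)], c("i1", "i2", "i3"))
  # and agrees with a simple counting-score oracle on ordering
  cs <- count_scores_oracle(recs)
  expect_equal(order(sc$score), order(cs[sc$item]))
})

test_that("scores are stable under re-seeded pair ordering", {
  set.seed(10)
  latent <- setNames(runif(150, 1, 9), sprintf("it%03d", 1:150))
  ts <- build_trial_set(names(latent), appearances = 12, trial_size = 6, seed = 11)
  cfg <- sim_config(n_words = 10, rater_noise = 0.5 * sd(latent),
                    compliance_rate = 1, seed = 12)
  recs <- simulate_raters(ts, latent, cfg)
  s1 <- value_learning(recs, seed = 100)
  s2 <- value_learning(recs, seed = 200)
  expect_gte(cor(s1$score, s2$score, method = "spearman"), 0.99)
  # determinism under the same seed
  expect_identical(s1, value_learning(recs, seed = 100))
})

test_that("affine rescaling of scores changes no reported r or R-squared", {
  set.seed(20)
  obs <- rnorm(80)
  pred <- obs + rnorm(80, 0, 0.7)
  base <- compare_valence_models(list(m = pred), obs)
  shifted <- compare_valence_models(list(m = pred), 3.2 * obs - 17)
  expect_equal(shifted$r, base$r, tolerance = 1e-12)
  expect_equal(shifted$r_squared, base$r_squared, tolerance = 1e-12)
})

test_that("extra wins never lower an item's score", {
  trials <- rbind(c("a", "b", "c"), c("b", "c", "a"), c("c", "a", "b"))
  recs <- make_records(trials, best = c("a", "b", "c"), worst = c("c", "c", "a"))
  sc0 <- value_learning(recs, vl_config(n_passes = 40), seed = 5)
  extra <- make_records(rbind(c("b", "a", "c")), best = "b", worst = "c",
                        participant = "p2")
  sc1 <- value_learning(rbind(recs, extra), vl_config(n_passes = 40), seed = 5)
  expect_gte(sc1$score[sc1$item == "b"], sc0$score[sc0$item == "b"])
})

test_that("catch-trial screening removes participants with more than one error", {
  catch <- make_catch_trials(trial_size = 4, n = 3)
  keys <- setNames(lapply(catch$trials, function(ct)
    list(positive = ct$positive, negative = ct$negative)),
    paste0("catch", 1:3))
  trial_items <- do.call(rbind, lapply(catch$trials, function(ct) ct$items))
  perfect <- make_records(trial_items,
                          best = vapply(catch$trials, `[[`, "", "positive"),
                          worst = vapply(catch$trials, `[[`, "", "negative"),
                          participant = "good", is_catch = TRUE)
  perfect$trial_id <- paste0("catch", 1:3)
  one_err <- perfect
  one_err$participant_id <- "oneoff"
  one_err$best[1] <- one_err$item2[1]  # one wrong best = one error
  two_err <- perfect
  two_err$participant_id <- "sloppy"
  two_err$best[1] <- two_err$item2[1]
  two_err$worst[2] <- two_err$item2[2]
  recs <- rbind(perfect, one_err, two_err)
  attr(recs, "catch_keys") <- keys
  out <- exclude_noncompliant(recs)
  expect_equal(out$excluded, "sloppy")
  expect_equal(unname(out$errors[c("good", "oneoff", "sloppy")]), c(0, 1, 2))
  expect_false("sloppy" %in% out$records$participant_id)
  # all perfect -> nobody excluded
  solo <- perfect
  attr(solo, "catch_keys") <- keys
  expect_length(exclude_noncompliant(solo)$excluded, 0)
  # a participant with no catch rows cannot be assessed
  nocatch <- make_records(rbind(c("a", "b", "c", "d")), "a", "b",
                          participant = "ghost")
  recs2 <- rbind(recs, nocatch)
  attr(recs2, "catch_keys") <- keys
  expect_error(exclude_noncompliant(recs2), "ghost")
})

test_that("split halves of identical deterministic raters agree almost perfectly", {
  latent <- setNames(seq(1, 9, length.out = 30), sprintf("d%02d", 1:30))
  ts <- build_trial_set(names(latent), appearances = 6, trial_size = 6, seed = 7)
  cfg <- sim_config(n_words = 10, rater_noise = 0, compliance_rate = 1, seed = 8)
  recs <- simulate_raters(ts, latent, cfg)
  # duplicate the deterministic choices into two pseudo-participants
  r1 <- recs; r1$participant_id <- "h1"
  r2 <- recs; r2$participant_id <- "h2"
  sh <- split_half_reliability(rbind(r1, r2), vl_config(n_passes = 60), seed = 9)
  expect_gte(sh$r, 0.99)
  expect_equal(sh$n_items, 30)
})
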