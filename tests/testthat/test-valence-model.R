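make_design_lexicon <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  list(X = X, lex = function(y) data.frame(word = paste0("w", seq_len(n)),
                                           valence = y, stringsAsFactors = FALSE))
}

test_that("exact linear structure is recovered perfectly", {
  d <- make_design_lexicon(50, 4)
  y <- 2 + 3 * d$X[, 2]
  m <- valence_model(d$lex(y), feature_spec(letters = TRUE), design = d$X)
  expect_equal(unname(m$coefficients), c(0, 3, 0, 0), tolerance = 1e-8)
  expect_equal(m$intercept, 2, tolerance = 1e-8)
  st <- fit_stats(m)
  expect_equal(st$r_squared, 1, tolerance = 1e-10)
  expect_equal(st$r, 1, tolerance = 1e-10)
})

test_that("a constant response yields zero slopes and R-squared zero", {
  d <- make_design_lexicon(30, 3)
  m <- valence_model(d$lex(rep(5, 30)), feature_spec(letters = TRUE), design = d$X)
  expect_equal(unname(m$coefficients), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(m$intercept, 5)
  expect_error(fit_stats(m), "zero variance")
  expect_equal(unname(predict(m, d$X[1:3, ])), rep(5, 3), tolerance = 1e-10)
})

test_that("OLS matches the normal-equations oracle to 1e-8", {
  d <- make_design_lexicon(200, 10, seed = 8)
  y <- drop(d$X %*% rnorm(10)) + rnorm(200)
  m <- valence_model(d$lex(y), feature_spec(letters = TRUE), design = d$X)
  Xi <- cbind(1, d$X)
  beta_oracle <- solve(crossprod(Xi), crossprod(Xi, y))
  expect_equal(unname(c(m$intercept, m$coefficients)), unname(drop(beta_oracle)),
               tolerance = 1e-8)
})

test_that("rank-deficient designs get the minimum-norm solution with aliased columns logged", {
  set.seed(2)
  X <- cbind(a = rnorm(40), b = 0, c = rnorm(40))
  X <- cbind(X, d = X[, "a"] + X[, "c"])  # exact collinearity
  y <- 1 + X[, "a"] - X[, "c"] + rnorm(40, 0, 0.01)
  lex <- data.frame(word = paste0("w", 1:40), valence = y)
  m <- valence_model(lex, feature_spec(letters = TRUE), design = X)
  expect_true("b" %in% m$aliased)
  # fitted values are still the least-squares projection
  ref <- lm(y ~ X[, "a"] + X[, "c"])
  expect_equal(m$fitted.values, unname(fitted(ref)), tolerance = 1e-8)
  # minimum-norm: among solutions, smallest coefficient norm; check against
  # the pseudoinverse directly
  Xc <- sweep(X, 2, colMeans(X))
  beta_pinv <- drop(MASS::ginv(Xc) %*% (y - mean(y)))
  expect_equal(unname(m$coefficients), beta_pinv, tolerance = 1e-8)
})

test_that("underdetermined fits are refused with actionable advice", {
  d <- make_design_lexicon(10, 12)
  expect_error(valence_model(d$lex(rnorm(10)), feature_spec(letters = TRUE),
                             design = d$X),
               "larger lexicon or a smaller feature spec")
})

test_that("AIC follows the documented n*log(RSS/n) + 2k convention", {
  d <- make_design_lexicon(10, 2, seed = 4)
  y <- drop(d$X %*% c(1, -1)) + rnorm(10)
  m <- valence_model(d$lex(y), feature_spec(letters = TRUE), design = d$X)
  st <- fit_stats(m)
  rss <- sum((y - m$fitted.values)^2)
  expect_equal(st$aic, 10 * log(rss / 10) + 2 * (3 + 1))
})

test_that("prediction reproduces fitted values on training data", {
  g <- small_world(seed = 31, n_words = 300)
  m <- valence_model(g$lexicon, feature_spec(letters = TRUE))
  expect_equal(unname(predict(m, g$lexicon$word)), unname(m$fitted.values),
               tolerance = 1e-10)
})

test_that("nested models never lose R-squared and letters duplicate inside bigrams+boundaries", {
  g <- small_world(seed = 13, n_words = 900)
  cmp <- run_experiment1(g$lexicon)$comparison
  r2 <- setNames(cmp$r_squared, cmp$model)
  expect_gte(r2[["letters_bigrams"]] + 1e-10, r2[["letters"]])
  expect_gte(r2[["letters_bigrams"]] + 1e-10, r2[["bigrams"]])
  # letter counts are linear combinations of bigram + boundary counts, so
  # the two wider models span the same column space and fit identically
  expect_equal(r2[["letters_bigrams"]], r2[["bigrams"]], tolerance = 1e-8)
})

test_that("model comparison accepts external predictor vectors", {
  set.seed(6)
  obs <- rnorm(100)
  noisy <- obs + rnorm(100, 0, 0.5)
  cmp <- compare_valence_models(list(self = obs, noisy = noisy), obs)
  expect_equal(cmp$r_squared[cmp$model == "self"], 1, tolerance = 1e-12)
  expect_equal(cmp$rank_aic[cmp$model == "self"], 1)
  expect_error(compare_valence_models(list(bad = rnorm(5)), obs), "misaligned")
})

test_that("letter-effect recovery from a planted lexicon is near-perfect", {
  g <- small_world(seed = 77, n_words = 2000)
  m <- valence_model(g$lexicon, feature_spec(letters = TRUE))
  expect_gte(cor(m$coefficients, g$letter_effects), 0.95)
})

test_that("models serialize to JSON and predict identically after reload", {
  g <- small_world(seed = 55, n_words = 900)
  m <- valence_model(g$lexicon, feature_spec(letters = TRUE, bigrams = TRUE,
                                             boundaries = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  save_valence_model(m, path)
  m2 <- load_valence_model(path)
  probe <- c("grawp", "simmy", "xexen")
  expect_equal(predict(m2, probe), predict(m, probe), tolerance = 1e-12)
})
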