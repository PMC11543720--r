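test_that("OSA distance handles identity, transposition and the restricted case", {
  expect_equal(osa_distance("abc", "abc"), 0L)
  expect_equal(osa_distance("ab", "ba"), 1L)
  # OSA forbids editing a transposed substring again: distance 3, where the
  # unrestricted Damerau-Levenshtein would give 2
  expect_equal(osa_distance("ca", "abc"), 3L)
  expect_equal(osa_distance("", "abc"), 3L)
  expect_equal(osa_distance("abc", ""), 3L)
  expect_error(osa_distance("ab!", "ab"), "lowercase")
  # vectorized with recycling
  expect_equal(osa_distance("bus", c("bus", "bug", "sub")), c(0L, 1L, 2L))
})

test_that("OSA matches the exhaustive edit-sequence oracle on all short pairs", {
  strs <- all_strings(c("a", "b", "c"), 3)
  got <- outer(strs, strs, osa_distance)
  want <- outer(seq_along(strs), seq_along(strs),
                Vectorize(function(i, j) osa_oracle(strs[i], strs[j])))
  expect_equal(got, want)
})

test_that("OSA is symmetric and not above plain Levenshtein", {
  lev <- function(a, b) drop(adist(a, b))
  set.seed(30)
  for (i in 1:60) {
    a <- paste(sample(letters[1:5], sample(0:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(letters[1:5], sample(0:6, 1), replace = TRUE), collapse = "")
    d <- osa_distance(a, b)
    expect_equal(d, osa_distance(b, a))
    expect_lte(d, lev(a, b))
  }
})

test_that("orthographic neighbors return all minimal-distance ties with mean valence", {
  lex <- clean_lexicon(c("bus", "bug", "cat"), c(5, 3, 7), quiet = TRUE)
  res <- nearest_orthographic("bux", lex)
  expect_setequal(res$neighbors, c("bus", "bug"))
  expect_equal(res$distance, 1)
  expect_equal(res$neighbor_valence, 4)
  # a query equal to a lexicon word is its own neighbor at distance zero
  res0 <- nearest_orthographic("cat", lex)
  expect_equal(res0$neighbors, "cat")
  expect_equal(res0$distance, 0)
})

test_that("orthographic scans match a brute-force full scan on random lexicons", {
  set.seed(31)
  lexw <- unique(replicate(50, paste(sample(letters[1:6], sample(2:6, 1),
                                            replace = TRUE), collapse = "")))
  lex <- clean_lexicon(lexw, runif(length(lexw), 1, 9), quiet = TRUE)
  for (i in 1:20) {
    q <- paste(sample(letters[1:6], sample(2:6, 1), replace = TRUE), collapse = "")
    res <- nearest_orthographic(q, lex)
    d_all <- vapply(lex$word, function(w) osa_oracle(q, w), numeric(1))
    expect_equal(res$distance, min(d_all))
    expect_setequal(res$neighbors, lex$word[d_all == min(d_all)])
  }
  # neighbor distance never increases when the lexicon grows
  bigger <- clean_lexicon(c(lex$word, "qqq"), c(lex$valence, 5), quiet = TRUE)
  for (q in c("abab", "fcfc")) {
    expect_lte(nearest_orthographic(q, bigger)$distance,
               nearest_orthographic(q, lex)$distance)
  }
})

test_that("semantic neighbors honor exclusions and match a brute-force scan", {
  set.seed(32)
  M <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("w%02d", 1:40), NULL))
  val <- runif(40, 1, 9)
  q <- rnorm(6)
  res <- nearest_semantic(q, M, val)
  d_all <- apply(M, 1, function(row) cosine_distance(q, row))
  expect_equal(res$neighbors, names(which.min(d_all)))
  expect_equal(res$distance, min(d_all), tolerance = 1e-12)
  # excluding the winner promotes the runner-up
  res2 <- nearest_semantic(q, M, val, exclude = res$neighbors)
  expect_equal(res2$neighbors, names(sort(d_all))[2])
  expect_error(nearest_semantic(q, M, val, exclude = rownames(M)), "entire lexicon")
  # identical vector -> distance zero
  res3 <- nearest_semantic(M["w05", ], M, val)
  expect_equal(res3$neighbors, "w05")
  expect_equal(res3$distance, 0, tolerance = 1e-12)
})

test_that("hub reporting flags a planted near-zero hub and stays quiet under the null", {
  set.seed(33)
  L <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(sprintf("w%02d", 1:30), NULL))
  # a tiny-norm vector pointing along the queries' mean direction attracts
  # disproportionately many nearest-neighbor wins
  hubdir <- rnorm(8)
  Q <- matrix(rep(hubdir, each = 25), 25, 8) + matrix(rnorm(25 * 8, 0, 0.3), 25, 8)
  L["w01", ] <- hubdir * 0.05
  rep1 <- hub_report(Q, L)
  expect_true(rep1$is_hub[rep1$word == "w01"])
  expect_equal(rep1$word[1], "w01")
  # uniform random vectors: no word should dominate many queries
  Q0 <- matrix(rnorm(200 * 8), 200, 8)
  L0 <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(sprintf("v%02d", 1:30), NULL))
  rep0 <- hub_report(Q0, L0, threshold = 0.2)
  expect_false(any(rep0$is_hub))
  # single query: exactly one winner with count 1
  rep_one <- hub_report(Q0[1, , drop = FALSE], L0)
  expect_equal(sum(rep_one$times_nearest), 1)
})

test_that("batch neighbor predictors line up with the single-query API", {
  lex <- clean_lexicon(c("bus", "bug", "cat", "dog"), c(5, 3, 7, 8), quiet = TRUE)
  nb <- neighbor_predictors(c("bux", "dog"), lex)
  expect_equal(nb$ortho_valence[1], 4)
  expect_equal(nb$ortho_valence[2], 8)
  expect_equal(nb$ortho_distance, c(1, 0))
})
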