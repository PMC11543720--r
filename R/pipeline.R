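#' Fit and compare the seven valence models on a lexicon
#'
#' The word-norms stage of the workflow: builds the design blocks once,
#' fits all seven canonical feature specifications ([seven_model_specs()])
#' by OLS on the lexicon's valence ratings, and scores them by R-squared,
#' correlation and AIC.
#'
#' @param lexicon a [clean_lexicon()].
#' @param embeddings an [embedding_table()]; `NULL` drops the four
#'   dimension-based specs.
#' @param selection which fitted model to return as `model` for downstream
#'   prediction (default `"full"`, falling back to the widest available).
#' @return List of class `experiment1_result`: `comparison` (a
#'   [compare_valence_models()] table), `models` (named list of
#'   `valence_model`s), `model` (the selected one).
#' @export
run_experiment1 <- function(lexicon, embeddings = NULL, selection = "full") {
  specs <- seven_model_specs()
  if (is.null(embeddings))
    specs <- Filter(function(s) !s$dimensions, specs)
  full_spec <- specs[[length(specs)]]
  design_all <- build_design_matrix(lexicon$word, full_spec, embeddings)
  models <- lapply(specs, function(sp) {
    cols <- feature_labels(sp, if (sp$dimensions) embeddings$dimension else 0L)
    valence_model(lexicon, sp, embeddings,
                  design = design_all[, cols, drop = FALSE])
  })
  rows <- lapply(names(models), function(nm) {
    st <- fit_stats(models[[nm]])
    data.frame(model = nm, r = st$r, r_squared = st$r_squared, aic = st$aic,
               n = st$n, k = st$k, stringsAsFactors = FALSE)
  })
  comparison <- do.call(rbind, rows)
  comparison$rank_r_squared <- rank(-comparison$r_squared, ties.method = "min")
  comparison$rank_aic <- rank(comparison$aic, ties.method = "min")
  class(comparison) <- c("valence_model_comparison", "data.frame")
  if (!selection %in% names(models)) selection <- names(models)[length(models)]
  structure(list(comparison = comparison, models = models,
                 model = models[[selection]], selection = selection),
            class = "experiment1_result")
}

#' @export
print.experiment1_result <- function(x, ...) {
  print(x$comparison)
  cat("selected model:", x$selection, "\n")
  invisible(x)
}

#' Predicted-valence columns for a set of strings under several models
#'
#' @param models named list of `valence_model`s.
#' @param strings character vector of (pseudo)words.
#' @param embeddings an [embedding_table()] for dimension specs.
#' @return Numeric matrix, one column per model.
#' @export
predicted_valence_matrix <- function(models, strings, embeddings = NULL) {
  out <- vapply(models, function(m)
    predict(m, strings, embeddings = embeddings), numeric(length(strings)))
  rownames(out) <- strings
  out
}

#' Score best-worst choices and compare predictor models
#'
#' The judgment-analysis stage: screens participants on catch trials,
#' converts the surviving best-worst choices into continuous valence indexes
#' by [value_learning()], measures split-half reliability, and regresses the
#' observed indexes on (i) each word-trained model's predicted valence and
#' (ii) the orthographic / semantic neighbor-valence predictors, including
#' the combined letters + neighbor models with nested F tests.
#'
#' @param records choice data.frame (with `catch_keys` attribute when catch
#'   screening is wanted).
#' @param models named list of word-trained `valence_model`s (typically
#'   `run_experiment1(...)$models`).
#' @param lexicon a [clean_lexicon()] supplying neighbor valences; `NULL`
#'   skips the neighbor block.
#' @param embeddings an [embedding_table()] for dimension specs and semantic
#'   neighbors.
#' @param vl a [vl_config()].
#' @param seed integer seed for scoring and the split-half draw.
#' @param semantic_exclude hub words excluded from the semantic scan.
#' @param screen run catch-trial compliance screening first.
#' @return List of class `experiment2_result`: `scores`, `split_half`,
#'   `excluded`, `comparison` (models x observed indexes),
#'   `neighbor_comparison` (baseline letters model, neighbor models,
#'   combined models) and `f_tests`.
#' @export
run_experiment2 <- function(records, models, lexicon = NULL, embeddings = NULL,
                            vl = vl_config(), seed, semantic_exclude = character(0),
                            screen = TRUE) {
  if (missing(seed)) stop("seed is required")
  excluded <- character(0)
  if (screen && length(attr(records, "catch_keys"))) {
    scr <- exclude_noncompliant(records)
    records <- scr$records
    excluded <- scr$excluded
  }
  scores <- value_learning(records, vl, seed = seed)
  sh <- split_half_reliability(records, vl, seed = seed + 10L)
  items <- scores$item
  pred <- predicted_valence_matrix(models, items, embeddings)
  predictors <- as.list(as.data.frame(pred))
  comparison <- compare_valence_models(predictors, scores$score)
  neighbor_comparison <- NULL
  f_tests <- NULL
  if (!is.null(lexicon)) {
    nb <- neighbor_predictors(items, lexicon, embeddings,
                              semantic_exclude = semantic_exclude)
    base <- pred[, "letters"]
    nb_models <- list(letters = base, orthographic = nb$ortho_valence)
    combined <- list(letters_orthographic = cbind(letters = base,
                                                  ortho = nb$ortho_valence))
    if (!is.null(embeddings)) {
      nb_models$semantic <- nb$sem_valence
      combined$letters_semantic <- cbind(letters = base, sem = nb$sem_valence)
      combined$letters_orthographic_semantic <-
        cbind(letters = base, ortho = nb$ortho_valence, sem = nb$sem_valence)
    }
    multi <- lapply(combined, function(X) {
      fitted_v <- fitted(lm(scores$score ~ X))
      st <- fit_stats(fitted_v, scores$score, k = ncol(X) + 1L)
      st
    })
    rows <- c(lapply(names(nb_models), function(nm) {
      st <- fit_stats(fitted(lm(scores$score ~ nb_models[[nm]])), scores$score, k = 2L)
      data.frame(model = nm, r = st$r, r_squared = st$r_squared, aic = st$aic,
                 n = st$n, k = st$k, stringsAsFactors = FALSE)
    }), lapply(names(multi), function(nm) {
      st <- multi[[nm]]
      data.frame(model = nm, r = st$r, r_squared = st$r_squared, aic = st$aic,
                 n = st$n, k = st$k, stringsAsFactors = FALSE)
    }))
    neighbor_comparison <- do.call(rbind, rows)
    neighbor_comparison$rank_r_squared <- rank(-neighbor_comparison$r_squared,
                                               ties.method = "min")
    neighbor_comparison$rank_aic <- rank(neighbor_comparison$aic, ties.method = "min")
    class(neighbor_comparison) <- c("valence_model_comparison", "data.frame")
    f_tests <- list(
      letters_vs_letters_orthographic = nested_f_test(
        scores$score, cbind(base), combined$letters_orthographic))
    if (!is.null(embeddings))
      f_tests$letters_orthographic_vs_all <- nested_f_test(
        scores$score, combined$letters_orthographic,
        combined$letters_orthographic_semantic)
    attr(neighbor_comparison, "predictors") <- nb
  }
  structure(list(scores = scores, split_half = sh, excluded = excluded,
                 comparison = comparison,
                 neighbor_comparison = neighbor_comparison,
                 f_tests = f_tests),
            class = "experiment2_result")
}

#' @export
print.experiment2_result <- function(x, ...) {
  cat(sprintf("Best-worst study: %d items scored, %d participants excluded, split-half r = %.3f\n",
              nrow(x$scores), length(x$excluded), x$split_half$r))
  print(x$comparison)
  if (!is.null(x$neighbor_comparison)) print(x$neighbor_comparison)
  invisible(x)
}

#' Run one fully synthetic best-worst valence study
#'
#' End-to-end driver over the synthetic generators: plant a lexicon, train
#' the word models, build candidate pseudowords, select a uniform-coverage
#' stimulus set, lay out balanced trials and sessions with catch trials,
#' simulate raters whose latent pseudoword valence is either the planted
#' letters signal (`world = "letters"`) or the orthographic-neighbor valence
#' (`world = "neighbor"`), screen, score and compare all predictor models.
#'
#' @param config a [sim_config()].
#' @param n_items stimulus-set size (default 150).
#' @param appearances,trial_size,trials_per_participant best-worst design
#'   constants (defaults 30, 6, 45).
#' @param n_slices valence slices for uniform sampling.
#' @param n_candidates candidate pool size.
#' @param world which planted signal drives the simulated raters.
#' @param with_dimensions also generate embeddings and fit the
#'   dimension-based specs.
#' @return List: the `experiment1_result`, the `experiment2_result`, the
#'   items, their latent valence, and the intermediate design objects.
#' @export
run_synthetic_study <- function(config, n_items = 150L, appearances = 30L,
                                trial_size = 6L, trials_per_participant = 45L,
                                n_slices = 25L, n_candidates = 2000L,
                                world = c("letters", "neighbor"),
                                with_dimensions = FALSE) {
  world <- match.arg(world)
  gen <- generate_lexicon(config)
  embeddings <- gen$embeddings
  if (with_dimensions && is.null(embeddings)) {
    emb <- generate_embedding_table(config, gen$lexicon$word)
    embeddings <- emb$table
  }
  exp1 <- run_experiment1(gen$lexicon, embeddings)
  cands <- generate_candidates(gen$lexicon, n_candidates, seed = config$seed + 3L)
  pool <- filter_candidates(cands, embeddings)
  elig <- pool$string[is.na(pool$excluded)]
  pred_sel <- predict(exp1$model, elig, embeddings = embeddings)
  items <- stratified_uniform_sample(pool[is.na(pool$excluded), ], pred_sel,
                                     n_target = n_items, n_slices = n_slices,
                                     seed = config$seed + 4L)
  latent <- switch(world,
    letters = {
      counts <- t(vapply(items, letter_counts, integer(26)))
      setNames(config$valence_anchor + drop(counts %*% gen$letter_effects), items)
    },
    neighbor = {
      nb <- neighbor_predictors(items, gen$lexicon)
      setNames(nb$ortho_valence, items)
    })
  trials <- build_trial_set(items, appearances, trial_size,
                            seed = config$seed + 5L)
  catch <- make_catch_trials(trial_size)
  sessions <- assign_sessions(trials, trials_per_participant, catch$trials,
                              seed = config$seed + 6L)
  records <- simulate_raters(sessions, c(latent, catch$latent), config)
  exp2 <- run_experiment2(records, exp1$models, lexicon = gen$lexicon,
                          embeddings = embeddings, seed = config$seed + 7L)
  list(exp1 = exp1, exp2 = exp2, items = items, latent = latent,
       lexicon = gen$lexicon, letter_effects = gen$letter_effects,
       embeddings = embeddings, trials = trials, sessions = sessions,
       records = records)
}

#' Train the per-string valence estimator
#'
#' Fits the two-predictor regression of observed best-worst valence indexes
#' on the letters-model prediction and the orthographic-neighbor valence --
#' the additive combination exposed by [predict_string()] -- and bundles
#' everything a later prediction needs.
#'
#' @param scores a `value_scores` data.frame of observed indexes.
#' @param letters_model a letters-only `valence_model`.
#' @param lexicon a [clean_lexicon()] for neighbor lookup.
#' @return List of class `string_predictor` with the letters model, lexicon
#'   and combined-regression coefficients.
#' @export
train_string_predictor <- function(scores, letters_model, lexicon) {
  stopifnot(inherits(scores, "value_scores"))
  lp <- predict(letters_model, scores$item)
  ov <- neighbor_predictors(scores$item, lexicon)$ortho_valence
  fit <- lm(scores$score ~ lp + ov)
  structure(list(letters_model = letters_model, lexicon = lexicon,
                 combined_coefficients = coef(fit)),
            class = "string_predictor")
}

#' Estimate the valence of one pseudoword three ways
#'
#' Returns the letters-model predicted valence, the mean valence of the
#' closest orthographic neighbor(s), and the additive combination, i.e. the
#' fitted two-predictor regression's prediction (not a raw sum). The first
#' two are on the 1-9 rating scale; the combination lives on the scale of
#' the observed value-learning scores it was trained on.
#'
#' @param string a lowercase alphabetic string.
#' @param predictor a [train_string_predictor()] result.
#' @return Named numeric vector: `letters`, `orthographic`, `combined`.
#' @export
predict_string <- function(string, predictor) {
  stopifnot(inherits(predictor, "string_predictor"))
  assert_word(string, "string")
  lp <- unname(predict(predictor$letters_model, string))
  ov <- nearest_orthographic(string, predictor$lexicon)$neighbor_valence
  cf <- predictor$combined_coefficients
  c(letters = lp, orthographic = ov,
    combined = unname(cf[1L] + cf[2L] * lp + cf[3L] * ov))
}
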