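#' Fit a linear valence model on surface-form and semantic features
#'
#' The central estimator of the package: ordinary least squares of mean
#' valence ratings on the feature blocks selected by a [feature_spec()]
#' (letter counts, interior bigram counts, boundary indicators, embedding
#' dimensions). High-dimensional bigram blocks are routinely rank deficient
#' (most of the 676 ordered letter pairs never occur); the fit therefore uses
#' the minimum-norm least-squares solution via the singular value
#' decomposition and records which columns were aliased.
#'
#' @param lexicon a [clean_lexicon()] (or any data.frame with `word` and
#'   `valence` columns) providing the training words and their ratings.
#' @param spec a [feature_spec()] selecting predictor blocks.
#' @param embeddings an [embedding_table()], required when the spec includes
#'   embedding dimensions.
#' @param design optional precomputed design matrix (rows aligned with
#'   `lexicon`); skips featurization, e.g. when fitting several specs on
#'   shared blocks.
#' @param include_word_vector passed to [build_design_matrix()].
#' @return An object of class `valence_model` with components `spec`,
#'   `intercept`, `coefficients` (named, aliased columns reported in
#'   `aliased`), `fitted.values`, `residuals`, `rss`, `rank`, `training_n`
#'   and `n_dims`.
#' @seealso [predict.valence_model()], [fit_stats()], [compare_valence_models()]
#' @examples
#' lex <- generate_lexicon(sim_config(n_words = 300, seed = 1))$lexicon
#' m <- valence_model(lex, feature_spec(letters = TRUE))
#' predict(m, c("bun", "smug"))
#' @export
valence_model <- function(lexicon, spec = feature_spec(letters = TRUE),
                          embeddings = NULL, design = NULL,
                          include_word_vector = FALSE) {
  stopifnot(is.data.frame(lexicon), all(c("word", "valence") %in% names(lexicon)))
  y <- as.numeric(lexicon$valence)
  if (is.null(design))
    design <- build_design_matrix(lexicon$word, spec, embeddings,
                                  include_word_vector = include_word_vector)
  fit <- min_norm_ols(design, y)
  structure(list(spec = spec,
                 intercept = fit$intercept,
                 coefficients = fit$coefficients,
                 aliased = fit$aliased,
                 fitted.values = fit$fitted,
                 residuals = y - fit$fitted,
                 rss = sum((y - fit$fitted)^2),
                 rank = fit$rank,
                 training_n = length(y),
                 observed = y,
                 n_dims = if (spec$dimensions) ncol(design) - length(feature_labels(spec, 0L)) else 0L,
                 call = match.call()),
            class = "valence_model")
}

# Minimum-norm OLS via SVD of the centered problem. The intercept is handled
# by centering so it never competes with collinear indicator blocks. Columns
# whose singular directions are discarded (below tol) are reported as
# aliased; all-zero columns (never-occurring bigrams) are the common case.
min_norm_ols <- function(X, y, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop("design rows and response length differ")
  if (n <= p)
    stop(sprintf(paste("only %d observations for %d predictors;",
                       "use a larger lexicon or a smaller feature spec"), n, p))
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  sv <- svd(Xc)
  keep <- sv$d > tol * max(sv$d, 1)
  r <- sum(keep)
  beta <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y - ybar)) / sv$d[keep])
  beta <- drop(beta)
  names(beta) <- colnames(X)
  zero_cols <- colnames(X)[apply(X, 2L, function(col) all(col == col[1L]))]
  list(intercept = ybar - sum(xbar * beta),
       coefficients = beta,
       fitted = drop(Xc %*% beta) + ybar,
       rank = r + 1L,  # slopes rank + intercept
       aliased = zero_cols)
}

#' @export
print.valence_model <- function(x, ...) {
  cat("Linear valence model\n")
  on <- names(Filter(isTRUE, unclass(x$spec)))
  cat("  features: ", paste(on, collapse = " + "), "\n", sep = "")
  cat(sprintf("  %d training words, %d columns (rank %d incl. intercept, %d aliased)\n",
              x$training_n, length(x$coefficients), x$rank, length(x$aliased)))
  cat(sprintf("  intercept %.4f, RSS %.4f\n", x$intercept, x$rss))
  invisible(x)
}

#' @export
coef.valence_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
fitted.valence_model <- function(object, ...) object$fitted.values

#' @export
residuals.valence_model <- function(object, ...) object$residuals

#' Predict valence for arbitrary strings
#'
#' Applies a fitted [valence_model()] to new strings, featurizing them under
#' the model's spec. Predictions are deliberately not clamped to the 1-9
#' rating scale: extreme strings can score outside it.
#'
#' @param object a `valence_model`.
#' @param newdata character vector of strings, or a precomputed design matrix
#'   with the model's columns.
#' @param embeddings an [embedding_table()] when the spec uses dimensions.
#' @param include_word_vector passed to featurization.
#' @param ... unused.
#' @return Named numeric vector of predicted valences.
#' @export
predict.valence_model <- function(object, newdata, embeddings = NULL,
                                  include_word_vector = FALSE, ...) {
  design <- if (is.matrix(newdata)) newdata
  else build_design_matrix(newdata, object$spec, embeddings,
                           include_word_vector = include_word_vector)
  if (ncol(design) != length(object$coefficients))
    stop("design has wrong number of columns for this model")
  drop(design %*% object$coefficients) + object$intercept
}

#' @export
summary.valence_model <- function(object, ...) {
  stats <- fit_stats(object)
  out <- list(model = object, stats = stats)
  class(out) <- "summary.valence_model"
  out
}

#' @export
print.summary.valence_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  in-sample R^2 = %.4f, r = %.4f, AIC = %.1f (n = %d, k = %d)\n",
              x$stats$r_squared, x$stats$r, x$stats$aic, x$stats$n, x$stats$k))
  invisible(x)
}

#' Fit statistics: R-squared, correlation and AIC
#'
#' Computes `R^2 = 1 - RSS/TSS`, `r = cor(fitted, observed)` and a Gaussian
#' log-likelihood AIC under the convention `AIC = n*log(RSS/n) + 2k`, with
#' `k` counting the estimated slopes' rank, the intercept and the error
#' variance. The additive AIC constant differs across software; orderings,
#' not absolute values, are the comparable quantity.
#'
#' @param object a `valence_model`, or a numeric vector of fitted values.
#' @param observed observed response; defaults to the model's training
#'   response.
#' @param k parameter count including intercept; required (or derived) when
#'   `object` is a plain vector.
#' @return List with `r_squared`, `r`, `aic`, `n`, `k`.
#' @export
fit_stats <- function(object, observed = NULL, k = NULL) {
  if (inherits(object, "valence_model")) {
    fitted_v <- object$fitted.values
    if (is.null(observed)) observed <- object$observed
    if (is.null(k)) k <- object$rank
  } else {
    fitted_v <- as.numeric(object)
    if (is.null(observed) || is.null(k)) stop("observed and k required")
  }
  n <- length(observed)
  if (var(observed) == 0) stop("observed values have zero variance")
  rss <- sum((observed - fitted_v)^2)
  tss <- sum((observed - mean(observed))^2)
  r <- if (var(fitted_v) == 0) 0 else cor(fitted_v, observed)
  list(r_squared = 1 - rss / tss,
       r = r,
       aic = n * log(rss / n) + 2 * (k + 1),
       n = n, k = k)
}

#' Compare valence models on a common item set
#'
#' Fits and scores a family of models against the same observed values. Each
#' entry of `models` is either a [feature_spec()] -- fitted by OLS on the
#' item strings -- or a numeric predictor vector (for instance a predicted
#' valence index or a neighbor-valence index), in which case the comparison
#' model is the univariate regression of the observed values on that
#' predictor.
#'
#' @param models named list of `feature_spec`s and/or numeric vectors.
#' @param observed numeric vector of observed valence (ratings or best-worst
#'   value scores).
#' @param words character vector of item strings; required when any entry is
#'   a `feature_spec`.
#' @param embeddings an [embedding_table()] for dimension specs.
#' @return Object of class `valence_model_comparison`: a data.frame with one
#'   row per model (`model`, `r`, `r_squared`, `aic`, `n`, `k`) plus rank
#'   columns by R-squared and by AIC.
#' @export
compare_valence_models <- function(models, observed, words = NULL,
                                   embeddings = NULL) {
  stopifnot(is.list(models), length(models) > 0L, !is.null(names(models)))
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    if (inherits(m, "feature_spec")) {
      if (is.null(words)) stop("words required to fit feature specs")
      lex <- data.frame(word = words, valence = observed, stringsAsFactors = FALSE)
      fitm <- valence_model(lex, m, embeddings)
      st <- fit_stats(fitm)
    } else if (is.numeric(m)) {
      if (length(m) != length(observed)) stop(sprintf("predictor '%s' misaligned with observed items", nm))
      lmfit <- lm(observed ~ m)
      st <- fit_stats(fitted(lmfit), observed, k = 2L)
    } else stop(sprintf("model '%s' is neither a feature_spec nor a numeric predictor", nm))
    data.frame(model = nm, r = st$r, r_squared = st$r_squared, aic = st$aic,
               n = st$n, k = st$k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank_r_squared <- rank(-out$r_squared, ties.method = "min")
  out$rank_aic <- rank(out$aic, ties.method = "min")
  class(out) <- c("valence_model_comparison", "data.frame")
  out
}

#' @export
print.valence_model_comparison <- function(x, digits = 3, ...) {
  cat("Model comparison (", nrow(x), " models, n = ", x$n[1L], " items)\n", sep = "")
  df <- as.data.frame(x)
  df$r <- round(df$r, digits); df$r_squared <- round(df$r_squared, digits)
  df$aic <- round(df$aic, 1)
  print(df[order(df$rank_aic), c("model", "r", "r_squared", "aic", "rank_r_squared", "rank_aic")],
        row.names = FALSE)
  invisible(x)
}

#' Nested-model F test
#'
#' Standard extra-sum-of-squares F test comparing a smaller linear model to a
#' larger one fit on the same observations, used to decide whether adding a
#' predictor block (e.g. a neighbor-valence index) significantly improves an
#' observed-valence regression.
#'
#' @param observed response vector.
#' @param predictors_small,predictors_large numeric matrices (or vectors) of
#'   predictors; the small set must be a subset of the large set's columns in
#'   the nesting sense (not checked symbolically).
#' @return List with `f`, `df1`, `df2`, `p_value`.
#' @export
nested_f_test <- function(observed, predictors_small, predictors_large) {
  small <- lm(observed ~ ., data = as.data.frame(as.matrix(predictors_small)))
  large <- lm(observed ~ ., data = as.data.frame(as.matrix(predictors_large)))
  rss0 <- sum(residuals(small)^2); rss1 <- sum(residuals(large)^2)
  df1 <- small$df.residual - large$df.residual
  df2 <- large$df.residual
  if (df1 <= 0) stop("models are not nested (no added parameters)")
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(f = f, df1 = df1, df2 = df2, p_value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Serialize / restore a valence model as JSON
#'
#' Writes a versioned JSON document holding the spec flags, column labels,
#' intercept and coefficients, so a trained model can be shipped and reused
#' without the training data.
#'
#' @param model a `valence_model`.
#' @param path output (input) file path.
#' @return `save_valence_model` returns the path; `load_valence_model` a
#'   `valence_model` (prediction-capable; training diagnostics are not
#'   restored).
#' @export
save_valence_model <- function(model, path) {
  stopifnot(inherits(model, "valence_model"))
  doc <- list(format = "pseudovalence-model", version = 1L,
              spec = unclass(model$spec),
              intercept = model$intercept,
              labels = names(model$coefficients),
              coefficients = unname(model$coefficients),
              training_n = model$training_n,
              rank = model$rank,
              n_dims = model$n_dims)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_valence_model
#' @export
load_valence_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "pseudovalence-model")) stop("not a valence-model file")
  spec <- do.call(feature_spec, as.list(doc$spec))
  structure(list(spec = spec,
                 intercept = doc$intercept,
                 coefficients = setNames(doc$coefficients, doc$labels),
                 aliased = character(0),
                 fitted.values = NULL, residuals = NULL, rss = NA_real_,
                 rank = doc$rank, training_n = doc$training_n,
                 observed = NULL, n_dims = doc$n_dims,
                 call = quote(load_valence_model())),
            class = "valence_model")
}
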