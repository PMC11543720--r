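#' Clean a raw valence-norms table
#'
#' Keeps only entries whose word is a plain lowercase alphabetic string (no
#' punctuation, capitals or whitespace), dropping duplicated words while
#' keeping the first occurrence. This mirrors the standard preprocessing of
#' published valence norms before surface-form featurization.
#'
#' @param words character vector of words.
#' @param valence numeric vector of mean valence ratings on the 1-9 scale.
#' @param quiet suppress the message reporting how many entries were removed.
#' @return A data.frame of class `clean_lexicon` with columns `word` and
#'   `valence`.
#' @examples
#' clean_lexicon(c("bus", "O'Neil", "two words"), c(5, 6, 4))
#' @export
clean_lexicon <- function(words, valence, quiet = FALSE) {
  if (length(words) == 0L) stop("raw entries must be non-empty")
  if (length(words) != length(valence)) stop("words and valence differ in length")
  if (!is.numeric(valence)) stop("valence must be numeric")
  keep <- is_clean_word(words) & !is.na(valence)
  words2 <- words[keep]
  valence2 <- valence[keep]
  dup <- duplicated(words2)
  n_removed <- sum(!keep) + sum(dup)
  out <- data.frame(word = words2[!dup], valence = valence2[!dup],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) stop("no valid entries after cleaning")
  if (!quiet && n_removed > 0L)
    message(sprintf("clean_lexicon: removed %d of %d entries (%d malformed/NA, %d duplicates)",
                    n_removed, length(words), sum(!keep), sum(dup)))
  class(out) <- c("clean_lexicon", "data.frame")
  out
}

#' Read a valence-norms file
#'
#' Reads a CSV/TSV norms table (UTF-8) and returns a cleaned lexicon. Column
#' names default to those of the widely used Warriner-style release.
#'
#' @param path file path.
#' @param word_col,valence_col column names holding the word and its mean
#'   valence.
#' @param sep field separator; `""` guesses from the file extension.
#' @inheritParams clean_lexicon
#' @return A `clean_lexicon` data.frame.
#' @export
read_norms <- function(path, word_col = "Word", valence_col = "V.Mean.Sum",
                       sep = "", quiet = FALSE) {
  if (!nzchar(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c(word_col, valence_col) %in% names(raw)))
    stop(sprintf("columns '%s' and '%s' not found in %s", word_col, valence_col, path))
  clean_lexicon(as.character(raw[[word_col]]), as.numeric(raw[[valence_col]]),
                quiet = quiet)
}

#' Letter counts of a word
#'
#' @param word a single lowercase alphabetic string.
#' @return Named integer vector of length 26 (a..z) counting how many times
#'   each letter occurs; the counts sum to `nchar(word)`.
#' @examples
#' letter_counts("happiness")
#' @export
letter_counts <- function(word) {
  assert_word(word)
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  tab <- table(factor(chars, levels = ALPHABET))
  setNames(as.integer(tab), letter_labels())
}

#' Interior bigram counts of a word
#'
#' Counts every ordered pair of adjacent letters inside the word. Word
#' boundary information is carried separately by [boundary_indicators()].
#'
#' @inheritParams letter_counts
#' @return Named integer vector of length 676 (aa..zz, row-major); counts sum
#'   to `nchar(word) - 1`.
#' @examples
#' bigram_counts("bus")
#' @export
bigram_counts <- function(word) {
  assert_word(word)
  n <- nchar(word)
  out <- setNames(integer(676L), bigram_labels())
  if (n >= 2L) {
    chars <- strsplit(word, "", fixed = TRUE)[[1L]]
    bg <- paste0(chars[-n], chars[-1L])
    tab <- table(factor(bg, levels = bigram_labels()))
    out <- setNames(as.integer(tab), bigram_labels())
  }
  out
}

#' Word-boundary indicators
#'
#' Indicator features for the first and last letter of a word, the `<b` and
#' `s>` style boundary markers of the word "bus".
#'
#' @inheritParams letter_counts
#' @return Named integer vector of length 52: 26 start flags (`<a`..`<z`)
#'   followed by 26 end flags (`a>`..`z>`); exactly one of each is set.
#' @export
boundary_indicators <- function(word) {
  assert_word(word)
  start <- setNames(integer(26L), start_labels())
  end <- setNames(integer(26L), end_labels())
  start[paste0("<", substr(word, 1L, 1L))] <- 1L
  end[paste0(substr(word, nchar(word), nchar(word)), ">")] <- 1L
  c(start, end)
}

#' Specify a surface-form / semantic feature set
#'
#' Selects which predictor blocks enter a design matrix. Column order is
#' fixed for reproducibility: letters a..z, interior bigrams aa..zz
#' (row-major), start indicators, end indicators, then embedding dimensions.
#'
#' @param letters,bigrams,boundaries,dimensions logical flags selecting the
#'   26 letter counts, 676 interior bigram counts, 52 boundary indicators and
#'   the embedding dimensions.
#' @return An object of class `feature_spec`.
#' @examples
#' feature_spec(letters = TRUE, bigrams = TRUE, boundaries = TRUE)
#' @export
feature_spec <- function(letters = FALSE, bigrams = FALSE, boundaries = FALSE,
                         dimensions = FALSE) {
  if (!any(letters, bigrams, boundaries, dimensions))
    stop("at least one feature block must be selected")
  structure(list(letters = letters, bigrams = bigrams, boundaries = boundaries,
                 dimensions = dimensions),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  on <- names(Filter(isTRUE, unclass(x)))
  cat("Feature set:", paste(on, collapse = " + "), "\n")
  invisible(x)
}

#' The seven canonical model specifications
#'
#' All combinations of the three information sources used throughout the
#' valence-modelling workflow: letters; bigrams; embedding dimensions;
#' letters + bigrams; letters + dimensions; bigrams + dimensions; and the
#' full model. Whenever bigrams are included the boundary indicators are
#' included with them, since word-initial/final markers are treated as
#' bigrams (`<b`, `s>`): letters + bigrams therefore spans 754 columns and
#' the full model 754 + D.
#'
#' @return Named list of [feature_spec()] objects.
#' @export
seven_model_specs <- function() {
  list(
    letters = feature_spec(letters = TRUE),
    bigrams = feature_spec(bigrams = TRUE, boundaries = TRUE),
    dimensions = feature_spec(dimensions = TRUE),
    letters_bigrams = feature_spec(letters = TRUE, bigrams = TRUE, boundaries = TRUE),
    letters_dimensions = feature_spec(letters = TRUE, dimensions = TRUE),
    bigrams_dimensions = feature_spec(bigrams = TRUE, boundaries = TRUE, dimensions = TRUE),
    full = feature_spec(letters = TRUE, bigrams = TRUE, boundaries = TRUE,
                        dimensions = TRUE)
  )
}

feature_labels <- function(spec, n_dims = 0L) {
  c(if (spec$letters) letter_labels(),
    if (spec$bigrams) bigram_labels(),
    if (spec$boundaries) c(start_labels(), end_labels()),
    if (spec$dimensions) dim_labels(n_dims))
}

#' Build a design matrix for a set of strings
#'
#' Rows follow the input order; columns follow the fixed ordering documented
#' in [feature_spec()]. When the spec includes embedding dimensions, each
#' string's semantic vector is composed from the table's character 4-grams
#' via [compose_vector()].
#'
#' @param words character vector of lowercase alphabetic strings.
#' @param spec a [feature_spec()].
#' @param embeddings an [embedding_table()]; required when
#'   `spec$dimensions` is `TRUE`.
#' @param include_word_vector passed to [compose_vector()]: also add the
#'   whole-string vector when the table has one.
#' @return Numeric matrix with one row per word and labelled columns.
#' @examples
#' m <- build_design_matrix(c("bus", "sub"), feature_spec(letters = TRUE))
#' dim(m)
#' @export
build_design_matrix <- function(words, spec, embeddings = NULL,
                                include_word_vector = FALSE) {
  stopifnot(inherits(spec, "feature_spec"))
  if (spec$dimensions && is.null(embeddings))
    stop("spec includes embedding dimensions but no embedding table was given")
  vapply(words, assert_word, character(1))
  n_dims <- if (spec$dimensions) embeddings$dimension else 0L
  labels <- feature_labels(spec, n_dims)
  out <- matrix(0, nrow = length(words), ncol = length(labels),
                dimnames = list(words, labels))
  for (i in seq_along(words)) {
    w <- words[i]
    row <- c(if (spec$letters) letter_counts(w),
             if (spec$bigrams) bigram_counts(w),
             if (spec$boundaries) boundary_indicators(w),
             if (spec$dimensions) compose_vector(w, embeddings,
                                                 include_word_vector = include_word_vector))
    out[i, ] <- row
  }
  out
}

#' Write a design matrix as CSV
#'
#' @param design matrix from [build_design_matrix()].
#' @param path output file.
#' @export
write_design_matrix <- function(design, path) {
  df <- data.frame(word = rownames(design), design, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
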