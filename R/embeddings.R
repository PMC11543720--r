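#' Construct an embedding table
#'
#' A table mapping character n-gram keys (containing the boundary markers
#' `<` and `>`) and optionally whole-word keys to fixed-dimension real
#' vectors, the container behind subword semantic-vector composition.
#'
#' @param vectors named list (or matrix with rownames) of vectors to be
#'   classified automatically: keys containing a boundary marker, or of
#'   exactly `ngram_n` characters, become n-gram keys; all others whole-word
#'   keys. Interior n-grams of long strings carry no markers, which is why
#'   plain length participates in the rule.
#' @param ngrams,words named lists (or matrices with rownames) assigned
#'   explicitly, bypassing classification; this is the unambiguous interface
#'   (a 4-letter word and an identical interior 4-gram may coexist).
#' @param ngram_n n-gram length used by the classification rule.
#' @return Object of class `embedding_table` with fields `dimension`,
#'   `ngram_vectors` and `word_vectors` (both environments keyed by string).
#' @examples
#' tab <- embedding_table(list("<bus" = c(1, 0), "bus>" = c(0, 1)))
#' compose_vector("bus", tab)
#' @export
embedding_table <- function(vectors = NULL, ngrams = NULL, words = NULL,
                            ngram_n = 4L) {
  as_list <- function(x) {
    if (is.null(x)) return(list())
    if (is.matrix(x)) {
      keys <- rownames(x)
      x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
      names(x) <- keys
    }
    x
  }
  vectors <- as_list(vectors); ngrams <- as_list(ngrams); words <- as_list(words)
  if (length(vectors)) {
    is_gram <- grepl("[<>]", names(vectors)) | nchar(names(vectors)) == ngram_n
    ngrams <- c(ngrams, vectors[is_gram])
    words <- c(words, vectors[!is_gram])
  }
  all_keys <- c(names(ngrams), names(words))
  if (length(all_keys) == 0L) stop("empty embedding table")
  if (is.null(all_keys) || any(!nzchar(all_keys))) stop("all vectors must be named")
  dims <- c(lengths(ngrams), lengths(words))
  if (length(unique(dims)) != 1L) stop("vectors differ in dimension")
  ngram_env <- list2env(lapply(ngrams, as.numeric), parent = emptyenv())
  word_env <- list2env(lapply(words, as.numeric), parent = emptyenv())
  structure(list(dimension = as.integer(dims[[1L]]),
                 ngram_vectors = ngram_env, word_vectors = word_env),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("Embedding table: %d n-gram keys, %d word keys, dimension %d\n",
              length(ls(x$ngram_vectors)), length(ls(x$word_vectors)), x$dimension))
  invisible(x)
}

#' Character n-grams of a boundary-wrapped string
#'
#' The string is wrapped in the boundary markers `<` and `>` and all
#' contiguous substrings of length `n` of the wrapped string are returned in
#' order, duplicates retained. With the default `n = 4`, `"bus"` yields
#' `"<bus"` and `"bus>"`.
#'
#' @param string a single non-empty lowercase string.
#' @param n n-gram length (default 4).
#' @return Character vector of n-grams; empty if the wrapped string is
#'   shorter than `n`.
#' @export
extract_ngrams <- function(string, n = 4L) {
  if (n < 1L) stop("n must be >= 1")
  assert_word(string, "string")
  wrapped <- paste0("<", string, ">")
  len <- nchar(wrapped)
  if (len < n) return(character(0))
  starts <- seq_len(len - n + 1L)
  substring(wrapped, starts, starts + n - 1L)
}

#' Compose a semantic vector for an arbitrary string
#'
#' Sums the embedding vectors of the string's character 4-grams (boundary
#' markers included), optionally adding the whole-string vector when the
#' table holds one -- the standard subword composition that gives
#' out-of-vocabulary strings, e.g. pseudowords, a position in semantic space.
#'
#' @param string lowercase string to compose.
#' @param table an [embedding_table()].
#' @param include_word_vector also add the whole-string vector if present.
#' @param n n-gram length.
#' @param normalize one of `"sum"` (default) or `"mean"`; `"mean"` divides by
#'   the number of vectors summed.
#' @return Numeric vector of the table's dimension.
#' @export
compose_vector <- function(string, table, include_word_vector = FALSE,
                           n = 4L, normalize = c("sum", "mean")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(table, "embedding_table"))
  grams <- extract_ngrams(string, n)
  out <- numeric(table$dimension)
  used <- 0L
  missing <- 0L
  for (g in grams) {
    v <- get0(g, envir = table$ngram_vectors, inherits = FALSE)
    if (is.null(v)) missing <- missing + 1L else { out <- out + v; used <- used + 1L }
  }
  if (include_word_vector) {
    v <- get0(string, envir = table$word_vectors, inherits = FALSE)
    if (!is.null(v)) { out <- out + v; used <- used + 1L }
  }
  if (used == 0L)
    stop(sprintf("'%s' is not composable: none of its %d n-grams are in the table",
                 string, length(grams)))
  attr_out <- if (normalize == "mean") out / used else out
  structure(attr_out, n_used = used, n_missing = missing)
}

#' Is a whole-word vector available for a string?
#'
#' Pseudoword candidates for which the embedding model learned a dedicated
#' whole-string vector (e.g. from typos in the training corpus) are usually
#' excluded from stimulus pools; this is the membership test behind that
#' filter.
#'
#' @inheritParams compose_vector
#' @return `TRUE` iff `string` is a whole-word key of the table.
#' @export
has_whole_word_vector <- function(string, table) {
  stopifnot(inherits(table, "embedding_table"))
  !is.null(get0(string, envir = table$word_vectors, inherits = FALSE))
}

#' Cosine distance between two vectors
#'
#' `1 - cos(v1, v2)`, ranging over \[0, 2\]: 0 for parallel, 1 for
#' orthogonal, 2 for opposite vectors.
#'
#' @param v1,v2 non-zero numeric vectors of equal length.
#' @return A number in \[0, 2\].
#' @export
cosine_distance <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors differ in dimension")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("cosine distance undefined for the zero vector")
  1 - sum(v1 * v2) / (n1 * n2)
}

#' Read an embedding table from word2vec-style text
#'
#' Expects the `.vec` text layout: a header line `"<count> <dimension>"`,
#' then one key and `dimension` floats per line, space-separated. Keys
#' containing `<` or `>`, or of exactly `ngram_n` characters, are treated as
#' n-gram keys, all others as whole-word keys (the flat file format has no
#' separate namespaces). Transparent to gzip via [base::gzfile()].
#'
#' @param path file path (`.vec`, optionally gzipped).
#' @param restrict_to optional character vector; only these keys are loaded.
#' @param ngram_n n-gram length for key classification.
#' @return An [embedding_table()].
#' @export
load_embedding_table <- function(path, restrict_to = NULL, ngram_n = 4L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  header <- strsplit(trimws(readLines(con, n = 1L)), "\\s+")[[1L]]
  if (length(header) != 2L) stop("malformed header line")
  dim <- as.integer(header[2L])
  vecs <- list()
  line_no <- 1L
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) break
    line_no <- line_no + 1L
    parts <- strsplit(trimws(ln), " ", fixed = TRUE)[[1L]]
    key <- parts[1L]
    if (!is.null(restrict_to) && !(key %in% restrict_to)) next
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (length(vals) != dim || anyNA(vals))
      stop(sprintf("line %d: expected %d numeric values for key '%s'",
                   line_no, dim, key))
    vecs[[key]] <- vals
  }
  embedding_table(vecs, ngram_n = ngram_n)
}

#' Write an embedding table in word2vec-style text
#'
#' @param table an [embedding_table()].
#' @param path output path; a `.gz` suffix writes gzipped text.
#' @export
save_embedding_table <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  keys <- c(ls(table$ngram_vectors), ls(table$word_vectors))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(keys), table$dimension), con)
  for (k in keys) {
    v <- get0(k, envir = table$ngram_vectors, inherits = FALSE)
    if (is.null(v)) v <- get(k, envir = table$word_vectors)
    writeLines(paste(k, paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
                              collapse = " ")), con)
  }
  invisible(path)
}

embedding_keys <- function(table) {
  c(ls(table$ngram_vectors), ls(table$word_vectors))
}

# Word vectors of a set of strings as a matrix (rows = strings), composing
# out-of-vocabulary strings from n-grams; stored whole-word vectors are used
# when present and preferred.
word_vector_matrix <- function(words, table, prefer_stored = TRUE) {
  out <- matrix(0, nrow = length(words), ncol = table$dimension,
                dimnames = list(words, NULL))
  for (i in seq_along(words)) {
    w <- words[i]
    v <- if (prefer_stored) get0(w, envir = table$word_vectors, inherits = FALSE)
    if (is.null(v)) v <- as.numeric(compose_vector(w, table))
    out[i, ] <- v
  }
  out
}
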