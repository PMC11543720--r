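#' Optimal string alignment (restricted Damerau-Levenshtein) distance
#'
#' Minimum number of unit-cost edits (insertion, deletion, substitution,
#' adjacent transposition) turning one string into the other, under the OSA
#' restriction that a transposed substring is never edited again. This is
#' the standard default of string-distance libraries; it differs from the
#' unrestricted Damerau-Levenshtein distance, e.g. `osa_distance("ca",
#' "abc")` is 3, not 2.
#'
#' @param s1,s2 character vectors over a-z (empty strings allowed); recycled
#'   to a common length.
#' @return Integer vector of distances.
#' @export
osa_distance <- function(s1, s2) {
  ok <- function(x) all(grepl("^[a-z]*$", x))
  if (!ok(s1) || !ok(s2)) stop("strings must be lowercase a-z")
  cpp_osa_distance(as.character(s1), as.character(s2))
}

#' Nearest orthographic neighbors in a lexicon
#'
#' Scans the full lexicon for the word(s) at minimal [osa_distance()] from
#' the query. Because the distance is integer-valued, ties are common; all
#' tied words are returned and their valences averaged (unweighted) into the
#' `neighbor_valence` predictor.
#'
#' @param query a pseudoword string.
#' @param lexicon a [clean_lexicon()] (columns `word`, `valence`).
#' @return Object of class `neighbor_result`: list with `query`, `neighbors`,
#'   `distance`, `neighbor_valence`.
#' @export
nearest_orthographic <- function(query, lexicon) {
  assert_word(query, "query")
  if (nrow(lexicon) == 0L) stop("lexicon is empty")
  d <- cpp_osa_distance(query, lexicon$word)
  dmin <- min(d)
  hit <- which(d == dmin)
  structure(list(query = query, neighbors = lexicon$word[hit],
                 distance = dmin,
                 neighbor_valence = mean(lexicon$valence[hit])),
            class = "neighbor_result")
}

#' Nearest semantic neighbor by cosine distance
#'
#' Finds the lexicon word whose stored vector has minimal cosine distance
#' from the query's composed vector. Words on `exclude` -- typically
#' poorly-embedded "hub" words that win for a disproportionate share of
#' queries, see [hub_report()] -- are removed before the scan. Exact ties
#' (rare with real-valued vectors) are all returned with their mean valence.
#'
#' @param query_vector numeric vector for the query (e.g. from
#'   [compose_vector()]).
#' @param lexicon_vectors numeric matrix, one row per lexicon word, rownames
#'   = words.
#' @param valence numeric vector of the words' valences, aligned with the
#'   matrix rows.
#' @param exclude character vector of words to remove before the scan.
#' @param query optional query string recorded in the result.
#' @return A `neighbor_result` (distance is the cosine distance).
#' @export
nearest_semantic <- function(query_vector, lexicon_vectors, valence,
                             exclude = character(0), query = NA_character_) {
  stopifnot(is.matrix(lexicon_vectors),
            length(valence) == nrow(lexicon_vectors))
  keep <- !(rownames(lexicon_vectors) %in% exclude)
  if (!any(keep)) stop("exclusion list removes the entire lexicon")
  M <- lexicon_vectors[keep, , drop = FALSE]
  val <- valence[keep]
  qn <- sqrt(sum(query_vector^2))
  if (qn == 0) stop("query vector is zero")
  rown <- sqrt(rowSums(M^2))
  if (any(rown == 0)) stop("lexicon contains a zero vector")
  d <- 1 - drop(M %*% query_vector) / (rown * qn)
  dmin <- min(d)
  hit <- which(d == dmin)
  structure(list(query = query, neighbors = rownames(M)[hit],
                 distance = dmin, neighbor_valence = mean(val[hit])),
            class = "neighbor_result")
}

#' @export
print.neighbor_result <- function(x, ...) {
  cat(sprintf("Nearest neighbor(s) of '%s': %s (distance %.4g, mean valence %.3f)\n",
              x$query, paste(x$neighbors, collapse = ", "), x$distance,
              x$neighbor_valence))
  invisible(x)
}

#' Neighbor-valence predictors for a batch of queries
#'
#' Convenience wrapper computing, for each query pseudoword, the mean valence
#' of its closest orthographic neighbors and/or of its closest semantic
#' neighbor.
#'
#' @param queries character vector of pseudowords.
#' @param lexicon a [clean_lexicon()].
#' @param embeddings an [embedding_table()]; `NULL` skips the semantic
#'   predictor.
#' @param semantic_exclude hub words excluded from the semantic scan.
#' @return data.frame with columns `query`, `ortho_valence`, `ortho_distance`
#'   and (when embeddings are given) `sem_valence`, `sem_distance`.
#' @export
neighbor_predictors <- function(queries, lexicon, embeddings = NULL,
                                semantic_exclude = character(0)) {
  ortho <- lapply(queries, nearest_orthographic, lexicon = lexicon)
  out <- data.frame(query = queries,
                    ortho_valence = vapply(ortho, `[[`, numeric(1), "neighbor_valence"),
                    ortho_distance = vapply(ortho, `[[`, numeric(1), "distance"),
                    stringsAsFactors = FALSE)
  if (!is.null(embeddings)) {
    M <- word_vector_matrix(lexicon$word, embeddings)
    sem <- lapply(queries, function(q) {
      nearest_semantic(as.numeric(compose_vector(q, embeddings)), M,
                       lexicon$valence, exclude = semantic_exclude, query = q)
    })
    out$sem_valence <- vapply(sem, `[[`, numeric(1), "neighbor_valence")
    out$sem_distance <- vapply(sem, `[[`, numeric(1), "distance")
  }
  out
}

#' Report semantic-neighbor hubs
#'
#' Counts how often each lexicon word is the single nearest semantic
#' neighbor across a set of queries. Words whose share of wins exceeds
#' `threshold` are flagged as hub candidates: poorly-embedded vectors that
#' attract out-of-vocabulary queries and should usually be placed on the
#' exclusion list of [nearest_semantic()]. Detection assists; exclusion
#' stays a configured decision.
#'
#' @param query_vectors numeric matrix of query vectors (rows = queries).
#' @param lexicon_vectors numeric matrix of word vectors, rownames = words.
#' @param threshold share of queries above which a word is flagged
#'   (default 0.05).
#' @return data.frame with columns `word`, `times_nearest`, `share`,
#'   `is_hub`, sorted by share; only words that win at least once appear.
#' @export
hub_report <- function(query_vectors, lexicon_vectors, threshold = 0.05) {
  stopifnot(is.matrix(query_vectors), is.matrix(lexicon_vectors))
  if (nrow(query_vectors) == 0L) stop("need at least one query")
  rown <- sqrt(rowSums(lexicon_vectors^2))
  qn <- sqrt(rowSums(query_vectors^2))
  sims <- (query_vectors %*% t(lexicon_vectors)) / outer(qn, rown)
  winners <- rownames(lexicon_vectors)[apply(sims, 1L, which.max)]
  tab <- sort(table(winners), decreasing = TRUE)
  out <- data.frame(word = names(tab), times_nearest = as.integer(tab),
                    share = as.numeric(tab) / nrow(query_vectors),
                    stringsAsFactors = FALSE)
  out$is_hub <- out$share > threshold
  out
}

#' Write neighbor predictor tables as CSV
#'
#' @param table a data.frame from [neighbor_predictors()]; multiple
#'   neighbors are semicolon-joined upstream so rows stay atomic.
#' @param path file path.
#' @export
write_neighbors_csv <- function(table, path) {
  write.table(table, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
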