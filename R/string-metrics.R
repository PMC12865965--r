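#' Character n-gram set of a string
#'
#' Distinct overlapping character n-grams, without boundary padding.
#' Strings shorter than `n` yield an empty set.
#'
#' @param x a single string.
#' @param n n-gram size (>= 1).
#' @return character vector of distinct n-grams.
#' @export
#' @examples
#' char_ngrams("abc", 2) # "ab" "bc"
char_ngrams <- function(x, n = 2L) {
  if (n < 1) abort_rx("n-gram size must be >= 1", "rxh_parameter_error")
  len <- nchar(x)
  if (is.na(len) || len < n) return(character(0))
  unique(substring(x, seq_len(len - n + 1L), seq.int(n, len)))
}

#' Jaccard similarity over character n-gram sets
#'
#' `|ngrams(a) ∩ ngrams(b)| / |ngrams(a) ∪ ngrams(b)|`, with n-grams
#' taken as sets (multiplicity ignored). If either string is shorter than
#' `n`, the score falls back to exact equality (1 or 0). Symmetric and
#' bounded in \[0, 1\].
#'
#' @param a,b strings (assumed already normalized).
#' @param n n-gram size; bigrams by default.
#' @return similarity in \[0, 1\].
#' @export
#' @examples
#' jaccard_ngram("abc", "abd") # 1/3
jaccard_ngram <- function(a, b, n = 2L) {
  if (n < 1) abort_rx("n-gram size must be >= 1", "rxh_parameter_error")
  if (nchar(a) < n || nchar(b) < n) return(as.numeric(a == b))
  ga <- char_ngrams(a, n)
  gb <- char_ngrams(b, n)
  inter <- sum(ga %in% gb)
  inter / (length(ga) + length(gb) - inter)
}

#' Unit-cost Levenshtein edit distance
#'
#' Dynamic-programming edit distance (insertions, deletions, substitutions,
#' all cost 1).
#'
#' @param a,b strings.
#' @return integer distance.
#' @export
#' @examples
#' lev_distance("kitten", "sitting") # 3
lev_distance <- function(a, b) {
  sa <- utf8ToInt(a)
  sb <- utf8ToInt(b)
  na <- length(sa)
  nb <- length(sb)
  if (na == 0L) return(nb)
  if (nb == 0L) return(na)
  prev <- 0L:nb
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    cur[1L] <- i
    for (j in seq_len(nb)) {
      cost <- if (sa[i] == sb[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' Normalized Levenshtein similarity
#'
#' `1 - d(a, b) / max(nchar(a), nchar(b))`. Two empty strings are defined
#' as similarity 1. Symmetric; equals 1 iff the strings are identical.
#'
#' @param a,b strings (assumed already normalized).
#' @return similarity in \[0, 1\].
#' @export
#' @examples
#' levenshtein_similarity("kitten", "sitting") # 1 - 3/7
levenshtein_similarity <- function(a, b) {
  m <- max(nchar(a), nchar(b))
  if (m == 0L) return(1)
  1 - lev_distance(a, b) / m
}

score_one <- function(query, candidate, metric, ngram_n = 2L) {
  switch(metric,
    jaccard_ngram = jaccard_ngram(query, candidate, ngram_n),
    levenshtein = levenshtein_similarity(query, candidate),
    abort_rx(sprintf("unknown metric: %s", metric), "rxh_parameter_error")
  )
}

#' Best-candidate search over a reference list
#'
#' Scores `query` against every candidate with the chosen metric and
#' returns the unique top-ranked candidate if its score reaches the
#' threshold. A tie at the top score is an ambiguity signal: no unique
#' best is returned, but all tied (and other at-threshold) candidates are
#' listed so the caller can queue the entry for review.
#'
#' @param query a normalized string.
#' @param candidates non-empty character vector of reference names.
#' @param metric `"jaccard_ngram"` or `"levenshtein"`.
#' @param threshold minimum similarity in \[0, 1\]; compared inclusively.
#' @param ngram_n n-gram size for the Jaccard metric.
#' @return list with elements `best` (one-row tibble or `NULL`),
#'   `over_threshold` (tibble of candidates scoring at/above threshold,
#'   ranked), `top_score`, and `top` (all candidates attaining the top
#'   score).
#' @export
extract_best <- function(query, candidates, metric = c("levenshtein", "jaccard_ngram"),
                         threshold = 0.9, ngram_n = 2L) {
  metric <- match.arg(metric)
  if (length(candidates) == 0L) {
    abort_rx("candidate list must be non-empty", "rxh_parameter_error")
  }
  if (threshold < 0 || threshold > 1) {
    abort_rx("threshold must be in [0, 1]", "rxh_parameter_error")
  }
  scores <- vapply(candidates, score_one, numeric(1),
    query = query, metric = metric, ngram_n = ngram_n,
    USE.NAMES = FALSE
  )
  ord <- order(-scores, candidates)
  ranked <- tibble(
    candidate = candidates[ord],
    score = scores[ord],
    metric = metric,
    rank = seq_along(ord)
  )
  eps <- 1e-12
  top_score <- ranked$score[1L]
  top <- ranked[ranked$score >= top_score - eps, , drop = FALSE]
  over <- ranked[ranked$score >= threshold - eps, , drop = FALSE]
  best <- if (nrow(top) == 1L && top_score >= threshold - eps) top else NULL
  list(best = best, over_threshold = over, top_score = top_score, top = top)
}
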