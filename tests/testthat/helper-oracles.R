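# Independent oracles, kept deliberately separate from the package's
# implementation paths.

# plain recursive edit distance (exponential; tiny strings only)
oracle_lev_recursive <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  cost <- if (substr(a, 1, 1) == substr(b, 1, 1)) 0L else 1L
  ta <- substr(a, 2, nchar(a))
  tb <- substr(b, 2, nchar(b))
  min(
    oracle_lev_recursive(ta, b) + 1L,
    oracle_lev_recursive(a, tb) + 1L,
    oracle_lev_recursive(ta, tb) + cost
  )
}

# memoised recursive edit distance (handles longer strings)
oracle_lev_memo <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- if (ca[i] == cb[j]) 0L else 1L
    val <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
      rec(i - 1L, j - 1L) + cost)
    memo[[key]] <- val
    val
  }
  rec(length(ca), length(cb))
}

# set-enumeration Jaccard oracle: builds gram sets with an explicit loop
oracle_jaccard <- function(a, b, n = 2L) {
  grams <- function(x) {
    out <- character(0)
    if (nchar(x) >= n) {
      for (i in 1:(nchar(x) - n + 1)) out <- c(out, substr(x, i, i + n - 1))
    }
    unique(out)
  }
  if (nchar(a) < n || nchar(b) < n) return(as.numeric(a == b))
  ga <- grams(a)
  gb <- grams(b)
  length(intersect(ga, gb)) / length(union(ga, gb))
}

# all strings over `alphabet` of length 0..max_len
enumerate_strings <- function(alphabet, max_len) {
  out <- ""
  level <- ""
  for (l in seq_len(max_len)) {
    level <- as.vector(outer(level, alphabet, paste0))
    out <- c(out, level)
  }
  out
}

random_string <- function(min_len, max_len, alphabet = letters[1:6]) {
  n <- sample(min_len:max_len, 1)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
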