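#' @section Text normalization rules:
#' Free-text entries are lowercased; punctuation is replaced by single
#' spaces, except that `.` and `-` are retained inside numeric dose tokens
#' (`"20-12.5"` survives whole) and `-` between alphabetic characters is
#' retained as the combination-product separator (`"lisinopril-hctz"`).
#' `/` between alphabetic characters is canonicalized to `-` so both
#' spellings of a combination product normalize identically.
#' @name textnorm
#' @keywords internal
NULL

# dose / unit / frequency tokens never act as drug-name candidates
.dose_token_re <- paste0(
  "^([0-9]+([.-][0-9]+)*|",
  "[0-9]+(mg|mcg|ug|ml|g|iu|meq)|",
  "mg|mcg|ug|ml|g|iu|meq|units?|tablets?|capsules?|puffs?|drops?|",
  "daily|nightly|weekly|monthly|once|twice|prn|bid|tid|qid|qd|qhs|qam|qpm",
  ")$"
)

is_dose_token <- function(tokens) {
  grepl(.dose_token_re, tokens)
}

#' Normalize a free-text medication string
#'
#' @param x character vector of raw medication text.
#' @return character vector of normalized text (lowercase, punctuation
#'   collapsed, dose tokens and combination hyphens preserved).
#' @export
#' @examples
#' normalize_text("Lipitor")                      # "lipitor"
#' normalize_text("lisinopril/HCTZ 20-12.5 mg")   # "lisinopril-hctz 20-12.5 mg"
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x[is.na(x)] <- ""
  # combination separators between letters -> canonical hyphen placeholder
  x <- gsub("(?<=[a-z])[/-](?=[a-z])", "\x01", x, perl = TRUE)
  # dose-internal "." and "-" between digits
  x <- gsub("(?<=[0-9])\\.(?=[0-9])", "\x02", x, perl = TRUE)
  x <- gsub("(?<=[0-9])-(?=[0-9])", "\x03", x, perl = TRUE)
  x <- gsub("[[:punct:]]+", " ", x)
  x <- chartr("\x01\x02\x03", "-.-", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Normalize raw medication entries
#'
#' Lowercases and de-punctuates each entry, tokenizes on whitespace, and
#' counts dose/frequency tokens (which are retained for audit but never
#' used as drug-name match candidates). Empty entries are kept and
#' flagged, never dropped.
#'
#' @param entries tibble with at least `record_id`, `participant_id`,
#'   `visit_id`, and a text column `med_text` (alias `raw_text` accepted).
#'   Extra columns are carried through.
#' @return the input tibble with added columns `norm_text`, `tokens`
#'   (list of character vectors), `n_dose_tokens`, `is_empty`.
#' @export
normalize_entries <- function(entries) {
  entries <- as_tibble(entries)
  if (!"med_text" %in% names(entries) && "raw_text" %in% names(entries)) {
    entries <- rename(entries, med_text = "raw_text")
  }
  require_columns(entries, c("record_id", "participant_id", "visit_id", "med_text"),
    "raw entries")
  key <- paste(entries$participant_id, entries$visit_id, entries$record_id)
  if (anyDuplicated(key)) {
    abort_rx("(participant_id, visit_id, record_id) must be unique",
      "rxh_validation_error")
  }
  entries$norm_text <- normalize_text(entries$med_text)
  entries$tokens <- strsplit(entries$norm_text, " ", fixed = TRUE)
  entries$n_dose_tokens <- vapply(
    entries$tokens, function(tk) sum(is_dose_token(tk)), integer(1)
  )
  entries$is_empty <- !nzchar(entries$norm_text)
  entries
}

name_tokens <- function(tokens) {
  tokens[!is_dose_token(tokens) & nzchar(tokens)]
}

#' Split a normalized name into combination components
#'
#' Combination products joined by `-` (or `/`, canonicalized to `-` during
#' normalization) are split into their component ingredients; the first
#' component is the primary active ingredient. Hyphen fragments shorter
#' than 3 characters are re-joined to their token (so `"co-codamol"`
#' becomes the single candidate `"cocodamol"` rather than a false split).
#'
#' @param x a normalized name string (dose tokens are ignored if present).
#' @return character vector of component candidates; the first element is
#'   the primary ingredient. Attribute `combination` is `TRUE` when the
#'   entry is a genuine multi-ingredient product.
#' @export
#' @examples
#' split_combination("lisinopril-hctz") # c("lisinopril", "hctz")
#' split_combination("co-codamol")      # "cocodamol"
split_combination <- function(x) {
  toks <- name_tokens(strsplit(normalize_text(x), " ", fixed = TRUE)[[1]])
  comps <- character(0)
  is_comb <- FALSE
  for (tk in toks) {
    if (grepl("-", tk, fixed = TRUE)) {
      parts <- strsplit(tk, "-", fixed = TRUE)[[1]]
      parts <- parts[nzchar(parts)]
      if (any(nchar(parts) < 3)) {
        comps <- c(comps, paste(parts, collapse = ""))
      } else {
        comps <- c(comps, parts)
        is_comb <- TRUE
      }
    } else {
      comps <- c(comps, tk)
    }
  }
  structure(comps, combination = is_comb)
}

#' Apply the OTC/vitamin/supplement exclusion filter
#'
#' An entry is excluded iff its whole normalized name equals an exclusion
#' term, or (token mode) any non-dose token equals an exclusion term.
#' The partition is total: every input row lands in exactly one output.
#'
#' @param entries normalized entries (from [normalize_entries()]).
#' @param exclusions character vector of normalized exclusion terms (see
#'   [load_exclusions()]).
#' @param mode `"exact_and_token"` (default), `"exact"`, or `"token"`.
#' @return list with tibbles `eligible` and `excluded`; `excluded` gains a
#'   `matched_exclusion` column naming the term that fired.
#' @export
filter_exclusions <- function(entries, exclusions,
                              mode = c("exact_and_token", "exact", "token")) {
  mode <- match.arg(mode)
  entries <- as_tibble(entries)
  if (length(exclusions) == 0L) {
    warn("exclusion filtering enabled with an empty exclusion list",
      class = "rxh_config_warning")
  }
  hit <- vapply(seq_len(nrow(entries)), function(i) {
    nt <- entries$norm_text[i]
    name_part <- paste(name_tokens(entries$tokens[[i]]), collapse = " ")
    if (mode %in% c("exact_and_token", "exact")) {
      if (nt %in% exclusions) return(nt)
      if (name_part %in% exclusions) return(name_part)
    }
    if (mode %in% c("exact_and_token", "token")) {
      tk <- name_tokens(entries$tokens[[i]])
      m <- tk[tk %in% exclusions]
      if (length(m)) return(m[1])
    }
    NA_character_
  }, character(1))
  excluded <- entries[!is.na(hit), , drop = FALSE]
  excluded$matched_exclusion <- hit[!is.na(hit)]
  list(
    eligible = entries[is.na(hit), , drop = FALSE],
    excluded = excluded
  )
}

#' Read a raw medication entries file
#'
#' @param path CSV/TSV with header columns `record_id`, `participant_id`,
#'   `visit_id`, `med_text` (extra columns pass through).
#' @return tibble of raw entries.
#' @export
read_raw_entries <- function(path) {
  read_table_auto(path,
    required = c("record_id", "participant_id", "visit_id", "med_text"),
    what = "raw entries file"
  )
}
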