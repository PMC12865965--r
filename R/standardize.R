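#' Standardization configuration
#'
#' Tunable parameters of the Phase-1 staged standardizer.
#'
#' @param fuzzy_threshold minimum similarity for an automatic fuzzy match
#'   (inclusive; default 0.90).
#' @param borderline_low lower edge of the borderline band; fuzzy scores in
#'   `[borderline_low, fuzzy_threshold)` are held for manual review
#'   (default 0.85).
#' @param ngram_n n-gram size for the Jaccard metric (default 2).
#' @param fuzzy_metric metric bound to the fuzzy stages: normalized
#'   Levenshtein similarity (default) or character n-gram Jaccard. At a
#'   0.90 threshold only the Levenshtein binding tolerates single-typo
#'   misspellings of typical-length drug names; the Jaccard binding is a
#'   stricter alternative.
#' @param exclusion_mode matching mode for the exclusion filter.
#' @param stages character vector of enabled automated stages, in order.
#' @return a `rxh_std_config` list.
#' @export
standardization_config <- function(fuzzy_threshold = 0.90,
                                   borderline_low = 0.85,
                                   ngram_n = 2L,
                                   fuzzy_metric = c("levenshtein", "jaccard_ngram"),
                                   exclusion_mode = "exact_and_token",
                                   stages = c("absolute", "fuzzy",
                                              "dict_absolute", "dict_fuzzy")) {
  fuzzy_metric <- match.arg(fuzzy_metric)
  if (!(borderline_low > 0 && borderline_low <= fuzzy_threshold &&
        fuzzy_threshold <= 1)) {
    abort_rx("need 0 < borderline_low <= fuzzy_threshold <= 1",
      "rxh_parameter_error")
  }
  structure(
    list(
      fuzzy_threshold = fuzzy_threshold,
      borderline_low = borderline_low,
      ngram_n = as.integer(ngram_n),
      fuzzy_metric = fuzzy_metric,
      exclusion_mode = exclusion_mode,
      stages = stages
    ),
    class = "rxh_std_config"
  )
}

match_result <- function(record_id, status, canonical_name = NA_character_,
                         method = NA_character_, score = NA_real_,
                         stage = NA_integer_, name_norm = NA_character_,
                         candidates = list(NULL)) {
  tibble(
    record_id = record_id, status = status, canonical_name = canonical_name,
    method = method, score = score, stage = as.integer(stage),
    name_norm = name_norm, candidates = candidates
  )
}

entry_name_parts <- function(entry_tokens) {
  toks <- name_tokens(entry_tokens)
  whole <- paste(toks, collapse = " ")
  comps <- split_combination(whole)
  list(
    tokens = toks,
    whole = whole,
    components = as.character(comps),
    is_combination = isTRUE(attr(comps, "combination"))
  )
}

#' Absolute (exact) lexicon matching
#'
#' Scans the whole (short-fragment-rejoined) name and, failing that, the
#' entry's non-dose tokens for exact case-insensitive lexicon hits.
#' Combination products are resolved by their primary active ingredient.
#' Space-separated tokens hitting two or more distinct canonical generics
#' are an ambiguity (a brand plus its own generic is not: both resolve to
#' one canonical).
#'
#' @param entry one row of a [normalize_entries()] tibble (or a list with
#'   `record_id` and `tokens`).
#' @param lexicon tibble from [build_lexicon()].
#' @return one-row MatchResult tibble with status `matched`, `ambiguous`,
#'   or `unmatched`.
#' @export
absolute_match <- function(entry, lexicon) {
  if (nrow(lexicon) == 0L) {
    abort_rx("lexicon must be non-empty", "rxh_parameter_error")
  }
  parts <- entry_name_parts(entry$tokens[[1]])
  rid <- entry$record_id
  lookup <- function(x) unique(lexicon$canonical[lexicon$name_norm %in% x])

  if (!nzchar(parts$whole)) {
    return(match_result(rid, "unmatched", stage = 1L, name_norm = parts$whole))
  }
  # scope 1: whole rejoined name
  hit <- lookup(parts$whole)
  if (length(hit) == 1L) {
    return(match_result(rid, "matched", hit, "absolute", 1, 1L, parts$whole))
  }
  # scope 2: combination -> primary active ingredient only
  if (parts$is_combination) {
    hit <- lookup(parts$components[1])
    if (length(hit) == 1L) {
      return(match_result(rid, "matched", hit, "absolute", 1, 1L, parts$whole))
    }
    return(match_result(rid, "unmatched", stage = 1L, name_norm = parts$whole))
  }
  # scope 3: individual alphabetic tokens
  hits <- lookup(parts$tokens)
  if (length(hits) == 1L) {
    return(match_result(rid, "matched", hits, "absolute", 1, 1L, parts$whole))
  }
  if (length(hits) >= 2L) {
    cand <- tibble(candidate = hits, score = 1, metric = "exact",
      rank = seq_along(hits))
    return(match_result(rid, "ambiguous", method = "absolute", stage = 1L,
      name_norm = parts$whole, candidates = list(cand)))
  }
  match_result(rid, "unmatched", stage = 1L, name_norm = parts$whole)
}

# queries tried in order for the fuzzy stages: whole name, then the
# primary combination component, then individual long-enough tokens
fuzzy_queries <- function(parts) {
  q <- parts$whole
  if (parts$is_combination) q <- c(q, parts$components[1])
  if (length(parts$tokens) > 1L) {
    q <- c(q, parts$tokens[nchar(parts$tokens) >= 4L])
  }
  unique(q[nzchar(q)])
}

classify_fuzzy <- function(rid, res, name, cfg, stage, method,
                           map_canonical = identity) {
  thr <- cfg$fuzzy_threshold
  low <- cfg$borderline_low
  eps <- 1e-12
  if (!is.null(res$best)) {
    return(match_result(rid, "matched", map_canonical(res$best$candidate),
      method, res$best$score, stage, name))
  }
  over <- res$over_threshold
  if (nrow(res$top) > 1L && res$top_score >= thr - eps) {
    cand <- res$top
    cand$candidate <- vapply(cand$candidate, map_canonical, character(1),
      USE.NAMES = FALSE)
    return(match_result(rid, "ambiguous", method = method,
      score = res$top_score, stage = stage, name_norm = name,
      candidates = list(cand)))
  }
  if (res$top_score >= low - eps && res$top_score < thr - eps) {
    cand <- res$top
    cand$candidate <- vapply(cand$candidate, map_canonical, character(1),
      USE.NAMES = FALSE)
    return(match_result(rid, "borderline", method = method,
      score = res$top_score, stage = stage, name_norm = name,
      candidates = list(cand)))
  }
  match_result(rid, "unmatched", score = res$top_score, stage = stage,
    name_norm = name)
}

#' Fuzzy lexicon matching with spelling tolerance
#'
#' Applied to entries unmatched by [absolute_match()]. The best lexicon
#' candidate (configured metric) is accepted when its score reaches the
#' threshold and it is the unique top; top-score ties at/above threshold
#' are ambiguous; scores in the borderline band are held for review.
#'
#' @inheritParams absolute_match
#' @param cfg a [standardization_config()].
#' @return one-row MatchResult tibble.
#' @export
fuzzy_match_stage <- function(entry, lexicon, cfg = standardization_config()) {
  parts <- entry_name_parts(entry$tokens[[1]])
  rid <- entry$record_id
  if (nrow(lexicon) == 0L || !nzchar(parts$whole)) {
    return(match_result(rid, "unmatched", stage = 2L, name_norm = parts$whole))
  }
  canon_of <- stats::setNames(lexicon$canonical, lexicon$name_norm)
  best_res <- NULL
  for (q in fuzzy_queries(parts)) {
    res <- extract_best(q, lexicon$name_norm, metric = cfg$fuzzy_metric,
      threshold = cfg$fuzzy_threshold, ngram_n = cfg$ngram_n)
    if (is.null(best_res) || res$top_score > best_res$top_score) best_res <- res
    if (res$top_score >= cfg$borderline_low - 1e-12) {
      best_res <- res
      break
    }
  }
  classify_fuzzy(rid, best_res, parts$whole, cfg, 2L, "fuzzy",
    map_canonical = function(x) unname(canon_of[x]))
}

#' Dictionary matching against expert-curated variants
#'
#' Exact lookup of the normalized whole name (and each combination
#' component) in the variant dictionary; failing that, fuzzy lookup over
#' dictionary keys at the configured threshold.
#'
#' @inheritParams fuzzy_match_stage
#' @param dict an `rxh_dictionary`.
#' @return one-row MatchResult tibble (stages 3/4).
#' @export
dictionary_match <- function(entry, dict, cfg = standardization_config()) {
  parts <- entry_name_parts(entry$tokens[[1]])
  rid <- entry$record_id
  if (is.null(dict) || nrow(dict) == 0L || !nzchar(parts$whole)) {
    return(match_result(rid, "unmatched", stage = 4L, name_norm = parts$whole))
  }
  canon_of <- stats::setNames(dict$canonical, dict$variant)
  keys <- c(parts$whole, if (parts$is_combination) parts$components[1])
  hit <- keys[keys %in% dict$variant]
  if (length(hit)) {
    return(match_result(rid, "matched", unname(canon_of[hit[1]]),
      "dict_absolute", 1, 3L, parts$whole))
  }
  if (!"dict_fuzzy" %in% cfg$stages) {
    return(match_result(rid, "unmatched", stage = 4L, name_norm = parts$whole))
  }
  best_res <- NULL
  for (q in fuzzy_queries(parts)) {
    res <- extract_best(q, dict$variant, metric = cfg$fuzzy_metric,
      threshold = cfg$fuzzy_threshold, ngram_n = cfg$ngram_n)
    if (is.null(best_res) || res$top_score > best_res$top_score) best_res <- res
    if (res$top_score >= cfg$borderline_low - 1e-12) {
      best_res <- res
      break
    }
  }
  classify_fuzzy(rid, best_res, parts$whole, cfg, 4L, "dict_fuzzy",
    map_canonical = function(x) unname(canon_of[x]))
}

#' Run the staged Phase-1 standardization over a corpus
#'
#' Stages run in fixed order (absolute, fuzzy, dictionary-absolute,
#' dictionary-fuzzy); each stage sees only the previous stage's unmatched
#' entries. Ambiguous and borderline results are frozen at first flagging
#' and never advance through later automated stages; entries still
#' unmatched after stage 4 form the expert queue. Empty entries go
#' straight to the unmatched queue.
#'
#' @param entries normalized, exclusion-filtered entries
#'   (from [normalize_entries()] / [filter_exclusions()]).
#' @param lexicon tibble from [build_lexicon()].
#' @param dict optional `rxh_dictionary`.
#' @param cfg a [standardization_config()].
#' @return list with `results` (one MatchResult row per entry), `queues`
#'   (`ambiguous`, `borderline`, `unmatched` tibbles), `counts`
#'   (per-stage StageCounts tibble), and `audit` (state-transition
#'   records).
#' @export
standardize_corpus <- function(entries, lexicon, dict = NULL,
                               cfg = standardization_config()) {
  entries <- as_tibble(entries)
  n_total <- nrow(entries)
  if (n_total == 0L) {
    empty <- match_result(character(0), character(0))[0, ]
    return(list(results = empty,
      queues = list(ambiguous = empty, borderline = empty, unmatched = empty),
      counts = stage_counts_empty(),
      audit = audit_empty()))
  }

  stage_defs <- list(
    list(stage = 1L, label = "Absolute Match",
      fn = function(e) absolute_match(e, lexicon)),
    list(stage = 2L, label = "Fuzzy Match",
      fn = function(e) fuzzy_match_stage(e, lexicon, cfg)),
    list(stage = 3L, label = "Absolute Match Through Expert-Curated Dictionary",
      fn = function(e) {
        r <- dictionary_match(e, dict,
          standardization_config(cfg$fuzzy_threshold, cfg$borderline_low,
            cfg$ngram_n, cfg$fuzzy_metric, cfg$exclusion_mode,
            stages = "dict_absolute"))
        r
      }),
    list(stage = 4L, label = "Fuzzy Match Through Expert-Curated Dictionary",
      fn = function(e) dictionary_match(e, dict, cfg))
  )
  stage_name <- c("absolute", "fuzzy", "dict_absolute", "dict_fuzzy")
  stage_defs <- stage_defs[stage_name %in% cfg$stages]

  pending <- seq_len(n_total)
  results <- vector("list", n_total)
  counts <- list()
  audit <- list()

  for (sd in stage_defs) {
    if (!length(pending)) {
      counts[[length(counts) + 1L]] <- stage_counts("Phase 1", sd$label,
        correct = 0L, ambiguous = 0L, unmatched = 0L, total = 0L)
      next
    }
    stage_in <- length(pending)
    new_matched <- 0L; new_flagged <- 0L
    still <- integer(0)
    for (i in pending) {
      entry <- entries[i, , drop = FALSE]
      if (entry$is_empty) {
        r <- match_result(entry$record_id, "unmatched", stage = sd$stage,
          name_norm = "")
      } else {
        r <- sd$fn(entry)
        r$stage <- sd$stage
      }
      if (r$status == "matched") {
        new_matched <- new_matched + 1L
        results[[i]] <- r
        audit[[length(audit) + 1L]] <- audit_record(
          record_id = r$record_id, phase = "phase1", stage = sd$stage,
          action = sd$label, before = "pending", after = "matched",
          score = r$score)
      } else if (r$status %in% c("ambiguous", "borderline")) {
        new_flagged <- new_flagged + 1L
        results[[i]] <- r
        audit[[length(audit) + 1L]] <- audit_record(
          record_id = r$record_id, phase = "phase1", stage = sd$stage,
          action = sd$label, before = "pending", after = r$status,
          score = r$score)
      } else {
        still <- c(still, i)
      }
    }
    counts[[length(counts) + 1L]] <- stage_counts("Phase 1", sd$label,
      correct = new_matched, ambiguous = new_flagged,
      unmatched = stage_in - new_matched - new_flagged, total = stage_in)
    pending <- still
  }

  for (i in pending) {
    entry <- entries[i, , drop = FALSE]
    parts <- entry_name_parts(entry$tokens[[1]])
    results[[i]] <- match_result(entry$record_id, "unmatched",
      stage = max(vapply(stage_defs, `[[`, integer(1), "stage")),
      name_norm = parts$whole)
    audit[[length(audit) + 1L]] <- audit_record(
      record_id = entry$record_id, phase = "phase1",
      stage = results[[i]]$stage, action = "queued for expert review",
      before = "pending", after = "unmatched")
  }

  results <- bind_rows(results)
  list(
    results = results,
    queues = list(
      ambiguous = dplyr::filter(results, .data$status == "ambiguous"),
      borderline = dplyr::filter(results, .data$status == "borderline"),
      unmatched = dplyr::filter(results, .data$status == "unmatched")
    ),
    counts = bind_rows(counts),
    audit = bind_rows(audit)
  )
}

#' Apply expert adjudication decisions to queued entries
#'
#' Accepted decisions turn queued (ambiguous/borderline/unmatched) entries
#' into `expert_resolved` results at stage 5, append the adjudicated
#' variant-to-canonical pair to the reusable dictionary with provenance,
#' and emit audit records. Rejections become terminal `rejected` results
#' excluded from downstream phases. A decision naming a record that is not
#' queued is a validation error.
#'
#' @param std output of [standardize_corpus()].
#' @param decisions tibble (or CSV path) with columns `record_id`,
#'   `action` (`accept`/`reject`), `canonical_name`, `reviewer`, `date`.
#' @param dict the current `rxh_dictionary` (may be empty).
#' @return list with updated `results`, grown `dictionary`, appended
#'   `audit`, and the stage-5 `counts` row.
#' @export
apply_expert_decisions <- function(std, decisions, dict = new_dictionary()) {
  if (is.character(decisions) && length(decisions) == 1L) {
    decisions <- read_table_auto(decisions,
      required = c("record_id", "action", "canonical_name"),
      what = "decisions file")
  }
  decisions <- as_tibble(decisions)
  require_columns(decisions, c("record_id", "action", "canonical_name"),
    "decisions")
  if (!"reviewer" %in% names(decisions)) decisions$reviewer <- "reviewer"
  if (!"date" %in% names(decisions)) decisions$date <- NA_character_

  results <- std$results
  queued_ids <- results$record_id[
    results$status %in% c("ambiguous", "borderline", "unmatched")]
  bad <- setdiff(decisions$record_id, queued_ids)
  if (length(bad)) {
    abort_rx(paste("decisions reference non-queued records:",
      paste(bad, collapse = ", ")), "rxh_validation_error")
  }

  audit <- list()
  new_var <- character(0); new_can <- character(0)
  new_src <- character(0); new_date <- character(0)
  n_accept <- 0L; n_reject <- 0L
  for (k in seq_len(nrow(decisions))) {
    d <- decisions[k, ]
    i <- match(d$record_id, results$record_id)
    before <- results$status[i]
    if (identical(d$action, "accept")) {
      canonical <- normalize_text(d$canonical_name)
      results$status[i] <- "expert_resolved"
      results$canonical_name[i] <- canonical
      results$method[i] <- "expert"
      results$stage[i] <- 5L
      n_accept <- n_accept + 1L
      variant <- results$name_norm[i]
      if (!is.na(variant) && nzchar(variant) && variant != canonical) {
        new_var <- c(new_var, variant)
        new_can <- c(new_can, canonical)
        new_src <- c(new_src, "expert-adjudicated")
        new_date <- c(new_date, as.character(d$date))
      }
      after <- "expert_resolved"
    } else {
      results$status[i] <- "rejected"
      results$stage[i] <- 5L
      n_reject <- n_reject + 1L
      after <- "rejected"
    }
    audit[[length(audit) + 1L]] <- audit_record(
      record_id = d$record_id, phase = "phase1", stage = 5L,
      action = paste("expert", d$action), before = before, after = after,
      actor = d$reviewer)
  }

  addition <- tibble(variant = new_var, canonical = new_can,
    source = new_src, date = new_date)
  addition <- addition[!addition$variant %in% dict$variant, , drop = FALSE]
  addition <- addition[!duplicated(addition$variant), , drop = FALSE]
  dictionary <- validate_dictionary(bind_rows(as_tibble(dict), addition))

  counts <- stage_counts("Phase 1", "Expert Review",
    correct = n_accept, ambiguous = 0L, unmatched = n_reject,
    total = nrow(decisions))

  list(results = results, dictionary = dictionary,
    audit = bind_rows(audit), counts = counts)
}
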