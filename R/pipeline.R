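#' Run the full four-phase harmonization pipeline
#'
#' Normalizes raw entries, applies the exclusion filter, runs the staged
#' Phase-1 standardization, maps standardized names to therapeutic
#' classes, builds the long and wide exposure datasets, and assembles the
#' stage-accounting report plus the audit stream. Identical inputs,
#' configuration and seeds produce identical outputs (manifests modulo
#' timestamps).
#'
#' @param entries raw entries tibble (`record_id`, `participant_id`,
#'   `visit_id`, `med_text`) or a CSV path.
#' @param refset an `rxh_refset`.
#' @param exclusions character vector of exclusion terms.
#' @param dict optional `rxh_dictionary`.
#' @param cfg a [standardization_config()].
#' @param classify_threshold Phase-2 fuzzy threshold.
#' @param merge_map optional class merge map tibble.
#' @param roster optional visit roster tibble.
#' @param level exposure column granularity (2, 3, or 4).
#' @param decisions optional expert-decision tibble/path applied after the
#'   automated stages.
#' @param classmap optional persistent classification map to reuse.
#' @return list with `normalized`, `eligible`, `excluded`, `std`
#'   (results/queues/counts), `dictionary`, `classification`
#'   (classmap/unresolved/counts), `long`, `unclassified`, `wide`,
#'   `summary`, `report`, `audit`, and `manifest`.
#' @export
run_pipeline <- function(entries, refset, exclusions,
                         dict = new_dictionary(),
                         cfg = standardization_config(),
                         classify_threshold = 0.90,
                         merge_map = NULL, roster = NULL, level = 4,
                         decisions = NULL, classmap = NULL) {
  if (is.character(entries) && length(entries) == 1L) {
    entries <- read_raw_entries(entries)
  }
  normalized <- normalize_entries(entries)
  parts <- filter_exclusions(normalized, exclusions, mode = cfg$exclusion_mode)

  std <- standardize_corpus(parts$eligible, build_lexicon(refset), dict, cfg)
  dictionary <- dict
  if (!is.null(decisions)) {
    upd <- apply_expert_decisions(std, decisions, dict)
    std$results <- upd$results
    std$counts <- bind_rows(std$counts, upd$counts)
    std$audit <- bind_rows(std$audit, upd$audit)
    std$queues <- list(
      ambiguous = dplyr::filter(upd$results, .data$status == "ambiguous"),
      borderline = dplyr::filter(upd$results, .data$status == "borderline"),
      unmatched = dplyr::filter(upd$results, .data$status == "unmatched")
    )
    dictionary <- upd$dictionary
  }

  resolved <- dplyr::filter(std$results,
    .data$status %in% c("matched", "expert_resolved"))
  classification <- classify_all(unique(resolved$canonical_name), refset,
    classmap = classmap, threshold = classify_threshold)

  records <- left_join(
    select(resolved, "record_id", "canonical_name"),
    select(parts$eligible, "record_id", "participant_id", "visit_id"),
    by = "record_id"
  )
  lw <- to_long(records, classification$classmap)
  wide <- to_wide(lw$long, merge_map = merge_map, roster = roster,
    level = level)

  counts <- bind_rows(std$counts, classification$counts)
  report <- build_report(counts)
  audit <- bind_rows(std$audit, classification$audit)

  manifest <- list(
    config = list(
      fuzzy_threshold = cfg$fuzzy_threshold,
      borderline_low = cfg$borderline_low,
      ngram_n = cfg$ngram_n,
      fuzzy_metric = cfg$fuzzy_metric,
      exclusion_mode = cfg$exclusion_mode,
      classify_threshold = classify_threshold,
      level = level
    ),
    counts = list(
      raw = nrow(normalized),
      eligible = nrow(parts$eligible),
      excluded = nrow(parts$excluded),
      matched = sum(std$results$status == "matched"),
      expert_resolved = sum(std$results$status == "expert_resolved"),
      ambiguous = sum(std$results$status == "ambiguous"),
      borderline = sum(std$results$status == "borderline"),
      unmatched = sum(std$results$status == "unmatched"),
      classified_names = length(unique(classification$classmap$canonical_name)),
      unresolved_names = nrow(classification$unresolved),
      exposure_rows = nrow(wide)
    ),
    timestamp = iso_timestamp()
  )

  list(
    normalized = normalized,
    eligible = parts$eligible,
    excluded = parts$excluded,
    std = std,
    dictionary = dictionary,
    classification = classification,
    long = lw$long,
    unclassified = lw$unclassified,
    wide = wide,
    summary = summarize_exposure(wide),
    report = report,
    audit = audit,
    manifest = manifest
  )
}

#' Write pipeline outputs to a directory
#'
#' Emits the documented CSV/JSONL artifact chain: results, queues, report,
#' long and wide exposure tables, dictionary, classification map, audit
#' stream, and the run manifest.
#'
#' @param run output of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of paths written.
#' @export
write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(x) file.path(out_dir, x)
  results_flat <- select(run$std$results, -"candidates")
  results_flat$score_pct <- round_half_up(100 * results_flat$score, 1)
  readr::write_csv(results_flat, p("results.csv"), na = "")
  for (q in names(run$std$queues)) {
    readr::write_csv(select(run$std$queues[[q]], -"candidates"),
      p(paste0("queue_", q, ".csv")), na = "")
  }
  readr::write_csv(run$report, p("report.csv"), na = "")
  readr::write_csv(run$long, p("exposure_long.csv"), na = "")
  readr::write_csv(run$wide, p("exposure_wide.csv"), na = "")
  excluded_flat <- run$excluded[, !vapply(run$excluded, is.list, logical(1))]
  readr::write_csv(excluded_flat, p("excluded.csv"), na = "")
  save_dictionary(run$dictionary, p("dictionary.csv"))
  save_classmap(run$classification$classmap, p("classmap.csv"))
  write_audit_log(run$audit, p("audit.jsonl"))
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  invisible(vapply(c("results.csv", "report.csv", "exposure_long.csv",
    "exposure_wide.csv", "dictionary.csv", "classmap.csv", "audit.jsonl",
    "manifest.json"), p, character(1)))
}
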