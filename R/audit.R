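#' Create a single audit record
#'
#' One append-only record per state transition: what happened, to which
#' record, at which phase/stage, by whom.
#'
#' @param record_id record or name the transition applies to.
#' @param phase pipeline phase label (e.g. `"phase1"`).
#' @param stage integer process number within the phase.
#' @param action human-readable action label.
#' @param before,after states before and after the transition.
#' @param score similarity score attached to the transition, if any.
#' @param actor `"automated"` or a reviewer id; every non-automated action
#'   must name its actor.
#' @param timestamp ISO-8601 timestamp (defaults to now, UTC).
#' @return one-row tibble.
#' @export
audit_record <- function(record_id, phase, stage, action, before, after,
                         score = NA_real_, actor = "automated",
                         timestamp = iso_timestamp()) {
  tibble(
    timestamp = timestamp,
    record_id = as.character(record_id),
    phase = phase,
    stage = as.integer(stage),
    action = action,
    before = before,
    after = after,
    score_pct = if (is.na(score)) NA_real_ else round_half_up(100 * score, 1),
    actor = actor
  )
}

audit_empty <- function() {
  audit_record("x", "p", 1L, "a", "b", "c")[0, ]
}

#' Write / read a JSON-lines audit stream
#'
#' One JSON object per line, append-friendly and diffable.
#'
#' @param audit tibble of audit records.
#' @param path `.jsonl` file path.
#' @param append append to an existing stream instead of overwriting.
#' @return `write_audit_log` returns `path` invisibly; `read_audit_log`
#'   returns a tibble.
#' @export
write_audit_log <- function(audit, path, append = FALSE) {
  lines <- vapply(seq_len(nrow(audit)), function(i) {
    jsonlite::toJSON(as.list(audit[i, ]), auto_unbox = TRUE, na = "null",
      digits = NA)
  }, character(1))
  if (append && file.exists(path)) {
    cat(lines, file = path, sep = "\n", append = TRUE)
    if (length(lines)) cat("\n", file = path, append = TRUE)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_audit_log
#' @export
read_audit_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    obj[vapply(obj, is.null, logical(1))] <- NA
    as_tibble(obj)
  })
  out <- bind_rows(rows)
  if (nrow(out)) {
    out$stage <- as.integer(out$stage)
    if (!"score_pct" %in% names(out)) out$score_pct <- NA_real_
    out$score_pct <- suppressWarnings(as.numeric(out$score_pct))
  }
  out
}

#' Verify that final results are explained by the audit trail
#'
#' Every terminal result state must be the `after` state of that record's
#' last audit transition; records with no audit trail, or whose trail ends
#' elsewhere, are reported as discrepancies (findings, not errors).
#'
#' @param audit audit tibble (or `.jsonl` path).
#' @param results results tibble with `record_id` and `status`.
#' @return list with logical `pass` and a `discrepancies` tibble.
#' @export
verify_audit_chain <- function(audit, results) {
  if (is.character(audit) && length(audit) == 1L) audit <- read_audit_log(audit)
  audit <- as_tibble(audit)
  last_state <- vapply(split(audit$after, audit$record_id), function(x) {
    x[length(x)]
  }, character(1))
  expected <- last_state[as.character(results$record_id)]
  bad <- is.na(expected) | expected != results$status
  discrepancies <- tibble(
    record_id = results$record_id[bad],
    result_status = results$status[bad],
    audit_final = unname(expected[bad])
  )
  list(pass = nrow(discrepancies) == 0L, discrepancies = discrepancies)
}
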