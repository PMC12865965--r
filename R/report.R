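#' Construct a validated per-process stage-count row
#'
#' Each automated or expert process contributes one accounting row:
#' entries newly matched (`correct`), newly flagged for review
#' (`ambiguous`, which also carries borderline holds), and entries left
#' `unmatched` for the next process. The three must sum to the process
#' input `total` — the report refuses to tabulate counts that leak or
#' duplicate entries.
#'
#' @param phase phase label (e.g. `"Phase 1"`).
#' @param process process label.
#' @param correct,ambiguous,unmatched non-negative counts.
#' @param total process input count; defaults to the sum of the three.
#' @return one-row tibble.
#' @export
#' @examples
#' stage_counts("Phase 1", "Absolute Match", 14273, 276, 2353)
stage_counts <- function(phase, process, correct, ambiguous, unmatched,
                         total = correct + ambiguous + unmatched) {
  if (any(c(correct, ambiguous, unmatched) < 0)) {
    abort_rx("stage counts must be non-negative", "rxh_parameter_error")
  }
  if (correct + ambiguous + unmatched != total) {
    abort_rx(
      sprintf(
        "conservation violated at %s / %s: %d + %d + %d != %d",
        phase, process, correct, ambiguous, unmatched, total
      ),
      "rxh_integrity_error"
    )
  }
  tibble(
    phase = phase, process = process,
    correct = as.integer(correct), ambiguous = as.integer(ambiguous),
    unmatched = as.integer(unmatched), total = as.integer(total)
  )
}

stage_counts_empty <- function() {
  stage_counts("p", "q", 0L, 0L, 0L)[0, ]
}

#' Percentage of a phase resolved by one process
#'
#' `100 * correct / phase_total`, rounded half-up to one decimal — the
#' convention under which 14,273 of 16,902 prints as 84.4.
#'
#' @param correct entries resolved by the process.
#' @param phase_total total entries entering the phase.
#' @return percentage on the 0–100 scale, one decimal.
#' @export
pct_of_phase <- function(correct, phase_total) {
  round_half_up(100 * correct / phase_total, 1)
}

#' Build the stage-accounting report
#'
#' One row per phase-process with counts and the share of the phase total
#' resolved by that process, plus a totals row per phase. Each row is
#' validated for conservation (`correct + ambiguous + unmatched = total`);
#' a violation is an integrity error naming the offending stage.
#'
#' @param counts tibble of [stage_counts()] rows, in process order.
#' @param phase_totals optional named vector of phase totals; by default
#'   the first process's input total within each phase.
#' @return report tibble with a `percentage` column (one decimal).
#' @export
build_report <- function(counts, phase_totals = NULL) {
  counts <- as_tibble(counts)
  require_columns(counts,
    c("phase", "process", "correct", "ambiguous", "unmatched", "total"),
    "stage counts")
  for (i in seq_len(nrow(counts))) {
    stage_counts(counts$phase[i], counts$process[i], counts$correct[i],
      counts$ambiguous[i], counts$unmatched[i], counts$total[i])
  }
  phases <- unique(counts$phase)
  if (is.null(phase_totals)) {
    phase_totals <- vapply(phases, function(p) {
      counts$total[counts$phase == p][1]
    }, numeric(1))
  }
  out <- list()
  for (p in phases) {
    rows <- counts[counts$phase == p, , drop = FALSE]
    rows$percentage <- pct_of_phase(rows$correct, phase_totals[[p]])
    total_row <- tibble(
      phase = p, process = "Total",
      correct = sum(rows$correct), ambiguous = NA_integer_,
      unmatched = rows$unmatched[nrow(rows)], total = phase_totals[[p]],
      percentage = pct_of_phase(sum(rows$correct), phase_totals[[p]])
    )
    out[[p]] <- bind_rows(rows, total_row)
  }
  bind_rows(out)
}

#' Draw a seeded QA review sample
#'
#' Uniform sampling without replacement from the assignment/result
#' population; the worksheet carries name, assignment, method, and score
#' for independent verification, with a dual-verification flag on complex
#' cases (fuzzy or expert methods).
#'
#' @param population tibble of assignments or results (must have a
#'   `method` column for the dual-verification flag to be meaningful).
#' @param n sample size, or
#' @param fraction fraction of the population (used when `n` is `NULL`).
#' @param seed integer seed; identical seeds reproduce identical samples.
#' @return the sampled rows with a `dual_verification` column.
#' @export
qa_sample <- function(population, n = NULL, fraction = NULL, seed = 1L) {
  population <- as_tibble(population)
  pop_n <- nrow(population)
  if (is.null(n)) {
    if (is.null(fraction)) {
      abort_rx("provide either n or fraction", "rxh_parameter_error")
    }
    n <- round(fraction * pop_n)
  }
  if (n > pop_n) {
    abort_rx(sprintf("sample size %d exceeds population %d", n, pop_n),
      "rxh_parameter_error")
  }
  idx <- withr::with_seed(seed, sample.int(pop_n, n))
  out <- population[sort(idx), , drop = FALSE]
  complex_methods <- c("fuzzy", "dict_fuzzy", "fuzzy_scdf", "expert")
  out$dual_verification <- if ("method" %in% names(out)) {
    out$method %in% complex_methods
  } else {
    FALSE
  }
  out
}
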