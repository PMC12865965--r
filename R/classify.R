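#' @section Therapeutic-class mapping:
#' Standardized generic names are mapped to classes in three sequential
#' stages: exact match against generic monograph titles, exact match
#' against trade names resolved through their generic, then fuzzy
#' (normalized Levenshtein) match against clinical-drug-form descriptions
#' at a 0.90 threshold. Assignments are cached in a persistent
#' classification map so known names are never recomputed.
#' @name class_mapper
#' @keywords internal
NULL

# dose-form words stripped from clinical-drug-form strings before fuzzy
# scoring, since free-text names lack them
.form_words <- c(
  "oral", "tablet", "tablets", "capsule", "capsules", "solution",
  "suspension", "injection", "injectable", "topical", "cream", "ointment",
  "ophthalmic", "nasal", "inhalation", "patch", "transdermal", "extended",
  "delayed", "release", "chewable", "product", "mg", "mcg", "ml", "spray",
  "drops", "syrup", "gel", "lotion", "powder", "suppository"
)

strip_form_words <- function(x) {
  toks <- strsplit(x, " ", fixed = TRUE)
  vapply(toks, function(tk) {
    keep <- tk[!(tk %in% .form_words) & !is_dose_token(tk)]
    paste(keep, collapse = " ")
  }, character(1))
}

class_assignment <- function(canonical_name, class_num, refset, method,
                             score = NA_real_) {
  ci <- match(class_num, refset$classes$AHFSClassNum)
  if (is.na(ci)) {
    abort_rx(sprintf("class number %s not in class table", class_num),
      "rxh_integrity_error")
  }
  ei <- match(class_num, refset$classes_extended$AHFSClassNum)
  ext <- refset$classes_extended[ei, ]
  tibble(
    canonical_name = canonical_name,
    ahfs_class_num = class_num,
    ahfs_class_text = refset$classes$AHFSClassText[ci],
    level2_text = ext$AHFSClassText_2,
    level3_text = ext$AHFSClassText_3,
    level4_text = ext$AHFSClassText_4,
    method = method,
    score = score
  )
}

assignments_for_generic <- function(name_norm, refset, method, score = NA_real_) {
  rows <- refset$generics[refset$generics$name_norm == name_norm, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  class_nums <- unique(
    refset$classes$AHFSClassNum[
      match(rows$AHFSClassID, refset$classes$AHFSClassID)]
  )
  bind_rows(lapply(class_nums, function(cn) {
    class_assignment(name_norm, cn, refset, method, score)
  }))
}

#' Exact match against generic monograph titles
#'
#' 100% text equivalence after case/punctuation normalization. A generic
#' legitimately listed under several classes yields one assignment row per
#' class.
#'
#' @param name a drug name (normalized internally).
#' @param refset an `rxh_refset`.
#' @return tibble of assignments (zero rows if no match).
#' @export
map_generic_exact <- function(name, refset) {
  nn <- normalize_text(name)
  out <- assignments_for_generic(nn, refset, "generic_exact")
  if (is.null(out)) {
    tibble()
  } else {
    mutate(out, canonical_name = nn)
  }
}

#' Exact match against trade names, resolved through the generic
#'
#' @inheritParams map_generic_exact
#' @return tibble of assignments; zero rows if no match. A trade name
#'   resolving to two or more generics with different classes is an
#'   ambiguity: the result carries attribute `ambiguous = TRUE` and must be
#'   routed to the expert queue.
#' @export
map_trade_name <- function(name, refset) {
  nn <- normalize_text(name)
  rows <- refset$tradenames[refset$tradenames$name_norm == nn, , drop = FALSE]
  if (nrow(rows) == 0L) return(tibble())
  gens <- unique(rows$gen_norm)
  out <- bind_rows(lapply(gens, function(g) {
    assignments_for_generic(g, refset, "trade_name")
  }))
  if (length(gens) > 1L && length(unique(out$ahfs_class_num)) > 1L) {
    attr(out, "ambiguous") <- TRUE
    return(out)
  }
  mutate(out, canonical_name = nn)
}

#' Fuzzy match against clinical-drug-form descriptions
#'
#' Best normalized-Levenshtein candidate among the clinical-drug-form
#' strings (dose-form words stripped by default); accepted when the score
#' reaches the threshold and the top candidate is unique. A top-score tie
#' carries attribute `ambiguous = TRUE` for expert routing.
#'
#' @inheritParams map_generic_exact
#' @param threshold minimum similarity (inclusive), default 0.90.
#' @param strip_forms strip dose-form suffix words from the reference
#'   strings before scoring (default `TRUE`).
#' @return tibble of assignments (zero rows if below threshold).
#' @export
map_fuzzy_scdf <- function(name, refset, threshold = 0.90, strip_forms = TRUE) {
  nn <- normalize_text(name)
  targets <- if (strip_forms) {
    strip_form_words(refset$scdf$scdf_norm)
  } else {
    refset$scdf$scdf_norm
  }
  keep <- nzchar(targets)
  if (!any(keep)) return(tibble())
  res <- extract_best(nn, targets[keep], metric = "levenshtein",
    threshold = threshold)
  idx_keep <- which(keep)
  if (!is.null(res$best)) {
    i <- idx_keep[match(res$best$candidate, targets[keep])]
    return(class_assignment(nn, refset$scdf$AHFSClassNum[i], refset,
      "fuzzy_scdf", res$best$score))
  }
  if (nrow(res$top) > 1L && res$top_score >= threshold - 1e-12) {
    out <- tibble()
    attr(out, "ambiguous") <- TRUE
    return(out)
  }
  tibble()
}

#' Classify unique standardized names into therapeutic classes
#'
#' Applies the persistent classification map first (known names are never
#' recomputed), then the three matching stages in order; names that no
#' stage resolves — or that resolve ambiguously — join the expert queue.
#'
#' @param names character vector of standardized names (deduplicated and
#'   de-NA'd internally).
#' @param refset an `rxh_refset`.
#' @param classmap optional existing classification map (tibble of
#'   assignment rows).
#' @param threshold fuzzy-stage similarity threshold.
#' @param strip_forms see [map_fuzzy_scdf()].
#' @return list with `classmap` (superset of the input map), `unresolved`
#'   (expert queue tibble), `counts` (StageCounts rows), and `audit`.
#' @export
classify_all <- function(names, refset, classmap = NULL, threshold = 0.90,
                         strip_forms = TRUE) {
  names <- unique(names[!is.na(names) & nzchar(names)])
  names <- normalize_text(names)
  names <- unique(names)
  known <- if (!is.null(classmap) && nrow(classmap)) {
    unique(classmap$canonical_name)
  } else {
    character(0)
  }
  todo <- setdiff(names, known)

  n_gen <- 0L; n_trade <- 0L; n_fuzzy <- 0L
  unresolved <- character(0)
  new_rows <- list()
  audit <- list()
  log_it <- function(nm, method, score = NA_real_) {
    audit[[length(audit) + 1L]] <<- audit_record(
      record_id = nm, phase = "phase2", stage = switch(method,
        generic_exact = 1L, trade_name = 2L, fuzzy_scdf = 3L, 4L),
      action = method, before = "unclassified",
      after = if (method == "unresolved") "queued" else "classified",
      score = score)
  }

  for (nm in todo) {
    a <- map_generic_exact(nm, refset)
    if (nrow(a)) {
      n_gen <- n_gen + 1L; new_rows[[nm]] <- a
      log_it(nm, "generic_exact")
      next
    }
    a <- map_trade_name(nm, refset)
    if (isTRUE(attr(a, "ambiguous"))) {
      unresolved <- c(unresolved, nm)
      log_it(nm, "unresolved")
      next
    }
    if (nrow(a)) {
      n_trade <- n_trade + 1L; new_rows[[nm]] <- a
      log_it(nm, "trade_name")
      next
    }
    a <- map_fuzzy_scdf(nm, refset, threshold, strip_forms)
    if (isTRUE(attr(a, "ambiguous"))) {
      unresolved <- c(unresolved, nm)
      log_it(nm, "unresolved")
      next
    }
    if (nrow(a)) {
      n_fuzzy <- n_fuzzy + 1L; new_rows[[nm]] <- a
      log_it(nm, "fuzzy_scdf", a$score[1])
      next
    }
    unresolved <- c(unresolved, nm)
    log_it(nm, "unresolved")
  }

  n_in <- length(todo)
  counts <- bind_rows(
    stage_counts("Phase 2", "Direct Matching to Generic Names",
      correct = n_gen, ambiguous = 0L,
      unmatched = n_in - n_gen, total = n_in),
    stage_counts("Phase 2", "Matching Trade Names",
      correct = n_trade, ambiguous = 0L,
      unmatched = n_in - n_gen - n_trade, total = n_in - n_gen),
    stage_counts("Phase 2", "Fuzzy Match to Clinical Drug Forms",
      correct = n_fuzzy, ambiguous = 0L,
      unmatched = length(unresolved), total = n_in - n_gen - n_trade)
  )

  classmap_out <- bind_rows(classmap, bind_rows(new_rows))
  list(
    classmap = classmap_out,
    unresolved = tibble(canonical_name = unresolved),
    counts = counts,
    audit = if (length(audit)) bind_rows(audit) else audit_empty()
  )
}

#' Save / load the persistent classification map
#'
#' @param classmap tibble of assignment rows.
#' @param path CSV path.
#' @return `save_classmap` returns `path` invisibly; `load_classmap`
#'   returns the tibble (with numeric `score`).
#' @export
save_classmap <- function(classmap, path) {
  readr::write_csv(classmap, path, na = "")
  invisible(path)
}

#' @rdname save_classmap
#' @export
load_classmap <- function(path) {
  df <- read_table_auto(path,
    required = c("canonical_name", "ahfs_class_num", "method"),
    what = "classification map")
  df$score <- suppressWarnings(as.numeric(df$score))
  df$ahfs_class_num <- canonical_class_num(df$ahfs_class_num)
  as_tibble(df)
}

#' Calibrate the fuzzy-matching threshold by banded expert sampling
#'
#' Draws a seeded stratified sample of candidate matches from each
#' similarity band, computes per-band precision from expert accept/reject
#' labels, and recommends the lowest band boundary above which every band
#' meets the precision target.
#'
#' @param labeled tibble with numeric `score` (0–1) and logical `accepted`.
#' @param bands list of `c(low, high)` band edges; the last band is closed
#'   on the right.
#' @param n_per_band matches sampled per band (default 5, i.e. 15 across
#'   the three default bands).
#' @param target precision target (default 0.9).
#' @param seed integer seed.
#' @return list with `table` (band, n sampled, precision) and
#'   `recommended` threshold.
#' @export
calibrate_threshold <- function(labeled,
                                bands = list(c(0.86, 0.90), c(0.90, 0.95),
                                             c(0.95, 1.00)),
                                n_per_band = 5L, target = 0.9, seed = 1L) {
  labeled <- as_tibble(labeled)
  require_columns(labeled, c("score", "accepted"), "labeled matches")
  rows <- withr::with_seed(seed, {
    lapply(seq_along(bands), function(bi) {
      b <- bands[[bi]]
      closed <- bi == length(bands)
      in_band <- labeled$score >= b[1] &
        (if (closed) labeled$score <= b[2] else labeled$score < b[2])
      pool <- which(in_band)
      if (!length(pool)) {
        return(tibble(band_low = b[1], band_high = b[2], n = 0L,
          precision = NA_real_))
      }
      take <- pool[sample.int(length(pool), min(n_per_band, length(pool)))]
      tibble(band_low = b[1], band_high = b[2], n = length(take),
        precision = mean(labeled$accepted[take]))
    })
  })
  tab <- bind_rows(rows)
  recommended <- NA_real_
  for (i in seq_len(nrow(tab))) {
    upper <- tab$precision[i:nrow(tab)]
    upper <- upper[!is.na(upper)]
    if (length(upper) && all(upper >= target)) {
      recommended <- tab$band_low[i]
      break
    }
  }
  list(table = tab, recommended = recommended)
}
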