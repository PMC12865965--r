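#' Synthetic-corpus generator configuration
#'
#' Defines the study conditions the generator emulates: free-text
#' medication entries with realistic noise — misspellings (up to ~17% of
#' entries, the rate reported for EHR free-text medication fields),
#' case variation, brand-for-generic swaps, dose/frequency suffixes,
#' combination products, and OTC/supplement distractors — over a
#' participant-by-visit structure.
#'
#' @param n_participants number of participants.
#' @param visits_per_participant visits per participant.
#' @param meds_per_visit medication entries recorded per visit.
#' @param n_generics number of synthetic generic drugs.
#' @param n_trade_per_generic trade names per generic.
#' @param n_classes number of leaf therapeutic classes.
#' @param misspelling_rate fraction of entries carrying a random
#'   misspelling (default 0.17).
#' @param brand_swap_rate fraction of entries reported by brand name.
#' @param dose_suffix_rate fraction with a dose/frequency suffix.
#' @param combination_rate fraction that are combination products.
#' @param otc_distractor_rate fraction of entries that are OTC/vitamin/
#'   supplement distractors.
#' @param case_noise_rate fraction with case variation.
#' @param max_edits_per_name maximum character edits per misspelling.
#' @param min_pairwise_distance minimum Levenshtein distance enforced
#'   between any two reference names (default 4, which guarantees that a
#'   1-edit misspelling is always strictly closer to its source than to
#'   any other name).
#' @param seed integer seed recorded in the output manifest.
#' @return a `rxh_gen_config` list.
#' @export
generator_config <- function(n_participants = 50L,
                             visits_per_participant = 4L,
                             meds_per_visit = 5L,
                             n_generics = 50L,
                             n_trade_per_generic = 2L,
                             n_classes = 20L,
                             misspelling_rate = 0.17,
                             brand_swap_rate = 0.25,
                             dose_suffix_rate = 0.30,
                             combination_rate = 0.05,
                             otc_distractor_rate = 0.10,
                             case_noise_rate = 0.30,
                             max_edits_per_name = 1L,
                             min_pairwise_distance = 4L,
                             seed = 1L) {
  rates <- c(misspelling_rate, brand_swap_rate, dose_suffix_rate,
    combination_rate, otc_distractor_rate, case_noise_rate)
  if (any(rates < 0 | rates > 1)) {
    abort_rx("all rates must be in [0, 1]", "rxh_parameter_error")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      visits_per_participant = as.integer(visits_per_participant),
      meds_per_visit = as.integer(meds_per_visit),
      n_generics = as.integer(n_generics),
      n_trade_per_generic = as.integer(n_trade_per_generic),
      n_classes = as.integer(n_classes),
      misspelling_rate = misspelling_rate,
      brand_swap_rate = brand_swap_rate,
      dose_suffix_rate = dose_suffix_rate,
      combination_rate = combination_rate,
      otc_distractor_rate = otc_distractor_rate,
      case_noise_rate = case_noise_rate,
      max_edits_per_name = as.integer(max_edits_per_name),
      min_pairwise_distance = as.integer(min_pairwise_distance),
      seed = as.integer(seed)
    ),
    class = "rxh_gen_config"
  )
}

.otc_terms <- c(
  "vitamin d", "vitamin c", "vitamin b12", "fish oil", "omega 3",
  "multivitamin", "calcium", "magnesium", "zinc", "melatonin",
  "ibuprofen", "acetaminophen", "aspirin", "glucosamine", "probiotic",
  "st johns wort"
)

.name_consonants <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r",
  "s", "t", "v", "z")
.name_vowels <- c("a", "e", "i", "o", "u")
.name_suffixes <- c("statin", "dipine", "sartan", "oxetine", "azepam",
  "prazole", "formin", "cillin", "mycin", "tidine", "parin", "azole",
  "olone")

# pronounceable candidate: three consonant-vowel syllables plus a common
# drug-name suffix; always at least 10 characters, so a single edit keeps
# normalized Levenshtein similarity >= 0.90
random_drug_name <- function() {
  syll <- paste0(sample(.name_consonants, 3, replace = TRUE),
    sample(.name_vowels, 3, replace = TRUE), collapse = "")
  paste0(syll, sample(.name_suffixes, 1))
}

sample_separated_names <- function(n, min_dist, existing = character(0),
                                   max_attempts = 400L * n) {
  names <- character(0)
  all_names <- existing
  attempts <- 0L
  while (length(names) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort_rx(paste(
        "could not generate", n, "names at minimum pairwise distance",
        min_dist, "- try fewer names or a smaller distance"),
        "rxh_generation_error")
    }
    cand <- random_drug_name()
    ok <- all(vapply(all_names, function(x) lev_distance(cand, x) >= min_dist,
      logical(1)))
    if (ok) {
      names <- c(names, cand)
      all_names <- c(all_names, cand)
    }
  }
  names
}

derive_seed <- function(seed, k) {
  (abs(as.integer(seed)) %% 900000007L) + as.integer(k)
}

.class_word1 <- c("Adrenergic", "Cholinergic", "Cardiac", "Central",
  "Gastric", "Renal", "Hepatic", "Neuronal", "Immune", "Metabolic",
  "Serotonergic", "Dopaminergic", "Vascular", "Endocrine", "Pulmonary",
  "Dermal")
.class_word2 <- c("Agents", "Inhibitors", "Blockers", "Modulators",
  "Stimulants", "Antagonists", "Analogues", "Regulators")

#' Generate a synthetic reference set
#'
#' Builds the five relational reference tables over pronounceable synthetic
#' drug names (pairwise Levenshtein distance at least
#' `min_pairwise_distance` across all generic and trade names), a 4-level
#' class-number grid, clinical-drug-form strings of the form
#' `"<generic> <form>"`, the OTC exclusion list, and a small seeded variant
#' dictionary. Deterministic under `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return list with `refset` (an `rxh_refset`), `exclusions`,
#'   `dictionary`, and a ground-truth `drug_table` (generic, trade names,
#'   class number).
#' @export
generate_reference <- function(cfg = generator_config()) {
  withr::with_seed(derive_seed(cfg$seed, 0L), {
    n_names <- cfg$n_generics * (1L + cfg$n_trade_per_generic)
    all_names <- sample_separated_names(n_names, cfg$min_pairwise_distance)
    generics <- all_names[seq_len(cfg$n_generics)]
    trades <- matrix(all_names[-seq_len(cfg$n_generics)],
      nrow = cfg$n_generics, ncol = cfg$n_trade_per_generic)

    # 4-level class grid: two-digit groups, leaves at depth 4
    g1 <- sprintf("%02d", seq(4, 92, by = 4))
    leafs <- character(0)
    while (length(leafs) < cfg$n_classes) {
      cand <- paste0(
        sample(g1, 1), ":", sample(sprintf("%02d", seq(4, 32, 4)), 1), ".",
        sample(sprintf("%02d", seq(2, 20, 2)), 1), ".",
        sample(sprintf("%02d", seq(2, 12, 2)), 1)
      )
      if (!cand %in% leafs) leafs <- c(leafs, cand)
    }
    lv <- derive_class_levels(leafs)
    all_nums <- unique(c(lv$level2, lv$level3, leafs))
    text_for <- function(num) {
      groups <- strsplit(num, "[:.]")[[1]]
      w1 <- .class_word1[(sum(as.integer(groups)) %% length(.class_word1)) + 1L]
      w2 <- .class_word2[(as.integer(groups[length(groups)]) %%
        length(.class_word2)) + 1L]
      paste(w1, w2, "Group", gsub("[:.]", "", num))
    }
    classes <- tibble(
      AHFSClassID = paste0("C", seq_along(all_nums)),
      AHFSClassNum = all_nums,
      AHFSClassText = vapply(all_nums, text_for, character(1))
    )

    drug_class_num <- sample(leafs, cfg$n_generics, replace = TRUE)
    drug_class_id <- classes$AHFSClassID[match(drug_class_num,
      classes$AHFSClassNum)]
    gen_tbl <- tibble(
      UN = sprintf("U%04d", seq_len(cfg$n_generics)),
      GenDrugName = generics,
      AHFSClassID = drug_class_id
    )
    trade_tbl <- tibble(
      UN = sprintf("T%04d", seq_len(cfg$n_generics * cfg$n_trade_per_generic)),
      Tradename = vapply(as.vector(trades), function(x) {
        paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
      }, character(1)),
      GenDrugName = rep(generics, times = cfg$n_trade_per_generic)
    )
    forms <- c("oral tablet", "oral capsule", "oral solution",
      "injectable solution", "topical cream", "extended release tablet")
    scdf_tbl <- tibble(
      SCDF_STR = paste(generics, sample(forms, cfg$n_generics, replace = TRUE)),
      SCDF_CUI = sprintf("CUI%05d", seq_len(cfg$n_generics)),
      AHFSClassNum = drug_class_num
    )

    refset <- new_refset(gen_tbl, trade_tbl, scdf_tbl, classes)

    # seeded dictionary: a handful of historically adjudicated misspellings
    n_seed <- max(1L, cfg$n_generics %/% 10L)
    seed_gen <- sample(generics, n_seed)
    seed_var <- vapply(seed_gen, function(g) apply_random_edit(g), character(1))
    keep <- seed_var != seed_gen & !seed_var %in% c(generics, tolower(trade_tbl$Tradename))
    dictionary <- new_dictionary(seed_var[keep], seed_gen[keep],
      source = "seeded", date = "2026-01-01")

    list(
      refset = refset,
      exclusions = .otc_terms,
      dictionary = dictionary,
      drug_table = tibble(
        generic = generics,
        class_num = drug_class_num,
        trades = lapply(seq_len(cfg$n_generics), function(i) {
          trade_tbl$Tradename[trade_tbl$GenDrugName == generics[i]]
        })
      )
    )
  })
}

apply_random_edit <- function(name) {
  letters_pool <- letters
  n <- nchar(name)
  op <- sample(c("sub", "ins", "del"), 1)
  pos <- sample.int(n, 1)
  chars <- strsplit(name, "")[[1]]
  if (op == "sub") {
    chars[pos] <- sample(letters_pool, 1)
  } else if (op == "ins") {
    chars <- append(chars, sample(letters_pool, 1), after = pos)
  } else if (n > 2L) {
    chars <- chars[-pos]
  }
  paste(chars, collapse = "")
}

#' Corrupt a reference name into realistic free text
#'
#' Applies, at the configured rates: brand-for-generic swap, up to
#' `max_edits_per_name` random character edits, a combination join with a
#' second generic (corruption touches the primary component only), case
#' variation, and a dose/frequency suffix. Uses the current RNG stream;
#' every applied operation is recorded.
#'
#' @param name a generic name from the reference set.
#' @param cfg a [generator_config()].
#' @param reference output of [generate_reference()].
#' @return list with `text` (the raw free-text entry) and `corruption`
#'   (one-row tibble of applied operations).
#' @export
corrupt_name <- function(name, cfg, reference) {
  surface <- name
  brand_swap <- stats::runif(1) < cfg$brand_swap_rate
  if (brand_swap) {
    trades <- reference$drug_table$trades[[
      match(name, reference$drug_table$generic)]]
    surface <- tolower(sample(trades, 1))
  }
  n_edits <- 0L
  if (stats::runif(1) < cfg$misspelling_rate && cfg$max_edits_per_name > 0L) {
    n_edits <- sample.int(cfg$max_edits_per_name, 1)
    for (k in seq_len(n_edits)) surface <- apply_random_edit(surface)
  }
  partner <- NA_character_
  if (stats::runif(1) < cfg$combination_rate) {
    others <- setdiff(reference$drug_table$generic, name)
    partner <- sample(others, 1)
    surface <- paste0(surface, "-", partner)
  }
  case_op <- "none"
  if (stats::runif(1) < cfg$case_noise_rate) {
    case_op <- sample(c("title", "upper"), 1)
    surface <- if (case_op == "title") {
      paste0(toupper(substr(surface, 1, 1)), substr(surface, 2, nchar(surface)))
    } else {
      toupper(surface)
    }
  }
  dose <- NA_character_
  if (stats::runif(1) < cfg$dose_suffix_rate) {
    dose <- sample(c("10 mg", "20 mg", "50 mg", "20-12.5 mg", "5 mg daily",
      "100 mcg", "2 tablets daily"), 1)
    surface <- paste(surface, dose)
  }
  list(
    text = surface,
    corruption = tibble(
      brand_swap = brand_swap, n_edits = n_edits, partner = partner,
      case_op = case_op, dose_suffix = dose
    )
  )
}

#' Generate a synthetic free-text medication corpus with ground truth
#'
#' Draws medications per participant-visit, corrupts their names, and
#' inserts OTC/supplement distractors at the configured rate. Every raw
#' entry has exactly one ground-truth record. Byte-identical under the
#' same configuration and seed.
#'
#' @param cfg a [generator_config()].
#' @param reference optional pre-generated [generate_reference()] output
#'   (regenerated from `cfg` when omitted).
#' @return list with `entries` (raw records tibble), `truth` (ground-truth
#'   tibble), `reference`, and `manifest` (config echo, seed, counts).
#' @export
generate_corpus <- function(cfg = generator_config(), reference = NULL) {
  if (is.null(reference)) reference <- generate_reference(cfg)
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    rows <- list()
    truths <- list()
    rid <- 0L
    for (p in seq_len(cfg$n_participants)) {
      pid <- sprintf("P%03d", p)
      for (v in seq_len(cfg$visits_per_participant)) {
        vid <- sprintf("V%d", v)
        for (m in seq_len(cfg$meds_per_visit)) {
          rid <- rid + 1L
          id <- sprintf("R%06d", rid)
          if (stats::runif(1) < cfg$otc_distractor_rate) {
            term <- sample(.otc_terms, 1)
            text <- term
            if (stats::runif(1) < cfg$dose_suffix_rate) {
              text <- paste(text, sample(c("500 mg", "1000 iu", "daily"), 1))
            }
            rows[[rid]] <- tibble(record_id = id, participant_id = pid,
              visit_id = vid, med_text = text)
            truths[[rid]] <- tibble(record_id = id, participant_id = pid,
              visit_id = vid, excluded = TRUE,
              true_canonical = NA_character_, true_class_num = NA_character_,
              brand_swap = FALSE, n_edits = 0L, partner = NA_character_,
              case_op = "none", dose_suffix = NA_character_)
          } else {
            gi <- sample.int(cfg$n_generics, 1)
            gname <- reference$drug_table$generic[gi]
            corr <- corrupt_name(gname, cfg, reference)
            rows[[rid]] <- tibble(record_id = id, participant_id = pid,
              visit_id = vid, med_text = corr$text)
            truths[[rid]] <- bind_cols(
              tibble(record_id = id, participant_id = pid, visit_id = vid,
                excluded = FALSE, true_canonical = gname,
                true_class_num = reference$drug_table$class_num[gi]),
              corr$corruption
            )
          }
        }
      }
    }
    entries <- bind_rows(rows)
    truth <- bind_rows(truths)
    list(
      entries = entries,
      truth = truth,
      reference = reference,
      manifest = list(
        config = unclass(cfg),
        seed = cfg$seed,
        counts = list(
          entries = nrow(entries),
          excluded_truth = sum(truth$excluded),
          participants = cfg$n_participants
        )
      )
    )
  })
}

#' Evaluate pipeline recovery against ground truth
#'
#' Compares pipeline outputs with the generator's ground truth:
#' standardization precision (correct canonical among matched entries) and
#' recall (matched-and-correct among eligible truths), classification
#' accuracy over resolved names, and cellwise agreement between the
#' produced exposure matrix and the truth matrix.
#'
#' @param results standardization results tibble.
#' @param classmap classification-map tibble.
#' @param wide exposure matrix from [to_wide()].
#' @param truth ground-truth tibble from [generate_corpus()].
#' @return one-row tibble of metrics.
#' @export
evaluate_recovery <- function(results, classmap, wide, truth) {
  results <- as_tibble(results)
  truth <- as_tibble(truth)
  if (!all(results$record_id %in% truth$record_id)) {
    abort_rx("results contain record_ids absent from ground truth",
      "rxh_validation_error")
  }
  merged <- left_join(results, truth, by = "record_id")
  eligible <- dplyr::filter(merged, !.data$excluded)
  matched <- dplyr::filter(eligible,
    .data$status %in% c("matched", "expert_resolved"))
  precision <- if (nrow(matched)) {
    mean(matched$canonical_name == matched$true_canonical)
  } else {
    NA_real_
  }
  recall <- if (nrow(eligible)) {
    sum(matched$canonical_name == matched$true_canonical) / nrow(eligible)
  } else {
    NA_real_
  }

  truth_map <- distinct(dplyr::filter(truth, !.data$excluded),
    .data$true_canonical, .data$true_class_num)
  resolved <- dplyr::filter(truth_map,
    .data$true_canonical %in% classmap$canonical_name)
  class_acc <- if (nrow(resolved)) {
    mean(vapply(seq_len(nrow(resolved)), function(i) {
      assigned <- classmap$ahfs_class_num[
        classmap$canonical_name == resolved$true_canonical[i]]
      resolved$true_class_num[i] %in% assigned
    }, logical(1)))
  } else {
    NA_real_
  }

  # truth exposure grid, built independently of to_wide()
  tru <- dplyr::filter(truth, !.data$excluded)
  tru_key <- paste(tru$participant_id, tru$visit_id)
  wide_key <- paste(wide$participant_id, wide$visit_id)
  all_keys <- sort(unique(c(tru_key, wide_key)))
  wide_cols <- setdiff(names(wide), c("participant_id", "visit_id"))
  wide_nums <- sub("\\|.*$", "", wide_cols)
  all_nums <- sort(unique(c(tru$true_class_num, wide_nums)))

  tm <- matrix(0L, length(all_keys), length(all_nums),
    dimnames = list(all_keys, all_nums))
  tm[cbind(match(tru_key, all_keys), match(tru$true_class_num, all_nums))] <- 1L

  pm <- matrix(0L, length(all_keys), length(all_nums),
    dimnames = list(all_keys, all_nums))
  wm <- as.matrix(wide[, wide_cols, drop = FALSE])
  pm[match(wide_key, all_keys), match(wide_nums, all_nums)] <- wm

  tibble(
    standardization_precision = precision,
    standardization_recall = recall,
    classification_accuracy = class_acc,
    exposure_cell_agreement = mean(pm == tm)
  )
}
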