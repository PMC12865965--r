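test_that("reference generation is deterministic under a seed", {
  cfg <- generator_config(n_generics = 12L, seed = 17L)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1$refset$generics, r2$refset$generics)
  expect_identical(r1$refset$tradenames, r2$refset$tradenames)
  expect_identical(as.data.frame(r1$dictionary), as.data.frame(r2$dictionary))
  expect_identical(r1$drug_table$class_num, r2$drug_table$class_num)
  # a different seed draws different names
  r3 <- generate_reference(generator_config(n_generics = 12L, seed = 18L))
  expect_false(identical(r1$refset$generics$GenDrugName,
    r3$refset$generics$GenDrugName))
})

test_that("all reference names keep the minimum pairwise edit distance", {
  ref <- study_corpus()$reference
  names <- c(ref$refset$generics$name_norm, ref$refset$tradenames$name_norm)
  expect_false(any(duplicated(names)))
  # exhaustive pairwise check via an independent implementation
  d <- utils::adist(names)
  expect_gte(min(d[upper.tri(d)]), 4L)
  # spot-check the independent distances against the package metric
  set.seed(21)
  for (k in 1:25) {
    ij <- sample(length(names), 2)
    expect_equal(lev_distance(names[ij[1]], names[ij[2]]),
      as.integer(d[ij[1], ij[2]]))
  }
})

test_that("generated names are long enough to survive one edit at 0.90", {
  ref <- study_corpus()$reference
  gens <- ref$refset$generics$name_norm
  expect_true(all(nchar(gens) >= 10L))
  set.seed(22)
  for (g in gens) {
    v <- rxharmonize:::apply_random_edit(g)
    expect_gte(levenshtein_similarity(v, g), 0.9 - 1e-12)
    # distance >= 4 between names means the edit cannot defect to a
    # different generic above the threshold
    others <- setdiff(gens, g)
    best_other <- max(vapply(others, function(o) {
      levenshtein_similarity(v, o)
    }, numeric(1)))
    expect_lt(best_other, 0.9)
  }
})

test_that("class numbers in the synthetic reference parse canonically", {
  rs <- study_corpus()$reference$refset
  expect_identical(canonical_class_num(rs$classes$AHFSClassNum),
    rs$classes$AHFSClassNum)
  lv <- derive_class_levels(rs$scdf$AHFSClassNum)
  expect_true(all(lv$level2 %in% rs$classes$AHFSClassNum))
  expect_true(all(lv$level3 %in% rs$classes$AHFSClassNum))
})

test_that("corrupt_name at zero rates is the identity", {
  cfg <- generator_config(misspelling_rate = 0, brand_swap_rate = 0,
    dose_suffix_rate = 0, combination_rate = 0, otc_distractor_rate = 0,
    case_noise_rate = 0, seed = 5L)
  ref <- generate_reference(generator_config(n_generics = 8L, seed = 5L))
  withr::with_seed(1L, {
    for (g in ref$drug_table$generic) {
      out <- corrupt_name(g, cfg, ref)
      expect_identical(out$text, g)
      expect_false(out$corruption$brand_swap)
      expect_equal(out$corruption$n_edits, 0L)
      expect_equal(out$corruption$case_op, "none")
    }
  })
  expect_error(generator_config(misspelling_rate = 1.2),
    class = "rxh_parameter_error")
})

test_that("corpus generation is deterministic with a full ground truth", {
  c1 <- study_corpus()
  c2 <- generate_corpus(generator_config(seed = 1L))
  expect_identical(c1$entries, c2$entries)
  expect_identical(c1$truth, c2$truth)
  expect_equal(nrow(c1$entries), 1000L)
  expect_identical(c1$entries$record_id, c1$truth$record_id)
  # every non-excluded truth names a real generic and its true class
  elig <- c1$truth[!c1$truth$excluded, ]
  expect_true(all(elig$true_canonical %in%
    c1$reference$refset$generics$name_norm))
  expect_true(all(elig$true_class_num %in%
    c1$reference$refset$classes$AHFSClassNum))
  # manifest echoes the configuration and counts
  expect_equal(c1$manifest$seed, 1L)
  expect_equal(c1$manifest$counts$entries, 1000L)
  expect_equal(c1$manifest$counts$excluded_truth, sum(c1$truth$excluded))
})

test_that("distractor frequency is consistent with its configured rate", {
  truth <- study_corpus()$truth
  n_otc <- sum(truth$excluded)
  # binomial(1000, 0.10): an observation outside [55, 155] has
  # probability < 1e-5 and would indicate a rate defect
  expect_gte(n_otc, 55L)
  expect_lte(n_otc, 155L)
  otc_entries <- normalize_text(study_corpus()$entries$med_text[truth$excluded])
  expect_true(all(vapply(otc_entries, function(s) {
    any(startsWith(s, rxharmonize:::.otc_terms))
  }, logical(1))))
})

test_that("a noise-free corpus standardizes perfectly at stage 1", {
  cfg <- generator_config(n_participants = 10L, misspelling_rate = 0,
    brand_swap_rate = 0, dose_suffix_rate = 0, combination_rate = 0,
    otc_distractor_rate = 0, case_noise_rate = 0, seed = 33L)
  corpus <- generate_corpus(cfg)
  run <- run_pipeline(corpus$entries, corpus$reference$refset,
    corpus$reference$exclusions, dict = corpus$reference$dictionary)
  expect_equal(nrow(run$excluded), 0L)
  expect_true(all(run$std$results$status == "matched"))
  expect_true(all(run$std$results$stage == 1L))
  m <- evaluate_recovery(run$std$results, run$classification$classmap,
    run$wide, corpus$truth)
  expect_equal(m$standardization_precision, 1.0)
  expect_equal(m$standardization_recall, 1.0)
  expect_equal(m$classification_accuracy, 1.0)
  expect_equal(m$exposure_cell_agreement, 1.0)
})

test_that("an exact-only threshold keeps precision while losing recall", {
  corpus <- study_corpus()
  cfg <- standardization_config(fuzzy_threshold = 1.0, borderline_low = 1.0)
  run <- run_pipeline(corpus$entries, corpus$reference$refset,
    corpus$reference$exclusions, dict = corpus$reference$dictionary,
    cfg = cfg)
  m <- evaluate_recovery(run$std$results, run$classification$classmap,
    run$wide, corpus$truth)
  expect_equal(m$standardization_precision, 1.0)
  expect_lt(m$standardization_recall, 1.0)
  # misspelled entries not in the dictionary are left for review
  expect_gt(nrow(run$std$queues$unmatched), 0L)
})

test_that("recovery evaluation rejects results from a foreign corpus", {
  corpus <- study_corpus()
  res <- tibble::tibble(record_id = "NOPE", status = "matched",
    canonical_name = "x")
  expect_error(
    evaluate_recovery(res, tibble::tibble(), tibble::tibble(), corpus$truth),
    class = "rxh_validation_error")
})

test_that("an impossible separation demand fails with guidance", {
  expect_error(
    rxharmonize:::sample_separated_names(500L, 15L, max_attempts = 600L),
    class = "rxh_generation_error")
})
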