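lex <- function() build_lexicon(tiny_refset())

test_that("absolute match resolves tokens against the lexicon", {
  e <- tiny_entries(c("fluoxetine 20 mg", "xyzzy", "Lipitor"))
  r1 <- absolute_match(e[1, ], lex())
  expect_equal(r1$status, "matched")
  expect_equal(r1$canonical_name, "fluoxetine")
  expect_equal(r1$method, "absolute")

  expect_equal(absolute_match(e[2, ], lex())$status, "unmatched")
  # brand resolves to its generic canonical
  r3 <- absolute_match(e[3, ], lex())
  expect_equal(r3$canonical_name, "atorvastatin")
})

test_that("two distinct generics in one entry are ambiguous", {
  e <- tiny_entries("fluoxetine lisinopril")
  r <- absolute_match(e[1, ], lex())
  expect_equal(r$status, "ambiguous")
  expect_setequal(r$candidates[[1]]$candidate, c("fluoxetine", "lisinopril"))
  # a brand plus its own generic is NOT ambiguous: one canonical
  e2 <- tiny_entries("lipitor atorvastatin")
  r2 <- absolute_match(e2[1, ], lex())
  expect_equal(r2$status, "matched")
  expect_equal(r2$canonical_name, "atorvastatin")
})

test_that("combination products resolve by primary active ingredient", {
  e <- tiny_entries("lisinopril-hctz 20-12.5 mg")
  r <- absolute_match(e[1, ], lex())
  expect_equal(r$status, "matched")
  expect_equal(r$canonical_name, "lisinopril")
})

test_that("fuzzy stage matches misspellings at the threshold", {
  # one edit on an 11-char name: levenshtein similarity 10/11 >= 0.90
  e <- tiny_entries("atorvastatn")
  r <- fuzzy_match_stage(e[1, ], lex(), standardization_config())
  expect_equal(r$status, "matched")
  expect_equal(r$canonical_name, "atorvastatin")
  expect_equal(r$method, "fuzzy")
  expect_gte(r$score, 0.90)

  # jaccard binding: threshold set just below the oracle bigram score
  s_oracle <- oracle_jaccard("amitriptiline", "amitriptyline", 2)
  cfgj <- standardization_config(fuzzy_threshold = s_oracle - 0.01,
    borderline_low = s_oracle - 0.02, fuzzy_metric = "jaccard_ngram")
  lx <- tibble::tibble(name_norm = "amitriptyline",
    canonical = "amitriptyline", kind = "generic")
  rj <- fuzzy_match_stage(tiny_entries("amitriptiline")[1, ], lx, cfgj)
  expect_equal(rj$status, "matched")
  expect_equal(rj$score, s_oracle)
})

test_that("scores inside the borderline band are held for review", {
  # one edit on an 8-char name: similarity 7/8 = 0.875 in [0.85, 0.90)
  lx <- tibble::tibble(name_norm = "belacrol", canonical = "belacrol",
    kind = "generic")
  e <- tiny_entries("belacrul")
  r <- fuzzy_match_stage(e[1, ], lx, standardization_config())
  expect_equal(r$status, "borderline")
  expect_equal(r$score, 0.875)
  expect_gte(nrow(r$candidates[[1]]), 1L)
})

test_that("dictionary stage matches variants exactly then fuzzily", {
  d <- new_dictionary("lipator", "atorvastatin")
  r <- dictionary_match(tiny_entries("lipator")[1, ], d,
    standardization_config())
  expect_equal(r$status, "matched")
  expect_equal(r$method, "dict_absolute")
  expect_equal(r$canonical_name, "atorvastatin")

  # one edit off the dictionary key, threshold relaxed to the oracle floor
  s <- levenshtein_similarity("lipator", "lipatorr")
  cfg <- standardization_config(fuzzy_threshold = s, borderline_low = s - 0.01)
  r2 <- dictionary_match(tiny_entries("lipatorr")[1, ], d, cfg)
  expect_equal(r2$status, "matched")
  expect_equal(r2$method, "dict_fuzzy")
  expect_equal(r2$canonical_name, "atorvastatin")

  r3 <- dictionary_match(tiny_entries("xyzzy")[1, ], new_dictionary(),
    standardization_config())
  expect_equal(r3$status, "unmatched")
})

test_that("corpus standardization conserves entries at every stage", {
  texts <- c("atorvastatin", "Lipitor 10 mg", "fluoxetine", "atorvastatn",
    "mystrydrug", "garbageword", "fluoxetine lisinopril", "")
  e <- tiny_entries(texts)
  std <- standardize_corpus(e, lex(),
    new_dictionary("mystrydrug", "atorvastatin"))
  expect_equal(nrow(std$results), length(texts))
  # every entry ends in exactly one terminal state
  expect_true(all(std$results$status %in%
    c("matched", "ambiguous", "borderline", "unmatched")))
  # per-stage conservation: correct + flagged + unmatched = stage input
  for (i in seq_len(nrow(std$counts))) {
    with(std$counts[i, ],
      expect_equal(correct + ambiguous + unmatched, total))
  }
  # stage pipelining: each stage's input is the previous stage's unmatched
  expect_equal(std$counts$total[1], length(texts))
  for (i in 2:nrow(std$counts)) {
    expect_equal(std$counts$total[i], std$counts$unmatched[i - 1])
  }
  # ground truth of this small corpus
  res <- std$results
  expect_equal(res$status[res$record_id == "R007"], "ambiguous")
  expect_equal(res$canonical_name[res$record_id == "R005"], "atorvastatin")
  expect_equal(res$status[res$record_id == "R006"], "unmatched")
  expect_equal(res$status[res$record_id == "R008"], "unmatched")
})

test_that("an all-clean corpus fully matches at stage 1", {
  e <- tiny_entries(c("atorvastatin", "lisinopril", "fluoxetine"))
  std <- standardize_corpus(e, lex())
  expect_equal(std$counts$correct[1], 3L)
  expect_true(all(std$results$stage == 1L))
})

test_that("a garbage-only corpus is fully unmatched with empty other queues", {
  e <- tiny_entries(c("qqq", "wwwww"))
  std <- standardize_corpus(e, lex())
  expect_equal(nrow(std$queues$unmatched), 2L)
  expect_equal(nrow(std$queues$ambiguous), 0L)
  expect_equal(nrow(std$queues$borderline), 0L)
})

test_that("raising the threshold never increases matched entries", {
  e <- tiny_entries(c("atorvastatin", "atorvastatn", "fluoxetine",
    "fluoxetin", "lisinopril", "lisinoprol", "garbage"))
  matched <- sapply(c(0.80, 0.90, 0.95, 1.00), function(thr) {
    cfg <- standardization_config(fuzzy_threshold = thr,
      borderline_low = min(0.85, thr))
    sum(standardize_corpus(e, lex(), cfg = cfg)$results$status == "matched")
  })
  expect_true(all(diff(matched) <= 0))
})

test_that("expert decisions resolve queues and grow the dictionary", {
  e <- tiny_entries(c("atorvastatin", "mystrydrug", "fluoxetine lisinopril"))
  std <- standardize_corpus(e, lex())
  expect_equal(nrow(std$queues$unmatched), 1L)
  expect_equal(nrow(std$queues$ambiguous), 1L)

  decisions <- tibble::tibble(
    record_id = c("R002", "R003"),
    action = c("accept", "reject"),
    canonical_name = c("atorvastatin", NA),
    reviewer = "pharmacist1", date = "2026-02-01"
  )
  upd <- apply_expert_decisions(std, decisions, new_dictionary())
  res <- upd$results
  expect_equal(res$status[res$record_id == "R002"], "expert_resolved")
  expect_equal(res$stage[res$record_id == "R002"], 5L)
  expect_equal(res$status[res$record_id == "R003"], "rejected")
  expect_true("mystrydrug" %in% upd$dictionary$variant)
  expect_equal(
    upd$dictionary$canonical[upd$dictionary$variant == "mystrydrug"],
    "atorvastatin")
  expect_equal(
    upd$dictionary$source[upd$dictionary$variant == "mystrydrug"],
    "expert-adjudicated")

  # decisions for non-queued records are rejected
  badd <- tibble::tibble(record_id = "R001", action = "accept",
    canonical_name = "x", reviewer = "r", date = NA)
  expect_error(apply_expert_decisions(std, badd), class = "rxh_validation_error")
})

test_that("dictionary growth lets a replay match formerly queued entries", {
  e <- tiny_entries(c("mystrydrug", "atorvastatin"))
  std <- standardize_corpus(e, lex())
  expect_equal(nrow(std$queues$unmatched), 1L)
  decisions <- tibble::tibble(record_id = "R001", action = "accept",
    canonical_name = "atorvastatin", reviewer = "r", date = NA)
  upd <- apply_expert_decisions(std, decisions)
  replay <- standardize_corpus(e, lex(), upd$dictionary)
  expect_equal(nrow(replay$queues$unmatched), 0L)
  r <- replay$results[replay$results$record_id == "R001", ]
  expect_equal(r$status, "matched")
  expect_equal(r$method, "dict_absolute")
  # monotonicity: the previously matched entry stays matched
  expect_equal(
    replay$results$status[replay$results$record_id == "R002"], "matched")
})

test_that("standardization is deterministic", {
  e <- tiny_entries(c("atorvastatn", "Lipitor", "garbage"))
  s1 <- standardize_corpus(e, lex())
  s2 <- standardize_corpus(e, lex())
  expect_identical(s1$results, s2$results)
  expect_identical(s1$counts, s2$counts)
})
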