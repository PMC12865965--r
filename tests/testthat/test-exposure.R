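mk_long <- function() {
  tibble::tibble(
    participant_id = c("P1", "P1", "P2"),
    visit_id = c("V1", "V1", "V1"),
    canonical_name = c("atorvastatin", "simvastatin", "lisinopril"),
    ahfs_class_num = c("24:06.08", "24:06.08", "24:32.04"),
    class_label = c("Statins", "Statins", "ACE Inhibitors")
  )
}

test_that("to_long joins records to the classification map", {
  cm <- tibble::tibble(
    canonical_name = c("atorvastatin", "lisinopril"),
    ahfs_class_num = c("24:06.08", "24:32.04"),
    ahfs_class_text = c("Statins", "ACE Inhibitors"),
    method = "generic_exact", score = NA_real_
  )
  records <- tibble::tibble(
    participant_id = c("P1", "P1", "P2"),
    visit_id = c("V1", "V2", "V1"),
    canonical_name = c("atorvastatin", "lisinopril", "mysterydrug")
  )
  out <- to_long(records, cm)
  expect_equal(nrow(out$long), 2L)
  expect_equal(out$long$ahfs_class_num, c("24:06.08", "24:32.04"))
  expect_equal(out$long$class_label[1], "Statins")
  # unmapped names are routed aside, never dropped
  expect_equal(out$unclassified$canonical_name, "mysterydrug")
  expect_equal(nrow(out$long) + nrow(out$unclassified), nrow(records))
})

test_that("to_long validates keys and handles an empty map", {
  bad <- tibble::tibble(participant_id = c("P1", NA), visit_id = "V1",
    canonical_name = "x")
  expect_error(to_long(bad, mk_long()), class = "rxh_validation_error")
  recs <- tibble::tibble(participant_id = "P1", visit_id = "V1",
    canonical_name = "x")
  out <- to_long(recs, NULL)
  expect_equal(nrow(out$long), 0L)
  expect_equal(nrow(out$unclassified), 1L)
})

test_that("wide matrix is binary: same-class meds collapse to one cell", {
  wide <- to_wide(mk_long())
  expect_equal(nrow(wide), 2L)
  cls <- setdiff(names(wide), c("participant_id", "visit_id"))
  expect_equal(cls, c("24:06.08|Statins", "24:32.04|ACE_Inhibitors"))
  # P1/V1 has two statins but the indicator is 1, not 2
  expect_equal(wide[["24:06.08|Statins"]], c(1L, 0L))
  expect_equal(wide[["24:32.04|ACE_Inhibitors"]], c(0L, 1L))
  expect_true(all(unlist(wide[cls]) %in% c(0L, 1L)))
})

test_that("every 1-cell is witnessed by a long row and vice versa", {
  long <- mk_long()
  wide <- to_wide(long)
  cls <- setdiff(names(wide), c("participant_id", "visit_id"))
  for (i in seq_len(nrow(wide))) {
    for (cn in cls) {
      num <- sub("\\|.*$", "", cn)
      witness <- any(long$participant_id == wide$participant_id[i] &
        long$visit_id == wide$visit_id[i] & long$ahfs_class_num == num)
      expect_equal(wide[[cn]][i] == 1L, witness)
    }
  }
})

test_that("a visit roster materializes all-zero rows", {
  roster <- tibble::tibble(participant_id = c("P1", "P2", "P3"),
    visit_id = "V1")
  wide <- to_wide(mk_long(), roster = roster)
  expect_equal(nrow(wide), 3L)
  p3 <- wide[wide$participant_id == "P3", ]
  expect_true(all(p3[, -(1:2)] == 0L))
  # without the roster the empty visit is absent
  expect_equal(nrow(to_wide(mk_long())), 2L)
})

test_that("a declared class universe adds empty columns, never loses data", {
  wide <- to_wide(mk_long(),
    class_universe = c("24:06.08", "24:32.04", "28:16.04.20"))
  expect_equal(ncol(wide), 2L + 3L)
  expect_true(all(wide[["28:16.04.20"]] == 0L))
  expect_error(to_wide(mk_long(), class_universe = "28:16.04.20"),
    class = "rxh_parameter_error")
})

test_that("merge maps consolidate columns transitively and reject cycles", {
  mm <- tibble::tibble(from_num = "24:32.04", to_num = "24:06.08")
  wide <- to_wide(mk_long(), merge_map = mm)
  cls <- setdiff(names(wide), c("participant_id", "visit_id"))
  expect_equal(length(cls), 1L)
  expect_true(startsWith(cls, "24:06.08"))
  expect_equal(wide[[cls]], c(1L, 1L))
  # chain a -> b -> c resolves to c
  chain <- tibble::tibble(from_num = c("24:32.04", "24:06.08"),
    to_num = c("24:06.08", "28:16"))
  expect_equal(
    rxharmonize:::resolve_merge_map("24:32.04", chain), "28:16")
  cyc <- tibble::tibble(from_num = c("24:06.08", "24:32.04"),
    to_num = c("24:32.04", "24:06.08"))
  expect_error(to_wide(mk_long(), merge_map = cyc),
    class = "rxh_config_error")
})

test_that("level roll-up aggregates columns along the hierarchy prefix", {
  long <- tibble::tibble(
    participant_id = c("P1", "P1", "P2"),
    visit_id = "V1",
    canonical_name = c("druga", "drugb", "drugc"),
    ahfs_class_num = c("28:16.04.20", "28:16.04.92", "24:06.08.04"),
    class_label = c("SSRIs", "SNRIs", "Statins")
  )
  w4 <- to_wide(long)
  expect_equal(ncol(w4), 2L + 3L)
  w3 <- to_wide(long, level = 3)
  cls3 <- setdiff(names(w3), c("participant_id", "visit_id"))
  # the two sibling leaves share a level-3 parent and collapse
  expect_setequal(sub("\\|.*$", "", cls3), c("28:16.04", "24:06.08"))
  expect_equal(w3[[grep("^28:16.04", cls3, value = TRUE)]], c(1L, 0L))
  w2 <- to_wide(long, level = 2)
  cls2 <- setdiff(names(w2), c("participant_id", "visit_id"))
  expect_setequal(sub("\\|.*$", "", cls2), c("28:16", "24:06"))
  # a visit exposed at level 4 stays exposed after roll-up
  expect_equal(rowSums(w3[cls3]) >= 1, rowSums(w4[, -(1:2)]) >= 1)
  expect_error(to_wide(long, level = 5), class = "rxh_parameter_error")
})

test_that("exposure summaries compute prevalence and polypharmacy", {
  s <- summarize_exposure(to_wide(mk_long()))
  expect_equal(s$prevalence$prevalence, c(0.5, 0.5))
  expect_equal(s$polypharmacy$n_classes, c(1, 1))
  # roster dilutes prevalence with true-zero visits
  roster <- tibble::tibble(participant_id = c("P1", "P2", "P3", "P4"),
    visit_id = "V1")
  s2 <- summarize_exposure(to_wide(mk_long(), roster = roster))
  expect_equal(s2$prevalence$prevalence, c(0.25, 0.25))
})

test_that("wide construction is deterministic and idempotent in ordering", {
  long <- mk_long()
  shuffled <- long[c(3, 1, 2), ]
  expect_identical(to_wide(long), to_wide(shuffled))
  expect_identical(to_wide(long), to_wide(long))
})
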