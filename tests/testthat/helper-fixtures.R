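# Small hand-built reference fixture (3 generics, brand names, classes)
# and a cached full-scale synthetic run shared across test files.

tiny_refset <- function() {
  generics <- tibble::tibble(
    UN = c("U1", "U2", "U3"),
    GenDrugName = c("atorvastatin", "lisinopril", "fluoxetine"),
    AHFSClassID = c("C1", "C2", "C3")
  )
  tradenames <- tibble::tibble(
    UN = c("T1", "T2", "T3"),
    Tradename = c("Lipitor", "Prinivil", "Prozac"),
    GenDrugName = c("atorvastatin", "lisinopril", "fluoxetine")
  )
  classes <- tibble::tibble(
    AHFSClassID = c("C1", "C2", "C3", "C4", "C5"),
    AHFSClassNum = c("24:06.08", "24:32.04", "28:16.04.20", "24:06", "28:16"),
    AHFSClassText = c(
      "Antihyperlipidemic Agents, Statins",
      "ACE Inhibitors",
      "SSRIs",
      "Antihyperlipidemic Agents",
      "Psychotherapeutic Agents"
    )
  )
  scdf <- tibble::tibble(
    SCDF_STR = c("atorvastatin oral tablet", "lisinopril oral tablet",
      "fluoxetine oral capsule"),
    SCDF_CUI = c("K1", "K2", "K3"),
    AHFSClassNum = c("24:06.08", "24:32.04", "28:16.04.20")
  )
  rxharmonize:::new_refset(generics, tradenames, scdf, classes)
}

tiny_entries <- function(texts, participant = "P1", visit = "V1") {
  normalize_entries(tibble::tibble(
    record_id = sprintf("R%03d", seq_along(texts)),
    participant_id = participant,
    visit_id = visit,
    med_text = texts
  ))
}

# cached study-scale corpus and pipeline run (seed fixed: these are the
# generator's default study conditions)
.fixture_cache <- new.env(parent = emptyenv())

study_corpus <- function() {
  if (is.null(.fixture_cache$corpus)) {
    .fixture_cache$corpus <- generate_corpus(generator_config(seed = 1L))
  }
  .fixture_cache$corpus
}

study_run <- function() {
  if (is.null(.fixture_cache$run)) {
    corpus <- study_corpus()
    .fixture_cache$run <- run_pipeline(
      corpus$entries, corpus$reference$refset, corpus$reference$exclusions,
      dict = corpus$reference$dictionary
    )
  }
  .fixture_cache$run
}
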