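#' Parse and canonicalize an AHFS-style classification number
#'
#' Classification numbers are 1 to 4 two-digit groups. The canonical
#' dialect separates the first pair with `:` and deeper groups with `.`
#' (as in `"08:12.06.04"`); all-`:` and all-`.` exports are accepted and
#' re-emitted canonically so joins stay exact.
#'
#' @param x character vector of class numbers.
#' @return character vector in canonical form.
#' @export
#' @examples
#' canonical_class_num("08.12.06.04") # "08:12.06.04"
canonical_class_num <- function(x) {
  vapply(as.character(x), function(num) {
    if (is.na(num) || !grepl("^[0-9]{2}([:.][0-9]{2}){0,3}$", num)) {
      abort_rx(sprintf("malformed classification number: %s", num),
        "rxh_parse_error")
    }
    groups <- strsplit(num, "[:.]")[[1]]
    format_class_groups(groups)
  }, character(1), USE.NAMES = FALSE)
}

format_class_groups <- function(groups) {
  if (length(groups) == 1L) return(groups)
  paste0(groups[1], ":", paste(groups[-1], collapse = "."))
}

#' Derive the level-2/3/4 prefixes of a classification number
#'
#' Level 2 is the first two 2-digit groups, level 3 the first three, and
#' level 4 all groups. Shallow numbers (fewer groups) repeat the deepest
#' available prefix, so every class always carries a complete set of
#' level labels.
#'
#' @param x character vector of class numbers (any accepted dialect).
#' @return tibble with columns `level2`, `level3`, `level4`.
#' @export
#' @examples
#' derive_class_levels("08:12.06.04")
#' derive_class_levels("24:06") # all three levels "24:06"
derive_class_levels <- function(x) {
  canon <- canonical_class_num(x)
  lv <- lapply(canon, function(num) {
    groups <- strsplit(num, "[:.]")[[1]]
    k <- length(groups)
    vapply(2:4, function(d) format_class_groups(groups[seq_len(min(d, k))]),
      character(1))
  })
  tibble(
    level2 = vapply(lv, `[`, character(1), 1L),
    level3 = vapply(lv, `[`, character(1), 2L),
    level4 = vapply(lv, `[`, character(1), 3L)
  )
}

new_refset <- function(generics, tradenames, scdf, classes,
                       classes_extended = NULL) {
  require_columns(generics, c("UN", "GenDrugName", "AHFSClassID"), "generics")
  require_columns(tradenames, c("UN", "Tradename", "GenDrugName"), "tradenames")
  require_columns(scdf, c("SCDF_STR", "SCDF_CUI", "AHFSClassNum"), "scdf")
  require_columns(classes, c("AHFSClassID", "AHFSClassNum", "AHFSClassText"),
    "classes")

  if (any(!nzchar(generics$GenDrugName))) {
    abort_rx("generics: GenDrugName must be non-empty", "rxh_schema_error")
  }
  if (anyDuplicated(generics$UN)) {
    abort_rx("generics: UN must be unique", "rxh_schema_error")
  }

  generics <- mutate(as_tibble(generics),
    name_norm = normalize_text(.data$GenDrugName))
  tradenames <- mutate(as_tibble(tradenames),
    name_norm = normalize_text(.data$Tradename),
    gen_norm = normalize_text(.data$GenDrugName))
  classes <- mutate(as_tibble(classes),
    AHFSClassNum = canonical_class_num(.data$AHFSClassNum))
  scdf <- mutate(as_tibble(scdf),
    AHFSClassNum = canonical_class_num(.data$AHFSClassNum),
    scdf_norm = normalize_text(.data$SCDF_STR))

  dangling <- list(
    `generics.AHFSClassID` =
      setdiff(generics$AHFSClassID, classes$AHFSClassID),
    `tradenames.GenDrugName` =
      setdiff(tradenames$gen_norm, generics$name_norm),
    `scdf.AHFSClassNum` =
      setdiff(scdf$AHFSClassNum, classes$AHFSClassNum)
  )
  dangling <- dangling[lengths(dangling) > 0]
  if (length(dangling)) {
    msg <- paste(
      vapply(names(dangling), function(k) {
        sprintf("%s -> {%s}", k, paste(dangling[[k]], collapse = ", "))
      }, character(1)),
      collapse = "; "
    )
    abort_rx(paste("dangling foreign keys:", msg), "rxh_integrity_error")
  }

  if (is.null(classes_extended)) {
    classes_extended <- build_classes_extended(classes)
  } else {
    require_columns(classes_extended,
      c("AHFSClassNum", "AHFSClassText_2", "AHFSClassText_3", "AHFSClassText_4"),
      "classes_extended")
    classes_extended <- mutate(as_tibble(classes_extended),
      AHFSClassNum = canonical_class_num(.data$AHFSClassNum))
  }

  structure(
    list(
      generics = generics,
      tradenames = tradenames,
      scdf = scdf,
      classes = classes,
      classes_extended = classes_extended,
      counts = c(
        generics = nrow(generics), tradenames = nrow(tradenames),
        scdf = nrow(scdf), classes = nrow(classes),
        classes_extended = nrow(classes_extended)
      )
    ),
    class = "rxh_refset"
  )
}

# level texts are the class texts of the level-prefix numbers where those
# prefixes exist as rows of the class table; otherwise the leaf text.
build_classes_extended <- function(classes) {
  lv <- derive_class_levels(classes$AHFSClassNum)
  text_of <- stats::setNames(classes$AHFSClassText, classes$AHFSClassNum)
  lookup <- function(nums, fallback) {
    out <- unname(text_of[nums])
    ifelse(is.na(out), fallback, out)
  }
  tibble(
    AHFSClassNum = classes$AHFSClassNum,
    AHFSClassText_2 = lookup(lv$level2, classes$AHFSClassText),
    AHFSClassText_3 = lookup(lv$level3, classes$AHFSClassText),
    AHFSClassText_4 = lookup(lv$level4, classes$AHFSClassText)
  )
}

#' @export
print.rxh_refset <- function(x, ...) {
  cat("<rxh_refset>\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-16s %d rows\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

#' Load the relational reference tables
#'
#' Reads the five reference tables (generic drugs, trade names, clinical
#' drug forms, classes, extended class texts), canonicalizes class
#' numbers, and verifies every foreign key. The extended-class table is
#' derived from the class table when no file is supplied.
#'
#' @param paths named list/vector of file paths with elements `generics`,
#'   `tradenames`, `scdf`, `classes`, and optionally `classes_extended`.
#' @return an `rxh_refset` with verified referential closure and per-table
#'   row counts.
#' @export
load_reference_set <- function(paths) {
  paths <- as.list(paths)
  need <- c("generics", "tradenames", "scdf", "classes")
  missing <- setdiff(need, names(paths))
  if (length(missing)) {
    abort_rx(paste("load_reference_set: missing paths for",
      paste(missing, collapse = ", ")), "rxh_parameter_error")
  }
  ext <- if (!is.null(paths$classes_extended)) {
    read_table_auto(paths$classes_extended, what = "classes_extended")
  }
  new_refset(
    generics = read_table_auto(paths$generics, what = "generics"),
    tradenames = read_table_auto(paths$tradenames, what = "tradenames"),
    scdf = read_table_auto(paths$scdf, what = "scdf"),
    classes = read_table_auto(paths$classes, what = "classes"),
    classes_extended = ext
  )
}

#' Write a reference set to a directory of CSV files
#'
#' @param refset an `rxh_refset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named paths written.
#' @export
write_reference_set <- function(refset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    generics = file.path(dir, "generics.csv"),
    tradenames = file.path(dir, "tradenames.csv"),
    scdf = file.path(dir, "scdf.csv"),
    classes = file.path(dir, "classes.csv"),
    classes_extended = file.path(dir, "classes_extended.csv")
  )
  readr::write_csv(select(refset$generics, "UN", "GenDrugName", "AHFSClassID"),
    paths[["generics"]])
  readr::write_csv(select(refset$tradenames, "UN", "Tradename", "GenDrugName"),
    paths[["tradenames"]])
  readr::write_csv(select(refset$scdf, "SCDF_STR", "SCDF_CUI", "AHFSClassNum"),
    paths[["scdf"]])
  readr::write_csv(select(refset$classes, "AHFSClassID", "AHFSClassNum",
    "AHFSClassText"), paths[["classes"]])
  readr::write_csv(refset$classes_extended, paths[["classes_extended"]])
  invisible(paths)
}

#' Build the standardization lexicon from a reference set
#'
#' Maps every normalized generic and trade name to its canonical generic
#' name (the normalized monograph title). Brand names therefore resolve to
#' the same canonical as their generic, so a brand plus its own generic in
#' one entry is a single-candidate match, not an ambiguity.
#'
#' @param refset an `rxh_refset`.
#' @return tibble with columns `name_norm`, `canonical`, `kind`.
#' @export
build_lexicon <- function(refset) {
  gen <- tibble(
    name_norm = refset$generics$name_norm,
    canonical = refset$generics$name_norm,
    kind = "generic"
  )
  tr <- tibble(
    name_norm = refset$tradenames$name_norm,
    canonical = refset$tradenames$gen_norm,
    kind = "trade"
  )
  distinct(bind_rows(gen, tr), .data$name_norm, .data$canonical,
    .keep_all = TRUE)
}

#' Load an exclusion list of OTC drugs, vitamins, and supplements
#'
#' @param path one-column CSV/TSV with header `term`.
#' @return character vector of normalized exclusion terms.
#' @export
load_exclusions <- function(path) {
  df <- read_table_auto(path, required = "term", what = "exclusion list")
  unique(normalize_text(df$term))
}

#' Create a variant dictionary
#'
#' The reusable expert-curated dictionary maps normalized variant spellings
#' (brands, misspellings, abbreviations) to canonical generic names, with
#' per-entry provenance.
#'
#' @param variant,canonical character vectors (recycled provenance below).
#' @param source provenance tag per entry: `"seeded"` or
#'   `"expert-adjudicated"`.
#' @param date decision date per entry (ISO text).
#' @return tibble of class `rxh_dictionary`.
#' @export
new_dictionary <- function(variant = character(0), canonical = character(0),
                           source = "seeded", date = NA_character_) {
  d <- tibble(
    variant = normalize_text(variant),
    canonical = normalize_text(canonical),
    source = rep_len(as.character(source), length(variant)),
    date = rep_len(as.character(date), length(variant))
  )
  validate_dictionary(d)
}

validate_dictionary <- function(d) {
  dup <- unique(d$variant[duplicated(d$variant)])
  if (length(dup)) {
    conflicts <- dplyr::filter(d, .data$variant %in% dup)
    conflicts <- distinct(conflicts, .data$variant, .data$canonical)
    real <- conflicts$variant[duplicated(conflicts$variant)]
    if (length(real)) {
      bad <- dplyr::filter(conflicts, .data$variant %in% real)
      abort_rx(
        paste0("conflicting dictionary entries: ",
          paste(sprintf("%s -> %s", bad$variant, bad$canonical),
            collapse = "; ")),
        "rxh_conflict_error"
      )
    }
    d <- d[!duplicated(d$variant), , drop = FALSE]
  }
  class(d) <- c("rxh_dictionary", class(d))
  d
}

#' Save / load the variant dictionary
#'
#' Two-column delimited text plus provenance columns; the round-trip is
#' lossless. Loading a file whose variants map to conflicting canonical
#' names raises a conflict error listing both mappings.
#'
#' @param dict an `rxh_dictionary`.
#' @param path CSV file path.
#' @return `save_dictionary` returns `path` invisibly; `load_dictionary`
#'   returns an `rxh_dictionary`.
#' @export
save_dictionary <- function(dict, path) {
  readr::write_csv(as_tibble(dict)[, c("variant", "canonical", "source", "date")],
    path, na = "")
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  df <- read_table_auto(path,
    required = c("variant", "canonical", "source", "date"),
    what = "dictionary")
  df$date[is.na(df$date)] <- NA_character_
  validate_dictionary(as_tibble(df))
}
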