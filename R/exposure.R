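#' Long-format medication-class pairings
#'
#' One row per record per assigned class, joined from standardized
#' results and the classification map. Records whose canonical name has
#' no class assignment are routed to an `unclassified` side table, never
#' silently dropped.
#'
#' @param records tibble with `participant_id`, `visit_id`,
#'   `canonical_name` (one row per standardized medication record).
#' @param classmap assignment tibble (from [classify_all()]).
#' @return list with `long` (participant, visit, name, class, label rows in
#'   deterministic order) and `unclassified`.
#' @export
to_long <- function(records, classmap) {
  records <- as_tibble(records)
  require_columns(records, c("participant_id", "visit_id", "canonical_name"),
    "classified records")
  if (any(is.na(records$participant_id) | is.na(records$visit_id) |
          !nzchar(as.character(records$participant_id)) |
          !nzchar(as.character(records$visit_id)))) {
    abort_rx("records lacking participant/visit keys", "rxh_validation_error")
  }
  if (is.null(classmap) || nrow(classmap) == 0L) {
    return(list(long = tibble(
      participant_id = character(0), visit_id = character(0),
      canonical_name = character(0), ahfs_class_num = character(0),
      class_label = character(0)
    ), unclassified = records))
  }
  cm <- select(as_tibble(classmap), "canonical_name", "ahfs_class_num",
    class_label = "ahfs_class_text")
  cm <- distinct(cm)
  joined <- left_join(records, cm, by = "canonical_name",
    relationship = "many-to-many")
  unclassified <- dplyr::filter(joined, is.na(.data$ahfs_class_num))
  long <- dplyr::filter(joined, !is.na(.data$ahfs_class_num))
  long <- select(long, "participant_id", "visit_id", "canonical_name",
    "ahfs_class_num", "class_label")
  long <- arrange(long, .data$participant_id, .data$visit_id,
    .data$canonical_name, .data$ahfs_class_num)
  list(long = long,
    unclassified = select(unclassified, dplyr::all_of(names(records))))
}

resolve_merge_map <- function(class_nums, merge_map) {
  if (is.null(merge_map) || nrow(merge_map) == 0L) return(class_nums)
  merge_map <- as_tibble(merge_map)
  require_columns(merge_map, c("from_num", "to_num"), "merge map")
  from <- canonical_class_num(merge_map$from_num)
  to <- canonical_class_num(merge_map$to_num)
  # transitive closure with cycle detection
  resolve <- function(x) {
    seen <- character(0)
    while (x %in% from) {
      if (x %in% seen) {
        abort_rx(sprintf("merge-map cycle involving %s", x),
          "rxh_config_error")
      }
      seen <- c(seen, x)
      x <- to[match(x, from)]
    }
    x
  }
  vapply(class_nums, resolve, character(1), USE.NAMES = FALSE)
}

class_column_label <- function(num, text) {
  txt <- gsub("[^A-Za-z0-9]+", "_", text)
  txt <- gsub("^_+|_+$", "", txt)
  paste0(num, "|", txt)
}

#' Wide participant-by-visit binary exposure matrix
#'
#' One row per distinct (participant, visit); one 0/1 column per
#' therapeutic class after merge-map application and optional roll-up to a
#' shallower hierarchy level. A cell is 1 iff at least one long row
#' witnesses that participant-visit-class. Visits with no eligible
#' medications appear as all-zero rows only when a visit roster is
#' supplied (absence of a row cannot otherwise be told from no data).
#'
#' @param long long rows from [to_long()].
#' @param class_universe optional character vector of class numbers the
#'   columns must cover (post-merge, post-roll-up); defaults to the
#'   classes present in the data.
#' @param merge_map optional tibble (`from_num`, `to_num`) consolidating
#'   pharmacologically similar classes; cycles are a configuration error.
#' @param roster optional tibble (`participant_id`, `visit_id`) of
#'   enrolled visits to materialize as all-zero rows.
#' @param level column granularity: 4 (default, full depth), 3, or 2.
#' @return tibble with key columns `participant_id`, `visit_id`, then one
#'   integer 0/1 column per class (named `num|label`).
#' @export
to_wide <- function(long, class_universe = NULL, merge_map = NULL,
                    roster = NULL, level = 4) {
  long <- as_tibble(long)
  nums <- resolve_merge_map(long$ahfs_class_num, merge_map)
  if (level %in% c(2, 3)) {
    lv <- derive_class_levels(nums)
    nums <- lv[[paste0("level", level)]]
  } else if (level != 4) {
    abort_rx("level must be 2, 3, or 4", "rxh_parameter_error")
  }
  long$class_key <- nums

  universe <- if (is.null(class_universe)) {
    sort(unique(nums))
  } else {
    extra <- setdiff(nums, class_universe)
    if (length(extra)) {
      abort_rx(paste("classes outside the declared universe:",
        paste(extra, collapse = ", ")), "rxh_parameter_error")
    }
    sort(unique(class_universe))
  }

  keys <- distinct(long, .data$participant_id, .data$visit_id)
  if (!is.null(roster)) {
    roster <- distinct(as_tibble(roster), .data$participant_id, .data$visit_id)
    keys <- distinct(bind_rows(keys, roster))
  }
  keys <- arrange(keys, .data$participant_id, .data$visit_id)

  label_of <- stats::setNames(long$class_label, long$class_key)
  cols <- vapply(universe, function(cn) {
    lab <- unname(label_of[cn])
    if (is.na(lab)) cn else class_column_label(cn, lab)
  }, character(1))

  mat <- matrix(0L, nrow = nrow(keys), ncol = length(universe),
    dimnames = list(NULL, cols))
  if (nrow(long)) {
    ri <- match(paste(long$participant_id, long$visit_id),
      paste(keys$participant_id, keys$visit_id))
    ci <- match(long$class_key, universe)
    mat[cbind(ri, ci)] <- 1L
  }
  bind_cols(keys, as_tibble(mat))
}

#' Summaries of an exposure matrix
#'
#' @param wide exposure matrix from [to_wide()].
#' @return list with `prevalence` (per-class column means) and
#'   `polypharmacy` (per-visit count of exposed classes, a class-level
#'   polypharmacy proxy).
#' @export
summarize_exposure <- function(wide) {
  wide <- as_tibble(wide)
  class_cols <- setdiff(names(wide), c("participant_id", "visit_id"))
  m <- as.matrix(wide[, class_cols, drop = FALSE])
  list(
    prevalence = tibble(
      class = class_cols,
      prevalence = if (nrow(m)) unname(colMeans(m)) else rep(0, ncol(m))
    ),
    polypharmacy = bind_cols(
      wide[, c("participant_id", "visit_id")],
      tibble(n_classes = if (ncol(m)) unname(rowSums(m)) else rep(0, nrow(wide)))
    )
  )
}
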