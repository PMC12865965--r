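#' Round half away from zero
#'
#' Base `round()` uses round-half-to-even; stage-accounting percentages are
#' conventionally rounded half-up (84.45 -> 84.5), so reports use this.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(84.45, 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

abort_rx <- function(message, class, ...) {
  abort(message, class = c(class, "rxh_error"), ...)
}

#' Sniff the field delimiter of a delimited text file
#'
#' Tables are accepted as comma- or tab-separated with a header row; the
#' delimiter is inferred from the header line.
#'
#' @param path file path.
#' @return `","` or `"\t"`.
#' @keywords internal
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (length(n_tab) && n_tab > n_com) "\t" else ","
}

read_table_auto <- function(path, required = NULL, what = basename(path)) {
  if (!file.exists(path)) {
    abort_rx(sprintf("file not found: %s", path), "rxh_io_error")
  }
  df <- readr::read_delim(
    path,
    delim = sniff_delim(path),
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE,
    progress = FALSE
  )
  if (!is.null(required)) require_columns(df, required, what)
  df
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_rx(
      sprintf(
        "%s: missing required column%s: %s",
        what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      "rxh_schema_error"
    )
  }
  invisible(df)
}

iso_timestamp <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z", tz = "UTC")
}
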