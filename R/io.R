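person_record_cols <- function() {
  c(person_id = "i", village_id = "i", income = "d", afi = "d", age = "i",
    gender = "i", marital = "i", work = "i", education = "i", insurance = "i",
    metotal = "d", water = "i", num_child = "i", neighbors = "i",
    strangers = "i", interperson = "i", psychological_capital = "i",
    srh_raw = "i", cesd = "i", padl = "i")
}

#' Write and read a person-level population table
#'
#' Comma-separated UTF-8 text with a header row holding the person-record
#' schema of [generate_population()]. Missing PADL (not interviewed, age at
#' or below the cutoff) is written as an empty cell and read back as `NA`,
#' never as 0. `read_population()` errors on a missing mandatory column
#' (naming it) and warns about unknown extra columns, which are kept.
#'
#' @param records Data frame of person records.
#' @param path File path.
#' @return `write_population()` returns `records` invisibly;
#'   `read_population()` returns a tibble.
#' @examples
#' pop <- generate_population(sim_config(n_villages = 2, residents_per_village = 3))
#' f <- tempfile(fileext = ".csv")
#' write_population(pop, f)
#' identical(read_population(f), pop)
#' @export
write_population <- function(records, path) {
  if (!is.data.frame(records)) abort("`records` must be a data frame.")
  missing_cols <- setdiff(names(person_record_cols()), names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("`records` lacks mandatory column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  readr::write_csv(records, path, na = "")
  invisible(records)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  schema <- person_record_cols()
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  missing_cols <- setdiff(names(schema), hdr)
  if (length(missing_cols) > 0) {
    abort(paste0("Input lacks mandatory column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  extra <- setdiff(hdr, names(schema))
  if (length(extra) > 0) {
    warn(paste0("Unknown column(s) kept as-is: ", paste(extra, collapse = ", "), "."))
  }
  spec <- paste(vapply(hdr, function(h) {
    if (h %in% names(schema)) schema[[h]] else "?"
  }, ""), collapse = "")
  out <- readr::read_csv(path, col_types = spec, na = c("", "NA"),
                         show_col_types = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(paste0("Malformed values in ", path, " (first at row ",
                 probs$row[1], ", column ", probs$col[1], ")."))
  }
  out
}
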