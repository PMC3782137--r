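#' Default scientific-name alias table
#'
#' Orthographic variants observed in the packaged liver-disorder survey and
#' resolved to a single canonical spelling at load time. Without aliasing,
#' spelling variants of the same binomial inflate distinct-species counts
#' (and deflate fidelity levels, whose denominator pools a species' records
#' across all disorders).
#'
#' @return A tibble with columns `raw` and `canonical`.
#' @examples
#' default_name_aliases()
#' @export
default_name_aliases <- function() {
  tibble(
    raw = c(
      "Scolopendra subspinipes mutilan L. Koch",
      "Capsella bursapastoris (L.) L.W.Medicus"
    ),
    canonical = c(
      "Scolopendra subspinipes mutilans L. Koch",
      "Capsella bursapastoris (L.) L. W. Medicus"
    )
  )
}

#' Normalize a scientific name
#'
#' Collapses runs of whitespace, trims leading/trailing spaces, and applies
#' an alias mapping of known orthographic variants. The operation is
#' idempotent: normalizing an already-canonical name returns it unchanged.
#'
#' @param raw Character vector of raw scientific-name strings (non-empty).
#' @param aliases Alias table as returned by [default_name_aliases()], or
#'   `NULL` for whitespace normalization only.
#' @return Character vector of canonical names.
#' @examples
#' normalize_name("Artemisia princeps  Pamp.")
#' normalize_name("Scolopendra subspinipes mutilan L. Koch")
#' @export
normalize_name <- function(raw, aliases = default_name_aliases()) {
  if (any(is.na(raw)) || any(!nzchar(trimws(raw)))) {
    eq_abort("scientific names must be non-empty strings",
             "ethnoquant_validation_error")
  }
  out <- squish(raw)
  if (!is.null(aliases) && nrow(aliases) > 0) {
    idx <- match(out, squish(aliases$raw))
    hit <- !is.na(idx)
    out[hit] <- aliases$canonical[idx[hit]]
  }
  out
}

survey_columns <- c("disorder", "scientific_name", "local_name", "mentions",
                    "kind", "used_parts", "preparations", "application",
                    "fl_printed")

allowed_kinds <- c("plant", "animal", "fungus")

new_survey_tbl <- function(df, aliases) {
  out <- as_tibble(df)
  class(out) <- c("survey_tbl", class(as_tibble(out)))
  attr(out, "name_aliases") <- aliases
  out
}

split_labels <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) character(0) else trimws(strsplit(s, ",")[[1]])
  })
}

#' Validate and construct a use-report survey table
#'
#' Takes a plain data frame of disorder-by-species use reports, normalizes
#' scientific names, canonicalizes disorder spellings (case-insensitively,
#' against the seven liver-disorder categories where they match), coerces
#' the set-valued columns (`used_parts`, `preparations`) to list columns,
#' and enforces the data model:
#' \itemize{
#'   \item `mentions` is a positive integer (one informant use report each),
#'   \item `kind` is one of `"plant"`, `"animal"`, `"fungus"`,
#'   \item `used_parts` and `preparations` are non-empty sets of non-empty
#'     labels,
#'   \item `application` is `"oral"` or `"topical"`,
#'   \item `(disorder, scientific_name)` pairs are unique after name
#'     normalization.
#' }
#' Violations raise a condition of class `ethnoquant_validation_error`
#' naming the offending rows.
#'
#' @param df Data frame with columns `disorder`, `scientific_name`,
#'   `mentions`, `kind`, `used_parts`, `preparations`, `application`, and
#'   optionally `local_name` and `fl_printed`. `used_parts` and
#'   `preparations` may be comma-separated strings or list columns.
#' @param aliases Alias table applied by [normalize_name()].
#' @return A validated `survey_tbl` tibble.
#' @seealso [read_survey()], [liver_survey()]
#' @export
as_survey <- function(df, aliases = default_name_aliases()) {
  required <- setdiff(survey_columns, c("local_name", "fl_printed"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    eq_abort(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      "ethnoquant_schema_error"
    )
  }
  df <- as_tibble(df)
  if (!"local_name" %in% names(df)) df$local_name <- NA_character_
  if (!"fl_printed" %in% names(df)) df$fl_printed <- NA_real_

  n <- nrow(df)
  if (n == 0) {
    out <- tibble(
      disorder = character(0), scientific_name = character(0),
      local_name = character(0), mentions = integer(0), kind = character(0),
      used_parts = list(), preparations = list(),
      application = character(0), fl_printed = numeric(0)
    )
    return(new_survey_tbl(out, aliases))
  }

  bad_rows <- function(cond, what) {
    if (any(cond)) {
      eq_abort(
        paste0(what, " (row ", paste(which(cond), collapse = ", "), ")"),
        "ethnoquant_validation_error"
      )
    }
  }

  mention_num <- suppressWarnings(as.numeric(df$mentions))
  bad_rows(is.na(mention_num) | mention_num < 1 | mention_num != floor(mention_num),
           "mentions must be a positive integer")
  df$mentions <- as.integer(mention_num)

  df$kind <- tolower(trimws(as.character(df$kind)))
  bad_rows(!df$kind %in% allowed_kinds,
           paste0("kind must be one of ", paste(allowed_kinds, collapse = ", ")))

  df$application <- tolower(trimws(as.character(df$application)))
  bad_rows(!df$application %in% c("oral", "topical"),
           "application must be 'oral' or 'topical'")

  if (!is.list(df$used_parts)) df$used_parts <- split_labels(df$used_parts)
  if (!is.list(df$preparations)) df$preparations <- split_labels(df$preparations)
  set_ok <- function(col) {
    vapply(col, function(s) length(s) > 0 && all(nzchar(s)), logical(1))
  }
  bad_rows(!set_ok(df$used_parts), "used_parts must be a non-empty set of labels")
  bad_rows(!set_ok(df$preparations), "preparations must be a non-empty set of labels")

  bad_rows(is.na(df$disorder) | !nzchar(trimws(df$disorder)),
           "disorder must be non-empty")
  df$disorder <- canonicalize_disorder(df$disorder)
  df$scientific_name <- normalize_name(df$scientific_name, aliases)
  df$local_name <- as.character(df$local_name)
  df$fl_printed <- suppressWarnings(as.numeric(df$fl_printed))

  key <- paste(df$disorder, df$scientific_name, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    bad_rows(duplicated(key),
             "duplicate (disorder, scientific_name) pair after normalization")
  }

  new_survey_tbl(df[, survey_columns], aliases)
}

#' Read a use-report survey from CSV or TSV
#'
#' Parses a delimited file with header columns `disorder`,
#' `scientific_name`, `local_name`, `mentions`, `kind`, `used_parts`,
#' `preparations`, `application`, `fl_printed` (the last two of
#' `local_name`/`fl_printed` optional), then validates it with
#' [as_survey()]. Set-valued fields are comma-separated inside a quoted
#' field, matching the convention of printed survey tables.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by file extension), `"csv"`, or `"tsv"`.
#' @param aliases Alias table applied to scientific names.
#' @return A validated `survey_tbl`.
#' @examples
#' surv <- liver_survey()
#' nrow(surv)            # 121 records
#' total_mentions(surv)  # 1514 use reports
#' @export
read_survey <- function(path, format = c("auto", "csv", "tsv"),
                        aliases = default_name_aliases()) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    eq_abort(paste0("file not found: ", path), "ethnoquant_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  df <- reader(path, col_types = readr::cols(.default = readr::col_character()),
               progress = FALSE)
  as_survey(df, aliases)
}

#' Write a survey table to CSV or TSV
#'
#' Serializes the set-valued columns comma-separated inside a quoted field,
#' so that [read_survey()] on the output reproduces the table
#' record-for-record (round-trip identity).
#'
#' @param table A `survey_tbl`.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"`, or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_survey <- function(table, path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  flat <- as_tibble(as.data.frame(lapply(table[survey_columns], function(col) {
    if (is.list(col)) vapply(col, paste, character(1), collapse = ", ") else col
  }), stringsAsFactors = FALSE, check.names = FALSE))
  writer <- if (format == "tsv") readr::write_tsv else readr::write_csv
  ok <- tryCatch({ writer(flat, path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) {
    eq_abort(paste0("cannot write to ", path, ": ", conditionMessage(ok)),
             "ethnoquant_io_error")
  }
  invisible(path)
}

#' The packaged liver-disorder survey
#'
#' Loads the full transcription of a published ethnomedicinal survey of
#' liver-disorder treatments in southern Korea: 121 disorder-by-species
#' records over seven ailment categories (fatigue recovery, hangover,
#' hepatitis, jaundice, liver cancer, liver cirrhosis, liver-related
#' ailments), 1,514 informant use reports, and 94 medicinal species
#' (57 plants, 34 animals, 3 fungi). The `fl_printed` column retains the
#' fidelity levels as printed in the source table for auditing with
#' [audit_printed_fl()]; it is never used in computation.
#'
#' @return A validated `survey_tbl` with 121 rows.
#' @export
liver_survey <- function() {
  path <- system.file("extdata", "liver_survey_table.csv",
                      package = "ethnoquant", mustWork = TRUE)
  read_survey(path, format = "csv")
}

#' Total number of use reports in a survey
#'
#' @param table A `survey_tbl`.
#' @return Integer sum of the `mentions` column.
#' @export
total_mentions <- function(table) {
  sum(table$mentions)
}

#' @exportS3Method generics::glance
glance.survey_tbl <- function(x, ...) {
  tibble(
    n_records = nrow(x),
    n_disorders = dplyr::n_distinct(x$disorder),
    n_species = dplyr::n_distinct(x$scientific_name),
    total_mentions = total_mentions(x)
  )
}

#' @export
print.survey_tbl <- function(x, ...) {
  cat("# Use-report survey: ", nrow(x), " records, ",
      dplyr::n_distinct(x$disorder), " disorders, ",
      dplyr::n_distinct(x$scientific_name), " species, ",
      total_mentions(x), " use reports\n", sep = "")
  NextMethod()
}
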