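#' Summary tabulations of a use-report survey
#'
#' Reproduces the descriptive tabulations customary in ethnomedicinal survey
#' reports: distinct species counts by kind, each disorder's species count
#' and its share of all species, the most-mentioned species, and the
#' used-part / preparation label inventories per kind.
#'
#' @param table A validated `survey_tbl`.
#' @param top_k How many top-mentioned species to rank (default 3).
#' @return An object of class `survey_summary`: a list with elements
#'   `species_by_kind`, `disorder_species_share` (percentages displayed
#'   half-away-from-zero to 1 decimal), `top_mentioned`, `part_inventory`,
#'   `preparation_inventory`, and `totals`.
#' @examples
#' summarize_survey(liver_survey())
#' @export
summarize_survey <- function(table, top_k = 3) {
  table <- strip_survey(table)
  species <- distinct(table, .data$scientific_name, .data$kind)
  total_sp <- nrow(species)

  species_by_kind <- species |>
    count(kind = .data$kind, name = "n_species") |>
    arrange(desc(.data$n_species), .data$kind)

  disorder_species_share <- table |>
    group_by(disorder = .data$disorder) |>
    summarise(n_species = dplyr::n_distinct(.data$scientific_name),
              .groups = "drop") |>
    mutate(
      pct_species = .data$n_species * 100 / .env$total_sp,
      pct_display = ratio_display(.data$n_species * 100, .env$total_sp, 1)
    ) |>
    arrange(desc(.data$n_species), .data$disorder)

  inventory <- function(col) {
    tibble(kind = rep(table$kind, lengths(table[[col]])),
           label = tolower(unlist(table[[col]]))) |>
      distinct() |>
      count(kind = .data$kind, name = "n_labels") |>
      arrange(.data$kind)
  }

  out <- list(
    species_by_kind = species_by_kind,
    disorder_species_share = disorder_species_share,
    top_mentioned = top_k_by_mentions(table, k = top_k),
    part_inventory = inventory("used_parts"),
    preparation_inventory = inventory("preparations"),
    totals = tibble(
      n_records = nrow(table),
      n_species = total_sp,
      n_disorders = dplyr::n_distinct(table$disorder),
      total_mentions = total_mentions(table)
    )
  )
  class(out) <- "survey_summary"
  out
}

#' Share of all use reports contributed by a set of species
#'
#' Sums the mentions of the named species across all disorders and divides
#' by the survey's total use reports.
#'
#' @param table A validated `survey_tbl`.
#' @param species Character vector of canonical scientific names; every name
#'   must occur in the table.
#' @return A one-row tibble with columns `n_species`, `mentions`,
#'   `total_mentions`, `share` (exact percentage) and `share_display`
#'   (half-away-from-zero, 2 decimals).
#' @examples
#' mention_share(liver_survey(), c(
#'   "Artemisia capillaris Thunb.", "Taraxacum platycarpum Dahlst.",
#'   "Hovenia dulcis Thunb."
#' ))  # share_display 50.99
#' @export
mention_share <- function(table, species) {
  unknown <- setdiff(species, table$scientific_name)
  if (length(unknown) > 0) {
    eq_abort(paste0("species not found in table: ",
                    paste(unknown, collapse = "; ")),
             "ethnoquant_lookup_error")
  }
  num <- sum(table$mentions[table$scientific_name %in% species])
  den <- total_mentions(table)
  tibble(
    n_species = length(unique(species)),
    mentions = num,
    total_mentions = den,
    share = num * 100 / den,
    share_display = ratio_display(num * 100, den, 2)
  )
}

#' Rank species by total mentions
#'
#' @param table A validated `survey_tbl`.
#' @param k Number of species to return (all, if fewer are available).
#' @param kind Optional filter: `"plant"`, `"animal"` or `"fungus"`.
#' @return A tibble with columns `scientific_name`, `kind`,
#'   `total_mentions`, sorted by mentions descending with ties broken by
#'   name ascending.
#' @examples
#' top_k_by_mentions(liver_survey(), k = 3, kind = "plant")
#' @export
top_k_by_mentions <- function(table, k = 3, kind = NULL) {
  stopifnot(k >= 1)
  df <- strip_survey(table)
  if (!is.null(kind)) {
    if (!kind %in% allowed_kinds) {
      eq_abort(paste0("unknown kind: ", kind), "ethnoquant_usage_error")
    }
    df <- filter(df, .data$kind == !!kind)
  }
  df |>
    group_by(scientific_name = .data$scientific_name, kind = .data$kind) |>
    summarise(total_mentions = sum(.data$mentions), .groups = "drop") |>
    arrange(desc(.data$total_mentions), .data$scientific_name) |>
    head(k)
}

#' @export
print.survey_summary <- function(x, ...) {
  t <- x$totals
  cat("# Survey summary: ", t$n_records, " records, ", t$n_species,
      " species, ", t$n_disorders, " disorders, ", t$total_mentions,
      " use reports\n", sep = "")
  cat("## Species by kind\n"); print(x$species_by_kind)
  cat("## Species per disorder\n"); print(x$disorder_species_share)
  cat("## Most mentioned\n"); print(x$top_mentioned)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.survey_summary <- function(x, ...) {
  x$disorder_species_share
}

#' @exportS3Method generics::glance
glance.survey_summary <- function(x, ...) {
  x$totals
}
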