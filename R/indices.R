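#' Informant consensus factor per ailment category
#'
#' For each disorder, the informant consensus factor is
#' \deqn{ICF = (n_{ur} - n_t) / (n_{ur} - 1)}
#' where \eqn{n_{ur}} is the number of use reports for the disorder (the sum
#' of the `mentions` column over its records) and \eqn{n_t} is the number of
#' distinct species recorded for it. ICF is 1 when all informants agree on a
#' single species, 0 when every report cites a different species, and is
#' undefined (returned as `NA`) when \eqn{n_{ur} \le 1}, where the formula
#' divides by zero.
#'
#' @param table A validated `survey_tbl`.
#' @return A tibble of class `icf_tbl` with one row per disorder and columns
#'   `disorder`, `n_ur`, `n_t`, `icf` (exact value, `NA` when undefined) and
#'   `icf_display` (rounded half-away-from-zero to 2 decimals).
#' @examples
#' compute_icf(liver_survey())
#' @export
compute_icf <- function(table) {
  out <- strip_survey(table) |>
    group_by(disorder = .data$disorder) |>
    summarise(
      n_ur = sum(.data$mentions),
      n_t = dplyr::n_distinct(.data$scientific_name),
      .groups = "drop"
    ) |>
    mutate(
      icf = ifelse(.data$n_ur > 1,
                   (.data$n_ur - .data$n_t) / (.data$n_ur - 1), NA_real_),
      icf_display = ifelse(.data$n_ur > 1,
                           ratio_display(.data$n_ur - .data$n_t,
                                         pmax(.data$n_ur - 1, 1), 2),
                           NA_real_)
    ) |>
    arrange(desc(.data$icf), .data$disorder)
  class(out) <- c("icf_tbl", class(out))
  out
}

#' Fidelity level per species-disorder record
#'
#' For each record, the fidelity level is
#' \deqn{FL(\%) = N_p \times 100 / N}
#' where \eqn{N_p} is the number of informants citing the species for this
#' particular disorder (the record's `mentions`) and \eqn{N} is the total
#' number of informants citing the species for any disorder (its mentions
#' summed across the whole table). FL is 100\% exactly when a species is
#' recorded for a single disorder.
#'
#' @param table A validated `survey_tbl`.
#' @return A tibble of class `fl_tbl` with one row per record and columns
#'   `scientific_name`, `kind`, `disorder`, `n_p`, `n_total`, `fl` (exact)
#'   and `fl_display` (rounded half-away-from-zero to 1 decimal).
#' @examples
#' fl <- compute_fl(liver_survey())
#' fl[fl$scientific_name == "Oenanthe javanica (Blume) DC.", ]
#' @export
compute_fl <- function(table) {
  out <- strip_survey(table) |>
    group_by(scientific_name = .data$scientific_name) |>
    mutate(n_total = sum(.data$mentions)) |>
    ungroup() |>
    mutate(
      n_p = .data$mentions,
      fl = .data$n_p * 100 / .data$n_total,
      fl_display = ratio_display(.data$n_p * 100, .data$n_total, 1)
    ) |>
    select("scientific_name", "kind", "disorder", "n_p", "n_total",
           "fl", "fl_display")
  class(out) <- c("fl_tbl", class(out))
  out
}

#' Census of species at 100\% fidelity, per disorder
#'
#' Counts, for each disorder, the species whose fidelity level for that
#' disorder is exactly 100\%. Equality is tested on the integer counts
#' (\eqn{N_p = N}), never on the rounded display value, so a species like
#' one cited twice for each of two disorders (exact FL 50) can never be
#' misclassified by rounding.
#'
#' @param fidelities An `fl_tbl` from [compute_fl()].
#' @return A tibble with columns `disorder` and `n_fl100`, ordered by count
#'   descending. Attributes `n_fl100_total` (sum of the counts) and
#'   `n_species_total` (distinct species in the input) carry the overall
#'   totals.
#' @examples
#' fl_100_census(compute_fl(liver_survey()))
#' @export
fl_100_census <- function(fidelities) {
  out <- fidelities |>
    filter(.data$n_p == .data$n_total) |>
    count(disorder = .data$disorder, name = "n_fl100") |>
    arrange(desc(.data$n_fl100), .data$disorder)
  attr(out, "n_fl100_total") <- sum(out$n_fl100)
  attr(out, "n_species_total") <- dplyr::n_distinct(fidelities$scientific_name)
  out
}

#' Audit printed fidelity levels against recomputed values
#'
#' Compares the `fl_printed` column carried along from the source table with
#' the fidelity level recomputed from the mention counts, and flags records
#' whose absolute difference from the recomputed display value exceeds
#' `tolerance`. This is the package's quality-control pass over transcribed
#' tables: printed FLs are stored for audit only and never enter any
#' computation.
#'
#' On the packaged liver-disorder survey the audit flags exactly the two
#' Plantago asiatica records: printed 100.0 for both hepatitis and jaundice,
#' which is arithmetically impossible for a species recorded for two
#' disorders (the recomputed value is 50.0 for each).
#'
#' @param table A validated `survey_tbl` with an `fl_printed` column.
#' @param fidelities An `fl_tbl`; recomputed from `table` if omitted.
#' @param tolerance Maximum allowed discrepancy in percentage points
#'   (default 0.05, i.e. agreement at the printed 1-decimal precision).
#' @return A tibble of discrepancies with columns `disorder`,
#'   `scientific_name`, `fl_printed`, `fl_recomputed`, `difference`.
#' @examples
#' audit_printed_fl(liver_survey())
#' @export
audit_printed_fl <- function(table, fidelities = compute_fl(table),
                             tolerance = 0.05) {
  audited <- strip_survey(table) |>
    select("disorder", "scientific_name", "fl_printed") |>
    filter(!is.na(.data$fl_printed)) |>
    left_join(
      select(fidelities, "disorder", "scientific_name",
             fl_recomputed = "fl_display"),
      by = c("disorder", "scientific_name")
    ) |>
    mutate(difference = .data$fl_printed - .data$fl_recomputed) |>
    filter(abs(.data$difference) > tolerance)
  as_tibble(audited)
}

#' @exportS3Method generics::glance
glance.icf_tbl <- function(x, ...) {
  defined <- x[!is.na(x$icf), ]
  tibble(
    n_disorders = nrow(x),
    n_defined = nrow(defined),
    icf_min = if (nrow(defined)) min(defined$icf) else NA_real_,
    icf_max = if (nrow(defined)) max(defined$icf) else NA_real_
  )
}

#' @exportS3Method generics::glance
glance.fl_tbl <- function(x, ...) {
  tibble(
    n_records = nrow(x),
    n_species = dplyr::n_distinct(x$scientific_name),
    n_fl100 = sum(x$n_p == x$n_total),
    fl_min = if (nrow(x)) min(x$fl) else NA_real_
  )
}
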