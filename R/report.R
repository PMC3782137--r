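#' Full analysis bundle for a survey
#'
#' Runs the whole pipeline -- validation, informant consensus factors,
#' fidelity levels, the FL = 100\% census, the printed-FL audit, the
#' bipartite network queries, and the summary tabulations -- and collects
#' the results in a single versioned list, suitable for serialization to
#' JSON with [write_report()]. Blocks follow the customary ordering of a
#' survey results section: tabulations, consensus, fidelity, network.
#'
#' @param table A validated `survey_tbl`.
#' @return A list of class `survey_report` with elements `schema_version`,
#'   `summary`, `icf`, `fl`, `fl100_census`, `audit`, `network`.
#' @examples
#' rep <- run_report(liver_survey())
#' rep$icf
#' @export
run_report <- function(table) {
  icf <- compute_icf(table)
  fl <- compute_fl(table)
  net <- build_network(table)
  smry <- summarize_survey(table)
  census <- fl_100_census(fl)
  structure(list(
    schema_version = "1.0",
    summary = list(
      totals = smry$totals,
      species_by_kind = smry$species_by_kind,
      disorder_species_share = smry$disorder_species_share,
      top_mentioned = smry$top_mentioned,
      part_inventory = smry$part_inventory,
      preparation_inventory = smry$preparation_inventory
    ),
    icf = as_tibble(icf),
    fl = as_tibble(fl),
    fl100_census = list(
      per_disorder = as_tibble(census),
      n_fl100_total = attr(census, "n_fl100_total"),
      n_species_total = attr(census, "n_species_total")
    ),
    audit = audit_printed_fl(table, fl),
    network = list(
      size = glance(net),
      species_degree = species_degree(net),
      kind_composition = disorder_kind_composition(net) |>
        mutate(exceptions = lapply(.data$exceptions, as.character))
    )
  ), class = "survey_report")
}

#' Write an analysis bundle to JSON
#'
#' @param report A `survey_report` from [run_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(path)
}
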