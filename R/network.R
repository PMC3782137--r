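#' Build the two-mode disorder-species network
#'
#' Constructs the bipartite "internetwork" of ailment categories and
#' medicinal species: one node per disorder, one node per canonical species
#' (carrying its kind -- plant, animal or fungus -- as a vertex attribute),
#' and one edge per survey record, weighted by the record's mention count.
#' Edges connect disorders to species only, so the graph is two-mode by
#' construction; species strength (sum of incident edge weights) equals the
#' species' total mentions across the survey.
#'
#' @param table A validated `survey_tbl`.
#' @return An [igraph::igraph] object of class `ethno_network` with vertex
#'   attributes `name`, `mode` (`"disorder"`/`"species"`), `kind` (empty
#'   string on disorder nodes) and `type` (logical, `TRUE` for species), and
#'   edge attribute `weight`.
#' @examples
#' net <- build_network(liver_survey())
#' igraph::vcount(net)  # 101 = 94 species + 7 disorders
#' igraph::ecount(net)  # 121 records
#' @export
build_network <- function(table) {
  table <- strip_survey(table)
  disorders <- sort(unique(table$disorder))
  species <- table |>
    distinct(.data$scientific_name, .data$kind) |>
    arrange(.data$scientific_name)
  vertices <- bind_rows(
    tibble(name = disorders, mode = "disorder", kind = ""),
    tibble(name = species$scientific_name, mode = "species",
           kind = species$kind)
  )
  edges <- tibble(
    from = table$disorder,
    to = table$scientific_name,
    weight = table$mentions
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  igraph::V(g)$type <- igraph::V(g)$mode == "species"
  class(g) <- c("ethno_network", class(g))
  g
}

#' Species degree in the disorder-species network
#'
#' The (unweighted) degree of a species node is the number of distinct
#' disorders it treats. The returned ranking breaks ties by total mention
#' weight descending, then by name ascending.
#'
#' @param net An `ethno_network` from [build_network()].
#' @return A tibble with columns `scientific_name`, `kind`, `degree`
#'   (distinct disorders treated) and `strength` (total mentions), sorted by
#'   degree descending.
#' @examples
#' head(species_degree(build_network(liver_survey())))
#' @export
species_degree <- function(net) {
  sp <- igraph::V(net)[igraph::V(net)$type]
  tibble(
    scientific_name = sp$name,
    kind = sp$kind,
    degree = as.integer(igraph::degree(net, v = sp)),
    strength = as.numeric(igraph::strength(net, vids = sp))
  ) |>
    arrange(desc(.data$degree), desc(.data$strength), .data$scientific_name)
}

#' Kind composition of each disorder's species neighborhood
#'
#' For each disorder node, counts its neighboring species by kind and lists
#' the exceptions: neighbors whose kind differs from the disorder's modal
#' (most frequent) kind. This reconstructs statements of the form "only
#' animals were used for fatigue recovery" or "liver cirrhosis used animals
#' except for one plant and one fungus". Ties for the modal kind are broken
#' alphabetically.
#'
#' @param net An `ethno_network` from [build_network()].
#' @return A tibble with one row per disorder: columns `disorder`,
#'   `n_plant`, `n_animal`, `n_fungus`, `modal_kind`, and `exceptions`
#'   (list column of species names not of the modal kind).
#' @examples
#' disorder_kind_composition(build_network(liver_survey()))
#' @export
disorder_kind_composition <- function(net) {
  dis <- igraph::V(net)[!igraph::V(net)$type]
  rows <- lapply(dis$name, function(d) {
    nb <- igraph::neighbors(net, d)
    counts <- table(factor(nb$kind, levels = allowed_kinds))
    tied <- names(counts)[counts == max(counts)]
    modal <- sort(tied)[1]
    tibble(
      disorder = d,
      n_plant = as.integer(counts[["plant"]]),
      n_animal = as.integer(counts[["animal"]]),
      n_fungus = as.integer(counts[["fungus"]]),
      modal_kind = modal,
      exceptions = list(sort(nb$name[nb$kind != modal]))
    )
  })
  bind_rows(rows) |> arrange(.data$disorder)
}

#' One-mode projection of the bipartite network
#'
#' Projects the two-mode network onto one node class. Two species (or two
#' disorders) are connected when they share at least one neighbor in the
#' other class, and the edge weight counts the shared neighbors: in species
#' mode, the number of disorders treating both species.
#'
#' @param net An `ethno_network`.
#' @param mode `"species"` or `"disorder"`.
#' @return An undirected weighted [igraph::igraph] with no self-loops.
#' @examples
#' pd <- project_one_mode(build_network(liver_survey()), "disorder")
#' igraph::E(pd)$weight
#' @export
project_one_mode <- function(net, mode = c("species", "disorder")) {
  mode <- tryCatch(match.arg(mode), error = function(e) {
    eq_abort("mode must be 'species' or 'disorder'", "ethnoquant_usage_error")
  })
  proj <- igraph::bipartite_projection(net, multiplicity = TRUE)
  # proj1 = type FALSE (disorders), proj2 = type TRUE (species)
  if (mode == "species") proj$proj2 else proj$proj1
}

#' Export a graph to GraphML or edge-list format
#'
#' GraphML output preserves all node attributes (`mode`, `kind`, `type`) and
#' the edge `weight`; re-importing it with [import_graph()] reproduces the
#' node and edge sets. The edge list is a three-column tab-delimited text
#' file (`source`, `target`, `weight`) with a header.
#'
#' @param graph An `ethno_network` or one-mode projection.
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    eq_abort("format must be 'graphml' or 'edgelist'", "ethnoquant_usage_error")
  })
  if (format == "graphml") {
    g <- graph
    class(g) <- "igraph"
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    if (is.null(el$weight)) el$weight <- 1
    readr::write_tsv(el[, c("from", "to", "weight")], path)
  }
  invisible(path)
}

#' Re-import a GraphML file written by [export_graph()]
#'
#' @param path Path to a GraphML file.
#' @return An [igraph::igraph] with the stored attributes.
#' @export
import_graph <- function(path) {
  if (!file.exists(path)) {
    eq_abort(paste0("file not found: ", path), "ethnoquant_io_error")
  }
  igraph::read_graph(path, format = "graphml")
}

#' @exportS3Method generics::glance
glance.ethno_network <- function(x, ...) {
  tibble(
    n_disorders = sum(!igraph::V(x)$type),
    n_species = sum(igraph::V(x)$type),
    n_edges = igraph::ecount(x),
    total_weight = sum(igraph::E(x)$weight),
    bipartite = igraph::is_bipartite(x)
  )
}

#' @exportS3Method generics::tidy
tidy.ethno_network <- function(x, ...) {
  el <- igraph::as_data_frame(x, what = "edges")
  as_tibble(el) |>
    rename(disorder = "from", scientific_name = "to") |>
    arrange(.data$disorder, .data$scientific_name)
}
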