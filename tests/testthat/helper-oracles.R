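# Independent oracles. These recount everything from scratch from a
# materialized one-row-per-individual-report table, sharing no code with the
# package's grouped-summary implementations.

expand_reports <- function(table) {
  data.frame(
    disorder = rep(table$disorder, table$mentions),
    species = rep(table$scientific_name, table$mentions),
    stringsAsFactors = FALSE
  )
}

oracle_icf <- function(table) {
  reports <- expand_reports(table)
  out <- lapply(split(reports, reports$disorder), function(d) {
    n_ur <- nrow(d)
    n_t <- length(unique(d$species))
    data.frame(disorder = d$disorder[[1]], n_ur = n_ur, n_t = n_t,
               icf = if (n_ur > 1) (n_ur - n_t) / (n_ur - 1) else NA_real_)
  })
  do.call(rbind, unname(out))
}

oracle_fl <- function(table) {
  reports <- expand_reports(table)
  totals <- table(reports$species)
  pair <- stats::aggregate(list(n_p = rep(1, nrow(reports))),
                           by = reports[c("species", "disorder")], FUN = sum)
  pair$n_total <- as.integer(totals[pair$species])
  pair$fl <- pair$n_p * 100 / pair$n_total
  pair
}

# Shared-neighbor counts by brute-force pairwise intersection.
oracle_projection <- function(table, mode) {
  if (mode == "species") {
    nb <- split(table$disorder, table$scientific_name)
  } else {
    nb <- split(table$scientific_name, table$disorder)
  }
  nodes <- sort(names(nb))
  edges <- list()
  if (length(nodes) >= 2) {
    for (i in seq_len(length(nodes) - 1)) {
      for (j in seq(i + 1, length(nodes))) {
        w <- length(intersect(nb[[nodes[i]]], nb[[nodes[j]]]))
        if (w > 0) {
          edges[[length(edges) + 1]] <-
            data.frame(a = nodes[i], b = nodes[j], weight = w)
        }
      }
    }
  }
  if (length(edges) == 0) {
    return(data.frame(a = character(0), b = character(0), weight = integer(0)))
  }
  do.call(rbind, edges)
}

# Random small survey tables for property tests: <= 6 disorders,
# <= 20 species, species deliberately shared across disorders.
random_table <- function(n_disorders = sample(1:6, 1),
                         n_species = sample(2:20, 1)) {
  pool <- sprintf("Species testensis %02d", seq_len(n_species))
  kinds <- sample(c("plant", "animal", "fungus"), n_species, replace = TRUE)
  rows <- do.call(rbind, lapply(seq_len(n_disorders), function(d) {
    picked <- sample(n_species, sample(seq_len(n_species), 1))
    data.frame(
      disorder = sprintf("ailment %d", d),
      scientific_name = pool[picked],
      mentions = sample(1:15, length(picked), replace = TRUE),
      kind = kinds[picked],
      used_parts = "whole part",
      preparations = "decoction",
      application = "oral",
      stringsAsFactors = FALSE
    )
  }))
  as_survey(rows, aliases = NULL)
}

sorted_proj_df <- function(g) {
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el) == 0) {
    return(data.frame(a = character(0), b = character(0), weight = integer(0)))
  }
  el$a <- pmin(el$from, el$to)
  el$b <- pmax(el$from, el$to)
  el <- el[order(el$a, el$b), c("a", "b", "weight")]
  rownames(el) <- NULL
  el
}
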