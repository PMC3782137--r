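# Synthetic surveys. A multi-ailment survey is emulated by a
# Dirichlet-multinomial allocation: each disorder has an eligible species
# subset; informant reports are spread over that subset with symmetric
# Dirichlet weights whose concentration parameter is the single consensus
# knob (small concentration -> reports pile onto few species -> high ICF;
# large -> even spread -> low ICF).

part_vocabulary <- c("whole part", "leaf", "root", "stem", "fruit", "larva")
prep_vocabulary <- c("decoction", "infusion", "juice", "powder", "dried",
                     "simmer")

#' Configuration for a synthetic use-report survey
#'
#' @param n_disorders Number of ailment categories (positive integer).
#' @param species_pool Size of the species pool (positive integer), or an
#'   explicit character vector of species names.
#' @param reports_per_disorder Target number of use reports per disorder
#'   (the realized \eqn{n_{ur}}).
#' @param concentration Symmetric Dirichlet concentration governing how
#'   reports spread over a disorder's eligible species. Small values
#'   concentrate reports on few species (high consensus, ICF near 1); large
#'   values spread them evenly (low consensus).
#' @param kind_probs Probabilities of assigning each species the kind
#'   plant / animal / fungus; must sum to 1.
#' @param multi_use_prob Probability that a species is eligible for every
#'   disorder rather than only its home disorder. Values above 0 are needed
#'   to exercise fidelity levels below 100\%.
#' @param seed Integer random seed; generation is fully deterministic given
#'   the seed and configuration.
#' @return A validated object of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(n_disorders = 3, species_pool = 30,
#'                         reports_per_disorder = 50, seed = 1)
#' generate_survey(cfg)
#' @export
synthetic_config <- function(n_disorders, species_pool,
                             reports_per_disorder = 100,
                             concentration = 0.5,
                             kind_probs = c(plant = 0.6, animal = 0.35,
                                            fungus = 0.05),
                             multi_use_prob = 0.2,
                             seed = 1L) {
  if (is.character(species_pool)) {
    pool <- species_pool
  } else {
    stopifnot(length(species_pool) == 1, species_pool >= 1)
    pool <- sprintf("Species synthetica %03d", seq_len(species_pool))
  }
  stopifnot(
    n_disorders >= 1, reports_per_disorder >= 1, concentration > 0,
    length(kind_probs) == 3, abs(sum(kind_probs) - 1) < 1e-9,
    multi_use_prob >= 0, multi_use_prob <= 1
  )
  if (length(pool) < n_disorders) {
    eq_abort("species_pool must supply at least one species per disorder",
             "ethnoquant_config_error")
  }
  structure(
    list(n_disorders = as.integer(n_disorders), species_pool = pool,
         reports_per_disorder = as.integer(reports_per_disorder),
         concentration = concentration,
         kind_probs = setNames(as.numeric(kind_probs), allowed_kinds),
         multi_use_prob = multi_use_prob, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

rdirichlet1 <- function(n, alpha) {
  g <- rgamma(n, shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, n)  # guard: all-zero draws at tiny alpha
  g / sum(g)
}

#' Generate a synthetic use-report survey
#'
#' Each species is assigned a home disorder (round-robin) and, with
#' probability `multi_use_prob`, made eligible for every disorder. For each
#' disorder, species weights are drawn from a symmetric
#' Dirichlet(`concentration`) over its eligible set and
#' `reports_per_disorder` reports are allocated by multinomial sampling;
#' species receiving at least one report become records with that mention
#' count. Used parts and preparations are drawn from fixed label
#' vocabularies. Identical configuration and seed give identical output.
#'
#' @param config A `synthetic_config`.
#' @return A validated `survey_tbl`.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    pool <- config$species_pool
    n_sp <- length(pool)
    kinds <- sample(allowed_kinds, n_sp, replace = TRUE,
                    prob = config$kind_probs)
    home <- rep_len(seq_len(config$n_disorders), n_sp)
    shared <- stats::runif(n_sp) < config$multi_use_prob
    disorders <- sprintf("disorder_%02d", seq_len(config$n_disorders))

    rows <- lapply(seq_len(config$n_disorders), function(d) {
      eligible <- which(home == d | shared)
      w <- rdirichlet1(length(eligible), config$concentration)
      counts <- as.integer(rmultinom(1, config$reports_per_disorder, w))
      keep <- counts > 0
      idx <- eligible[keep]
      if (length(idx) == 0) return(NULL)
      tibble(
        disorder = disorders[d],
        scientific_name = pool[idx],
        local_name = NA_character_,
        mentions = counts[keep],
        kind = kinds[idx],
        used_parts = lapply(idx, function(i)
          sample(part_vocabulary, sample(1:2, 1))),
        preparations = lapply(idx, function(i)
          sample(prep_vocabulary, sample(1:2, 1))),
        application = sample(c("oral", "topical"), length(idx),
                             replace = TRUE, prob = c(0.9, 0.1)),
        fl_printed = NA_real_
      )
    })
    as_survey(bind_rows(rows), aliases = NULL)
  })
}

#' Mean ICF as a function of the Dirichlet concentration
#'
#' Simulation diagnostic for the synthetic generator: for each concentration
#' on a grid, generates `n_replicates` surveys (seeds derived
#' deterministically from the configuration seed), computes the informant
#' consensus factor of every disorder, and reports the mean and standard
#' deviation. Mean ICF decreases as concentration grows, since larger
#' concentrations spread reports evenly over species.
#'
#' @param config A `synthetic_config`; its `concentration` field is
#'   overridden by the grid.
#' @param concentrations Numeric grid of concentration values.
#' @param n_replicates Replicates per grid point (at least 2).
#' @return A tibble of class `icf_curve` with columns `concentration`,
#'   `mean_icf`, `sd_icf`, `n_replicates`.
#' @export
expected_icf_curve <- function(config,
                               concentrations = c(0.05, 0.2, 0.5, 2, 10),
                               n_replicates = 100) {
  stopifnot(n_replicates >= 2, all(concentrations > 0))
  rows <- lapply(seq_along(concentrations), function(i) {
    icfs <- unlist(lapply(seq_len(n_replicates), function(r) {
      cfg <- config
      cfg$concentration <- concentrations[i]
      cfg$seed <- (config$seed + 7919L * i + r) %% .Machine$integer.max
      icf <- compute_icf(generate_survey(cfg))
      icf$icf[!is.na(icf$icf)]
    }))
    tibble(concentration = concentrations[i],
           mean_icf = mean(icfs), sd_icf = sd(icfs),
           n_replicates = n_replicates)
  })
  out <- bind_rows(rows) |> arrange(.data$concentration)
  class(out) <- c("icf_curve", class(out))
  out
}
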