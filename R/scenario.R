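#' Truncated geometric sighting-multiplicity distribution
#'
#' Probability mass over the number of sightings of an animal per primary
#' occasion (conditional on being seen at all), defaulting to a geometric
#' distribution truncated to `1..max_ns`. Field data show a strong skew: in
#' the Alaskan resighting programmes about half of the seen juveniles were
#' seen exactly once per summer, with a heavy tail of animals seen 5+ times
#' at intensively monitored rookeries.
#'
#' @param prob success probability of the geometric; `prob` is also the mass
#'   on a single sighting before truncation. Default 0.51.
#' @param max_ns upper truncation point (support is `1:max_ns`). Default 10.
#' @return numeric vector of probabilities of length `max_ns`, summing to 1.
#' @examples
#' ns_geometric()
#' @export
ns_geometric <- function(prob = 0.51, max_ns = 10L) {
  check_prob(prob, "prob")
  max_ns <- check_count(max_ns, "max_ns", min = 1L)
  p <- prob * (1 - prob)^(seq_len(max_ns) - 1)
  p / sum(p)
}

#' Define a simulation scenario
#'
#' Collects the generative quantities of an individual-based weaning study:
#' age-specific apparent survival, age-specific weaning probabilities (the
#' weaned state is absorbing), per-primary resighting probability,
#' per-sighting state-detection probability, and the distribution of the
#' number of sightings per seen primary. Defaults describe a Southeast
#' Alaska-style study: first-year survival 0.55 and 0.85 afterwards, weaning
#' probability 0.6 over ages 0-1 and 1-2 and 0.9 over 2-3, resighting
#' probability 0.8, and state-detection probability 0.25 per sighting.
#'
#' @param n_individuals number of pups released (>= 1).
#' @param n_cohorts number of birth years over which releases are spread
#'   evenly (cohorts occupy the first `n_cohorts` study years).
#' @param n_years number of study years (>= 2).
#' @param seasons_per_year 1 (annual primaries) or 2 (EARLY/LATE primaries
#'   per summer, Gulf of Alaska style).
#' @param phi_by_age apparent survival probability per annual age interval;
#'   the last element is recycled for older ages. Death and permanent
#'   emigration are confounded, as in any CJS model.
#' @param psi_by_age probability of weaning over each annual age interval
#'   (age 0 to 1 first); last element recycled. Weaned is absorbing.
#' @param psi_summer weaning probability over the within-summer EARLY-to-LATE
#'   interval, used only when `seasons_per_year = 2`. Default 0.118.
#' @param p per-primary resighting probability: scalar, or a vector of one
#'   value per study year (fixed year offsets).
#' @param delta probability that a single sighting of a truly unweaned animal
#'   yields a definitive suckling code "S" (else "u"). Sightings of weaned
#'   animals always yield "u".
#' @param ns_distribution probability vector over the number of sightings
#'   `1..K` per seen primary, `K >= 5`; see [ns_geometric()].
#' @param haulout_fraction probability a sighting occurs at a haul-out
#'   (site class "H") rather than a rookery ("R").
#' @param prop_female expected proportion of female pups.
#' @param seed optional integer seed used by [simulate_encounters()].
#' @return an object of class `sim_scenario` (a validated list).
#' @seealso [simulate_encounters()]
#' @examples
#' sc <- sim_scenario(n_individuals = 100, n_years = 4, n_cohorts = 1, seed = 1)
#' sc
#' @export
sim_scenario <- function(n_individuals = 3000L,
                         n_cohorts = 4L,
                         n_years = 7L,
                         seasons_per_year = 1L,
                         phi_by_age = c(0.55, 0.85),
                         psi_by_age = c(0.6, 0.6, 0.9),
                         psi_summer = 0.118,
                         p = 0.8,
                         delta = 0.25,
                         ns_distribution = ns_geometric(),
                         haulout_fraction = 0.3,
                         prop_female = 0.5,
                         seed = NULL) {
  n_individuals <- check_count(n_individuals, "n_individuals", min = 1L)
  n_years <- check_count(n_years, "n_years", min = 2L)
  n_cohorts <- check_count(n_cohorts, "n_cohorts", min = 1L)
  if (n_cohorts >= n_years)
    stop("`n_cohorts` must be smaller than `n_years` so every cohort has a resight year",
         call. = FALSE)
  if (!seasons_per_year %in% c(1L, 2L))
    stop("`seasons_per_year` must be 1 or 2", call. = FALSE)
  check_prob(phi_by_age, "phi_by_age")
  check_prob(psi_by_age, "psi_by_age")
  check_prob(psi_summer, "psi_summer")
  check_prob(p, "p")
  if (!length(p) %in% c(1L, n_years))
    stop("`p` must be a scalar or one value per study year", call. = FALSE)
  check_prob(delta, "delta")
  check_prob(haulout_fraction, "haulout_fraction")
  check_prob(prop_female, "prop_female")
  if (!is.numeric(ns_distribution) || length(ns_distribution) < 5L ||
      anyNA(ns_distribution) || any(ns_distribution < 0) || sum(ns_distribution) <= 0)
    stop("`ns_distribution` must be non-negative with support 1..K, K >= 5", call. = FALSE)
  ns_distribution <- ns_distribution / sum(ns_distribution)

  structure(list(
    n_individuals = n_individuals, n_cohorts = n_cohorts, n_years = n_years,
    seasons_per_year = as.integer(seasons_per_year),
    phi_by_age = phi_by_age, psi_by_age = psi_by_age, psi_summer = psi_summer,
    p = p, delta = delta, ns_distribution = ns_distribution,
    haulout_fraction = haulout_fraction, prop_female = prop_female,
    seed = seed
  ), class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Weaning study simulation scenario\n")
  cat(sprintf("  %d individuals, %d cohort(s), %d years, %d season(s)/year\n",
              x$n_individuals, x$n_cohorts, x$n_years, x$seasons_per_year))
  cat("  phi by age:", paste(format(x$phi_by_age), collapse = ", "), "\n")
  cat("  psi by age:", paste(format(x$psi_by_age), collapse = ", "), "\n")
  if (x$seasons_per_year == 2L) cat("  psi within-summer:", format(x$psi_summer), "\n")
  cat("  p:", paste(format(x$p), collapse = ", "), " delta:", format(x$delta), "\n")
  invisible(x)
}
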