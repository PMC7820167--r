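#' Study rookeries, regions and mean birth dates
#'
#' Reference table of the eight rookery groups used throughout the package
#' (Prince William Sound pools two small neighbouring rookeries). Mean birth
#' dates (assumed constant over years) are 8, 9, 13, 14 and 4 June for
#' Ugamak, Marmot, Sugarloaf, Prince William Sound and the Southeast Alaska
#' rookeries respectively, expressed here as day of year.
#'
#' @return data.frame with columns `rookery`, `region`, `population`
#'   (eastern/western stock) and `birth_doy` (mean birth date, day of year).
#' @examples
#' rookery_info()
#' @export
rookery_info <- function() {
  data.frame(
    rookery = c("Forrester", "Hazy", "WhiteSisters", "Graves",
                "PWS", "Sugarloaf", "Marmot", "Ugamak"),
    region = c("SEAK", "SEAK", "SEAK", "SEAK", "PWS", "CGOA", "CGOA", "EAI"),
    population = c(rep("eastern", 4L), rep("western", 4L)),
    birth_doy = c(155L, 155L, 155L, 155L, 165L, 164L, 160L, 159L),
    stringsAsFactors = FALSE
  )
}

#' Simulate encounter records from a weaning-study scenario
#'
#' Individual-based simulator with the statistical structure the
#' multistate CJS model assumes. Every pup is released in the unweaned state
#' in its birth year (its release record carries the definitive code "S").
#' Between primaries, animals survive with the age-specific probability `phi`
#' and, conditional on survival, unweaned animals wean with probability `psi`
#' (weaned and dead are absorbing; within-summer intervals are closed to
#' mortality). Conditional on being alive in a later primary, an animal is
#' seen with probability `p`; if seen, its number of sightings `ns` is drawn
#' from `ns_distribution`, and each sighting of a truly unweaned animal
#' independently shows the suckling code "S" with probability `delta`
#' (otherwise "u"); sightings of weaned animals always show "u". Sightings
#' occur at a haul-out with probability `haulout_fraction`.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed; defaults to `scenario$seed`. The caller's RNG
#'   stream is left untouched.
#' @return an object of class `sim_encounters`: a list with elements
#'   `records` (one row per sighting: `animal_id`, `year`, `season`, `code`,
#'   `site_class`), `covariates` (per animal: sex, natal rookery, region,
#'   population, maternal haplotype, neonatal mass, capture day, cohort),
#'   `truth` (latent state S/W/D per animal and primary, for recovery
#'   checks), `layout` and `scenario`.
#' @examples
#' sim <- simulate_encounters(sim_scenario(n_individuals = 50, n_cohorts = 1,
#'                                         n_years = 4, seed = 1))
#' head(sim$records)
#' @export
simulate_encounters <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed(seed, simulate_encounters_(scenario))
}

simulate_encounters_ <- function(sc) {
  layout <- sim_layout(sc)
  TT <- nrow(layout)
  n <- sc$n_individuals
  ids <- sprintf("A%05d", seq_len(n))
  years <- sort(unique(layout$year))

  cohort <- years[rep_len(seq_len(sc$n_cohorts), n)]
  release_season <- if (sc$seasons_per_year == 1L) "S" else "L"
  release <- layout_primary(layout, cohort, release_season)

  covariates <- simulate_covariates(ids, cohort, sc)

  phi_age <- function(age) sc$phi_by_age[pmin(age + 1L, length(sc$phi_by_age))]
  psi_age <- function(age) sc$psi_by_age[pmin(age + 1L, length(sc$psi_by_age))]
  p_year <- rep_len(sc$p, length(years))
  names(p_year) <- years

  # latent states: 0 = unweaned, 1 = weaned, 2 = dead; NA before release
  state <- matrix(NA_integer_, n, TT)
  state[cbind(seq_len(n), release)] <- 0L

  rec <- vector("list", TT)
  itype <- interval_types(layout)
  K <- length(sc$ns_distribution)

  for (t in seq_len(TT)[-1L]) {
    act <- which(release < t)
    if (length(act)) {
      prev <- state[act, t - 1L]
      age0 <- layout$year[t - 1L] - cohort[act]
      if (itype[t - 1L] == "summer") {
        phi <- rep(1, length(act))
        psi <- rep(sc$psi_summer, length(act))
      } else {
        phi <- phi_age(age0)
        psi <- psi_age(age0)
      }
      alive <- prev != 2L & stats::rbinom(length(act), 1L, phi) == 1L
      wean <- prev == 0L & alive & stats::rbinom(length(act), 1L, psi) == 1L
      new <- ifelse(!alive | prev == 2L, 2L, ifelse(prev == 1L | wean, 1L, 0L))
      state[act, t] <- new

      live <- act[new != 2L]
      if (length(live)) {
        seen <- live[stats::rbinom(length(live), 1L,
                                   p_year[as.character(layout$year[t])]) == 1L]
        if (length(seen)) {
          ns <- sample.int(K, length(seen), replace = TRUE,
                           prob = sc$ns_distribution)
          rid <- rep(seen, ns)
          unw <- state[rid, t] == 0L  # row index recycled per sighting
          code <- ifelse(unw & stats::rbinom(length(rid), 1L, sc$delta) == 1L,
                         "S", "u")
          site <- ifelse(stats::rbinom(length(rid), 1L, sc$haulout_fraction) == 1L,
                         "H", "R")
          rec[[t]] <- data.frame(animal_id = ids[rid],
                                 year = layout$year[t],
                                 season = layout$season[t],
                                 code = code, site_class = site,
                                 stringsAsFactors = FALSE)
        }
      }
    }
  }

  release_rec <- data.frame(animal_id = ids, year = cohort,
                            season = release_season, code = "S",
                            site_class = "R", stringsAsFactors = FALSE)
  records <- rbind(release_rec, do.call(rbind, rec[!vapply(rec, is.null, TRUE)]))
  records <- records[order(records$animal_id, records$year, records$season), ]
  rownames(records) <- NULL

  truth <- data.frame(
    animal_id = rep(ids, TT),
    primary = rep(seq_len(TT), each = n),
    year = rep(layout$year, each = n),
    season = rep(layout$season, each = n),
    state = c("S", "W", "D")[as.vector(state) + 1L],
    stringsAsFactors = FALSE
  )
  truth <- truth[!is.na(truth$state), ]
  truth <- truth[order(truth$animal_id, truth$primary), ]
  rownames(truth) <- NULL

  structure(list(records = records, covariates = covariates, truth = truth,
                 layout = layout, scenario = sc),
            class = "sim_encounters")
}

simulate_covariates <- function(ids, cohort, sc) {
  n <- length(ids)
  rk <- rookery_info()
  i <- sample.int(nrow(rk), n, replace = TRUE)
  sex <- ifelse(stats::rbinom(n, 1L, sc$prop_female) == 1L, "F", "M")
  mixing <- rk$rookery[i] %in% c("Graves", "WhiteSisters")
  mtHap <- ifelse(mixing,
                  sample(c("E", "W", "U"), n, replace = TRUE,
                         prob = c(0.4, 0.4, 0.2)),
                  ifelse(rk$population[i] == "eastern", "E", "W"))
  day <- sample(14:29, n, replace = TRUE)
  slope <- ifelse(rk$population[i] == "western", 0.337, 0.164)
  base <- ifelse(rk$population[i] == "western", 33, 29.5)
  mass <- base + 3.5 * (sex == "M") + slope * day + stats::rnorm(n, 0, 2.2)
  data.frame(animal_id = ids, cohort = cohort, sex = sex,
             natal_rookery = rk$rookery[i], region = rk$region[i],
             population = rk$population[i], mtHap = mtHap,
             mass_kg = round(mass, 1),
             capture_day = rk$birth_doy[i] + day,
             stringsAsFactors = FALSE)
}

#' @export
print.sim_encounters <- function(x, ...) {
  cat(sprintf("Simulated encounters: %d animals, %d sighting records, %d primaries\n",
              nrow(x$covariates), nrow(x$records), nrow(x$layout)))
  invisible(x)
}
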