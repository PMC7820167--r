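#' Published reference estimates for Steller sea lions
#'
#' Small tables of published estimates from a large mark-recapture analysis
#' of Steller sea lions born in Southeast Alaska and the Gulf of Alaska
#' (4,447 pups marked 2000-2016), shipped with the package as worked-example
#' inputs and cross-checks for the derived-quantity operations.
#'
#' * `steller_psi_estimates()`: interval weaning probabilities by group.
#'   Southeast Alaska groups (`SEAK_F`, `SEAK_M`) carry the annual estimates
#'   `a01` (common rate over ages 0-1 and 1-2), `a2` and `a3p` (shared
#'   between sexes; repeated per group). Gulf rookeries (`Ugamak`, `PWS`,
#'   `Marmot`, `Sugarloaf`) carry the early-season estimates `a0` and `a1`,
#'   with the shared within-summer rate `a01summer` and the annual `a2p`
#'   rate under group `GOA`. Per-sighting state-detection estimates are the
#'   `delta` rows.
#' * `steller_weaned_by_age()`: the derived cumulative proportions weaned by
#'   ages 1-4 per group, with 95% intervals.
#' * `steller_mass_model_aic()`: the AIC table of the neonatal body-mass
#'   model selection (models over natal rookery, sex, population and
#'   capture-day effects).
#'
#' @return a data.frame.
#' @examples
#' head(steller_psi_estimates())
#' @name steller_tables
NULL

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "weanmark", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname steller_tables
#' @export
steller_psi_estimates <- function() read_extdata("steller_psi_estimates.tsv")

#' @rdname steller_tables
#' @export
steller_weaned_by_age <- function() read_extdata("steller_weaned_by_age.tsv")

#' @rdname steller_tables
#' @export
steller_mass_model_aic <- function() read_extdata("steller_mass_model_aic.tsv")
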