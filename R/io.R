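#' Read and write encounter records
#'
#' Encounter files are tab-delimited text with a header and one row per
#' sighting: `animal_id`, `year`, `season` (`E`/`L`, or `S` for single-season
#' studies), `code` (`S` = seen suckling or laying on top of a female,
#' `u` = seen but state unknown) and `site_class` (`R` = rookery,
#' `H` = haul-out). The round trip `read_encounters(write_encounters(x))` is
#' lossless.
#'
#' @param records data.frame of encounter records (e.g.
#'   `simulate_encounters()$records`).
#' @param path file path.
#' @return `read_encounters()` returns the validated data.frame;
#'   `write_encounters()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' sim <- simulate_encounters(sim_scenario(n_individuals = 20, n_cohorts = 1,
#'                                         n_years = 3, seed = 2))
#' write_encounters(sim$records, f)
#' identical(read_encounters(f), sim$records)
#' @export
write_encounters <- function(records, path) {
  validate_encounters(records)
  utils::write.table(records[, encounter_cols()], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_encounters
#' @export
read_encounters <- function(path) {
  df <- utils::read.delim(path, colClasses = c(animal_id = "character",
                                               year = "integer",
                                               season = "character",
                                               code = "character",
                                               site_class = "character"))
  validate_encounters(df)
  df
}

encounter_cols <- function() c("animal_id", "year", "season", "code", "site_class")

validate_encounters <- function(df) {
  miss <- setdiff(encounter_cols(), names(df))
  if (length(miss))
    stop("encounter records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!df$code %in% c("S", "u"))
  if (length(bad))
    stop(sprintf("unknown behavior code \"%s\" at row %d (expected S or u)",
                 df$code[bad[1L]], bad[1L]), call. = FALSE)
  bad <- which(!df$season %in% c("E", "L", "S"))
  if (length(bad))
    stop(sprintf("unknown season \"%s\" at row %d (expected E, L or S)",
                 df$season[bad[1L]], bad[1L]), call. = FALSE)
  bad <- which(!df$site_class %in% c("R", "H"))
  if (length(bad))
    stop(sprintf("unknown site class \"%s\" at row %d (expected R or H)",
                 df$site_class[bad[1L]], bad[1L]), call. = FALSE)
  if (anyNA(df$year))
    stop(sprintf("missing or non-integer year at row %d", which(is.na(df$year))[1L]),
         call. = FALSE)
  invisible(df)
}

#' Read and write per-animal covariate tables
#'
#' Tab-delimited text, one row per animal: `animal_id`, `cohort` (birth
#' year), `sex`, `natal_rookery`, `region`, `population`, `mtHap` (maternal
#' haplotype: E, W or U for unknown), `mass_kg` (neonatal mass at capture)
#' and `capture_day` (day of year of capture).
#'
#' @param covariates data.frame of per-animal covariates.
#' @param path file path.
#' @return `read_covariates()` returns the data.frame; `write_covariates()`
#'   returns `path` invisibly.
#' @export
write_covariates <- function(covariates, path) {
  if (!"animal_id" %in% names(covariates))
    stop("covariates lack an `animal_id` column", call. = FALSE)
  utils::write.table(covariates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$animal_id <- as.character(df$animal_id)
  if (anyDuplicated(df$animal_id))
    stop("duplicated animal_id in covariate file", call. = FALSE)
  df
}
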