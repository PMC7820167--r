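#' Robust-design occasion layouts
#'
#' An occasion layout lists the primary occasions of a study (year, season,
#' and the number of secondary sighting slots each primary carries) and the
#' type of interval between consecutive primaries: `"annual"` (open to
#' mortality and weaning) or `"summer"` (the EARLY-to-LATE gap within one
#' summer, closed to mortality but open to weaning). Secondary slots are
#' capped at five; primaries outside the juvenile-cohort years carry a single
#' slot because adults only ever have data in the first secondary occasion.
#'
#' @param years calendar years of the study, in order.
#' @param seasons_per_year 1 (one primary per summer) or 2 (EARLY and LATE).
#' @param secondary_years years whose primaries carry five secondary slots
#'   (the years with marked juveniles in the population).
#' @param release_year optional year of a single-slot release-only primary
#'   prepended before `years` (used when the first cohort is released the
#'   year before resighting begins).
#' @return a data.frame of class `occasion_layout` with columns `primary`,
#'   `year`, `season`, `n_slots`, and attribute `interval_type` (length
#'   number of primaries minus one).
#' @examples
#' n_columns(seak_layout())  # 54
#' n_columns(goa_layout())   # 161
#' @export
occasion_layout <- function(years, seasons_per_year = 1L, secondary_years = years,
                            release_year = NULL) {
  if (length(years) < 1L || is.unsorted(years, strictly = TRUE))
    stop("`years` must be strictly increasing", call. = FALSE)
  if (!seasons_per_year %in% c(1L, 2L))
    stop("`seasons_per_year` must be 1 or 2", call. = FALSE)
  if (seasons_per_year == 1L) {
    df <- data.frame(year = years, season = "S")
  } else {
    df <- data.frame(year = rep(years, each = 2L), season = c("E", "L"))
  }
  df$n_slots <- ifelse(df$year %in% secondary_years, 5L, 1L)
  if (!is.null(release_year)) {
    if (release_year >= years[1L]) stop("`release_year` must precede `years`", call. = FALSE)
    df <- rbind(data.frame(year = release_year,
                           season = if (seasons_per_year == 1L) "S" else "L",
                           n_slots = 1L), df)
  }
  df$primary <- seq_len(nrow(df))
  df <- df[, c("primary", "year", "season", "n_slots")]
  itype <- ifelse(diff(df$year) == 0L, "summer", "annual")
  structure(df, interval_type = itype, class = c("occasion_layout", "data.frame"))
}

#' @rdname occasion_layout
#' @details `seak_layout()` is the Southeast Alaska configuration: 18 annual
#'   primaries (2001-2018) with five secondary slots only in the nine
#'   juvenile-cohort years (2002-2008, 2017-2018), giving 9*5 + 9 = 54
#'   capture-history columns. `goa_layout()` is the Gulf of Alaska
#'   configuration: 16 years (2001-2016) with EARLY and LATE primaries of
#'   five slots each, plus one release occasion for the 2000 cohort,
#'   giving 16*2*5 + 1 = 161 columns.
#' @export
seak_layout <- function() {
  occasion_layout(2001:2018, seasons_per_year = 1L,
                  secondary_years = c(2002:2008, 2017:2018))
}

#' @rdname occasion_layout
#' @export
goa_layout <- function() {
  occasion_layout(2001:2016, seasons_per_year = 2L, secondary_years = 2001:2016,
                  release_year = 2000)
}

#' @rdname occasion_layout
#' @param layout an `occasion_layout`.
#' @return `n_columns()`: the total number of capture-history columns
#'   (sum of secondary slots over primaries).
#' @export
n_columns <- function(layout) {
  stopifnot(inherits(layout, "occasion_layout"))
  sum(layout$n_slots)
}

interval_types <- function(layout) attr(layout, "interval_type")

# primary index for (year, season) pairs; NA when outside the layout
layout_primary <- function(layout, year, season) {
  match(paste(year, season), paste(layout$year, layout$season))
}

# layout used by the simulator: first study year 2001-like indexing
sim_layout <- function(scenario) {
  years <- 2000L + seq_len(scenario$n_years)
  occasion_layout(years, seasons_per_year = scenario$seasons_per_year)
}
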