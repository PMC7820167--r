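#' Build a robust-design capture history for one animal
#'
#' Converts the encounter records of a single animal into a robust-design
#' capture history over the primary occasions of `layout`. The release
#' primary (the animal's birth year) is assigned the definitive code "S" in
#' its first secondary slot. For juveniles with `x <= 5` sightings in a
#' primary, the secondary history is those codes (in record order) followed
#' by `5 - x` zeros; with `x > 5`, exactly five are retained, favoring
#' haul-out over rookery sightings to counterbalance high resight effort at
#' natal sites: all haul-out records are taken first and a uniform random
#' draw from the rookery records fills to five (if haul-out records alone
#' exceed five, five of them are drawn uniformly). The per-primary covariate
#' `ns` is the uncapped number of sightings; adults (and single-slot
#' primaries) carry data only in the first secondary slot with `ns = 1`, and
#' `ns` is set to 1 as a placeholder for unseen primaries so that only the
#' first secondary slot ever carries a free resighting probability.
#'
#' @param records encounter records of one animal (see [read_encounters()]).
#' @param cohort the animal's birth year.
#' @param layout an [occasion_layout()].
#' @param juvenile_ages ages (years) treated as juvenile, default `1:3`.
#' @param seasons seasons retained (the seasonal window); default all
#'   seasons present in `layout`.
#' @param seed optional integer seed for the 5-of-x selection; encoding with
#'   the same seed is bit-identical.
#' @return an object of class `capture_history`: list with `animal_id`,
#'   `cohort`, `release` (primary index), `obs` (primaries x 5 character
#'   matrix over `{0, S, u}`) and `ns` (per-primary sighting count).
#' @examples
#' lay <- occasion_layout(2000:2003)
#' rec <- data.frame(animal_id = "A1",
#'                   year = c(2000, rep(2001, 3), rep(2002, 2)),
#'                   season = "S",
#'                   code = c("S", "u", "u", "S", "u", "u"),
#'                   site_class = "R")
#' h <- build_history(rec, cohort = 2000, layout = lay)
#' history_strings(h)
#' @export
build_history <- function(records, cohort, layout, juvenile_ages = 1:3,
                          seasons = NULL, seed = NULL) {
  stopifnot(inherits(layout, "occasion_layout"))
  validate_encounters(records)
  id <- unique(records$animal_id)
  if (length(id) > 1L)
    stop("`records` spans multiple animals: ", paste(id, collapse = ", "),
         call. = FALSE)
  if (length(id) == 0L) id <- NA_character_
  seasons <- seasons %||% unique(layout$season)
  records <- records[records$season %in% seasons, , drop = FALSE]
  if (any(records$year < cohort))
    stop(sprintf("animal %s sighted before its release year %d", id, cohort),
         call. = FALSE)
  if (any(records$year > max(layout$year)))
    stop(sprintf("animal %s sighted outside the occasion calendar", id),
         call. = FALSE)
  release_season <- if (all(layout$season == "S")) "S" else "L"
  release <- layout_primary(layout, cohort,
                            if (cohort %in% layout$year) release_season else NA)
  if (is.na(release)) {
    # cohort released at a dedicated release-only primary, if present
    release <- which(layout$year == cohort)[1L]
    if (is.na(release) || !length(release))
      stop(sprintf("cohort %d is outside the occasion calendar", cohort),
           call. = FALSE)
  }

  TT <- nrow(layout)
  obs <- matrix("0", TT, 5L)
  ns <- rep(1L, TT)
  obs[release, 1L] <- "S"

  prim <- layout_primary(layout, records$year, records$season)
  if (anyNA(prim))
    stop(sprintf("animal %s has sightings outside the occasion calendar", id),
         call. = FALSE)
  if (any(prim < release))
    stop(sprintf("animal %s sighted before its release occasion", id),
         call. = FALSE)
  later <- prim > release
  records <- records[later, , drop = FALSE]
  prim <- prim[later]

  with_seed(seed, {
    for (t in unique(prim)) {
      rows <- which(prim == t)
      x <- length(rows)
      age <- layout$year[t] - cohort
      if (layout$n_slots[t] == 5L && age %in% juvenile_ages) {
        keep <- if (x <= 5L) rows else
          select_sightings(rows, records$site_class[rows] == "H")
        codes <- records$code[keep]
        obs[t, seq_along(codes)] <- codes
        ns[t] <- x
      } else {
        obs[t, 1L] <- if (any(records$code[rows] == "S")) "S" else "u"
        ns[t] <- 1L
      }
    }
  })

  structure(list(animal_id = id, cohort = cohort, release = release,
                 obs = obs, ns = ns),
            class = "capture_history")
}

# retain 5 of x > 5 sightings, haul-outs first; uniform draws break ties
select_sightings <- function(rows, is_haulout) {
  resample <- function(x, k) x[sample.int(length(x), k)]
  ho <- rows[is_haulout]
  rk <- rows[!is_haulout]
  keep <- if (length(ho) >= 5L) resample(ho, 5L) else
    c(ho, resample(rk, 5L - length(ho)))
  sort(keep)
}

#' @export
print.capture_history <- function(x, ...) {
  cat(sprintf("Capture history for %s (cohort %d, release primary %d)\n",
              x$animal_id, x$cohort, x$release))
  cat(" ", paste(history_strings(x), collapse = " "), "\n")
  cat("  ns:", paste(x$ns, collapse = ","), "\n")
  invisible(x)
}

#' Display capture histories as code strings
#'
#' @param x a `capture_history` or `wean_dataset`.
#' @param layout optional layout used to truncate each primary to its number
#'   of secondary slots; full five-slot strings are shown otherwise.
#' @return character vector (one string per primary for a single history;
#'   one concatenated string per animal for a dataset).
#' @export
history_strings <- function(x, layout = NULL) {
  if (inherits(x, "wean_dataset"))
    return(apply(x$codes, 1L, paste, collapse = ""))
  stopifnot(inherits(x, "capture_history"))
  slots <- if (is.null(layout)) rep(5L, nrow(x$obs)) else layout$n_slots
  vapply(seq_len(nrow(x$obs)),
         function(t) paste(x$obs[t, seq_len(slots[t])], collapse = ""), "")
}

#' Encode a whole encounter dataset
#'
#' Builds one capture history per animal listed in `covariates` (animals
#' never resighted after release get an all-zero history past their release
#' primary) and assembles them into an aligned history matrix. Each animal's
#' 5-of-x selection uses a seed derived from `seed` and the animal's
#' position, so re-encoding with the same seed is bit-identical.
#'
#' @param records encounter records for any number of animals.
#' @param covariates per-animal covariates with at least `animal_id` and
#'   `cohort` (birth year).
#' @param layout an [occasion_layout()].
#' @inheritParams build_history
#' @param seed integer seed for the 5-of-x selections.
#' @return a `wean_dataset`, see [assemble_dataset()].
#' @export
encode_dataset <- function(records, covariates, layout, juvenile_ages = 1:3,
                           seasons = NULL, seed = NULL) {
  validate_encounters(records)
  if (!all(c("animal_id", "cohort") %in% names(covariates)))
    stop("`covariates` must contain animal_id and cohort", call. = FALSE)
  unknown <- setdiff(unique(records$animal_id), covariates$animal_id)
  if (length(unknown))
    stop("records for animal(s) missing from covariates: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  byid <- split(seq_len(nrow(records)), records$animal_id)
  histories <- vector("list", nrow(covariates))
  for (i in seq_len(nrow(covariates))) {
    id <- covariates$animal_id[i]
    rows <- byid[[id]]
    rec <- if (is.null(rows))
      records[0L, , drop = FALSE] else records[rows, , drop = FALSE]
    h <- build_history(rec, cohort = covariates$cohort[i], layout = layout,
                       juvenile_ages = juvenile_ages, seasons = seasons,
                       seed = if (is.null(seed)) NULL else seed + i)
    h$animal_id <- id
    histories[[i]] <- h
  }
  out <- assemble_dataset(histories, layout)
  out$covariates <- as.data.frame(covariates)
  out
}

#' Assemble capture histories into an aligned dataset
#'
#' Aligns per-animal capture histories on a common occasion calendar,
#' producing the full history matrix (one column per secondary slot of each
#' primary), the per-primary `ns` matrix, and an occasion index map giving
#' the year, season and secondary slot of every column. The Southeast Alaska
#' layout yields 54 columns and the Gulf of Alaska layout 161.
#'
#' @param histories list of [build_history()] results on the same layout.
#' @param layout the common [occasion_layout()].
#' @return an object of class `wean_dataset`: list with `animal_id`,
#'   `cohort`, `release`, `codes` (animals x columns character matrix),
#'   `obs` (animals x primaries x 5 array), `ns`, `nS`, `nu`, `seen`
#'   matrices (animals x primaries), `occasion_map` and `layout`.
#' @export
assemble_dataset <- function(histories, layout) {
  stopifnot(inherits(layout, "occasion_layout"))
  if (!length(histories)) stop("no histories to assemble", call. = FALSE)
  TT <- nrow(layout)
  n <- length(histories)
  ok <- vapply(histories, function(h)
    inherits(h, "capture_history") && nrow(h$obs) == TT, TRUE)
  if (!all(ok))
    stop("history ", which(!ok)[1L], " is not on the supplied occasion calendar",
         call. = FALSE)

  obs <- array("0", c(n, TT, 5L))
  ns <- matrix(1L, n, TT)
  for (i in seq_len(n)) {
    obs[i, , ] <- histories[[i]]$obs
    ns[i, ] <- histories[[i]]$ns
  }
  nS <- apply(obs == "S", c(1L, 2L), sum)
  nu <- apply(obs == "u", c(1L, 2L), sum)
  seen <- nS + nu > 0L

  cols <- do.call(rbind, lapply(seq_len(TT), function(t)
    data.frame(primary = t, year = layout$year[t], season = layout$season[t],
               secondary = seq_len(layout$n_slots[t]))))
  cols$column <- seq_len(nrow(cols))
  codes <- matrix("0", n, nrow(cols))
  for (t in seq_len(TT)) {
    sel <- cols$primary == t
    codes[, cols$column[sel]] <- obs[, t, seq_len(layout$n_slots[t])]
  }

  structure(list(
    animal_id = vapply(histories, function(h) h$animal_id, ""),
    cohort = vapply(histories, function(h) as.integer(h$cohort), 1L),
    release = vapply(histories, function(h) as.integer(h$release), 1L),
    codes = codes, obs = obs, ns = ns, nS = nS, nu = nu, seen = seen,
    occasion_map = cols[, c("column", "primary", "year", "season", "secondary")],
    layout = layout
  ), class = "wean_dataset")
}

#' @export
print.wean_dataset <- function(x, ...) {
  cat(sprintf("Robust-design weaning dataset: %d animals, %d primaries, %d columns\n",
              length(x$animal_id), nrow(x$layout), ncol(x$codes)))
  invisible(x)
}

#' Write a history file
#'
#' One row per animal: `animal_id`, the concatenated code string over all
#' occasion columns (alphabet `{0, S, u}`), and the comma-separated `ns`
#' vector. The occasion map is written as a sidecar table at
#' `paste0(path, ".occasions.tsv")`.
#'
#' @param dataset a `wean_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_histories <- function(dataset, path) {
  stopifnot(inherits(dataset, "wean_dataset"))
  df <- data.frame(animal_id = dataset$animal_id,
                   history = history_strings(dataset),
                   ns = apply(dataset$ns, 1L, paste, collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$occasion_map, paste0(path, ".occasions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
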