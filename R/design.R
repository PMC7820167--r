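#' Convert an encoded dataset to model-ready form
#'
#' Extracts from a `wean_dataset` the quantities the hidden Markov
#' likelihood needs: per-animal release primaries, per-primary seen
#' indicators, counts of definitive ("S") and unknown ("u") codes among the
#' retained secondary slots, the `ns` covariate, ages, and the interval
#' types between primaries.
#'
#' @param dataset a `wean_dataset` from [encode_dataset()] or
#'   [assemble_dataset()].
#' @param covariates per-animal covariates (must cover every animal);
#'   defaults to those attached by [encode_dataset()].
#' @return an object of class `mvms_data`.
#' @export
as_mvms_data <- function(dataset, covariates = dataset$covariates) {
  stopifnot(inherits(dataset, "wean_dataset"))
  if (is.null(covariates))
    covariates <- data.frame(animal_id = dataset$animal_id,
                             cohort = dataset$cohort)
  m <- match(dataset$animal_id, covariates$animal_id)
  if (anyNA(m))
    stop("covariates missing for animal(s): ",
         paste(utils::head(dataset$animal_id[is.na(m)], 5L), collapse = ", "),
         call. = FALSE)
  covariates <- covariates[m, , drop = FALSE]
  rownames(covariates) <- NULL
  layout <- dataset$layout
  # age (years) of each animal at each primary
  age <- outer(dataset$cohort, layout$year, function(co, yr) yr - co)
  structure(list(
    n = length(dataset$animal_id), T = nrow(layout),
    animal_id = dataset$animal_id,
    release = dataset$release,
    seen = dataset$seen, nS = dataset$nS, nu = dataset$nu, ns = dataset$ns,
    age = age, interval_type = interval_types(layout),
    covariates = covariates, layout = layout
  ), class = "mvms_data")
}

#' @export
print.mvms_data <- function(x, ...) {
  cat(sprintf("mvms_data: %d animals, %d primaries (%d annual, %d within-summer intervals)\n",
              x$n, x$T, sum(x$interval_type == "annual"),
              sum(x$interval_type == "summer")))
  invisible(x)
}

#' Design data for the four model parameters
#'
#' Builds one data.frame per parameter with a row per (animal, slot):
#' survival `phi` and weaning probability `psi` over the intervals between
#' consecutive primaries, and resighting probability `p` and state-detection
#' probability `delta` at each primary. Columns include the animal
#' covariates, `age` (at the interval start, or at the primary), `firstyear`
#' (0/1), an age-class label `ac` (`a0`, `a1`, `a2`, `a3p`), the weaning-age
#' label `wage` (`a0`, `a1`, `a2`, `a3p`, or `summer` for the within-summer
#' interval of two-season layouts), `ac2` (`juv`/`adult`), and a `fix`
#' column of fixed real values (NA = free). The returned data.frames may be
#' edited (e.g. setting `fix`) before passing them to [fit_mvms()].
#'
#' Fixed-parameter conventions applied here: `phi` is fixed to 1 over
#' within-summer intervals (closed to mortality). The remaining conventions
#' are structural in the likelihood: survival is 1 between secondary slots,
#' resighting of secondaries `2..min(ns, 5)` is certain and impossible
#' beyond, and the weaned state can never be detected definitively.
#'
#' @param data an `mvms_data`.
#' @return named list of data.frames (`phi`, `psi`, `p`, `delta`).
#' @export
design_data <- function(data) {
  stopifnot(inherits(data, "mvms_data"))
  n <- data$n; TT <- data$T
  lay <- data$layout
  cov <- data$covariates

  grid <- function(slots, start_year, season, itype = NULL) {
    df <- data.frame(
      id = rep(data$animal_id, times = length(slots)),
      slot = rep(slots, each = n),
      year = rep(start_year, each = n),
      season = rep(season, each = n)
    )
    if (!is.null(itype)) df$interval_type <- rep(itype, each = n)
    df <- cbind(df, cov[rep(seq_len(n), times = length(slots)),
                        setdiff(names(cov), "animal_id"), drop = FALSE])
    rownames(df) <- NULL
    df$age <- df$year - df$cohort
    df$firstyear <- as.integer(df$age == 0L)
    df$ac <- c("a0", "a1", "a2", "a3p")[pmin(pmax(df$age, 0L), 3L) + 1L]
    df$ac2 <- ifelse(df$age >= 4L, "adult", "juv")
    df$fix <- NA_real_
    df
  }

  J <- TT - 1L
  itv <- grid(seq_len(J), lay$year[-TT], lay$season[-TT], data$interval_type)
  itv$wage <- ifelse(itv$interval_type == "summer", "summer", itv$ac)
  phi <- itv
  phi$fix[phi$interval_type == "summer"] <- 1
  psi <- itv

  occ <- grid(seq_len(TT), lay$year, lay$season)
  p <- occ
  delta <- occ
  list(phi = phi, psi = psi, p = p, delta = delta)
}

# Build per-parameter design matrices. phi and p may depend on the latent
# weaning state through a `weanW` term (0 = unweaned, 1 = weaned); psi is a
# transition out of S only and delta for state W is fixed to 0, so neither
# may reference weanW.
prepare_mvms <- function(data, formulas, ddl) {
  defaults <- list(phi = ~1, psi = ~1, p = ~1, delta = ~1)
  formulas <- utils::modifyList(defaults, formulas[!vapply(formulas, is.null, TRUE)])
  parts <- list()
  offset <- 0L
  for (nm in c("phi", "psi", "p", "delta")) {
    df <- ddl[[nm]]
    f <- formulas[[nm]]
    vars <- all.vars(f)
    if ("weanW" %in% vars && nm %in% c("psi", "delta"))
      stop(sprintf("`weanW` cannot appear in the %s model", nm), call. = FALSE)
    missing_vars <- setdiff(vars, c(names(df), "weanW"))
    if (length(missing_vars))
      stop(sprintf("%s design data lacks term(s): %s", nm,
                   paste(missing_vars, collapse = ", ")), call. = FALSE)
    used <- intersect(vars, names(df))
    if (length(used)) {
      bad <- used[vapply(used, function(v) anyNA(df[[v]]), TRUE)]
      if (length(bad))
        stop(sprintf("non-finite %s linear predictor: missing values in term %s",
                     nm, paste(bad, collapse = ", ")), call. = FALSE)
    }
    two_state <- nm %in% c("phi", "p")
    dfx <- if (two_state) {
      rbind(cbind(df, weanW = 0), cbind(df, weanW = 1))
    } else df
    X <- stats::model.matrix(f, dfx)
    if (ncol(X)) {
      free <- rep(is.na(df$fix), if (two_state) 2L else 1L)
      qrX <- qr(X[free, , drop = FALSE])
      if (qrX$rank < ncol(X)) {
        aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
        warning(sprintf("%s design is rank-deficient; aliased column(s): %s",
                        nm, paste(aliased, collapse = ", ")), call. = FALSE)
      }
    }
    parts[[nm]] <- list(
      X = X, k = ncol(X), two_state = two_state,
      N = nrow(df), idx = offset + seq_len(ncol(X)),
      fix_idx = which(!is.na(df$fix)), fix_val = df$fix[!is.na(df$fix)],
      labels = if (ncol(X)) paste0(nm, ":", colnames(X)) else character(0)
    )
    offset <- offset + ncol(X)
  }
  list(parts = parts, k = offset, formulas = formulas,
       n = data$n, T = data$T,
       labels = unlist(lapply(parts, `[[`, "labels"), use.names = FALSE))
}

# real-scale parameter matrices for one theta; logit link, fixes bypass it
slot_probs <- function(prep, theta) {
  out <- list()
  eta_max <- 0
  for (nm in names(prep$parts)) {
    pt <- prep$parts[[nm]]
    if (pt$k) {
      eta <- drop(pt$X %*% theta[pt$idx])
    } else eta <- numeric(pt$N * (1L + pt$two_state))
    if (pt$two_state) {
      eS <- eta[seq_len(pt$N)]; eW <- eta[pt$N + seq_len(pt$N)]
    } else eS <- eW <- eta
    free <- setdiff(seq_len(pt$N), pt$fix_idx)
    if (length(free)) eta_max <- max(eta_max, abs(eS[free]), abs(eW[free]))
    prS <- stats::plogis(eS); prW <- stats::plogis(eW)
    prS[pt$fix_idx] <- pt$fix_val
    prW[pt$fix_idx] <- pt$fix_val
    nc <- if (nm %in% c("phi", "psi")) prep$T - 1L else prep$T
    out[[paste0(nm, "_S")]] <- matrix(prS, prep$n, nc)
    out[[paste0(nm, "_W")]] <- matrix(prW, prep$n, nc)
  }
  out$eta_max <- eta_max
  out
}
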