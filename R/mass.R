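#' Neonatal body-mass model set
#'
#' The nine-candidate linear model set used to adjust neonatal body mass for
#' capture date/age: simplifications of the most complex model
#' `mass ~ nr * sex + population * day`, where `nr` is natal rookery, `day`
#' is the number of days between capture and the rookery-specific mean birth
#' date, and `population` (eastern/western) allows the daily growth rate to
#' differ between stocks.
#'
#' @return named list of model formulas.
#' @export
mass_model_set <- function() {
  list(
    "1" = mass ~ nr * sex + population * day,
    "2" = mass ~ nr * sex + day,
    "3" = mass ~ nr * sex,
    "4" = mass ~ nr + sex + population * day,
    "5" = mass ~ nr + sex + day,
    "6" = mass ~ nr + sex,
    "7" = mass ~ sex + population * day,
    "8" = mass ~ sex + day,
    "9" = mass ~ sex
  )
}

#' Fit and rank the neonatal body-mass models
#'
#' Fits each candidate as an ordinary (Gaussian, identity link) linear model
#' and ranks them by AIC with Akaike weights. `npar` counts estimated
#' coefficients plus the residual variance; aliased coefficients (e.g. the
#' `population` main effect, which is a function of rookery) do not count.
#'
#' @param data data.frame with columns `mass` (kg), `nr`, `sex`,
#'   `population`, `day`.
#' @param models named list of formulas, default [mass_model_set()].
#' @return data.frame of class `mass_model_table` sorted by AIC with
#'   columns `model`, `formula`, `npar`, `AIC`, `dAIC`, `weight`; the
#'   fitted `lm` objects are in `attr(, "fits")`.
#' @examples
#' d <- simulate_mass(n = 300, seed = 1)
#' fit_mass_models(d)
#' @export
fit_mass_models <- function(data, models = mass_model_set()) {
  need <- c("mass", "nr", "sex", "population", "day")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("mass data lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (v in c("nr", "sex", "population")) {
    if (length(unique(data[[v]])) < 2L)
      warning(sprintf("factor `%s` has a single level; its terms are aliased", v),
              call. = FALSE)
  }
  fits <- lapply(models, function(f) stats::lm(f, data = data))
  aic <- vapply(fits, stats::AIC, 0)
  npar <- vapply(fits, function(m) as.integer(attr(stats::logLik(m), "df")), 1L)
  tab <- data.frame(model = names(models),
                    formula = vapply(models, function(f) deparse(f[[3L]]), ""),
                    npar = npar, AIC = aic, dAIC = aic - min(aic),
                    weight = aic_weights(aic))
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  structure(tab, fits = fits, class = c("mass_model_table", "data.frame"))
}

#' @export
print.mass_model_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$AIC <- round(df$AIC, 1); df$dAIC <- round(df$dAIC, 1)
  df$weight <- round(df$weight, 2)
  print(df, ...)
  invisible(x)
}

#' Population-specific daily growth slopes from a fitted mass model
#'
#' Extracts the per-population slope of `day` (kg/day) from one of the
#' fitted mass models by differencing model predictions one day apart.
#'
#' @param fit an `lm` from [fit_mass_models()] (e.g.
#'   `attr(tab, "fits")[["1"]]`) whose data contain `population` and `day`.
#' @return named numeric vector of slopes, one per population level.
#' @export
day_slopes <- function(fit) {
  stopifnot(inherits(fit, "lm"))
  mf <- stats::model.frame(fit)
  pops <- sort(unique(as.character(mf$population)))
  vapply(setNames(pops, pops), function(pp) {
    row <- mf[as.character(mf$population) == pp, , drop = FALSE][1L, ]
    nd <- rbind(row, row)
    nd$day <- c(0, 1)
    diff(stats::predict(fit, newdata = nd))
  }, 0)
}

#' Adjust neonatal mass for capture date/age
#'
#' Removes the estimated daily growth between the rookery-specific mean
#' birth date and capture: `mass - day * beta_day`. `mass_at_day()`
#' back-projects the adjusted mass to a common reference age, by default 30
#' days past the mean birth date, as used for among-rookery size summaries.
#' `center_by_sex()` expresses masses as deviations from the sex-specific
#' means, the form in which mass enters the survival and weaning models.
#'
#' @param mass mass at capture (kg).
#' @param day days between capture and the rookery-specific mean birth date.
#' @param beta_day estimated growth slope (kg/day) for the animal's
#'   population; vectorised.
#' @return adjusted mass in kg.
#' @examples
#' adjust_mass(40, 20, 0.337)     # 33.26
#' mass_at_day(40, 20, 0.337)     # mass projected to day 30
#' @export
adjust_mass <- function(mass, day, beta_day) {
  if (anyNA(day)) stop("`day` contains missing values", call. = FALSE)
  if (anyNA(mass)) stop("`mass` contains missing values", call. = FALSE)
  mass - day * beta_day
}

#' @rdname adjust_mass
#' @param target_day reference age in days past the mean birth date.
#' @export
mass_at_day <- function(mass, day, beta_day, target_day = 30) {
  adjust_mass(mass, day, beta_day) + target_day * beta_day
}

#' @rdname adjust_mass
#' @param sex vector of sex codes aligned with `mass`.
#' @export
center_by_sex <- function(mass, sex) {
  mass - stats::ave(mass, sex)
}

#' Cubic B-spline basis for a mass covariate
#'
#' Deterministic cubic B-spline basis with `df` columns, interior knots at
#' quantiles of the data and boundary knots at the data range, for fitting
#' nonlinear mass effects on survival or weaning probability.
#'
#' @param x numeric covariate values.
#' @param df degrees of freedom, one of 3-6.
#' @return numeric matrix with `df` columns (class `bspline_basis`), whose
#'   columns lie in `[0, 1]` and, together with the implicit intercept,
#'   form a partition of unity.
#' @export
bspline_basis <- function(x, df = 4L) {
  if (!df %in% 3:6) stop("`df` must be 3, 4, 5 or 6", call. = FALSE)
  if (anyNA(x)) stop("`x` contains missing values", call. = FALSE)
  ux <- unique(x)
  if (length(ux) < df + 1L)
    stop(sprintf("need at least %d distinct values for df = %d", df + 1L, df),
         call. = FALSE)
  if (diff(range(x)) == 0) stop("`x` is constant", call. = FALSE)
  b <- splines::bs(x, df = df)
  m <- matrix(as.numeric(b), nrow = length(x))
  colnames(m) <- paste0("bs", seq_len(ncol(m)))
  attr(m, "knots") <- attr(b, "knots")
  attr(m, "boundary") <- attr(b, "Boundary.knots")
  m
}

#' Simulate a neonatal body-mass dataset
#'
#' Generates capture masses under the most complex candidate model
#' (`nr * sex + population * day`): rookery- and sex-specific cell means
#' with western pups larger and growing faster (default slopes 0.337 kg/day
#' western, 0.164 eastern), capture days uniform over 14-29 days past the
#' rookery-specific mean birth date, and Gaussian residuals.
#'
#' @param n number of pups.
#' @param beta_day named slopes per population (kg/day).
#' @param sigma residual standard deviation (kg).
#' @param sex_dimorphism mean male minus female mass (kg), plus a small
#'   rookery-by-sex perturbation so the full interaction model is the truth.
#' @param seed integer seed.
#' @return data.frame with `mass`, `nr`, `sex`, `population`, `day`.
#' @export
simulate_mass <- function(n = 1000L,
                          beta_day = c(eastern = 0.164, western = 0.337),
                          sigma = 1.5, sex_dimorphism = 3.5, seed = NULL) {
  rk <- rookery_info()
  with_seed(seed, {
    i <- sample.int(nrow(rk), n, replace = TRUE)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    day <- sample(14:29, n, replace = TRUE)
    base <- ifelse(rk$population[i] == "western", 31.5, 28)
    base <- base + 0.4 * (seq_len(nrow(rk)) %% 3L)[i]  # among-rookery spread
    # rookery-specific sexual dimorphism so the full interaction is the truth
    nr_sex <- (c(-1, 1, 0, -0.5, 0.5, 1, -1, 0.5))[i] * (sex == "M")
    mass <- base + sex_dimorphism * (sex == "M") + nr_sex +
      beta_day[rk$population[i]] * day + stats::rnorm(n, 0, sigma)
    data.frame(mass = as.numeric(mass), nr = rk$rookery[i], sex = sex,
               population = rk$population[i], day = day,
               stringsAsFactors = FALSE)
  })
}
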