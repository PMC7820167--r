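#' Fit a multistate CJS model with state uncertainty
#'
#' Maximum-likelihood fitting of the hidden Markov formulation of the
#' multistate Cormack-Jolly-Seber model with latent weaning states. All four
#' parameters (survival `phi`, weaning probability `psi`, resighting
#' probability `p`, state-detection probability `delta`) use a logit link
#' with formula-based design matrices over the [design_data()] columns;
#' `phi` and `p` may depend on the latent weaning state through the term
#' `weanW`. Slots with non-NA `fix` values in the design data bypass the
#' link. Optimisation is quasi-Newton (BFGS) from `theta0` (default: zero on
#' the link scale, i.e. probabilities of one half), optionally with
#' additional jittered starts, and the covariance matrix is the inverse of a
#' central finite-difference Hessian of the negative log-likelihood at the
#' optimum.
#'
#' @param data an [as_mvms_data()] object.
#' @param formulas named list of model formulas for any of `phi`, `psi`,
#'   `p`, `delta`; missing entries default to `~1`.
#' @param ddl design data, default [design_data()]`(data)`; may be edited
#'   (e.g. `ddl$psi$fix[...] <- 0`) before fitting.
#' @param theta0 starting coefficient vector on the link scale.
#' @param starts number of optimisation starts; starts beyond the first are
#'   jittered by `rnorm(k, 0, jitter)` around `theta0` and the best optimum
#'   is kept.
#' @param jitter standard deviation of the start jitter.
#' @param seed seed for the jittered starts.
#' @param control passed to [stats::optim()] (BFGS).
#' @param hessian compute the Hessian and covariance matrix?
#' @return an object of class `mvms_fit` with elements `coefficients`,
#'   `vcov`, `loglik`, `AIC`, `npar`, `convergence`, `boundary` (TRUE when a
#'   free linear predictor exceeds 15 in absolute value, i.e. a probability
#'   estimated at the 0/1 boundary), `formulas`, `data`, `ddl` and `prep`.
#'   Estimates with `boundary = TRUE` should be read as 0/1 with collapsed
#'   intervals.
#' @seealso [aic_weights()], [slot_probabilities()], [bootstrap_ci()]
#' @export
fit_mvms <- function(data, formulas = list(), ddl = design_data(data),
                     theta0 = NULL, starts = 1L, jitter = 0.5, seed = NULL,
                     control = list(), hessian = TRUE) {
  stopifnot(inherits(data, "mvms_data"))
  prep <- prepare_mvms(data, formulas, ddl)
  k <- prep$k
  theta0 <- theta0 %||% numeric(k)
  if (length(theta0) != k)
    stop(sprintf("theta0 has length %d; model has %d free coefficients",
                 length(theta0), k), call. = FALSE)
  control <- utils::modifyList(list(maxit = 1000L, reltol = 1e-12), control)

  negll <- function(theta) {
    v <- -sum(forward_loglik_all(data, slot_probs(prep, theta)))
    if (!is.finite(v)) 1e10 else v
  }

  if (k == 0L) {
    val <- negll(numeric(0))
    fit <- list(par = numeric(0), value = val, convergence = 0L, counts = c(0L, 0L))
  } else {
    starts_mat <- matrix(rep(theta0, starts), ncol = starts)
    if (starts > 1L)
      starts_mat[, -1L] <- starts_mat[, -1L] +
        with_seed(seed, stats::rnorm(k * (starts - 1L), 0, jitter))
    fits <- lapply(seq_len(starts), function(s)
      stats::optim(starts_mat[, s], negll, method = "BFGS", control = control))
    fit <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
    # a long first line-search step can strand the optimiser on the flat
    # saturated part of the logit scale; pull extreme coefficients back to
    # a moderate value and re-optimise while that improves the likelihood
    for (round in 1:2) {
      if (slot_probs(prep, fit$par)$eta_max <= 15) break
      ref <- stats::optim(pmin(pmax(fit$par, -3), 3), negll, method = "BFGS",
                          control = control)
      if (ref$value < fit$value - 1e-8) fit <- ref else break
    }
  }
  if (fit$convergence != 0L)
    warning("optimiser reported non-convergence (code ", fit$convergence, ")",
            call. = FALSE)

  theta <- fit$par
  names(theta) <- prep$labels
  pr <- slot_probs(prep, theta)
  boundary <- pr$eta_max > 15

  vc <- NULL
  if (hessian && k > 0L) {
    H <- stats::optimHess(theta, negll)
    vc <- tryCatch(solve(H), error = function(e) {
      warning("Hessian is singular; using a pseudo-inverse", call. = FALSE)
      MASS::ginv(H)
    })
    vc <- (vc + t(vc)) / 2
    dimnames(vc) <- list(prep$labels, prep$labels)
  } else if (k == 0L) {
    vc <- matrix(0, 0L, 0L)
  }

  structure(list(
    coefficients = theta, vcov = vc,
    loglik = -fit$value, AIC = 2 * fit$value + 2 * k, npar = k,
    convergence = list(code = fit$convergence, counts = fit$counts,
                       message = fit$message %||% ""),
    boundary = boundary, formulas = prep$formulas,
    data = data, ddl = ddl, prep = prep,
    fingerprint = data_fingerprint(data)
  ), class = "mvms_fit")
}

data_fingerprint <- function(data) {
  c(n = data$n, T = data$T, seen = sum(data$seen), nS = sum(data$nS),
    nu = sum(data$nu), ns = sum(data$ns), rel = sum(data$release))
}

#' @export
print.mvms_fit <- function(x, ...) {
  cat("Multistate CJS (hidden Markov) fit\n")
  for (nm in names(x$formulas))
    cat(sprintf("  %-5s %s\n", nm, deparse(x$formulas[[nm]])))
  cat(sprintf("  logLik %.3f, npar %d, AIC %.2f\n", x$loglik, x$npar, x$AIC))
  if (x$boundary) cat("  note: estimate(s) at the 0/1 boundary\n")
  if (x$convergence$code != 0L) cat("  WARNING: non-convergence reported\n")
  invisible(x)
}

#' @export
coef.mvms_fit <- function(object, ...) object$coefficients

#' @export
vcov.mvms_fit <- function(object, ...) object$vcov

#' @export
logLik.mvms_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, class = "logLik")
}

#' @export
summary.mvms_fit <- function(object, ...) {
  se <- if (is.null(object$vcov) || !length(object$coefficients)) NULL else
    sqrt(pmax(diag(object$vcov), 0))
  tab <- data.frame(term = names(object$coefficients),
                    estimate = unname(object$coefficients),
                    se = if (is.null(se)) NA_real_ else unname(se))
  tab$z <- tab$estimate / tab$se
  structure(list(coefficients = tab, loglik = object$loglik,
                 AIC = object$AIC, npar = object$npar,
                 boundary = object$boundary), class = "summary.mvms_fit")
}

#' @export
print.summary.mvms_fit <- function(x, ...) {
  print(x$coefficients, digits = 4)
  cat(sprintf("logLik %.3f  AIC %.2f  npar %d\n", x$loglik, x$AIC, x$npar))
  invisible(x)
}

#' Real-scale parameter values per animal and occasion slot
#'
#' Applies the link and the fixed-value conventions to a coefficient vector,
#' returning the per-slot survival, weaning, resighting and state-detection
#' probabilities implied by a fitted model. Useful for derived quantities
#' and as the transformation step of the parametric bootstrap.
#'
#' @param fit an `mvms_fit`.
#' @param theta coefficient vector, default the MLE.
#' @return list of matrices: `phi_S`, `phi_W` (animals x intervals; survival
#'   of unweaned and weaned animals), `psi_S` (weaning probability per
#'   interval), `p_S`, `p_W`, `delta_S` (animals x primaries).
#' @export
slot_probabilities <- function(fit, theta = stats::coef(fit)) {
  stopifnot(inherits(fit, "mvms_fit"))
  pr <- slot_probs(fit$prep, theta)
  pr[c("phi_S", "phi_W", "psi_S", "p_S", "p_W", "delta_S")]
}

#' Akaike weights for a model set
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with
#' `Delta_i = AIC_i - min(AIC)`.
#'
#' @param fits either a numeric vector of AIC values or a list of
#'   `mvms_fit` objects fitted to the same dataset.
#' @return for numeric input, a numeric vector of weights summing to 1; for
#'   a list of fits, a data.frame with `npar`, `AIC`, `dAIC` and `weight`
#'   in the input order.
#' @examples
#' round(aic_weights(c(464.1, 471.2, 488.8)), 2)
#' @export
aic_weights <- function(fits) {
  if (is.numeric(fits)) {
    d <- fits - min(fits)
    w <- exp(-d / 2)
    return(w / sum(w))
  }
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, TRUE, "mvms_fit")))
  fp <- vapply(fits, `[[`, numeric(7L), "fingerprint")
  if (length(fits) > 1L && any(fp[, -1L, drop = FALSE] != fp[, 1L]))
    stop("models were fitted to different datasets", call. = FALSE)
  aic <- vapply(fits, `[[`, 0, "AIC")
  data.frame(model = names(fits) %||% seq_along(fits),
             npar = vapply(fits, `[[`, 0L, "npar"),
             AIC = aic, dAIC = aic - min(aic),
             weight = aic_weights(aic))
}
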