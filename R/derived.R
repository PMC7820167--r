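#' Compose two sequential weaning probabilities
#'
#' Combines the weaning probability over an early interval with that over
#' the following interval into the probability of having weaned by the end
#' of both: `a + (1 - a) * b`, algebraically equal to `1 - (1 - a)(1 - b)`.
#' Used to append the within-summer (EARLY-to-LATE) weaning probability to
#' the early-season estimates of two-season layouts so that all rookeries
#' share the same late-June seasonal cutoff.
#'
#' @param psi_early,psi_late probabilities in `[0, 1]` (vectorised).
#' @return composed probability, in `[0, 1]`.
#' @examples
#' compose_seasonal(0.836, 0.118)  # 0.855
#' @export
compose_seasonal <- function(psi_early, psi_late) {
  check_prob(psi_early, "psi_early")
  check_prob(psi_late, "psi_late")
  psi_early + (1 - psi_early) * psi_late
}

#' Cumulative proportion weaned by age
#'
#' Applies the recursion `W_1 = psi_1`, `W_x = W_{x-1} + (1 - W_{x-1}) *
#' psi_x` to a sequence of per-interval weaning probabilities, yielding the
#' cumulative proportion of pups weaned by the end of each age interval.
#'
#' @param psi numeric vector of interval weaning probabilities (first
#'   element: age 0 to 1).
#' @return numeric vector `W` of the same length; non-decreasing, in
#'   `[0, 1]`.
#' @examples
#' cumulative_weaning(c(0.616, 0.616, 0.905, 1.000))
#' @export
cumulative_weaning <- function(psi) {
  if (length(psi) == 0L) stop("`psi` must contain at least one interval",
                              call. = FALSE)
  check_prob(psi, "psi")
  W <- numeric(length(psi))
  W[1L] <- psi[1L]
  for (x in seq_along(psi)[-1L]) W[x] <- W[x - 1L] + (1 - W[x - 1L]) * psi[x]
  W
}

#' Within-primary probability of detecting the unweaned state
#'
#' With per-sighting state-detection probability `delta` and `ns` sightings
#' within a primary occasion, the probability that at least one sighting
#' shows the definitive suckling code is `1 - (1 - delta)^ns`; it approaches
#' 1 geometrically as `ns` grows, which is the reason for the robust design.
#'
#' @param delta per-sighting state-detection probability.
#' @param ns number of sightings within the primary (integer >= 1).
#' @return probability of classifying the animal as unweaned.
#' @examples
#' detection_within_primary(0.226, 5)  # 0.722
#' @export
detection_within_primary <- function(delta, ns) {
  check_prob(delta, "delta")
  if (any(ns < 1L) || any(ns != round(ns)))
    stop("`ns` must be an integer >= 1", call. = FALSE)
  1 - (1 - delta)^ns
}

#' Parametric bootstrap confidence intervals for derived quantities
#'
#' Draws coefficient vectors from a multivariate normal centred at the
#' maximum-likelihood estimate with the estimated covariance matrix (the
#' inverse negative Hessian of the log-likelihood), transforms each draw to
#' the derived scale with `derived_fn`, and returns equal-tailed percentile
#' intervals. Because draws are taken on the link scale and transformed,
#' derived probabilities respect `[0, 1]` by construction.
#'
#' @param fit an `mvms_fit` (or any list with `coefficients` and `vcov`).
#' @param derived_fn function mapping a coefficient vector to a numeric
#'   vector of derived quantities (through the links and composition
#'   operations, e.g. via [slot_probabilities()] and
#'   [cumulative_weaning()]).
#' @param n_boot number of bootstrap draws (default 10000).
#' @param seed integer seed for the draws.
#' @param level confidence level, default 0.95.
#' @return list of class `wean_ci` with `estimate`, `lower`, `upper`,
#'   `level`, `n_boot`.
#' @export
bootstrap_ci <- function(fit, derived_fn, n_boot = 10000L, seed = NULL,
                         level = 0.95) {
  theta <- fit$coefficients
  vc <- fit$vcov
  if (is.null(vc)) stop("fit has no covariance matrix", call. = FALSE)
  est <- derived_fn(theta)
  k <- length(theta)
  if (k == 0L || all(vc == 0)) {
    draws <- matrix(rep(est, each = n_boot), n_boot)
  } else {
    ev <- eigen(vc, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      warning("covariance matrix is not positive semi-definite; projecting",
              call. = FALSE)
      es <- eigen(vc, symmetric = TRUE)
      vc <- es$vectors %*% diag(pmax(es$values, 0), k) %*% t(es$vectors)
    }
    th <- with_seed(seed, MASS::mvrnorm(n_boot, theta, vc, tol = 1e-6))
    if (is.null(dim(th))) th <- matrix(th, ncol = k)
    draws <- t(apply(th, 1L, derived_fn))
    if (length(est) == 1L) draws <- matrix(as.vector(draws), ncol = 1L)
  }
  alpha <- (1 - level) / 2
  lower <- apply(draws, 2L, stats::quantile, probs = alpha, names = FALSE)
  upper <- apply(draws, 2L, stats::quantile, probs = 1 - alpha, names = FALSE)
  structure(list(estimate = est, lower = lower, upper = upper,
                 level = level, n_boot = n_boot), class = "wean_ci")
}

#' @export
print.wean_ci <- function(x, ...) {
  df <- data.frame(estimate = x$estimate, lower = x$lower, upper = x$upper)
  cat(sprintf("%d%% parametric bootstrap intervals (%d draws)\n",
              round(100 * x$level), x$n_boot))
  print(df, digits = 4)
  invisible(x)
}

#' Cumulative weaning schedules for the study groups
#'
#' Builds the per-group cumulative proportions weaned by ages 1-4 from a
#' table of interval weaning-probability estimates shaped like
#' [steller_psi_estimates()]: Southeast Alaska sexes use the annual
#' sequence (`a01`, `a01`, `a2`, `a3p`); Gulf of Alaska rookeries first
#' compose their early-season `a0*` and `a1*` estimates with the shared
#' within-summer probability `a01summer`, then continue the recursion with
#' the annual `a2p` rate for ages 3 and 4.
#'
#' @param psi_table data.frame with columns `group`, `parameter`,
#'   `estimate`.
#' @return data.frame with columns `group`, `age` (1-4) and `W` (cumulative
#'   proportion weaned).
#' @examples
#' weaning_by_group(steller_psi_estimates())
#' @export
weaning_by_group <- function(psi_table) {
  stopifnot(all(c("group", "parameter", "estimate") %in% names(psi_table)))
  get <- function(g, par) {
    v <- psi_table$estimate[psi_table$group == g & psi_table$parameter == par]
    if (length(v) != 1L)
      stop(sprintf("need exactly one estimate for %s / %s", g, par),
           call. = FALSE)
    v
  }
  goa_groups <- unique(psi_table$group[psi_table$parameter == "a0"])
  seak_groups <- unique(psi_table$group[psi_table$parameter == "a01"])
  out <- list()
  for (g in seak_groups) {
    psi <- c(get(g, "a01"), get(g, "a01"), get(g, "a2"), get(g, "a3p"))
    out[[g]] <- data.frame(group = g, age = 1:4, W = cumulative_weaning(psi))
  }
  if (length(goa_groups)) {
    s <- get("GOA", "a01summer")
    a2p <- get("GOA", "a2p")
    for (g in goa_groups) {
      psi <- c(compose_seasonal(get(g, "a0"), s),
               compose_seasonal(get(g, "a1"), s), a2p, a2p)
      out[[g]] <- data.frame(group = g, age = 1:4, W = cumulative_weaning(psi))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
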