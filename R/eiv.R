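#' Errors-in-variables linear regression by maximum likelihood
#'
#' Fits `y = alpha + beta * xi` where both the predictor and the response
#' are measured with known error: observed `x_i ~ N(xi_i, se_x_i^2)` and
#' `y_i ~ N(alpha + beta * xi_i, se_y_i^2)`. Ignoring the predictor error
#' (ordinary least squares) attenuates the slope toward zero; the
#' errors-in-variables likelihood corrects this, which matters when relating
#' derived life-history estimates (each with its own standard error) across
#' a handful of rookeries.
#'
#' Two likelihoods are available. The default `"structural"` form treats the
#' latent `xi_i` as draws from `N(mu, tau^2)`, so each pair `(x_i, y_i)` is
#' bivariate normal with covariance `beta * tau^2`; this avoids the
#' incidental-parameter problem at small n and yields a likelihood-ratio
#' test of `beta = 0`. The `"functional"` form profiles the `xi_i` out as
#' incidental parameters, equivalent to minimising
#' `sum (y - a - b x)^2 / (se_y^2 + b^2 se_x^2)`. With equal measurement
#' errors on both axes, both reduce to orthogonal (Deming) regression; with
#' all errors zero the fit falls back to ordinary least squares.
#'
#' @param data data.frame with columns `x`, `se_x`, `y`, `se_y` and
#'   optionally `label` (one row per unit, e.g. rookery).
#' @param method `"structural"` (default) or `"functional"`.
#' @return object of class `eiv_fit`: list with `coefficients`
#'   (`intercept`, `slope`), `se` (for the structural method), `mu`, `tau2`,
#'   `loglik`, `p_value` (structural likelihood-ratio test of zero slope),
#'   `method`, `n`, and `note` (non-NULL when the OLS fallback was used).
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 4), se_x = 0.1,
#'                 y = c(2.1, 1.4, 1.2, 0.4), se_y = 0.1)
#' fit_eiv(d)
#' @export
fit_eiv <- function(data, method = c("structural", "functional")) {
  method <- match.arg(method)
  need <- c("x", "se_x", "y", "se_y")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("EIV data lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- data$x; y <- data$y; sx <- data$se_x; sy <- data$se_y
  n <- length(x)
  if (n < 3L) stop("need at least 3 units to estimate a slope", call. = FALSE)
  if (any(sx < 0) || any(sy < 0))
    stop("standard errors must be non-negative", call. = FALSE)

  if (all(sx == 0) && all(sy == 0)) {
    ols <- stats::lm(y ~ x)
    co <- stats::coef(ols)
    return(structure(list(
      coefficients = c(intercept = unname(co[1L]), slope = unname(co[2L])),
      se = c(intercept = summary(ols)$coefficients[1L, 2L],
             slope = summary(ols)$coefficients[2L, 2L]),
      mu = mean(x), tau2 = stats::var(x), loglik = NA_real_,
      p_value = summary(ols)$coefficients[2L, 4L],
      method = "ols", n = n,
      note = "all measurement errors are zero; ordinary least squares used"
    ), class = "eiv_fit"))
  }

  ols_b <- stats::cov(x, y) / stats::var(x)
  ols_a <- mean(y) - ols_b * mean(x)
  sy2g <- pmax(sy^2, 1e-12)  # guard for exact-zero response errors

  if (method == "functional") {
    # profile the incidental xi_i and the intercept out: minimise
    # sum (y - a - b x)^2 / (se_y^2 + b^2 se_x^2) over b alone
    alpha_of <- function(b) {
      w <- 1 / (sy2g + b^2 * sx^2)
      sum(w * (y - b * x)) / sum(w)
    }
    Qb <- function(b) {
      a <- alpha_of(b)
      sum((y - a - b * x)^2 / (sy2g + b^2 * sx^2))
    }
    b_hat <- refine_1d(Qb, ols_b)
    a_hat <- alpha_of(b_hat)
    return(structure(list(
      coefficients = c(intercept = a_hat, slope = b_hat),
      se = c(intercept = NA_real_, slope = NA_real_),
      mu = mean(x), tau2 = NA_real_, loglik = -Qb(b_hat) / 2,
      p_value = NA_real_, method = method, n = n, note = NULL
    ), class = "eiv_fit"))
  }

  # structural likelihood, profiled in stages: for given slope b and latent
  # variance t2, the mean parameters (mu, alpha) are a closed-form GLS
  # solution; t2 is profiled by 1-d optimisation, then b by 1-d optimisation.
  nll_full <- function(a, b, mu, t2) {
    v11 <- t2 + sx^2
    v22 <- b^2 * t2 + sy2g
    v12 <- b * t2
    dt <- v11 * v22 - v12^2
    dx <- x - mu; dy <- y - a - b * mu
    0.5 * sum(2 * log(2 * pi) + log(dt) +
                (v22 * dx^2 - 2 * v12 * dx * dy + v11 * dy^2) / dt)
  }
  mean_gls <- function(b, t2) {
    v11 <- t2 + sx^2
    v22 <- b^2 * t2 + sy2g
    v12 <- b * t2
    dt <- v11 * v22 - v12^2
    i11 <- v22 / dt; i12 <- -v12 / dt; i22 <- v11 / dt
    # mean vector is A %*% c(mu, alpha) with A = rbind(c(1, 0), c(b, 1))
    a11 <- sum(i11 + 2 * b * i12 + b^2 * i22)
    a12 <- sum(i12 + b * i22)
    a22 <- sum(i22)
    r1 <- sum(i11 * x + i12 * y + b * (i12 * x + i22 * y))
    r2 <- sum(i12 * x + i22 * y)
    d2 <- a11 * a22 - a12^2
    c(mu = (r1 * a22 - r2 * a12) / d2, alpha = (a11 * r2 - a12 * r1) / d2)
  }
  lt_lo <- log(max(stats::var(x), mean(sx^2), 1e-8)) - 30
  lt_hi <- log(max(stats::var(x), mean(sx^2), 1e-8)) + 5
  prof_t2 <- function(b) {
    stats::optimize(function(lt) {
      m <- mean_gls(b, exp(lt))
      nll_full(m[["alpha"]], b, m[["mu"]], exp(lt))
    }, c(lt_lo, lt_hi), tol = 1e-12)
  }
  pnll <- function(b) prof_t2(b)$objective
  b_hat <- refine_1d(pnll, ols_b)
  t2_hat <- exp(prof_t2(b_hat)$minimum)
  m_hat <- mean_gls(b_hat, t2_hat)
  value <- nll_full(m_hat[["alpha"]], b_hat, m_hat[["mu"]], t2_hat)
  if (t2_hat < 1e-8 * max(stats::var(x), mean(sx^2)))
    warning(paste("slope is weakly identified: the estimated latent spread is",
                  "negligible relative to the predictor measurement error"),
            call. = FALSE)

  # null model (beta = 0): x and y decouple, closed-form means
  nll0 <- function(lt) {
    t2 <- exp(lt)
    vx <- t2 + sx^2
    mu <- sum(x / vx) / sum(1 / vx)
    a <- sum(y / sy2g) / sum(1 / sy2g)
    0.5 * sum(log(2 * pi * vx) + (x - mu)^2 / vx) +
      0.5 * sum(log(2 * pi * sy2g) + (y - a)^2 / sy2g)
  }
  value0 <- stats::optimize(nll0, c(lt_lo, lt_hi), tol = 1e-12)$objective
  lrt <- 2 * (value0 - value)
  p <- stats::pchisq(max(lrt, 0), df = 1L, lower.tail = FALSE)

  se <- rep(NA_real_, 2L)
  par_hat <- c(m_hat[["alpha"]], b_hat, m_hat[["mu"]], log(t2_hat))
  H <- tryCatch(stats::optimHess(par_hat, function(par)
    nll_full(par[1L], par[2L], par[3L], exp(par[4L]))),
    error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) se <- sqrt(pmax(diag(V)[1:2], 0))
  }

  structure(list(
    coefficients = c(intercept = m_hat[["alpha"]], slope = b_hat),
    se = c(intercept = se[1L], slope = se[2L]),
    mu = m_hat[["mu"]], tau2 = t2_hat,
    loglik = -value, p_value = p, method = method, n = n, note = NULL
  ), class = "eiv_fit")
}

# high-precision 1-d minimisation around a starting value, widening the
# bracket until the optimum is interior
refine_1d <- function(fn, b0, width = NULL) {
  width <- width %||% max(1, 2 * abs(b0))
  for (i in 1:8) {
    o <- stats::optimize(fn, c(b0 - width, b0 + width), tol = 1e-12)
    at_edge <- min(o$minimum - (b0 - width), (b0 + width) - o$minimum) <
      1e-6 * width
    if (!at_edge) return(newton_polish(fn, o$minimum))
    b0 <- o$minimum
    width <- width * 4
  }
  newton_polish(fn, o$minimum)
}

# central-difference Newton steps past Brent's sqrt(eps) accuracy floor
newton_polish <- function(fn, b, h = NULL) {
  h <- h %||% max(1e-6, 1e-6 * abs(b))
  for (i in 1:4) {
    fp <- fn(b + h); fm <- fn(b - h); f0 <- fn(b)
    g <- (fp - fm) / (2 * h)
    hess <- (fp - 2 * f0 + fm) / h^2
    if (!is.finite(g) || !is.finite(hess) || hess <= 0) break
    step <- g / hess
    if (!is.finite(step) || abs(step) > 1) break
    b <- b - step
    if (abs(step) < 1e-13) break
  }
  b
}

#' @export
print.eiv_fit <- function(x, ...) {
  cat(sprintf("Errors-in-variables regression (%s), n = %d\n", x$method, x$n))
  cat(sprintf("  intercept %.4f (SE %.4f)\n", x$coefficients[1L], x$se[1L]))
  cat(sprintf("  slope     %.4f (SE %.4f)\n", x$coefficients[2L], x$se[2L]))
  if (is.finite(x$p_value %||% NA))
    cat(sprintf("  LRT p-value (slope = 0): %.4g\n", x$p_value))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
coef.eiv_fit <- function(object, ...) object$coefficients

#' Deming (orthogonal) regression
#'
#' Closed-form errors-in-variables slope when the ratio of measurement-error
#' variances `lambda = var_y / var_x` is known; `lambda = 1` is orthogonal
#' regression. Used as an independent cross-check of [fit_eiv()].
#'
#' @param x,y observed values.
#' @param lambda error-variance ratio.
#' @return named vector `intercept`, `slope`.
#' @export
deming_regression <- function(x, y, lambda = 1) {
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  b <- (syy - lambda * sxx + sqrt((syy - lambda * sxx)^2 +
                                  4 * lambda * sxy^2)) / (2 * sxy)
  c(intercept = mean(y) - b * mean(x), slope = b)
}
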