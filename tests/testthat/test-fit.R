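test_that("a model with every parameter fixed at truth just evaluates the likelihood", {
  sml <- small_sim_data(n = 150, seed = 31)
  md <- sml$data
  ddl <- design_data(md)
  ddl$phi$fix[ddl$phi$age == 0] <- 0.55
  ddl$phi$fix[is.na(ddl$phi$fix)] <- 0.85
  ddl$psi$fix <- ifelse(ddl$psi$age <= 1, 0.6, 0.9)
  ddl$p$fix <- 0.8
  ddl$delta$fix <- 0.25
  fit <- fit_mvms(md, formulas = list(phi = ~0, psi = ~0, p = ~0, delta = ~0),
                  ddl = ddl)
  expect_identical(fit$npar, 0L)
  expect_equal(fit$AIC, -2 * fit$loglik, tolerance = 1e-12)
  pr <- slot_probabilities(fit)
  expect_true(all(pr$psi_S %in% c(0.6, 0.9)))
  # likelihood equals the per-animal recursion at the fixed values
  ll <- sum(vapply(seq_len(md$n), function(i)
    forward_loglik(md$seen[i, ], md$nS[i, ], md$nu[i, ], md$release[i],
                   phi = pr$phi_S[i, ], psi = pr$psi_S[i, ],
                   p = pr$p_S[i, ], delta = pr$delta_S[i, ]), 0))
  expect_equal(fit$loglik, ll, tolerance = 1e-10)
})

test_that("fitting the generating model recovers the truth within 3 SEs", {
  sml <- small_sim_data(n = 900, seed = 57)
  md <- sml$data
  ddl <- design_data(md)
  ddl$psi$wage2 <- ifelse(ddl$psi$wage %in% c("a0", "a1"), "a01", "a2p")
  fit <- fit_mvms(md, formulas = list(phi = ~firstyear, psi = ~wage2,
                                      p = ~1, delta = ~1), ddl = ddl)
  truth <- c(qlogis(0.85), qlogis(0.55) - qlogis(0.85),
             qlogis(0.6), qlogis(0.9) - qlogis(0.6),
             qlogis(0.8), qlogis(0.25))
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(coef(fit) - truth) < 3 * se))
  expect_identical(fit$convergence$code, 0L)
  expect_false(fit$boundary)
  # vcov is symmetric positive semi-definite at the interior optimum
  expect_true(all(eigen(fit$vcov, symmetric = TRUE)$values > 0))
})

test_that("weaning-state-dependent resighting is estimable via the weanW term", {
  # simulate with equal p for both states, fit p ~ weanW: the weanW
  # coefficient should be small and the model must not error
  sml <- small_sim_data(n = 500, seed = 77)
  fit <- fit_mvms(sml$data, formulas = list(phi = ~firstyear, psi = ~1,
                                            p = ~weanW, delta = ~1))
  expect_true("p:weanW" %in% names(coef(fit)))
  expect_lt(abs(coef(fit)[["p:weanW"]]),
            3 * sqrt(diag(fit$vcov)[["p:weanW"]]) + 1)
  # weanW is rejected in psi and delta models (the W state cannot wean
  # again, and detecting the weaned state is impossible by convention)
  expect_error(fit_mvms(sml$data, formulas = list(psi = ~weanW)), "weanW")
  expect_error(fit_mvms(sml$data, formulas = list(delta = ~weanW)), "weanW")
})

test_that("rank-deficient designs trigger a warning naming aliased columns", {
  sml <- small_sim_data(n = 100, seed = 41)
  ddl <- design_data(sml$data)
  ddl$phi$dup <- ddl$phi$firstyear
  expect_warning(
    fit_mvms(sml$data, formulas = list(phi = ~firstyear + dup), ddl = ddl,
             hessian = FALSE),
    "aliased")
})

test_that("theta length mismatches are rejected", {
  sml <- small_sim_data(n = 60, seed = 5)
  fit <- fit_mvms(sml$data, hessian = FALSE)
  expect_error(dataset_loglik(fit, c(coef(fit), 0)), "free coefficients")
  expect_error(fit_mvms(sml$data, theta0 = numeric(10)), "theta0")
})

test_that("AIC weights follow the exp(-dAIC/2) formula and sum to one", {
  expect_identical(aic_weights(100), 1)
  expect_equal(aic_weights(c(10, 10)), c(0.5, 0.5))
  w <- aic_weights(c(464.1, 471.2, 488.8, 496.9, 546.5, 568.4, 811.3,
                     1465.3, 1466.1))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(round(w, 2), c(0.97, 0.03, rep(0, 7)))
  # list-of-fits interface enforces a common dataset
  a <- small_sim_data(n = 60, seed = 6)
  b <- small_sim_data(n = 61, seed = 6)
  fa <- fit_mvms(a$data, hessian = FALSE)
  fb <- fit_mvms(b$data, hessian = FALSE)
  expect_error(aic_weights(list(fa, fb)), "different datasets")
  tab <- aic_weights(list(m0 = fa, m0b = fa))
  expect_equal(tab$weight, c(0.5, 0.5))
})

test_that("two-season layouts fit with summer intervals closed to mortality", {
  sc <- sim_scenario(n_individuals = 700, n_cohorts = 1, n_years = 4,
                     seasons_per_year = 2, phi_by_age = c(0.6, 0.85),
                     psi_by_age = 0.5, psi_summer = 0.2, seed = 314)
  sim <- simulate_encounters(sc)
  ds <- encode_dataset(sim$records, sim$covariates, sim$layout, seed = 315)
  md <- as_mvms_data(ds)
  expect_identical(sum(md$interval_type == "summer"), 4L)
  ddl <- design_data(md)
  # within-summer survival is fixed to 1 before any formula applies
  expect_true(all(ddl$phi$fix[ddl$phi$interval_type == "summer"] == 1))
  ddl$psi$summer <- as.integer(ddl$psi$interval_type == "summer")
  fit <- fit_mvms(md, formulas = list(phi = ~firstyear, psi = ~summer,
                                      p = ~1, delta = ~1), ddl = ddl,
                  control = list(reltol = 1e-9))
  pr <- slot_probabilities(fit)
  expect_true(all(pr$phi_S[, md$interval_type == "summer"] == 1))
  co <- coef(fit)
  expect_lt(abs(plogis(co[["psi:(Intercept)"]]) - 0.5), 0.1)
  expect_lt(abs(plogis(co[["psi:(Intercept)"]] + co[["psi:summer"]]) - 0.2), 0.1)
})
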