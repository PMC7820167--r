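test_that("scenario validation rejects bad inputs, naming the field", {
  expect_error(sim_scenario(delta = 1.2), "delta")
  expect_error(sim_scenario(phi_by_age = c(0.5, -0.1)), "phi_by_age")
  expect_error(sim_scenario(n_years = 1), "n_years")
  expect_error(sim_scenario(ns_distribution = c(0.5, 0.5)), "ns_distribution")
  expect_error(sim_scenario(n_cohorts = 5, n_years = 5), "n_cohorts")
})

test_that("weaned and dead are absorbing; psi = 0 means nobody ever weans", {
  sc <- sim_scenario(n_individuals = 400, n_cohorts = 1, n_years = 5,
                     psi_by_age = 0, seed = 11)
  sim <- simulate_encounters(sc)
  expect_true(all(sim$truth$state %in% c("S", "D")))
  # absorbing death: no non-dead state after a dead state for any animal
  by_animal <- split(sim$truth$state, sim$truth$animal_id)
  expect_true(all(vapply(by_animal, function(s) {
    d <- which(s == "D")
    !length(d) || all(s[seq.int(min(d), length(s))] == "D")
  }, TRUE)))
  # no sighting records of dead animals
  key_rec <- paste(sim$records$animal_id, sim$records$year, sim$records$season)
  key_dead <- with(sim$truth[sim$truth$state == "D", ],
                   paste(animal_id, year, season))
  expect_length(intersect(key_rec, key_dead), 0)
})

test_that("perfect observation limit: seen every primary, always coded S", {
  sc <- sim_scenario(n_individuals = 200, n_cohorts = 1, n_years = 4,
                     phi_by_age = 1, psi_by_age = 0, p = 1, delta = 1,
                     ns_distribution = c(1, 0, 0, 0, 0), seed = 3)
  sim <- simulate_encounters(sc)
  expect_true(all(sim$records$code == "S"))
  # every animal has exactly one record per primary
  tab <- table(sim$records$animal_id)
  expect_true(all(tab == sc$n_years))
})

test_that("latent weaning rate matches the generative psi at age 1", {
  sc <- sim_scenario(n_individuals = 5000, n_cohorts = 1, n_years = 3,
                     psi_by_age = 0.6, seed = 7)
  sim <- simulate_encounters(sc)
  age1 <- sim$truth[sim$truth$year == 2002 & sim$truth$state != "D", ]
  phat <- mean(age1$state == "W")
  se <- sqrt(0.6 * 0.4 / nrow(age1))
  expect_lt(abs(phat - 0.6), 2 * se)
})

test_that("observed S-coding frequency follows 1 - (1 - delta)^ns", {
  sc <- sim_scenario(n_individuals = 5000, n_cohorts = 1, n_years = 3,
                     psi_by_age = 0.2, delta = 0.25, seed = 19)
  sim <- simulate_encounters(sc)
  truly_S <- sim$truth[sim$truth$state == "S", ]
  key <- paste(sim$records$animal_id, sim$records$year)
  cohort <- sim$covariates$cohort[match(sim$records$animal_id,
                                        sim$covariates$animal_id)]
  rec_S <- sim$records[key %in% paste(truly_S$animal_id, truly_S$year) &
                         sim$records$year > cohort, ]
  grp <- split(rec_S$code, paste(rec_S$animal_id, rec_S$year))
  ns <- lengths(grp)
  anyS <- vapply(grp, function(co) any(co == "S"), TRUE)
  for (k in 1:3) {
    sel <- ns == k
    expect_gt(sum(sel), 100)
    expected <- 1 - (1 - 0.25)^k
    se <- sqrt(expected * (1 - expected) / sum(sel))
    expect_lt(abs(mean(anyS[sel]) - expected), 2 * se)
  }
  # weaned animals never show a definitive code
  truly_W <- sim$truth[sim$truth$state == "W", ]
  rec_W <- sim$records[key %in% paste(truly_W$animal_id, truly_W$year), ]
  expect_true(all(rec_W$code == "u"))
})

test_that("two-season scenarios produce EARLY/LATE primaries and summer weaning", {
  sc <- sim_scenario(n_individuals = 800, n_cohorts = 1, n_years = 3,
                     seasons_per_year = 2, psi_by_age = 0.3, psi_summer = 0.4,
                     phi_by_age = 1, seed = 5)
  sim <- simulate_encounters(sc)
  expect_setequal(unique(sim$records$season), c("E", "L"))
  # weaning between EARLY and LATE of the same year happens at rate psi_summer
  tr <- sim$truth
  e <- tr[tr$year == 2002 & tr$season == "E" & tr$state == "S", "animal_id"]
  l <- tr[tr$year == 2002 & tr$season == "L", ]
  l <- l[l$animal_id %in% e, ]
  phat <- mean(l$state == "W")
  se <- sqrt(0.4 * 0.6 / nrow(l))
  expect_lt(abs(phat - 0.4), 2 * se)
})

test_that("encounter files round-trip losslessly and reject bad rows", {
  sim <- simulate_encounters(sim_scenario(n_individuals = 30, n_cohorts = 1,
                                          n_years = 3, seed = 2))
  f <- tempfile(fileext = ".tsv")
  write_encounters(sim$records, f)
  expect_identical(read_encounters(f), sim$records)

  # empty collection: header-only file, read returns empty
  write_encounters(sim$records[0, ], f)
  expect_identical(nrow(read_encounters(f)), 0L)

  bad <- sim$records
  bad$code[5] <- "X"
  f2 <- tempfile(fileext = ".tsv")
  utils::write.table(bad, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_encounters(f2), "\"X\".*row 5")
})
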