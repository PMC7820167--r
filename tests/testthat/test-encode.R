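worked_records <- function() {
  data.frame(
    animal_id = "A1",
    year = c(2000, rep(2001, 3), rep(2002, 7)),
    season = "S",
    code = c("S", "u", "u", "S", "u", "u", "u", "S", "u", "u", "u"),
    site_class = "R",
    stringsAsFactors = FALSE
  )
}

test_that("the worked four-primary encoding example is reproduced", {
  lay <- occasion_layout(2000:2003)
  h <- build_history(worked_records(), cohort = 2000, layout = lay, seed = 1)
  s <- history_strings(h)
  expect_identical(s[1], "S0000")        # release year
  expect_identical(s[2], "uuS00")        # 3 sightings at age 1
  expect_identical(s[4], "00000")        # unseen at age 3
  # age 2: exactly 5 of the 7 codes retained, in record order
  codes3 <- strsplit(s[3], "")[[1]]
  expect_identical(sum(codes3 != "0"), 5L)
  expect_true(all(codes3 %in% c("S", "u")))
  expect_identical(h$ns, c(1L, 3L, 7L, 1L))
})

test_that("an animal never resighted gets release S and all-zero primaries", {
  lay <- occasion_layout(2000:2003)
  rec <- worked_records()[1, ]
  h <- build_history(rec, cohort = 2000, layout = lay)
  expect_identical(history_strings(h), c("S0000", "00000", "00000", "00000"))
  expect_identical(h$ns, rep(1L, 4))  # placeholder ns for unseen primaries
})

test_that("haul-out sightings are always retained when selecting 5 of x", {
  lay <- occasion_layout(2000:2002)
  rec <- data.frame(
    animal_id = "A1", year = c(2000, rep(2001, 6)), season = "S",
    code = c("S", "S", "u", "u", "S", "u", "u"),
    site_class = c("R", "H", "R", "R", "H", "R", "R"),
    stringsAsFactors = FALSE
  )
  # the two haul-out records carry the only S codes at age 1
  for (seed in 1:50) {
    h <- build_history(rec, cohort = 2000, layout = lay, seed = seed)
    expect_identical(sum(h$obs[2, ] == "S"), 2L)
    expect_identical(h$ns[2], 6L)
  }
  # more than five haul-outs: five of them, uniformly
  rec$site_class <- c("R", rep("H", 6))
  h <- build_history(rec, cohort = 2000, layout = lay, seed = 4)
  expect_identical(sum(h$obs[2, ] != "0"), 5L)
})

test_that("under chance-respecting selection an S at a haul-out is never dropped", {
  # exhaustive property: with x = 6, one S code at a haul-out, the S survives
  # every possible uniform fill of the remaining rookery slots
  lay <- occasion_layout(2000:2002)
  base <- data.frame(
    animal_id = "A1", year = c(2000, rep(2001, 6)), season = "S",
    code = c("S", "S", rep("u", 5)),
    site_class = c("R", "H", rep("R", 5)),
    stringsAsFactors = FALSE
  )
  kept <- vapply(1:64, function(s) {
    h <- build_history(base, cohort = 2000, layout = lay, seed = s)
    any(h$obs[2, ] == "S")
  }, TRUE)
  expect_true(all(kept))
})

test_that("re-encoding with the same seed is bit-identical", {
  sim <- simulate_encounters(sim_scenario(n_individuals = 120, n_cohorts = 2,
                                          n_years = 5, seed = 8,
                                          ns_distribution = ns_geometric(0.2)))
  d1 <- encode_dataset(sim$records, sim$covariates, sim$layout, seed = 99)
  d2 <- encode_dataset(sim$records, sim$covariates, sim$layout, seed = 99)
  expect_identical(d1$codes, d2$codes)
  expect_identical(d1$ns, d2$ns)
})

test_that("adults carry data only in the first secondary slot with ns = 1", {
  lay <- occasion_layout(2000:2005)
  rec <- data.frame(
    animal_id = "A1", year = c(2000, rep(2004, 3)), season = "S",
    code = c("S", "u", "u", "u"), site_class = "R",
    stringsAsFactors = FALSE
  )
  h <- build_history(rec, cohort = 2000, layout = lay)
  expect_identical(h$obs[5, ], c("u", "0", "0", "0", "0"))
  expect_identical(h$ns[5], 1L)
})

test_that("occasion layouts have the documented column counts", {
  expect_identical(n_columns(seak_layout()), 54L)
  expect_identical(n_columns(goa_layout()), 161L)
  expect_identical(n_columns(occasion_layout(2001:2003)), 15L)
  sim <- simulate_encounters(sim_scenario(n_individuals = 40, n_cohorts = 1,
                                          n_years = 3, seed = 1))
  ds <- encode_dataset(sim$records, sim$covariates, sim$layout, seed = 1)
  expect_identical(ncol(ds$codes), 15L)
  expect_identical(nrow(ds$occasion_map), 15L)
  # occasion map indexes every column by year, season and secondary slot
  expect_identical(ds$occasion_map$column, 1:15)
  expect_identical(unique(ds$occasion_map$secondary), 1:5)
})

test_that("encoding errors are informative", {
  lay <- occasion_layout(2000:2002)
  two <- rbind(worked_records()[1:2, ],
               transform(worked_records()[1, ], animal_id = "A2"))
  expect_error(build_history(two, cohort = 2000, layout = lay),
               "multiple animals")
  early <- data.frame(animal_id = "A1", year = 1999, season = "S",
                      code = "u", site_class = "R")
  expect_error(build_history(early, cohort = 2000, layout = lay),
               "before its release year")
  late <- data.frame(animal_id = "A1", year = 2010, season = "S",
                     code = "u", site_class = "R")
  expect_error(build_history(late, cohort = 2000, layout = lay),
               "outside the occasion calendar")
  # assembling histories built on a different calendar fails
  h <- build_history(worked_records(), cohort = 2000,
                     layout = occasion_layout(2000:2003), seed = 1)
  expect_error(assemble_dataset(list(h), lay), "calendar")
})

test_that("history files round-trip through write_histories", {
  sim <- simulate_encounters(sim_scenario(n_individuals = 25, n_cohorts = 1,
                                          n_years = 3, seed = 13))
  ds <- encode_dataset(sim$records, sim$covariates, sim$layout, seed = 2)
  f <- tempfile(fileext = ".txt")
  write_histories(ds, f)
  df <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_identical(df$history, unname(history_strings(ds)))
  expect_true(file.exists(paste0(f, ".occasions.tsv")))
})
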