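# Synthetic weighted survey population generator.

test_that("empty and deterministic generation", {
  cfg <- synth_config(n_records = 0)
  empty <- generate_population(cfg)
  expect_equal(nrow(empty), 0)
  expect_equal(sum(empty$weight), 0)

  cfg <- synth_config(n_records = 300, seed = 99)
  expect_identical(generate_population(cfg), generate_population(cfg))
  # a different seed produces a different draw
  expect_false(identical(generate_population(cfg),
                         generate_population(cfg, seed = 100)))
})

test_that("generated records satisfy the survey-record invariants", {
  pop <- generate_population(synth_config(n_records = 1000, seed = 5))
  expect_equal(nrow(pop), 1000)
  expect_true(all(pop$weight > 0))
  expect_equal(sum(pop$weight), 3857703, tolerance = 1e-3)
  mins <- pop[, c("transport_min", "leisure_min", "other_min", "vigorous_min")]
  expect_true(all(mins >= 0))
  expect_true(all(pop$vigorous_min <=
                    pop$transport_min + pop$leisure_min + pop$other_min + 1e-9))
  expect_true(all(pop$age_years >= 20 & pop$age_years <= 64))
  expect_true(all(pop$bmi > 15 & pop$bmi < 50))
})

test_that("derived step bands and activity categories are internally consistent", {
  pop <- generate_population(synth_config(n_records = 2000, seed = 6))
  prof <- activity_profile(pop)
  # the step band is a deterministic function of transport minutes
  expect_equal(prof$daily_steps, pop$transport_min * 100 / 7)
  # category from recomputed MET-minutes matches the stored minutes
  expect_equal(as.character(prof$activity_category),
               as.character(classify_activity(
                 met_minutes(pop$transport_min, pop$leisure_min,
                             pop$other_min, pop$vigorous_min))))
})

test_that("weighted marginals are recovered within 2 percentage points", {
  cfg <- synth_config(n_records = 5000, seed = 21)
  pop <- generate_population(cfg)
  s <- summarize_population(pop)
  for (char in names(cfg$marginals)) {
    target <- 100 * cfg$marginals[[char]]
    got <- s$pct[s$characteristic == char]
    names(got) <- s$category[s$characteristic == char]
    for (cat in names(target)) {
      expect_lt(abs(got[[cat]] - target[[cat]]), 2,
                label = sprintf("|%s:%s %.2f - %.2f|", char, cat,
                                got[[cat]], target[[cat]]))
    }
  }
})

test_that("summaries are exact weighted percentages", {
  recs <- make_records(2, sex = c("male", "female"), weight = c(1, 3))
  s <- summarize_population(recs)
  expect_equal(s$pct[s$characteristic == "sex" & s$category == "male"], 25)
  expect_equal(attr(s, "represented_population"), 4)

  one <- make_records(1, weight = 17)
  s1 <- summarize_population(one)
  expect_true(all(s1$pct == 100))

  zero <- make_records(2, weight = 0)
  expect_error(summarize_population(zero), class = "walkdiab_degenerate_error")
  expect_error(summarize_population(make_records(0)),
               class = "walkdiab_degenerate_error")
})

test_that("incompatible transport and step marginals are a configuration error", {
  m <- default_marginals()
  m$transport_band <- c("0" = 40, "1-75" = 20, "76-149" = 12.3, ">=150" = 27.7)
  expect_error(synth_config(marginals = m),
               regexp = "transport band.*step band",
               class = "walkdiab_config_error")
  # too much step mass below 1000 steps for the transport bands to supply
  m <- default_marginals()
  m$step_band <- c("0" = 46.2, "1-999" = 30, "1000-2999" = 7.3,
                   "3000-4999" = 4.8, ">=5000" = 11.2)
  expect_error(synth_config(marginals = m), class = "walkdiab_config_error")
})

test_that("a configured missing share produces incomplete risk-factor records", {
  cfg <- synth_config(n_records = 2000, seed = 31, missing_share = 0.039)
  pop <- generate_population(cfg)
  factor_cols <- c("bmi", "ethnicity", "education", "immigrant",
                   "hypertension", "heart_disease", "smoking",
                   "income_quintile")
  n_incomplete <- sum(rowSums(is.na(pop[factor_cols])) > 0)
  expect_gt(n_incomplete / nrow(pop), 0.02)
  expect_lt(n_incomplete / nrow(pop), 0.06)
})

test_that("survey CSV round-trips with a seed-recording sidecar", {
  cfg <- synth_config(n_records = 50, seed = 77)
  pop <- generate_population(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(pop, path, config = cfg)
  back <- read_survey_csv(path)
  expect_equal(nrow(back), 50)
  expect_equal(back$weight, pop$weight)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$seed, 77)
  expect_equal(meta$n_records, 50)
})

test_that("invalid configurations are rejected with named errors", {
  expect_error(synth_config(n_records = -1), class = "walkdiab_config_error")
  expect_error(synth_config(total_population = 0),
               class = "walkdiab_config_error")
  expect_error(synth_config(missing_share = 1), class = "walkdiab_config_error")
  expect_error(synth_config(transport_cap = 300),
               class = "walkdiab_config_error")
})
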