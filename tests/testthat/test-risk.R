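# Weibull proportional-hazards risk engine.

test_that("linear predictor applies centered sex-specific coefficients", {
  cf <- toy_coefficients()
  # all-zero coefficients reduce to the intercept
  cf0 <- cf
  for (s in names(cf0$sexes)) {
    cf0$sexes[[s]]$terms <- lapply(cf0$sexes[[s]]$terms, function(tm) {
      tm$coefficient <- 0
      tm
    })
  }
  rec <- make_records(1)
  expect_equal(linear_predictor(rec, cf0), cf0$sexes$male$intercept)

  # hand arithmetic: -4 + 0.05 * (50 - 40) + 0.3 * (1 - 0.2)
  rec <- make_records(1, age_years = 50L, smoking = "current")
  expect_equal(linear_predictor(rec, cf), -4 + 0.5 + 0.24)
  # binary indicator at reference level contributes -coef * center
  rec2 <- make_records(1, age_years = 40L, smoking = "never")
  expect_equal(linear_predictor(rec2, cf), -4 - 0.3 * 0.2)
  # female branch uses its own set
  rec3 <- make_records(1, sex = "female", age_years = 45L)
  expect_equal(linear_predictor(rec3, cf), -4.5 + 0.04 * 5 - 0.25 * 0.2)
  # missing predictor value yields NA, not an error
  rec4 <- make_records(1, smoking = NA_character_)
  expect_true(is.na(linear_predictor(rec4, cf)))
})

test_that("ten-year risk is the Weibull distribution function at the horizon", {
  expect_equal(ten_year_risk(log(0.01), shape = 1), 1 - exp(-0.1))
  expect_equal(ten_year_risk(-Inf, shape = 1.3), 0)
  # strictly increasing in eta and horizon
  e <- seq(-8, 0, length.out = 20)
  expect_true(all(diff(ten_year_risk(e, 1.2)) > 0))
  r_by_h <- vapply(1:10, function(h) ten_year_risk(-5, 1.2, h), numeric(1))
  expect_true(all(diff(r_by_h) > 0))
  expect_true(all(ten_year_risk(rnorm(50), 0.8) >= 0 &
                    ten_year_risk(rnorm(50), 0.8) <= 1))
  expect_error(ten_year_risk(NA_real_, 1), class = "walkdiab_validation_error")
  expect_error(ten_year_risk(0, -1), class = "walkdiab_validation_error")
})

test_that("eligibility applies the two-stage exclusion rules", {
  recs <- make_records(6,
    age_years = c(19L, 70L, 40L, 40L, 40L, 30L),
    smoking = c("never", "never", NA, "never", "never", "never"),
    diabetes = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    region_eligible = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  el <- apply_eligibility(recs)
  expect_equal(el$reason[1], "age<20")
  expect_false(el$risk_eligible[1])
  # over-64 records still get a risk but leave the analysis set
  expect_true(el$risk_eligible[2])
  expect_false(el$analysis_eligible[2])
  expect_equal(el$reason[2], "age>64")
  expect_equal(el$reason[3], "missing risk factor information")
  expect_equal(el$reason[4], "prior diabetes")
  expect_equal(el$reason[5], "outside region")
  expect_true(el$analysis_eligible[6])
  expect_true(is.na(el$reason[6]))
})

test_that("compute_risk attaches risks only to stage-one-eligible records", {
  cf <- toy_coefficients()
  recs <- make_records(3, age_years = c(40L, 19L, 70L))
  res <- suppressMessages(compute_risk(recs, cf))
  expect_true(is.na(res$risk10[2]))
  expect_false(is.na(res$risk10[3])) # risk computed, analysis-excluded
  expect_equal(res$risk10[1],
               ten_year_risk(linear_predictor(recs[1, ], cf), 1.2))
  expect_true(all(res$risk10 >= 0 & res$risk10 <= 1, na.rm = TRUE))
})

test_that("population risk is the weighted mean and weighted case sum", {
  tbl <- tibble::tibble(weight = c(1, 3), risk10 = c(0.1, 0.2),
                        analysis_eligible = TRUE)
  agg <- population_risk(tbl)
  expect_equal(agg$mean_risk, 0.175)
  expect_equal(agg$cases, 0.7)

  # equal risks collapse to that risk times the population
  tbl2 <- tibble::tibble(weight = runif(10, 1, 5), risk10 = 0.07,
                         analysis_eligible = TRUE)
  agg2 <- population_risk(tbl2)
  expect_equal(agg2$mean_risk, 0.07)
  expect_equal(agg2$cases, 0.07 * sum(tbl2$weight))

  # brute-force weighted sum oracle on a random table
  set.seed(41)
  tbl3 <- tibble::tibble(weight = rexp(50) + 0.1, risk10 = runif(50, 0, 0.3),
                         analysis_eligible = runif(50) > 0.2)
  agg3 <- population_risk(tbl3)
  num <- 0; den <- 0
  for (i in 1:50) {
    if (tbl3$analysis_eligible[i]) {
      num <- num + tbl3$weight[i] * tbl3$risk10[i]
      den <- den + tbl3$weight[i]
    }
  }
  expect_equal(agg3$mean_risk, num / den)
  expect_equal(agg3$cases, num)
  # weighted mean lies between the eligible extremes
  el <- tbl3$risk10[tbl3$analysis_eligible]
  expect_gte(agg3$mean_risk, min(el))
  expect_lte(agg3$mean_risk, max(el))

  expect_error(population_risk(tbl3[tbl3$weight < 0, ]),
               class = "walkdiab_degenerate_error")
})

test_that("annual incidence telescopes exactly to the horizon case count", {
  cf <- toy_coefficients()
  set.seed(42)
  recs <- make_records(40,
    sex = sample(c("male", "female"), 40, replace = TRUE),
    age_years = sample(20:64, 40, replace = TRUE),
    weight = runif(40, 100, 2000),
    smoking = sample(c("never", "current"), 40, replace = TRUE))
  res <- suppressMessages(compute_risk(recs, cf))
  inc <- annual_incidence(res, cf)
  expect_true(all(inc$cases >= 0))
  expect_equal(sum(inc$cases), population_risk(res)$cases, tolerance = 1e-12)

  # shape = 1 reduces yearly increments to the exponential decay pattern
  cf1 <- toy_coefficients()
  cf1$sexes$male$weibull_shape <- 1
  one <- tibble::tibble(record_id = "a", sex = "male", weight = 1,
                        eta = log(0.05), risk10 = NA, analysis_eligible = TRUE)
  inc1 <- annual_incidence(one, cf1)
  lambda <- 0.05
  expect_equal(inc1$cases,
               exp(-lambda * (0:9)) - exp(-lambda * (1:10)))

  # a relative-risk vector scales every increment
  inc_rr <- annual_incidence(res, cf, rr = rep(0.74, nrow(res)))
  expect_equal(inc_rr$cases, 0.74 * inc$cases)
})

test_that("coefficient configuration is validated on load", {
  expect_error(risk_coefficients(list(sexes = list())),
               class = "walkdiab_config_error")
  bad <- list(schema_version = "x",
              sexes = list(male = list(weibull_shape = -1, intercept = 0,
                                       terms = list()),
                           female = list(weibull_shape = 1, intercept = 0,
                                         terms = list())))
  expect_error(risk_coefficients(bad), class = "walkdiab_config_error")
  # a term without a centering constant is rejected
  bad2 <- toy_coefficients()
  bad2$sexes$male$terms[[1]]$center <- NULL
  expect_error(risk_coefficients(unclass(bad2)),
               class = "walkdiab_config_error")
  # the shipped default loads and is labelled synthetic
  cf <- default_risk_coefficients()
  expect_s3_class(cf, "risk_coefficients")
  expect_match(cf$label, "SYNTHETIC", ignore.case = TRUE)
})

test_that("risk is monotone in predictors with positive coefficients", {
  cf <- toy_coefficients()
  ages <- seq(20L, 64L, by = 4L)
  recs <- make_records(length(ages), age_years = ages)
  eta <- linear_predictor(recs, cf)
  expect_true(all(diff(ten_year_risk(eta, 1.2)) > 0))
})
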