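# Incidence-based attributable-cost calculator.

test_that("follow-up year costs resolve with the year-8 carry-forward rule", {
  sch <- toy_schedule()
  expect_equal(resolve_cost(1, "male", sch), 2200)
  expect_equal(resolve_cost(9, "male", sch), resolve_cost(8, "male", sch))
  expect_equal(resolve_cost(10, "female", sch), 1960)
  expect_error(resolve_cost(11, "male", sch),
               class = "walkdiab_validation_error")
  expect_error(resolve_cost(0, "male", sch),
               class = "walkdiab_validation_error")
})

test_that("survivor counts follow the year-by-year mortality product", {
  sch0 <- toy_schedule(mort_male = rep(0, 10))
  expect_equal(survivors(1000, "male", sch0, 1:10), rep(1000, 10))
  sch1 <- toy_schedule(mort_male = rep(0.1, 10))
  expect_equal(survivors(1000, "male", sch1, 3), 810)
  # arbitrary schedule vs an explicit iterative product
  set.seed(61)
  mort <- runif(10, 0, 0.2)
  sch2 <- toy_schedule(mort_female = mort)
  alive <- 500
  for (k in 1:10) {
    expect_equal(survivors(500, "female", sch2, k), alive)
    alive <- alive * (1 - mort[k])
  }
  expect_true(all(diff(survivors(100, "male", sch1, 1:10)) <= 0))
})

test_that("closed forms: flat costs without mortality, and horizon truncation", {
  flat <- toy_schedule(cost_male = rep(1500, 8), mort_male = rep(0, 10))
  all_year1 <- tibble::tibble(sex = "male", year = 1, cases = 200)
  res <- attributable_costs(all_year1, flat)
  expect_equal(res$total, 10 * 200 * 1500)
  expect_equal(res$by_year$cost, rep(200 * 1500, 10))

  # a case diagnosed in the last year accrues only its first-year cost
  last <- tibble::tibble(sex = "male", year = 10, cases = 1)
  sch <- toy_schedule(mort_male = rep(0, 10))
  expect_equal(attributable_costs(last, sch)$total,
               resolve_cost(1, "male", sch))

  expect_error(attributable_costs(
    tibble::tibble(sex = "male", year = 1, cases = -5), sch),
    class = "walkdiab_validation_error")
  expect_error(attributable_costs(
    tibble::tibble(sex = "male", year = 12, cases = 5), sch),
    class = "walkdiab_validation_error")
})

test_that("random instances match the brute-force (d, y) enumeration oracle", {
  set.seed(62)
  for (i in 1:20) {
    sch <- toy_schedule(
      cost_male = runif(8, 500, 3000),
      cost_female = runif(8, 500, 3000),
      mort_male = runif(10, 0, 0.1),
      mort_female = runif(10, 0, 0.1)
    )
    cases <- tidyr::expand_grid(sex = c("male", "female"), year = 1:10)
    cases$cases <- runif(nrow(cases), 0, 5000)
    res <- attributable_costs(cases, sch)
    expect_equal(res$total, oracle_costs_total(cases, sch), tolerance = 1e-10)
    expect_equal(sum(res$by_year$cost), res$total)
  }
})

test_that("costs are linear in case counts and savings difference exactly", {
  sch <- toy_schedule()
  cases <- tibble::tibble(sex = rep(c("male", "female"), each = 10),
                          year = rep(1:10, 2),
                          cases = runif(20, 100, 1000))
  base <- attributable_costs(cases, sch)
  doubled <- cases
  doubled$cases <- 2 * doubled$cases
  expect_equal(attributable_costs(doubled, sch)$total, 2 * base$total)

  # uniform rr scaling of cases scales costs, so savings = (1 - rr) * total
  rr <- 0.74
  scaled <- cases
  scaled$cases <- rr * scaled$cases
  scen <- attributable_costs(scaled, sch)
  expect_equal(cost_savings(base, scen), (1 - rr) * base$total)
  expect_equal(cost_savings(base, base), 0)

  other <- toy_schedule(currency = "other $")
  expect_error(cost_savings(base, attributable_costs(cases, other)),
               class = "walkdiab_validation_error")
})

test_that("a two-year toy example matches hand computation", {
  # 10 male cases in year 1, 4 in year 2; costs c1 = 100, c2 = 80;
  # mortality 0.5 after the first follow-up year
  sch <- toy_schedule(cost_male = c(100, 80, rep(0, 6)),
                      mort_male = c(0.5, rep(0, 9)))
  cases <- tibble::tibble(sex = "male", year = c(1, 2), cases = c(10, 4))
  res <- attributable_costs(cases, sch, horizon_years = 2)
  # year 1: 10 * 100; year 2: survivors 5 * 80 + new 4 * 100
  expect_equal(res$by_year$cost, c(1000, 5 * 80 + 400))
  expect_equal(res$total, 1800)
})

test_that("discounting and schedule validation behave", {
  sch <- toy_schedule(mort_male = rep(0, 10), cost_male = rep(1000, 8))
  cases <- tibble::tibble(sex = "male", year = 1, cases = 1)
  disc <- attributable_costs(cases, sch, discount_rate = 0.05)
  expect_equal(disc$by_year$cost, 1000 / 1.05^(0:9))

  expect_error(cost_schedule(list(sexes = list(male = list()))),
               class = "walkdiab_config_error")
  bad <- list(currency_label = "x", sexes = list(
    male = list(excess_cost_by_followup_year = rep(1, 9),
                mortality_by_followup_year = rep(0, 10)),
    female = list(excess_cost_by_followup_year = rep(1, 8),
                  mortality_by_followup_year = rep(0, 10))))
  expect_error(cost_schedule(bad), class = "walkdiab_config_error")
  expect_match(default_cost_schedule()$label, "SYNTHETIC")
})
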