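# Independent oracles used across the suite. Each is written as a direct,
# unoptimised transcription of the definition being checked, deliberately
# sharing no code with the implementation.

# Weighted quartile of a single element by explicit cumulative-weight scan.
oracle_weighted_quartile <- function(i, values, weights) {
  total <- sum(weights)
  cuts <- numeric(3)
  for (k in 1:3) {
    p <- k / 4
    cum <- 0
    for (v in sort(unique(values))) {
      cum <- cum + sum(weights[values == v])
      if (cum / total >= p - 1e-12) {
        cuts[k] <- v
        break
      }
    }
  }
  x <- values[i]
  if (x <= cuts[1]) "Q1" else if (x <= cuts[2]) "Q2" else
    if (x <= cuts[3]) "Q3" else "Q4"
}

# Exhaustive (diagnosis year d, calendar year y) double loop for the cost
# calculator, with survival as an explicit product of yearly factors.
oracle_costs_total <- function(annual_cases, schedule, horizon = 10) {
  total <- 0
  for (i in seq_len(nrow(annual_cases))) {
    d <- annual_cases$year[i]
    sex <- annual_cases$sex[i]
    cases <- annual_cases$cases[i]
    mort <- schedule$sexes[[sex]]$mortality_by_followup_year
    costs <- schedule$sexes[[sex]]$excess_cost_by_followup_year
    for (y in seq_len(horizon)) {
      if (y < d) next
      fy <- y - d + 1
      alive <- cases
      if (fy > 1) {
        for (k in seq_len(fy - 1)) alive <- alive * (1 - mort[k])
      }
      per_patient <- if (fy <= 8) costs[fy] else costs[8]
      total <- total + alive * per_patient
    }
  }
  total
}

# Weibull event times with cumulative hazard H(t) = t^rho * e^eta, drawn via
# stats::rweibull (scale b satisfies b^-rho = e^eta).
simulate_event_times <- function(n, rho, eta) {
  stats::rweibull(n, shape = rho, scale = exp(-eta / rho))
}

# Maximum-likelihood refit of (rho, eta) from fully observed event times
# under the proportional-hazards Weibull density
# f(t) = rho * t^(rho-1) * e^eta * exp(-t^rho * e^eta).
fit_weibull_ph <- function(times) {
  nll <- function(par) {
    rho <- exp(par[1])
    eta <- par[2]
    -sum(log(rho) + (rho - 1) * log(times) + eta - times^rho * exp(eta))
  }
  fit <- stats::optim(c(0, -1), nll, method = "BFGS")
  c(rho = exp(fit$par[1]), eta = fit$par[2])
}

# Small toy coefficient set used by several risk tests (both sexes identical
# shape, hand-checkable terms).
toy_coefficients <- function() {
  risk_coefficients(list(
    schema_version = "test-1",
    sexes = list(
      male = list(
        weibull_shape = 1.2,
        intercept = -4,
        terms = list(
          list(predictor = "age_years", coefficient = 0.05, center = 40),
          list(predictor = "smoking", category = "current",
               coefficient = 0.3, center = 0.2)
        )
      ),
      female = list(
        weibull_shape = 1.1,
        intercept = -4.5,
        terms = list(
          list(predictor = "age_years", coefficient = 0.04, center = 40),
          list(predictor = "smoking", category = "current",
               coefficient = 0.25, center = 0.2)
        )
      )
    )
  ))
}

# Minimal complete survey record(s) accepted by the eligibility and risk
# stages; fields can be overridden per test.
make_records <- function(n = 1, ...) {
  base <- tibble::tibble(
    record_id = sprintf("t%03d", seq_len(n)),
    weight = 1,
    sex = "male",
    age_years = 40L,
    income_quintile = "Q3",
    bmi = 26,
    ethnicity = "white",
    education = "post_secondary",
    immigrant = FALSE,
    hypertension = FALSE,
    heart_disease = FALSE,
    smoking = "never",
    diabetes = FALSE,
    transport_min = 0,
    leisure_min = 0,
    other_min = 0,
    vigorous_min = 0,
    region_eligible = TRUE
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

toy_schedule <- function(cost_male = c(2200, 1450, 1500, 1580, 1680, 1800,
                                       1950, 2120),
                         cost_female = c(2050, 1350, 1400, 1470, 1560, 1670,
                                         1810, 1960),
                         mort_male = rep(0.02, 10),
                         mort_female = rep(0.015, 10),
                         currency = "toy CAD") {
  cost_schedule(list(
    currency_label = currency,
    sexes = list(
      male = list(excess_cost_by_followup_year = cost_male,
                  mortality_by_followup_year = mort_male),
      female = list(excess_cost_by_followup_year = cost_female,
                    mortality_by_followup_year = mort_female)
    )
  ))
}
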