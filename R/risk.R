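# Weibull proportional-hazards risk engine. Ten-year diabetes risk per
# respondent is 1 - exp(-t^rho * e^eta): cumulative hazard H(t) = t^rho * e^eta
# with sex-specific shape rho and linear predictor eta built from centered
# coefficients, the parameterization used by population risk tools such as
# DPoRT. Coefficient values are configuration: the shipped default file is a
# synthetic example, not a published coefficient set.

#' Load and validate a risk-coefficient configuration
#'
#' The coefficient schema is sex-stratified: for each sex a Weibull shape
#' `rho > 0`, an intercept, and a list of terms. Each term names a predictor
#' column, optionally a category (making the term an indicator for that
#' category), a coefficient and a centering constant; the linear predictor is
#' `intercept + sum(coefficient * (value - center))`. Centering constants let
#' a coefficient set be adjusted to a population's baseline risk-factor
#' means.
#'
#' @param x A file path (JSON or YAML) or an already-parsed list.
#' @return A validated `risk_coefficients` object.
#' @export
risk_coefficients <- function(x) {
  cfg <- if (is.character(x)) read_config_file(x) else x
  if (is.null(cfg$schema_version)) {
    stop_config("risk coefficient configuration lacks a schema_version")
  }
  if (!all(c("male", "female") %in% names(cfg$sexes))) {
    stop_config("risk coefficients must provide sets for 'male' and 'female'")
  }
  for (sex in names(cfg$sexes)) {
    set <- cfg$sexes[[sex]]
    if (is.null(set$weibull_shape) || set$weibull_shape <= 0) {
      stop_config("weibull_shape for sex '%s' must be positive", sex)
    }
    if (is.null(set$intercept) || !is.finite(set$intercept)) {
      stop_config("intercept for sex '%s' must be finite", sex)
    }
    terms <- normalize_terms(set$terms, sex)
    cfg$sexes[[sex]]$terms <- terms
  }
  structure(cfg, class = "risk_coefficients")
}

# accept either a data frame (from JSON arrays of objects) or a list of lists
normalize_terms <- function(terms, sex) {
  if (is.data.frame(terms)) {
    terms <- purrr::transpose(as.list(terms))
  }
  purrr::map(terms, function(tm) {
    if (is.null(tm$predictor) || is.null(tm$coefficient)) {
      stop_config("every term for sex '%s' needs a predictor and coefficient",
                  sex)
    }
    if (is.null(tm$center) || is.na(tm$center)) {
      stop_config("term '%s' (sex '%s') lacks a centering constant",
                  tm$predictor, sex)
    }
    if (!is.null(tm$category) && is.na(tm$category)) tm$category <- NULL
    tm
  })
}

#' Synthetic example risk coefficients
#'
#' Loads the coefficient file shipped with the package. These values are a
#' synthetic, clearly-labelled example with plausible effect directions
#' (risk increasing with age, BMI, hypertension, heart disease, current
#' smoking, low income and low education); they are not an estimate of any
#' published risk algorithm, whose coefficient values are supplied by the
#' user as configuration.
#'
#' @return A `risk_coefficients` object.
#' @export
default_risk_coefficients <- function() {
  risk_coefficients(system.file("extdata", "synthetic_risk_coefficients.json",
                                package = "walkdiab", mustWork = TRUE))
}

#' Centered linear predictor for each record
#'
#' @param records Survey records with a `sex` column and every predictor
#'   named by the coefficient terms.
#' @param coeffs A [risk_coefficients()] object.
#' @return Numeric vector of linear predictors; `NA` where a record is
#'   missing any required predictor (such records are flagged ineligible
#'   downstream rather than erroring).
#' @export
linear_predictor <- function(records, coeffs) {
  check_columns(records, "sex", "survey records")
  eta <- rep(NA_real_, nrow(records))
  for (sex in names(coeffs$sexes)) {
    idx <- which(records$sex == sex)
    if (length(idx) == 0) next
    set <- coeffs$sexes[[sex]]
    acc <- rep(set$intercept, length(idx))
    for (tm in set$terms) {
      if (!tm$predictor %in% names(records)) {
        stop_config("coefficient term references unknown predictor '%s'",
                    tm$predictor)
      }
      raw <- records[[tm$predictor]][idx]
      value <- if (!is.null(tm$category)) {
        as.numeric(raw == tm$category)
      } else {
        as.numeric(raw)
      }
      acc <- acc + tm$coefficient * (value - tm$center)
    }
    eta[idx] <- acc
  }
  eta
}

#' Ten-year risk under the Weibull proportional-hazards form
#'
#' `risk = 1 - exp(-(horizon^shape) * exp(eta))`, i.e. the distribution
#' function at the horizon of a Weibull with cumulative hazard
#' `H(t) = t^shape * exp(eta)`. Strictly increasing in both `eta` and
#' `horizon`.
#'
#' @param eta Linear predictor(s).
#' @param shape Weibull shape `rho > 0`.
#' @param horizon_years Risk horizon in years (default 10).
#' @return Probabilities in `[0, 1]`.
#' @export
#' @examples
#' ten_year_risk(log(0.01), shape = 1) # 1 - exp(-0.1)
ten_year_risk <- function(eta, shape, horizon_years = 10) {
  if (any(is.na(eta) | is.nan(eta))) {
    stop_validation("eta must not contain missing values")
  }
  if (any(shape <= 0) || any(horizon_years <= 0)) {
    stop_validation("shape and horizon_years must be positive")
  }
  1 - exp(-(horizon_years^shape) * exp(eta))
}

DPORT_FACTOR_COLUMNS <- c("age_years", "sex", "bmi", "ethnicity", "education",
                          "immigrant", "hypertension", "heart_disease",
                          "income_quintile", "smoking")

#' Two-stage eligibility flags
#'
#' Risk is computed for all adults 20 and over without prior diabetes and
#' with complete risk-factor information (stage one); the analysis set is
#' then restricted to the study population, ages 20-64 living in the target
#' region (stage two). Records failing stage two still receive a risk but are
#' excluded from population aggregates.
#'
#' @param records Survey records; an absent `diabetes` or `region_eligible`
#'   column is treated as all-`FALSE` / all-`TRUE` respectively.
#' @param factor_columns Columns that must be non-missing for the risk score.
#' @param max_age Upper age bound of the study population.
#' @return A tibble with `record_id`, `risk_eligible`, `analysis_eligible`
#'   and `reason` (`NA` for analysis-eligible records).
#' @export
apply_eligibility <- function(records,
                              factor_columns = DPORT_FACTOR_COLUMNS,
                              max_age = 64) {
  check_columns(records, c("record_id", "age_years"), "survey records")
  diabetes <- if ("diabetes" %in% names(records)) records$diabetes else FALSE
  region <- if ("region_eligible" %in% names(records)) {
    records$region_eligible
  } else {
    TRUE
  }
  present <- intersect(factor_columns, names(records))
  complete <- rowSums(is.na(records[present])) == 0
  reason <- rep(NA_character_, nrow(records))
  reason[!complete] <- "missing risk factor information"
  reason[isTRUE_vec(diabetes)] <- "prior diabetes"
  reason[records$age_years < 20] <- "age<20"
  risk_eligible <- is.na(reason)
  reason[risk_eligible & records$age_years > max_age] <-
    sprintf("age>%d", max_age)
  reason[risk_eligible & !isTRUE_vec(region) &
           records$age_years <= max_age] <- "outside region"
  tibble(
    record_id = records$record_id,
    risk_eligible = risk_eligible,
    analysis_eligible = risk_eligible & is.na(reason),
    reason = reason
  )
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Compute per-record ten-year risk with eligibility
#'
#' Convenience wrapper combining [apply_eligibility()], [linear_predictor()]
#' and [ten_year_risk()]: risk is computed for stage-one-eligible records and
#' `NA` otherwise, and the share excluded for missing risk factors is
#' reported in a message (survey analyses track this exclusion rate).
#'
#' @param records Survey records.
#' @param coeffs A [risk_coefficients()] object.
#' @param horizon_years Risk horizon (default 10).
#' @param quiet Suppress the exclusion-share message.
#' @return A tibble with `record_id`, `sex`, `weight`, `eta`, `risk10`,
#'   `risk_eligible`, `analysis_eligible`, `reason`.
#' @export
compute_risk <- function(records, coeffs = default_risk_coefficients(),
                         horizon_years = 10, quiet = FALSE) {
  check_columns(records, c("record_id", "weight", "sex"), "survey records")
  elig <- apply_eligibility(records)
  eta <- linear_predictor(records, coeffs)
  shape <- shape_for_sex(records$sex, coeffs)
  risk10 <- rep(NA_real_, nrow(records))
  ok <- elig$risk_eligible & !is.na(eta)
  risk10[ok] <- ten_year_risk(eta[ok], shape[ok], horizon_years)
  eta[!ok] <- NA_real_
  if (!quiet) {
    n_missing <- sum(elig$reason == "missing risk factor information",
                     na.rm = TRUE)
    message(sprintf(
      "excluded for missing risk factor information: %d of %d (%.1f%%)",
      n_missing, nrow(records), 100 * n_missing / max(1, nrow(records))))
  }
  tibble(
    record_id = records$record_id,
    sex = records$sex,
    weight = records$weight,
    eta = eta,
    risk10 = risk10,
    risk_eligible = elig$risk_eligible,
    analysis_eligible = elig$analysis_eligible,
    reason = elig$reason
  )
}

shape_for_sex <- function(sex, coeffs) {
  vapply(sex, function(s) {
    if (s %in% names(coeffs$sexes)) coeffs$sexes[[s]]$weibull_shape
    else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
}

#' Population-level risk and expected case count
#'
#' The population risk is the weighted mean of individual risks over the
#' analysis-eligible records, and the expected number of new cases is that
#' mean multiplied by the represented population (equivalently the weighted
#' sum of individual risks).
#'
#' @param risk_tbl Output of [compute_risk()], optionally with risks already
#'   scenario-adjusted.
#' @param risk_col Name of the risk column to aggregate (default `risk10`).
#' @return A one-row tibble: `mean_risk`, `cases`, `population`.
#' @export
population_risk <- function(risk_tbl, risk_col = "risk10") {
  check_columns(risk_tbl, c("weight", risk_col, "analysis_eligible"),
                "risk results")
  el <- risk_tbl[isTRUE_vec(risk_tbl$analysis_eligible), ]
  if (nrow(el) == 0) {
    stop_degenerate("no analysis-eligible records")
  }
  total <- sum(el$weight)
  if (!isTRUE(total > 0)) {
    stop_degenerate("total weight of eligible records is zero")
  }
  cases <- sum(el$weight * el[[risk_col]])
  tibble(mean_risk = cases / total, cases = cases, population = total)
}

#' Expected new cases by year of diagnosis
#'
#' Splits each individual's horizon risk into yearly increments of their own
#' Weibull distribution function, `F(y) - F(y-1)` with
#' `F(y) = 1 - exp(-y^rho * e^eta)`, weights them, and sums by sex and year.
#' The yearly values telescope exactly to the horizon case count. An optional
#' relative-risk vector scales every increment (the convention used when a
#' scenario scales the ten-year risk).
#'
#' @param risk_tbl Output of [compute_risk()] (analysis-eligible rows are
#'   used).
#' @param coeffs A [risk_coefficients()] object (provides the sex-specific
#'   shapes).
#' @param horizon_years Integer horizon (default 10).
#' @param rr Optional per-record relative risk multiplier (length 1 or
#'   `nrow(risk_tbl)`); default 1.
#' @return A tibble `sex`, `year`, `cases` with one row per sex and year.
#' @export
annual_incidence <- function(risk_tbl, coeffs = default_risk_coefficients(),
                             horizon_years = 10, rr = 1) {
  check_columns(risk_tbl, c("sex", "weight", "eta", "analysis_eligible"),
                "risk results")
  if (horizon_years < 1 || horizon_years != round(horizon_years)) {
    stop_validation("horizon_years must be a positive integer")
  }
  rr <- if (length(rr) == 1) rep(rr, nrow(risk_tbl)) else rr
  if (length(rr) != nrow(risk_tbl)) {
    stop_validation("rr must have length 1 or nrow(risk_tbl)")
  }
  el <- isTRUE_vec(risk_tbl$analysis_eligible) & !is.na(risk_tbl$eta)
  tbl <- risk_tbl[el, ]
  rr <- rr[el]
  shape <- shape_for_sex(tbl$sex, coeffs)
  years <- seq_len(horizon_years)
  per_year <- purrr::map(years, function(y) {
    inc <- exp(-((y - 1)^shape) * exp(tbl$eta)) -
      exp(-(y^shape) * exp(tbl$eta))
    tibble(sex = tbl$sex, year = y, cases = tbl$weight * rr * inc)
  })
  bind_rows(per_year) %>%
    group_by(.data$sex, .data$year) %>%
    summarise(cases = sum(.data$cases), .groups = "drop") %>%
    arrange(.data$sex, .data$year)
}
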