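# Physical-activity metrics derived from self-reported weekly minutes:
# MET-minutes, activity categories, active-transport step counts, and
# weighted physical-activity quartiles.

MET_MODERATE <- 3 # active transport, leisure, other: moderate intensity
MET_VIGOROUS <- 6 # vigorous-intensity minutes (a subset of the three totals)

ACTIVITY_LEVELS <- c("sedentary", "somewhat", "moderate", "active")
TRANSPORT_BAND_LEVELS <- c("0", "1-75", "76-149", ">=150")
STEP_BAND_LEVELS <- c("0", "1-999", "1000-2999", "3000-4999", ">=5000")
QUARTILE_LEVELS <- c("Q1", "Q2", "Q3", "Q4")
STEPS_PER_WALKING_MINUTE <- 100 # moderate walking at 3 METs ~ 100 steps/min

#' Weekly MET-minutes from reported activity minutes
#'
#' Respondents report weekly minutes of active transportation, leisure-time
#' activity and other activity, all treated as moderate intensity (3
#' MET/minute), plus how many of those minutes were vigorous (6 MET/minute).
#' Vigorous minutes are a subset of the three totals, so moderate minutes are
#' the total minus the vigorous minutes:
#' `MET-min/week = 3 * (total - vigorous) + 6 * vigorous`.
#'
#' @param transport_min,leisure_min,other_min Weekly minutes in each reported
#'   activity category (non-negative).
#' @param vigorous_min Weekly vigorous-intensity minutes, at most the sum of
#'   the three category totals.
#' @return Numeric vector of MET-minutes per week.
#' @export
#' @examples
#' met_minutes(100, 50, 0, 30) # 3*120 + 6*30 = 540
met_minutes <- function(transport_min, leisure_min, other_min, vigorous_min) {
  args <- vctrs_recycle(transport_min, leisure_min, other_min, vigorous_min)
  transport_min <- args[[1]]; leisure_min <- args[[2]]
  other_min <- args[[3]]; vigorous_min <- args[[4]]
  ok <- !is.na(transport_min) & !is.na(leisure_min) &
    !is.na(other_min) & !is.na(vigorous_min)
  if (any(c(transport_min, leisure_min, other_min, vigorous_min)[
    !is.na(c(transport_min, leisure_min, other_min, vigorous_min))] < 0)) {
    stop_validation("activity minutes must be non-negative")
  }
  total <- transport_min + leisure_min + other_min
  if (any(ok & vigorous_min > total + 1e-9)) {
    stop_validation("vigorous minutes cannot exceed total activity minutes")
  }
  MET_MODERATE * (total - vigorous_min) + MET_VIGOROUS * vigorous_min
}

# minimal common-length recycling for scalar-or-vector arguments
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, function(a) {
    if (length(a) == n) a else if (length(a) == 1) rep(a, n) else
      stop_validation("arguments must have length 1 or %d", n)
  })
}

#' Classify weekly MET-minutes into activity categories
#'
#' Categories follow the survey convention: sedentary (0 MET-min/week),
#' somewhat active (1-449), moderately active (450-899), active (>= 900).
#'
#' @param met_min_week Non-negative numeric vector of MET-minutes per week.
#' @return Factor with levels `sedentary`, `somewhat`, `moderate`, `active`.
#' @export
#' @examples
#' classify_activity(c(0, 449, 450, 900))
classify_activity <- function(met_min_week) {
  if (any(met_min_week < 0, na.rm = TRUE)) {
    stop_validation("MET-minutes must be non-negative")
  }
  idx <- ifelse(met_min_week == 0, 1L,
         ifelse(met_min_week < 450, 2L,
         ifelse(met_min_week < 900, 3L, 4L)))
  factor(ACTIVITY_LEVELS[idx], levels = ACTIVITY_LEVELS)
}

#' Daily step-count equivalent of weekly active-transport minutes
#'
#' Moderate-intensity walking (3 METs) is taken as 100 steps per minute, so
#' `daily steps = weekly transport minutes * 100 / 7`. The value is returned
#' unrounded; use [round_step_count()] for the reporting convention.
#'
#' @param weekly_transport_min Non-negative weekly active-transport minutes.
#' @return Steps per day (numeric, unrounded).
#' @export
#' @examples
#' daily_step_count(25)  # 357.14...
#' daily_step_count(150) # 2142.86...
daily_step_count <- function(weekly_transport_min) {
  if (any(weekly_transport_min < 0, na.rm = TRUE)) {
    stop_validation("weekly transport minutes must be non-negative")
  }
  weekly_transport_min * STEPS_PER_WALKING_MINUTE / 7
}

#' Reporting-rounded daily step-count equivalent
#'
#' Rounds the daily step equivalent of a weekly walking increment the way the
#' results are reported: to the nearest ten steps for increments below 150
#' min/week, and to the nearest hundred at 150 min/week and above.
#'
#' @param weekly_transport_min Weekly walking minutes (non-negative).
#' @return Rounded steps per day.
#' @export
#' @examples
#' round_step_count(25)  # 360
#' round_step_count(150) # 2100
round_step_count <- function(weekly_transport_min) {
  steps <- daily_step_count(weekly_transport_min)
  ifelse(weekly_transport_min < 150,
         round_half_up(steps, -1),
         round_half_up(steps, -2))
}

transport_band <- function(transport_min) {
  idx <- ifelse(transport_min == 0, 1L,
         ifelse(transport_min <= 75, 2L,
         ifelse(transport_min < 150, 3L, 4L)))
  factor(TRANSPORT_BAND_LEVELS[idx], levels = TRANSPORT_BAND_LEVELS)
}

step_band <- function(daily_steps) {
  idx <- ifelse(daily_steps == 0, 1L,
         ifelse(daily_steps < 1000, 2L,
         ifelse(daily_steps < 3000, 3L,
         ifelse(daily_steps < 5000, 4L, 5L))))
  factor(STEP_BAND_LEVELS[idx], levels = STEP_BAND_LEVELS)
}

#' Weighted quartile labels
#'
#' Assigns each element the quartile of the weighted empirical distribution it
#' falls in. Cut points are lower weighted quantiles (the smallest observed
#' value whose cumulative weight share reaches 0.25 / 0.50 / 0.75); elements
#' at or below a cut point fall in the lower quartile, so tied values always
#' share a quartile. With `weighted = FALSE` all weights are treated as equal.
#'
#' @param values Numeric vector.
#' @param weights Positive weights, same length as `values`.
#' @param weighted If `FALSE`, ignore `weights` (all respondents count
#'   equally). Weighted is the default for survey data.
#' @return Factor with levels `Q1`..`Q4` (unused upper quartiles may be empty
#'   when ties collapse groups).
#' @export
#' @examples
#' weighted_quartiles(1:8, rep(1, 8))
weighted_quartiles <- function(values, weights, weighted = TRUE) {
  if (length(values) == 0) {
    stop_degenerate("cannot compute quartiles of an empty vector")
  }
  if (length(weights) != length(values)) {
    stop_validation("values and weights must have equal length")
  }
  if (any(weights <= 0 | is.na(weights))) {
    stop_validation("weights must be positive and non-missing")
  }
  if (!weighted) weights <- rep(1, length(values))
  ord <- order(values)
  cw <- cumsum(weights[ord]) / sum(weights)
  # lower weighted quantile: smallest value with cumulative share >= p
  cuts <- vapply(c(0.25, 0.5, 0.75), function(p) {
    values[ord][which(cw >= p - 1e-12)[1]]
  }, numeric(1))
  idx <- 1L + (values > cuts[1]) + (values > cuts[2]) + (values > cuts[3])
  factor(QUARTILE_LEVELS[idx], levels = QUARTILE_LEVELS)
}

#' Per-respondent activity profile
#'
#' Derives the full set of physical-activity metrics for a survey table:
#' weekly MET-minutes, activity category, active-transport minute band, daily
#' step count and band, and the weighted physical-activity quartile.
#'
#' @param records Data frame of survey records with columns `record_id`,
#'   `weight`, `transport_min`, `leisure_min`, `other_min`, `vigorous_min`.
#' @param weighted Whether quartiles use sampling weights (default) or equal
#'   weights.
#' @return A tibble keyed by `record_id` with columns `met_min_week`,
#'   `activity_category`, `transport_band`, `daily_steps`, `step_band`,
#'   `pa_quartile`.
#' @export
activity_profile <- function(records, weighted = TRUE) {
  check_columns(records, c("record_id", "weight", "transport_min",
                           "leisure_min", "other_min", "vigorous_min"),
                "survey records")
  met <- met_minutes(records$transport_min, records$leisure_min,
                     records$other_min, records$vigorous_min)
  steps <- daily_step_count(records$transport_min)
  tibble(
    record_id = records$record_id,
    met_min_week = met,
    activity_category = classify_activity(met),
    transport_band = transport_band(records$transport_min),
    daily_steps = steps,
    step_band = step_band(steps),
    pa_quartile = weighted_quartiles(met, records$weight, weighted = weighted)
  )
}
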