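# Walking-intervention scenarios: target-group selection, log-linear
# interpolation of relative risk reductions, risk shifting, and population
# benefit.
#
# The effect anchor is a meta-analytic 26% relative risk reduction in type 2
# diabetes incidence at 11.25 MET-h/week of activity, equivalent to 150
# min/week of moderate walking. Reductions for smaller weekly increments are
# obtained by linearizing the reduction on the natural log scale:
# RR(m) = exp(log(1 - 0.26) * m / 150).

#' Relative risk for a weekly walking increment
#'
#' Log-linear interpolation from the single anchor reduction at 150 min/week:
#' `RR(m) = exp(log(1 - rr_reduction_at_150) * m / 150)`. The exact RR is
#' used in all computation; [rr_reduction_pct()] gives the whole-percent
#' reduction used in tables.
#'
#' @param minutes Weekly walking increment in minutes, in `[0, 150]` unless
#'   `allow_extrapolation = TRUE`.
#' @param rr_reduction_at_150 Anchor reduction at 150 min/week (default
#'   0.26).
#' @param allow_extrapolation Permit increments beyond 150 min/week
#'   (log-linear extrapolation; off by default).
#' @return Relative risk in `(0, 1]`.
#' @export
#' @examples
#' rr_for_minutes(150) # 0.74
#' rr_reduction_pct(c(25, 50, 75, 100, 150)) # 5 10 14 18 26
rr_for_minutes <- function(minutes, rr_reduction_at_150 = 0.26,
                           allow_extrapolation = FALSE) {
  if (rr_reduction_at_150 <= 0 || rr_reduction_at_150 >= 1) {
    stop_validation("rr_reduction_at_150 must be in (0, 1)")
  }
  if (any(minutes < 0)) {
    stop_validation("walking minutes must be non-negative")
  }
  if (!allow_extrapolation && any(minutes > 150)) {
    stop_validation(paste0(
      "walking increments beyond 150 min/week are outside the anchored ",
      "range; set allow_extrapolation = TRUE to extrapolate"))
  }
  exp(log(1 - rr_reduction_at_150) * minutes / 150)
}

#' @rdname rr_for_minutes
#' @export
rr_reduction_pct <- function(minutes, rr_reduction_at_150 = 0.26,
                             allow_extrapolation = FALSE) {
  round_half_up(100 * (1 - rr_for_minutes(minutes, rr_reduction_at_150,
                                          allow_extrapolation)))
}

#' Specify a walking scenario
#'
#' Three target groups are modelled: scenario 1 targets individuals with low
#' weekly physical activity (weighted quartiles 1 and 2); scenario 2 targets
#' individuals with fewer than 1000 daily steps from active transportation;
#' scenario 3 targets individuals who reported no active transportation (0
#' steps). In every scenario the effect is withheld from respondents with
#' high baseline activity (quartiles 3 and 4 by default).
#'
#' @param scenario_id 1, 2 or 3.
#' @param walking_increment_min Added weekly walking minutes, in `(0, 150]`.
#' @param rr_reduction_at_150 Anchor reduction (default 0.26).
#' @param quartile_exclusion Physical-activity quartiles never targeted.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(scenario_id, walking_increment_min,
                          rr_reduction_at_150 = 0.26,
                          quartile_exclusion = c("Q3", "Q4")) {
  if (!scenario_id %in% 1:3) {
    stop_validation("scenario_id must be 1, 2 or 3")
  }
  if (walking_increment_min <= 0 || walking_increment_min > 150) {
    stop_validation("walking_increment_min must be in (0, 150]")
  }
  if (rr_reduction_at_150 <= 0 || rr_reduction_at_150 >= 1) {
    stop_validation("rr_reduction_at_150 must be in (0, 1)")
  }
  structure(
    list(scenario_id = as.integer(scenario_id),
         walking_increment_min = walking_increment_min,
         rr_reduction_at_150 = rr_reduction_at_150,
         quartile_exclusion = quartile_exclusion),
    class = "scenario_spec"
  )
}

#' Target-group membership for a scenario
#'
#' @param profiles Activity profiles (see [activity_profile()]) with
#'   `pa_quartile` and `daily_steps`.
#' @param spec A [scenario_spec()].
#' @return Logical vector: whether each respondent is in the scenario's
#'   target group (never `TRUE` for excluded quartiles).
#' @export
select_target <- function(profiles, spec) {
  check_columns(profiles, c("pa_quartile", "daily_steps"),
                "activity profiles")
  member <- switch(as.character(spec$scenario_id),
    "1" = profiles$pa_quartile %in% c("Q1", "Q2"),
    "2" = profiles$daily_steps < 1000,
    "3" = profiles$daily_steps == 0,
    stop_validation("unknown scenario_id %s", spec$scenario_id)
  )
  member & !(as.character(profiles$pa_quartile) %in% spec$quartile_exclusion)
}

#' Apply a relative risk reduction to targeted respondents
#'
#' Members of the target group have their risk multiplied by `rr`;
#' non-members are unchanged. The default applies the reduction directly to
#' the estimated risk (a risk ratio); `mode = "hazard"` instead treats `rr`
#' as a hazard ratio, `risk' = 1 - (1 - risk)^rr`, for sensitivity analysis.
#'
#' @param risks Numeric risks in `[0, 1]`.
#' @param member Logical membership flags (same length).
#' @param rr Relative risk in `(0, 1]`.
#' @param mode `"risk"` (default) or `"hazard"`.
#' @return Adjusted risks, still in `[0, 1]`.
#' @export
apply_scenario <- function(risks, member, rr, mode = c("risk", "hazard")) {
  mode <- match.arg(mode)
  if (rr <= 0 || rr > 1) {
    stop_validation("rr must be in (0, 1]")
  }
  if (length(member) != length(risks)) {
    stop_validation("risks and member must have equal length")
  }
  adj <- if (mode == "risk") risks * rr else 1 - (1 - risks)^rr
  ifelse(isTRUE_vec(member), adj, risks)
}

#' Population benefit of a scenario
#'
#' Compares baseline and scenario population aggregates (as from
#' [population_risk()]) over the identical eligible population: absolute risk
#' reduction in percentage points and cases prevented, both exact differences.
#'
#' @param baseline,scenario One-row aggregates with `mean_risk`, `cases`,
#'   `population`.
#' @return A one-row tibble: `baseline_mean_risk`, `scenario_mean_risk`,
#'   `absolute_risk_reduction` (percentage points), `baseline_cases`,
#'   `scenario_cases`, `cases_prevented`.
#' @export
population_benefit <- function(baseline, scenario) {
  check_columns(baseline, c("mean_risk", "cases", "population"), "baseline")
  check_columns(scenario, c("mean_risk", "cases", "population"), "scenario")
  if (abs(baseline$population - scenario$population) >
      1e-6 * baseline$population) {
    stop_validation(paste0(
      "baseline and scenario aggregates cover different populations ",
      "(%.1f vs %.1f)"), baseline$population, scenario$population)
  }
  tibble(
    baseline_mean_risk = baseline$mean_risk,
    scenario_mean_risk = scenario$mean_risk,
    absolute_risk_reduction = 100 * (baseline$mean_risk - scenario$mean_risk),
    baseline_cases = baseline$cases,
    scenario_cases = scenario$cases,
    cases_prevented = baseline$cases - scenario$cases
  )
}
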