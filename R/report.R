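# End-to-end orchestration: survey records (real or synthetic) -> activity
# profiles -> per-record risk -> scenario grid -> cases prevented and cost
# savings, rendered in the baseline-vs-increment layout of the published
# scenario tables.

#' Run the full projection pipeline
#'
#' Resolves the input population (a survey table, a CSV path, or a
#' [synth_config()] to generate from), derives activity profiles, computes
#' per-record ten-year risk, and evaluates every requested
#' scenario-by-increment combination against the baseline: mean risk,
#' expected cases, attributable costs, absolute risk reduction, cases
#' prevented and cost savings. All stored values carry full precision;
#' rounding happens only in [render_table3()].
#'
#' @param records A survey tibble, a CSV path, or `NULL` to generate a
#'   synthetic population from `synth`.
#' @param synth A [synth_config()] used when `records` is `NULL`.
#' @param coeffs A [risk_coefficients()] object or file path.
#' @param schedule A [cost_schedule()] object or file path.
#' @param scenarios Tibble with columns `scenario_id` and `increment`
#'   (min/week); defaults to the full 3-scenario x (25, 50, 75, 100, 150)
#'   grid. `NULL` runs the baseline only.
#' @param rr_reduction_at_150 Anchor relative risk reduction at 150 min/week.
#' @param horizon_years Projection horizon (default 10).
#' @param seed Seed for synthetic generation (defaults to the seed in
#'   `synth`).
#' @param weighted_quartiles Whether activity quartiles use sampling weights.
#' @param quiet Suppress progress/exclusion messages.
#' @return A `walkdiab_projection` object: list with `population_summary`,
#'   `exclusions`, `baseline` (aggregate, annual incidence, cost result),
#'   `scenario_results` (one row per scenario x increment) and `meta`.
#' @export
#' @examples
#' \donttest{
#' proj <- run_pipeline(synth = synth_config(n_records = 500, seed = 1),
#'                      scenarios = scenario_grid(increments = c(25, 150)))
#' tidy(proj)
#' }
run_pipeline <- function(records = NULL,
                         synth = synth_config(),
                         coeffs = default_risk_coefficients(),
                         schedule = default_cost_schedule(),
                         scenarios = scenario_grid(),
                         rr_reduction_at_150 = 0.26,
                         horizon_years = 10,
                         seed = NULL,
                         weighted_quartiles = TRUE,
                         quiet = TRUE) {
  if (is.character(coeffs)) coeffs <- risk_coefficients(coeffs)
  if (is.character(schedule)) schedule <- cost_schedule(schedule)
  if (!is.null(scenarios)) {
    check_columns(scenarios, c("scenario_id", "increment"), "scenario grid")
    if (nrow(scenarios) == 0) {
      stop_config("the scenario grid is empty; pass NULL for a baseline-only run")
    }
  }
  if (is.null(records)) {
    if (!is.null(seed)) synth$seed <- seed
    records <- generate_population(synth)
  } else if (is.character(records)) {
    records <- read_survey_csv(records)
  }
  if (nrow(records) == 0) {
    stop_degenerate("the input population is empty")
  }

  profile <- activity_profile(records, weighted = weighted_quartiles)
  risk <- compute_risk(records, coeffs, horizon_years, quiet = quiet)
  stopifnot(identical(profile$record_id, risk$record_id))

  baseline_agg <- population_risk(risk)
  baseline_inc <- annual_incidence(risk, coeffs, horizon_years)
  baseline_cost <- attributable_costs(baseline_inc, schedule, horizon_years)

  scenario_results <- NULL
  if (!is.null(scenarios)) {
    scenario_results <- purrr::pmap(scenarios, function(scenario_id,
                                                        increment, ...) {
      spec <- scenario_spec(scenario_id, increment, rr_reduction_at_150)
      member <- select_target(profile, spec)
      rr <- rr_for_minutes(increment, rr_reduction_at_150)
      adj <- risk
      adj$risk10 <- apply_scenario(risk$risk10, member, rr)
      scen_agg <- population_risk(adj)
      rr_vec <- ifelse(member, rr, 1)
      scen_inc <- annual_incidence(risk, coeffs, horizon_years, rr = rr_vec)
      scen_cost <- attributable_costs(scen_inc, schedule, horizon_years)
      benefit <- population_benefit(baseline_agg, scen_agg)
      el <- isTRUE_vec(risk$analysis_eligible)
      tibble(
        scenario_id = as.integer(scenario_id),
        increment = increment,
        rr = rr,
        rr_reduction_pct = rr_reduction_pct(increment, rr_reduction_at_150),
        target_population = sum(risk$weight[el & member]),
        mean_risk = scen_agg$mean_risk,
        cases = scen_agg$cases,
        cost_total = scen_cost$total,
        absolute_risk_reduction = benefit$absolute_risk_reduction,
        cases_prevented = benefit$cases_prevented,
        cost_savings = cost_savings(baseline_cost, scen_cost)
      )
    }) %>%
      bind_rows() %>%
      arrange(.data$scenario_id, .data$increment)
  }

  exclusions <- risk %>%
    filter(!is.na(.data$reason)) %>%
    group_by(reason = .data$reason) %>%
    summarise(n = dplyr::n(), weight = sum(.data$weight), .groups = "drop")

  structure(
    list(
      population_summary = summarize_population(records),
      exclusions = exclusions,
      baseline = list(aggregate = baseline_agg, incidence = baseline_inc,
                      cost = baseline_cost),
      scenario_results = scenario_results,
      meta = list(horizon_years = horizon_years,
                  rr_reduction_at_150 = rr_reduction_at_150,
                  currency = schedule$currency_label,
                  n_records = nrow(records),
                  seed = if (!is.null(seed)) seed else synth$seed)
    ),
    class = "walkdiab_projection"
  )
}

#' Default scenario grid
#'
#' @param scenario_ids Scenario identifiers (default 1:3).
#' @param increments Weekly walking increments in minutes (default 25, 50,
#'   75, 100, 150).
#' @return Tibble with columns `scenario_id`, `increment`.
#' @export
scenario_grid <- function(scenario_ids = 1:3,
                          increments = c(25, 50, 75, 100, 150)) {
  tidyr::expand_grid(scenario_id = scenario_ids, increment = increments)
}

#' Render the scenario table
#'
#' Formats a projection in the published layout: one panel per scenario with
#' columns Baseline, +25 min, ..., and rows for 10-year risk (%), new cases
#' (thousands), attributable costs (currency billions), absolute risk
#' reduction (percentage points), cases prevented (thousands) and cost
#' savings (currency millions). Rounding (half-up) is applied at this
#' presentation layer only: risk and risk reduction to 1 decimal, case counts
#' in thousands to 1 decimal, costs in billions to 2 decimals, savings in
#' millions to 1 decimal.
#'
#' @param proj A `walkdiab_projection` from [run_pipeline()].
#' @param increments Increments to render (default: all present); an absent
#'   increment is an error.
#' @param check_rounding Warn when a rounded delta row differs from the
#'   difference of its rounded absolute rows by more than one unit in the
#'   last place (rounding can make printed deltas disagree with printed
#'   absolutes).
#' @return A tibble: `scenario`, `measure`, then one column per table column.
#' @export
render_table3 <- function(proj, increments = NULL, check_rounding = FALSE) {
  res <- proj$scenario_results
  if (is.null(res)) {
    res <- tibble(scenario_id = integer(), increment = numeric())
  }
  if (is.null(increments)) increments <- sort(unique(res$increment))
  base <- proj$baseline$aggregate
  base_cost <- proj$baseline$cost$total
  measures <- c("10-year diabetes risk (%)",
                "Number of new diabetes cases (thousands)",
                sprintf("Health care costs attributable to diabetes (%s, billions)",
                        proj$meta$currency),
                "Absolute risk reduction from baseline (%)",
                "Number of diabetes cases prevented (thousands)",
                sprintf("Health care cost savings (%s, millions)",
                        proj$meta$currency))
  baseline_col <- c(round_half_up(100 * base$mean_risk, 1),
                    round_half_up(base$cases / 1e3, 1),
                    round_half_up(base_cost / 1e9, 2), NA, NA, NA)
  scenario_ids <- if (nrow(res) > 0) sort(unique(res$scenario_id)) else integer()
  if (length(scenario_ids) == 0) {
    return(tibble(scenario = NA_integer_, measure = measures,
                  Baseline = baseline_col))
  }
  panels <- purrr::map(scenario_ids, function(sid) {
    panel <- tibble(scenario = sid, measure = measures,
                    Baseline = baseline_col)
    for (inc in increments) {
      row <- res[res$scenario_id == sid & res$increment == inc, ]
      if (nrow(row) != 1) {
        stop_validation("no results for scenario %d at +%s min", sid,
                        format(inc))
      }
      col <- c(round_half_up(100 * row$mean_risk, 1),
               round_half_up(row$cases / 1e3, 1),
               round_half_up(row$cost_total / 1e9, 2),
               round_half_up(row$absolute_risk_reduction, 1),
               round_half_up(row$cases_prevented / 1e3, 1),
               round_half_up(row$cost_savings / 1e6, 1))
      if (check_rounding) {
        check_delta_consistency(panel$Baseline, col, sid, inc)
      }
      panel[[sprintf("+%g min", inc)]] <- col
    }
    panel
  })
  bind_rows(panels)
}

# rounded deltas can disagree with differences of rounded absolutes; warn
# when the disagreement exceeds one unit in the last printed place
check_delta_consistency <- function(baseline_col, col, sid, inc) {
  prevented_from_abs <- baseline_col[2] - col[2]
  if (abs(prevented_from_abs - col[5]) > 0.1 + 1e-9) {
    warn(sprintf(
      "scenario %d +%g min: printed cases prevented (%.1f) differs from the difference of printed case counts (%.1f) by more than 0.1 thousand",
      sid, inc, col[5], prevented_from_abs))
  }
  savings_from_abs <- (baseline_col[3] - col[3]) * 1000
  if (abs(savings_from_abs - col[6]) > 10 + 1e-9) {
    warn(sprintf(
      "scenario %d +%g min: printed cost savings (%.1f M) differs from the difference of printed cost totals (%.0f M) by more than 10 M",
      sid, inc, col[6], savings_from_abs))
  }
}

#' Write projection outputs to a directory
#'
#' Writes `population_summary.csv`, `table3.csv` (the rendered layout) and
#' `results.json` (full-precision scenario results and baseline). Re-running
#' on identical inputs overwrites identical outputs.
#'
#' @param proj A `walkdiab_projection`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_projection <- function(proj, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(proj$population_summary, file.path(dir, "population_summary.csv"),
            row.names = FALSE)
  write.csv(render_table3(proj), file.path(dir, "table3.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(baseline = proj$baseline$aggregate,
         baseline_cost_total = proj$baseline$cost$total,
         annual_incidence = proj$baseline$incidence,
         scenario_results = proj$scenario_results,
         meta = proj$meta),
    file.path(dir, "results.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
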