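# broom-style accessors and plots for fitted projection objects.

#' @export
print.walkdiab_projection <- function(x, ...) {
  b <- x$baseline$aggregate
  cat("<walkdiab_projection>\n")
  cat(sprintf("  population: %s records representing %s persons\n",
              format(x$meta$n_records, big.mark = ","),
              format(round(b$population), big.mark = ",")))
  cat(sprintf("  baseline %d-year risk: %.1f%%  (%.1f thousand cases)\n",
              x$meta$horizon_years, 100 * b$mean_risk, b$cases / 1e3))
  cat(sprintf("  baseline attributable cost: %.2f billion %s\n",
              x$baseline$cost$total / 1e9, x$meta$currency))
  if (!is.null(x$scenario_results)) {
    cat(sprintf("  scenarios evaluated: %d (use tidy() for the grid)\n",
                nrow(x$scenario_results)))
  }
  invisible(x)
}

#' Tidy a projection into its scenario grid
#'
#' @param x A `walkdiab_projection`.
#' @param ... Unused.
#' @return Tibble with one row per scenario x walking increment: relative
#'   risk, mean risk, cases, costs, absolute risk reduction, cases prevented
#'   and cost savings (full precision).
#' @method tidy walkdiab_projection
#' @export
tidy.walkdiab_projection <- function(x, ...) {
  if (is.null(x$scenario_results)) {
    return(tibble(scenario_id = integer(), increment = numeric()))
  }
  x$scenario_results
}

#' One-row baseline summary of a projection
#'
#' @param x A `walkdiab_projection`.
#' @param ... Unused.
#' @return One-row tibble: records, represented population, baseline mean
#'   risk, expected cases, attributable cost and horizon.
#' @method glance walkdiab_projection
#' @export
glance.walkdiab_projection <- function(x, ...) {
  b <- x$baseline$aggregate
  tibble(
    n_records = x$meta$n_records,
    population = b$population,
    mean_risk = b$mean_risk,
    cases = b$cases,
    cost_total = x$baseline$cost$total,
    currency = x$meta$currency,
    horizon_years = x$meta$horizon_years
  )
}

#' Plot cases prevented by walking increment
#'
#' One line per target-group scenario: expected diabetes cases prevented
#' (thousands) against the weekly walking increment.
#'
#' @param object A `walkdiab_projection` with scenario results.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot walkdiab_projection
#' @export
autoplot.walkdiab_projection <- function(object, ...) {
  res <- tidy(object)
  if (nrow(res) == 0) {
    stop_degenerate("projection has no scenario results to plot")
  }
  res$scenario <- factor(res$scenario_id,
                         labels = scenario_labels()[sort(unique(res$scenario_id))])
  ggplot2::ggplot(res, ggplot2::aes(x = .data$increment,
                                    y = .data$cases_prevented / 1e3,
                                    colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Added walking (min/week)",
                  y = "Diabetes cases prevented (thousands)",
                  colour = "Target group") +
    ggplot2::theme_minimal()
}

scenario_labels <- function() {
  c("1: low physical activity (Q1-Q2)",
    "2: <1000 steps/day",
    "3: no active transportation")
}

#' Plot the weighted population distribution
#'
#' Bar chart of the weighted category percentages for each summarised
#' characteristic of a survey population.
#'
#' @param records Survey records (as from [generate_population()]).
#' @return A ggplot object.
#' @export
plot_population <- function(records) {
  s <- summarize_population(records)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$category, y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~characteristic, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Weighted share (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
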