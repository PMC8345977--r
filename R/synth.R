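# Synthetic weighted survey populations with the marginal structure of the
# study cohort (adults 20-64 in a large metropolitan area), so the risk,
# scenario and cost stages can be exercised without restricted survey
# microdata.

#' Default marginal distributions for the synthetic population
#'
#' Published weighted percentages for the study cohort (sex, age band, income
#' quintile, BMI band, weekly activity category, active-transport minute band,
#' daily step-count band). Printed survey percentages may not total 100
#' because of missing observations and rounding; [synth_config()] rescales
#' each map to sum to one.
#'
#' @return Named list of named numeric vectors (percent shares).
#' @export
default_marginals <- function() {
  list(
    sex = c(male = 47.9, female = 52.1),
    age_band = c("20-44" = 57.6, "45-64" = 42.4),
    income_quintile = c(Q1 = 19.3, Q2 = 19.5, Q3 = 19.8, Q4 = 21.3, Q5 = 20.1),
    bmi_band = c("<25" = 49.0, "25-29.9" = 32.7, ">=30" = 14.5),
    activity_category = c(sedentary = 17.5, somewhat = 21.0,
                          moderate = 18.6, active = 42.9),
    transport_band = c("0" = 46.2, "1-75" = 13.5, "76-149" = 12.1,
                       ">=150" = 27.7),
    step_band = c("0" = 46.2, "1-999" = 12.9, "1000-2999" = 19.9,
                  "3000-4999" = 9.3, ">=5000" = 11.2)
  )
}

#' Default prevalences for risk factors without published cohort marginals
#'
#' The cohort table does not print marginals for ethnicity, education,
#' immigrant status, smoking, hypertension or heart disease; these defaults
#' are free parameters chosen as plausible values for a large, diverse urban
#' adult population and are intended only to exercise the risk engine.
#'
#' @return Named list: binary factors as single probabilities, categorical
#'   factors as named share vectors.
#' @export
default_prevalences <- function() {
  list(
    hypertension = 0.15,
    heart_disease = 0.03,
    immigrant = 0.47,
    smoking = c(never = 0.55, former = 0.25, current = 0.20),
    ethnicity = c(white = 0.48, south_asian = 0.16, east_asian = 0.11,
                  black = 0.08, other = 0.17),
    education = c(less_than_secondary = 0.09, secondary_grad = 0.24,
                  post_secondary = 0.67)
  )
}

#' Configuration for the synthetic survey population generator
#'
#' @param n_records Number of survey records to generate.
#' @param total_population Population represented by the records: the sum of
#'   sampling weights is rescaled to this value.
#' @param seed Integer seed making generation reproducible.
#' @param marginals Named list of category share maps (see
#'   [default_marginals()]); each map is rescaled to sum to one.
#' @param risk_factor_prevalences Prevalences for factors without published
#'   marginals (see [default_prevalences()]).
#' @param missing_share Share of records in which one randomly chosen risk
#'   factor is set missing (mimics survey item non-response). Default 0.
#' @param transport_cap Upper bound (min/week) for draws in the open-ended
#'   top transport band. Must exceed 350 so the top step band is reachable.
#' @param weight_sdlog Log-scale standard deviation of the log-normal
#'   sampling-weight draw (weights are positive and right-skewed, like design
#'   weights).
#' @return A validated `synth_config` object.
#' @export
synth_config <- function(n_records = 5160,
                         total_population = 3857703,
                         seed = 1L,
                         marginals = default_marginals(),
                         risk_factor_prevalences = default_prevalences(),
                         missing_share = 0,
                         transport_cap = 600,
                         weight_sdlog = 0.5) {
  marginals <- lapply(marginals, function(m) m / sum(m))
  cfg <- structure(
    list(n_records = n_records, total_population = total_population,
         seed = seed, marginals = marginals,
         risk_factor_prevalences = risk_factor_prevalences,
         missing_share = missing_share, transport_cap = transport_cap,
         weight_sdlog = weight_sdlog),
    class = "synth_config"
  )
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (length(cfg$n_records) != 1 || is.na(cfg$n_records) ||
      cfg$n_records < 0 || cfg$n_records != round(cfg$n_records)) {
    stop_config("n_records must be a single non-negative integer")
  }
  if (cfg$total_population <= 0) {
    stop_config("total_population must be positive")
  }
  if (cfg$missing_share < 0 || cfg$missing_share >= 1) {
    stop_config("missing_share must be in [0, 1)")
  }
  if (cfg$transport_cap <= 350) {
    stop_config("transport_cap must exceed 350 min/week (top step band)")
  }
  required <- names(default_marginals())
  missing <- setdiff(required, names(cfg$marginals))
  if (length(missing) > 0) {
    stop_config("marginals missing for: %s", paste(missing, collapse = ", "))
  }
  for (nm in names(cfg$marginals)) {
    m <- cfg$marginals[[nm]]
    if (any(m < 0 | m > 1) || abs(sum(m) - 1) > 1e-9) {
      stop_config("marginal '%s' must be proportions summing to 1", nm)
    }
  }
  # transport-minute and step-band marginals describe the same underlying
  # minutes (steps = minutes * 100 / 7), so their implied CDFs must agree
  resolve_transport_intervals(cfg$marginals$transport_band,
                              cfg$marginals$step_band, cfg$transport_cap)
  invisible(cfg)
}

# The transport-band and step-band marginals jointly pin down a distribution
# over weekly transport minutes: steps/day = minutes * 100/7 is strictly
# increasing, so each marginal fixes the minute-scale CDF at its own band
# edges. Merging both sets of edges gives refined intervals whose
# probabilities must all be non-negative for the two marginals to be
# compatible.
resolve_transport_intervals <- function(p_transport, p_steps, cap) {
  if (abs(p_transport[["0"]] - p_steps[["0"]]) > 1e-6) {
    stop_config(paste0(
      "transport band '0 min' proportion (%.4f) is incompatible with step ",
      "band '0 steps' proportion (%.4f): both describe the same respondents"),
      p_transport[["0"]], p_steps[["0"]])
  }
  # minute-scale edges: transport bands 0 / 1-75 / 76-149 / >=150,
  # step thresholds 1000, 3000, 5000 steps/day -> 70, 210, 350 min/week
  t_edges <- c(0, 75, 150, cap)
  s_edges <- c(0, 1000 * 7 / 100, 3000 * 7 / 100, 5000 * 7 / 100, cap)
  cdf <- rbind(
    data.frame(edge = t_edges, cum = cumsum(p_transport), src = "transport"),
    data.frame(edge = s_edges, cum = cumsum(p_steps), src = "steps")
  )
  cdf <- cdf[order(cdf$edge, cdf$src), ]
  cdf <- cdf[!duplicated(cdf$edge), ]
  probs <- diff(c(0, cdf$cum))
  if (any(probs < -1e-9)) {
    bad <- which(probs < -1e-9)[1]
    stop_config(paste0(
      "transport band and step band marginals are incompatible near %.1f ",
      "min/week (implied probability %.4f < 0); adjust the pair of maps"),
      cdf$edge[bad], probs[bad])
  }
  data.frame(lower = c(0, cdf$edge[-nrow(cdf)]), upper = cdf$edge,
             prob = pmax(probs, 0))
}

# Weighted quota assignment: permute records at random, then split the
# cumulative weight at the configured shares. Weighted category shares are
# reproduced up to a single record's weight, which keeps every marginal
# calibrated at any sample size while the assignment stays random.
quota_assign <- function(categories, probs, weights, ord = NULL) {
  n <- length(weights)
  if (is.null(ord)) ord <- order(runif(n))
  w <- weights[ord]
  mid <- (cumsum(w) - w / 2) / sum(w)
  idx <- findInterval(mid, cumsum(probs), left.open = TRUE) + 1L
  idx[idx > length(categories)] <- length(categories)
  out <- integer(n)
  out[ord] <- idx
  categories[out]
}

#' Generate a synthetic weighted survey population
#'
#' Draws `n_records` survey respondents whose weighted marginal distributions
#' reproduce the configured shares. Transport minutes and daily step counts
#' are linked deterministically through the step formula, and each record's
#' activity category is consistent with its drawn minutes by construction;
#' all other characteristics are drawn independently.
#'
#' @param config A [synth_config()] object.
#' @param seed Seed override; defaults to the seed stored in `config`.
#' @return A tibble of survey records (one row per respondent) with sampling
#'   weight, demographics, risk factors and weekly activity minutes. The sum
#'   of weights equals `config$total_population`.
#' @export
#' @examples
#' pop <- generate_population(synth_config(n_records = 200, seed = 7))
#' sum(pop$weight)
generate_population <- function(config = synth_config(), seed = config$seed) {
  validate_synth_config(config)
  n <- config$n_records
  if (n == 0) return(empty_population())
  m <- config$marginals
  prev <- config$risk_factor_prevalences

  with_seed(seed, {
    weight <- rlnorm(n, meanlog = 0, sdlog = config$weight_sdlog)
    weight <- weight * config$total_population / sum(weight)

    # transport minutes from the merged transport-band x step-band partition
    iv <- resolve_transport_intervals(m$transport_band, m$step_band,
                                      config$transport_cap)
    iv_idx <- quota_assign(seq_len(nrow(iv)), iv$prob, weight)
    transport_min <- ifelse(
      iv$upper[iv_idx] == 0, 0,
      runif(n, iv$lower[iv_idx], iv$upper[iv_idx])
    )

    # activity categories: weighted quotas walked from the most active
    # category down the records sorted by descending transport minutes, so a
    # record's category can always accommodate the MET-minutes its transport
    # alone implies (the most-walking records get the most active categories)
    act_levels <- ACTIVITY_LEVELS
    p_act <- m$activity_category[act_levels]
    ord <- order(-transport_min, runif(n))
    cat_rev <- quota_assign(rev(act_levels), rev(p_act), weight, ord = ord)
    activity_category <- factor(cat_rev, levels = act_levels)
    upper_met <- c(sedentary = 0, somewhat = 449, moderate = 899,
                   active = Inf)[as.character(activity_category)]
    if (any(3 * transport_min > upper_met + 1e-9)) {
      stop_config(paste0(
        "activity category marginals are incompatible with the transport ",
        "minute distribution: too little probability on the active end"))
    }

    # fill leisure/other/vigorous minutes to land total MET-minutes inside
    # the assigned category band
    lower_met <- c(sedentary = 0, somewhat = 1, moderate = 450,
                   active = 900)[as.character(activity_category)]
    top_met <- pmax(1800, 3.75 * transport_min)
    hi <- ifelse(is.infinite(upper_met), top_met, upper_met)
    met_target <- runif(n, pmax(3 * transport_min, lower_met), hi)
    met_target[activity_category == "sedentary"] <- 0
    vf <- runif(n, 0, 0.25)
    pos <- transport_min > 0
    vf[pos] <- pmin(vf[pos],
                    pmax(0, met_target[pos] / (3 * transport_min[pos]) - 1))
    total_min <- ifelse(met_target == 0, 0, met_target / (3 * (1 + vf)))
    vigorous_min <- vf * total_min
    slack <- pmax(0, total_min - transport_min)
    leisure_share <- runif(n)
    leisure_min <- slack * leisure_share
    other_min <- slack - leisure_min

    records <- tibble(
      record_id = sprintf("r%05d", seq_len(n)),
      weight = weight,
      sex = quota_assign(names(m$sex), m$sex, weight),
      age_years = draw_age(quota_assign(names(m$age_band), m$age_band,
                                        weight)),
      income_quintile = quota_assign(names(m$income_quintile),
                                     m$income_quintile, weight),
      bmi = draw_bmi(quota_assign(names(m$bmi_band), m$bmi_band, weight)),
      ethnicity = quota_assign(names(prev$ethnicity), prev$ethnicity, weight),
      education = quota_assign(names(prev$education), prev$education, weight),
      immigrant = quota_assign(c(TRUE, FALSE),
                               c(prev$immigrant, 1 - prev$immigrant), weight),
      hypertension = quota_assign(c(TRUE, FALSE),
                                  c(prev$hypertension, 1 - prev$hypertension),
                                  weight),
      heart_disease = quota_assign(
        c(TRUE, FALSE), c(prev$heart_disease, 1 - prev$heart_disease), weight),
      smoking = quota_assign(names(prev$smoking), prev$smoking, weight),
      diabetes = FALSE,
      transport_min = transport_min,
      leisure_min = leisure_min,
      other_min = other_min,
      vigorous_min = vigorous_min,
      region_eligible = TRUE
    )

    if (config$missing_share > 0) {
      miss <- quota_assign(c(TRUE, FALSE),
                           c(config$missing_share, 1 - config$missing_share),
                           weight)
      miss_cols <- c("bmi", "ethnicity", "education", "immigrant",
                     "hypertension", "heart_disease", "smoking",
                     "income_quintile")
      pick <- sample(miss_cols, n, replace = TRUE)
      for (col in miss_cols) {
        records[[col]][miss & pick == col] <- NA
      }
    }
    records
  })
}

draw_age <- function(band) {
  ifelse(band == "20-44", sample(20:44, length(band), replace = TRUE),
         sample(45:64, length(band), replace = TRUE))
}

draw_bmi <- function(band) {
  lo <- c("<25" = 18.5, "25-29.9" = 25, ">=30" = 30)[band]
  hi <- c("<25" = 25, "25-29.9" = 30, ">=30" = 45)[band]
  runif(length(band), lo, hi)
}

empty_population <- function() {
  tibble(
    record_id = character(), weight = numeric(), sex = character(),
    age_years = integer(), income_quintile = character(), bmi = numeric(),
    ethnicity = character(), education = character(), immigrant = logical(),
    hypertension = logical(), heart_disease = logical(),
    smoking = character(), diabetes = logical(), transport_min = numeric(),
    leisure_min = numeric(), other_min = numeric(), vigorous_min = numeric(),
    region_eligible = logical()
  )
}

#' Weighted distribution of population characteristics
#'
#' Summarises a survey table the way cohort baseline tables are reported:
#' weighted category percentages for sex, age band, income quintile, BMI
#' band, activity category, transport-minute band and step-count band.
#'
#' @param records Survey records (as from [generate_population()]).
#' @return A tibble with columns `characteristic`, `category`, `weight` and
#'   `pct` (weighted percent). The represented population (sum of weights) is
#'   attached as attribute `represented_population`.
#' @export
summarize_population <- function(records) {
  if (nrow(records) == 0) {
    stop_degenerate("cannot summarise an empty population")
  }
  total <- sum(records$weight, na.rm = TRUE)
  if (!isTRUE(total > 0)) {
    stop_degenerate("total sampling weight is zero")
  }
  profile <- activity_profile(records)
  chars <- list(
    sex = records$sex,
    age_band = ifelse(records$age_years <= 44, "20-44", "45-64"),
    income_quintile = records$income_quintile,
    bmi_band = as.character(cut(records$bmi, c(-Inf, 25, 30, Inf),
                                labels = c("<25", "25-29.9", ">=30"),
                                right = FALSE)),
    activity_category = as.character(profile$activity_category),
    transport_band = as.character(profile$transport_band),
    step_band = as.character(profile$step_band)
  )
  out <- purrr::imap(chars, function(x, nm) {
    tibble(characteristic = nm, category = as.character(x),
           weight = records$weight) %>%
      group_by(.data$characteristic, .data$category) %>%
      summarise(weight = sum(.data$weight), .groups = "drop") %>%
      mutate(pct = 100 * .data$weight / total)
  }) %>%
    bind_rows()
  attr(out, "represented_population") <- total
  out
}

#' Write and read survey record CSVs
#'
#' `write_survey_csv()` writes one row per record with the documented header
#' and a JSON sidecar (`<path>.meta.json`) recording the seed and population
#' totals so a run can be reproduced. `read_survey_csv()` reads the file back
#' as a tibble.
#'
#' @param records Survey records tibble.
#' @param path Output CSV path.
#' @param config Optional [synth_config()] whose seed and totals are recorded
#'   in the sidecar.
#' @return `write_survey_csv()` returns `path` invisibly; `read_survey_csv()`
#'   returns a tibble.
#' @export
write_survey_csv <- function(records, path, config = NULL) {
  write.csv(records, path, row.names = FALSE)
  meta <- list(
    n_records = nrow(records),
    represented_population = sum(records$weight),
    seed = if (!is.null(config)) config$seed,
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
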