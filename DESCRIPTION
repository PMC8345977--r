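Package: walkdiab
Title: Population Projections of Diabetes Cases Prevented by Increased Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A population risk pipeline for projecting the diabetes-prevention
    impact of increases in walking. Computes 10-year diabetes risk for weighted
    survey respondents from a configurable Weibull proportional-hazards risk
    score (the parameterization used by population risk tools such as DPoRT),
    derives physical-activity metrics (MET-minutes, activity categories, active
    transport step counts, weighted activity quartiles), applies
    walking-increment scenarios whose relative risk reductions are interpolated
    log-linearly from a single meta-analytic anchor, and converts annual
    incident cases into 10-year health-care costs attributable to diabetes with
    sex-specific per-year excess costs and mortality attrition. Includes a
    synthetic survey-population generator calibrated to published marginal
    distributions so the full pipeline can be exercised without restricted
    survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
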