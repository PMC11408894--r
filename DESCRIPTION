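Package: useis
Title: User Satisfaction Evaluation Indicator Systems for Health Apps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds user satisfaction evaluation indicator systems (USEIS)
    for mobile health apps from app-store review corpora. Cleans and
    summarizes labeled review corpora, computes task-technology-fit
    availability metrics (functional utilization and demand satisfaction
    rates) from app function-demand incidence matrices, derives indicator
    and criterion importance weights with a review-proportion-driven
    analytic hierarchy process (pairwise-comparison judgment matrices,
    principal-eigenvector weights, consistency ratios), and aggregates
    per-indicator positive-review shares into criterion-level and overall
    satisfaction scores with improvement-priority rankings. Includes a
    seedable synthetic-data generator for corpora and app cohorts, and
    bundled fixture hierarchies for a US/China hypertension-app scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
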