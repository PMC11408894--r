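# useis

Builds **user satisfaction evaluation indicator systems (USEIS)** for mobile
health apps from app-store review corpora, with a worked focus on
hypertension management apps (HMAs) in the United States and China.

Developers and health-informatics researchers want to know *which* aspects
of an app drive satisfaction, *how much* each aspect matters, and *where*
improvement effort pays off. `useis` answers this from user-generated
content alone: given reviews labeled with a topic and a binary sentiment
polarity (from an upstream topic model and sentiment classifier), it

1. **cleans the corpus** — bots (injected predicate), blanks, garbled and
   off-language text, advertisement-like reviews, duplicates, and reviews
   whose star rating contradicts their sentiment polarity;
2. **derives importance weights** with a review-proportion-driven analytic
   hierarchy process (AHP): per comparison set, topic frequency-proportion
   gaps are mapped onto Saaty's 1–9 scale via
   `scale = min(9, 1 + floor(8·d/d_max))`, the resulting positive
   reciprocal judgment matrix is solved by power iteration for its
   principal eigenvector, and every matrix must pass the consistency test
   `CR = CI/RI ≤ 0.1` with `CI = (λ_max − n)/(n − 1)`;
3. **scores satisfaction** — each indicator's positive-review share is its
   initial satisfaction; criterion satisfaction is the local-weight average,
   overall satisfaction the comprehensive-weight average (`S = Σ g_i s_i`),
   plus an improvement ranking by `g_i (1 − s_i)`;
4. **measures task-technology fit** of an app cohort: per-app functional
   utilization rate (share of functions meeting ≥ 1 demand) and demand
   satisfaction rate (share of demands met by ≥ 1 function), bin
   distributions, per-dimension coverage, and unmet demands;
5. **simulates** seedable synthetic corpora and app cohorts with the
   statistical structure above, and bundles the published US/CN evaluation
   hierarchies (`fixture_us_cn()`) with their satisfaction tables.

## Worked example

```r
library(useis)

ds     <- default_scenario(n_reviews = 50000, seed = 1) # fixed synthetic scenario
corpus <- simulate_reviews(ds$spec)
res    <- apply_filters(corpus, bot_predicate = flag_bot_authors)
res$report
#> <review filter report>
#>   input:    50000
#>   retained: 44981
#>   removed bot:                 982
#>   removed blank:               509
#>   removed garbled:             516
#>   removed advertisement:       516
#>   removed duplicate:           1513
#>   removed polarity_mismatch:   983
```

Every removal is attributed to exactly one reason and the counts add back
to the input size. Weights and consistency from the cleaned corpus:

```r
fit <- ahp_weights(ds$hierarchy, topic_proportions(res$corpus, "US"))
fit$consistency
#>   set                     n lambda_max     CI    RI     CR pass
#> 1 criteria                6       6.10 0.0209  1.24 0.0169 TRUE
#> 2 Usability               3       3.02 0.0109  0.58 0.0187 TRUE
#> 3 Monitoring function     2       2    0       0    0      TRUE
#> ...
```

All consistency ratios are below 0.1, so the weights are admissible.
Scoring with per-topic positive shares:

```r
scored <- score_hierarchy(ds$hierarchy, fit, positive_shares(res$corpus, "US"))
scored
#> <scored hierarchy> User satisfaction
#>   Usability (0.7530)
#>     Convenience                          0.7871
#>     Page design                          0.8623
#>     Advertising distribution             0.2094
#>   ...
#>   overall satisfaction: 0.6829

head(improvement_priorities(scored), 3)
#>   indicator            criterion       global_weight satisfaction priority rank
#> 1 Convenience          Usability              0.464         0.787   0.0987    1
#> 2 Data synchronization Data management        0.0566        0.202   0.0452    2
#> 3 Reliability          Availability           0.0618        0.294   0.0436    3
```

The overall score 0.6829 sits between the worst and best indicator shares;
the priority ranking surfaces heavily weighted, poorly rated indicators
(high importance × dissatisfaction) first. The bundled published systems
reproduce their reference aggregates:

```r
fx <- fixture_us_cn()
round(score_hierarchy(fx$us$hierarchy, fx$us$weights, fx$us$satisfaction)$overall, 4)
#> [1] 0.6861
round(score_hierarchy(fx$cn$hierarchy, fx$cn$weights, fx$cn$satisfaction)$overall, 4)
#> [1] 0.7891
```

An end-to-end run (`run_pipeline(run_config(out_dir = "out", seed = 1))`)
writes `report.json`, `tables/*.csv`, and a `manifest.json` with checksums;
identical config and seed give a byte-identical bundle. A thin CLI with
`run` / `preprocess` / `ahp` / `score` / `ttf` / `simulate` subcommands
lives at `inst/scripts/useis.R`.

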