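---
title: "Methods: review-proportion-driven satisfaction evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: review-proportion-driven satisfaction evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(useis)
```

## The problem

App stores hold large volumes of user reviews of mobile health apps —
here, hypertension management apps (HMAs) in the United States and China.
Each review carries a star rating (1–5) and, after upstream topic modelling
and sentiment classification, a topic label (the aspect of the app the user
is talking about, e.g. *Convenience* or *Data synchronization*) and a binary
polarity (*positive*/*negative*). `useis` turns such a labeled corpus into a
**user satisfaction evaluation indicator system (USEIS)**: a three-layer
hierarchy (target → criteria → indicators) with importance weights derived
by the analytic hierarchy process (AHP), scored with per-indicator
positive-review shares, plus task-technology-fit (TTF) availability metrics
for the app cohort itself.

Two ideas carry the method:

1. **Review frequency as importance.** Instead of expert questionnaires,
   pairwise importance judgments are read off the corpus: topics that users
   mention more often matter more to them, and the *gap* between two topics'
   review-frequency proportions sets the strength of the pairwise judgment.
2. **Positive share as satisfaction.** The proportion of a topic's
   polarity-labeled reviews that are positive is that indicator's initial
   satisfaction value; weighting and linear aggregation produce criterion
   and overall satisfaction.

## Preprocessing model

`apply_filters()` removes, in a fixed order, reviews that would distort
either proportions or shares: bot-authored reviews (via an injected
predicate — bot detection models are an external concern), blank text,
garbled text (fewer than 2 letter characters in any script), text not in
the market's target script (fewer than 2 characters of the market's
configured script class: Latin for the US store, Han for the Chinese
stores), advertisement-like text (configurable keyword list), duplicates
(same app, same author, same whitespace-normalised case-folded text — the
narrowest rule that cannot delete legitimate repeats across apps or users),
and finally reviews whose star rating contradicts their sentiment polarity.
A 4–5-star review classified negative, or a 1–2-star review classified
positive, indicates a labeling or gaming artefact; 3 stars is ambiguous and
never removed. Each removed review is attributed to exactly one reason (the
first matching stage), so the filter report's counts always add back to the
input size, and the pass is idempotent.

## From proportions to weights

For a comparison set with proportions $p_1,\dots,p_n$ (the indicator topics
inside one criterion, or the criterion sums themselves), let
$d_{ij} = |p_i - p_j|$ and $d_{\max} = \max_{ij} d_{ij}$. The default
importance-scale correspondence table maps differences onto Saaty's 1–9
scale by equal-width steps:

$$s(d) \;=\; \min\!\left(9,\; 1 + \left\lfloor 8\,d / d_{\max} \right\rfloor\right),$$

so equal proportions give scale 1 and the largest in-set gap gives scale 9.
The judgment matrix is $a_{ij} = s(d_{ij})$ when $p_i > p_j$, its
reciprocal when $p_i < p_j$, and 1 on ties and the diagonal — a positive
reciprocal matrix by construction. The table is rebuilt per comparison set,
so each set is scaled by its own maximum difference; a user-supplied table
(`read_scale_table()`, right-closed bins) can replace the default
everywhere. Ties map to scale 1 exactly; no perturbation is applied.

Weights are the principal eigenvector: for positive matrices
Perron–Frobenius guarantees a simple dominant eigenvalue with a positive
eigenvector, so `principal_eigenvector()` uses plain power iteration with
L1 normalisation (tolerance `1e-12`, cap 10,000 iterations), and tests
verify agreement with a dense eigendecomposition to `1e-8`. Consistency is
gated in the standard way:

$$CI = \frac{\lambda_{\max} - n}{n - 1}, \qquad CR = \frac{CI}{RI_n},$$

with Saaty's random-index table ($RI_3 = 0.58,\dots,RI_{10} = 1.49$;
orders above 10 require a user-supplied table). A matrix passes when
$CR \le 0.1$; orders 1–2 are consistent by convention ($CR = 0$).
Hierarchical total ranking multiplies criterion weight by local indicator
weight to give comprehensive (global) weights, and the combined consistency
ratio pools the indicator blocks as
$\sum_c W_c\,CI_c \,/\, \sum_c W_c\,RI_c$ (defined 0 when every block has
order ≤ 2), also required to be ≤ 0.1. `ahp_weights()` refuses synthesis
if any single-level test fails, naming the offending matrix, and the
pipeline aborts before scoring.

## Scoring and priorities

With global weights $g_i$, local weights $w_{i|c}$, criterion weights
$W_c$ and indicator satisfactions $s_i$ (positive shares):

- criterion satisfaction $S_c = \sum_{i \in c} w_{i|c}\, s_i$,
- overall satisfaction $S = \sum_i g_i s_i = \sum_c W_c S_c$.

The two routes are algebraically identical; `score_hierarchy()` computes
both and asserts agreement to `1e-12` as an internal invariant. Scores are
reported at 4 decimal places. `improvement_priorities()` ranks indicators
by $g_i (1 - s_i)$ — high importance and low satisfaction first — with ties
broken by weight, then label.

## Task-technology fit

An app's fit matrix is binary functions × demands incidence over a demand
catalog. The functional utilization rate is the share of functions meeting
at least one demand; the demand satisfaction rate is the share of demands
met by at least one function. A function serving several demands, or a
demand served by several functions, counts once — the rates measure
coverage, not multiplicity. Cohort summaries report mean rates, counts per
demand-satisfaction bin, per-dimension coverage, and cohort-level unmet
demands. Bins over percent rates are
$[0,20], (20,40], (40,60], (60,80], (80,100]$ — lower-open except the
first, upper-closed, so a rate of exactly 80% falls in $(60,80]$ and does
not count as "exceeding 80%". Percentages are rounded half-even to 2
decimals.

## The synthetic-data generator

No review corpus or incidence data is deposited with the published
analysis, so the generator defines the study conditions every test runs
under.

`simulate_reviews()` draws topic from the proportion vector, polarity from
the per-topic positive share, and a concordant rating (positive → 5 with
probability 0.7 else 4; negative → 1 with probability 0.6 else 2; 3-star
mass 0 by default — only concordance matters downstream, the split merely
shapes the marginal rating distribution). Contamination of each kind is
injected per record at the specified rates: duplicates copy an earlier clean
record's app/author/text, bot records get `bot:`-prefixed authors,
mismatch records get a discordant rating, and so on. Everything runs under
a single seed (`withr::with_seed`), so generation is a pure function of the
spec.

The **default scenario** (`default_scenario()`) fixes six criteria with
review proportions 0.45, 0.20, 0.12, 0.10, 0.08, 0.05, split into 14
indicator topics as (0.25, 0.12, 0.08), (0.12, 0.08), (0.07, 0.03, 0.02),
(0.06, 0.04), (0.05, 0.03), (0.03, 0.02) — a long-tailed profile typical of
topic-model output, with splits chosen at design time to be internally
consistent under the scale mapping. Per-topic positive shares span 0.21 to
0.87, mirroring the satisfied-to-dissatisfied spread seen in app-store
data, and default contamination is moderate (3% duplicates, 2% bots, 2%
mismatches, 1% each blank/garbled/ads). What the generator does **not**
emulate: natural review text (placeholders only), topical or temporal
correlation between reviews by the same author, market-specific rating
culture, or classifier error in the upstream topic/sentiment labels.
Passing tests therefore demonstrate correctness of the computational
pipeline under clean label semantics, not robustness to labeling noise.

`simulate_fit_matrices()` meets each catalog demand independently with the
target probability and attaches met demands to 3–8 candidate functions, so
generated functions always serve at least one demand (utilization 1 —
matching how functions are catalogued from what apps actually do) unless
`allow_dead_functions` keeps all-zero rows.

## The bundled US/CN systems

`fixture_us_cn()` carries the published US (6 criteria / 12 indicators) and
Chinese (6 criteria / 10 indicators) hypertension-app hierarchies with
their published per-indicator satisfaction values, criterion satisfactions,
overall satisfactions (0.6861 US, 0.7891 CN) and the three largest
comprehensive weights per country. The full weight vectors were published
only in supplementary material, so the fixture's weight set is a
**synthetic reconstruction**: for two-indicator criteria the local weights
are uniquely determined by the published criterion satisfaction; the three
published comprehensive weights pin three criterion weights; the remaining
free parameters are fixed once (US: usability criterion weight 0.48,
monitoring-effect 0.09; CN: cost 0.05) and the rest solved exactly from the
sum-to-one and published-overall constraints. The reconstruction reproduces
every published aggregate and keeps the published top-3 ranking, but it is
not the original weighting — conclusions about individual non-top weights
should not be drawn from it.

## Numerical and design choices

- **Scale mapping** uses the explicit equal-width formula above; it is the
  simplest monotone rule anchored at (0 → 1) and (d\_max → 9), and it is
  overridable per run.
- **Degenerate comparison sets** (all proportions equal) yield the
  all-ones matrix and uniform weights; single-indicator criteria get local
  weight 1 and a trivially consistent report.
- **Criterion satisfaction** uses local weights renormalised within the
  criterion (single-indicator criteria therefore inherit their indicator's
  value unchanged, consistent with the published tables).
- **Positive share** is positives / (positives + negatives); reviews
  without a polarity label are excluded from the denominator.
- **Problem sizes in tests**: eigensolver fidelity on 200 random reciprocal
  matrices of order 3–7; availability oracles on random matrices up to
  12×15; binomial recovery at n = 1,000 reviews over 20 seeds; end-to-end
  recovery at n = 50,000 reviews over 10 seeds with absolute tolerance
  0.01 on overall satisfaction — the sampling error a corpus of that size
  implies.

## Known limitations

- The proportion-to-scale mapping is a step function, so judgment matrices
  (hence weights) are piecewise constant in the proportions: tiny sampling
  fluctuations can flip one scale step. At n = 50,000 this moves overall
  satisfaction by well under 0.01, but at a few thousand reviews weight
  jitter dominates share noise.
- Importance-as-frequency is an assumption: a topic can be rarely mentioned
  yet critical (safety-related failures). The weighting inherits any
  coverage bias of the upstream topic model.
- Binary polarity discards neutral sentiment; if an upstream classifier
  emits neutrals they must be mapped or dropped before input.
- The consistency gate rejects, it does not repair: a failing matrix stops
  the run rather than adjusting judgments.

## A worked run

```{r, eval = FALSE}
ds <- default_scenario(n_reviews = 50000, seed = 1)
corpus <- simulate_reviews(ds$spec)
res <- apply_filters(corpus, bot_predicate = flag_bot_authors)
fit <- ahp_weights(ds$hierarchy, topic_proportions(res$corpus, "US"))
scored <- score_hierarchy(ds$hierarchy, fit, positive_shares(res$corpus, "US"))
scored
improvement_priorities(scored)
```

or, end to end with artifacts on disk:

```{r, eval = FALSE}
bundle <- run_pipeline(run_config(out_dir = "useis-out", seed = 1))
```
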