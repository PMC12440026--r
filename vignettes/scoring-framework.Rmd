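---
title: "Catalog-driven summary scoring: model, missingness contracts, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catalog-driven summary scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortscores)
```

## The problem

Longitudinal cohort studies release *tabulated data*: rectangular tables of
item-level responses (questionnaire items, replicate physiological
readings) keyed by participant and study event. Analyses rarely use the raw
items; they use *summary scores* — means, sums, counts, and normatively
standardized t-scores over defined item sets — and the scientific value of
those scores depends entirely on two things being explicit and
reproducible: **which items** feed each score, and **how missing items are
handled**.

cohortscores makes both declarative. Every score is a catalog entry naming
its items, its scoring *kernel*, and its parameters; the engine validates,
computes, and returns, and a per-score `_nm` companion records how many
items were missing when each value was computed.

## The naming grammar

Scores and items are named by a hierarchical grammar:

```
<domain>_<respondent>_<table>(__<scale_segment>)*_<suffix>
```

with seven research-domain codes (`ab`, `fc`, `mh`, `nc`, `nt`, `ph`,
`su`), a respondent code (`p` parent, `y` youth), a table code for the
instrument, double-underscore-introduced scale/subscale segments, and a
suffix naming the statistic. So `fc_p_fes__cohes_mean` is the mean of the
parent family-environment cohesion subscale and `ph_y_bp__sys_nm` is the
number of missing systolic readings. `parse_score_name()` and
`render_score_name()` are exact inverses; the round trip is
property-tested over generated names.

```{r}
parse_score_name("fc_p_fes__cohes_mean")
```

## Scoring kernels and the missingness contract

Nine row-wise kernels cover the catalog. Writing `nm` for the number of
missing items in a row and `n` for the item count:

| kernel | value | missing when |
|---|---|---|
| `ss_nm` | `nm` | never |
| `ss_mean` | mean of observed items | `nm > max_na` or all items missing |
| `ss_sum` | sum of observed items | as `ss_mean` |
| `ss_prsum` | `sum(observed) * n/(n - nm)` | as `ss_mean` |
| `ss_max` | max of observed items | as `ss_mean` |
| `ss_mean_pos` | mean of observed items `> 0` | no positive observed item |
| `ss_count` | count of observed items in `target_levels` | all items missing |
| `ss_count_cond` | count of satisfied row predicates | a predicate with `missing_policy = "missing"` hits a missing value |
| `ss_tscore` | exact norm-table lookup of a raw score | raw score missing |

`max_na` — the maximum number of missing items tolerated — is the central
stringency parameter. It is an integer in `[0, n]`, defaulting to 0 for
directly constructed definitions; each catalog entry declares the default
its instrument's scoring guidelines prescribe (1 for the nine-item
family-environment subscales here). Raising `max_na` can only convert
missing results into computed ones, never change an already-computed
value; this monotonicity is property-tested.

Three deliberate choices in the contract:

* **All-missing rows are always missing**, even when `max_na >= n`: a
  score from zero items would be a 0/0.
* **Proration** uses the standard psychometric factor `n/(n - nm)` on the
  observed sum — the estimate of the full-scale sum assuming the missing
  items resemble the observed ones. It is applied as `sum * (n/(n - nm))`
  so that with `nm = 0` the prorated sum equals the plain sum bit-for-bit.
* **`ss_count` treats missing items as contributing zero** (the count is a
  lower bound by construction) and is missing only when every item is
  missing; `ss_mean_pos` averages strictly positive observed values,
  excluding zeros and negatives.

`ss_tscore` performs exact lookup only. Interpolation between raw scores
would silently manufacture norms, so a raw score outside the table's
domain is an error naming the score and stratum, not an `NA`. Normative
tables are user-supplied (real cohort norms are typically proprietary);
the package ships a small synthetic exemplar
(`inst/extdata/norms_synthetic.tsv`) for illustration and testing.

No kernel rounds: full floating-point values are emitted, and consumers
format.

## The engine: validate, compute, return

All scoring goes through the standard `data` / `name` / `combine`
contract:

```{r}
cat_obj <- read_catalog(example_catalog_path())
d <- simulate_items(
  n_rows = 5, n_items = 9,
  pattern = missingness_pattern(per_row = c(0, 1, 2, 0, 1), seed = 7),
  prefix = "fc_p_fes__cohes", seed = 7
)
defn <- cat_obj$definitions$fc_p_fes__cohes_mean
compute_score(d, defn, combine = FALSE)
```

Validation runs fully before anything is computed and reports *all*
violations at once (missing columns, wrong types, out-of-range
parameters) — friendlier than first-failure errors when running a whole
catalog. Errors carry a machine-readable `kind` alongside the message, so
"informative error" is a testable property, not a style aspiration. A
computed column that would collide with an existing column is an error,
never a silent overwrite: silent overwrites are how release tables become
irreproducible.

Sentinel missing codes (e.g. numeric refuse-to-answer or don't-know codes
such as 777/999) are catalog-level configuration, recoded to missing
*before* any kernel runs and before the `_nm` companion is counted; the
raw input columns are returned untouched.

`compute_group()` is the `_all`-style convenience path: it folds
`compute_score()` over a catalog group in catalog order, with `_nm`
companions emitted immediately after their parent score. The
blood-pressure group `ph_y_bp` therefore yields exactly six columns:
`sys_mean`, `sys_nm`, `dia_mean`, `dia_nm`, `hrate_mean`, `hrate_nm`.
With `combine = FALSE` the result keeps the identifier columns (rather
than returning bare vectors) so it always joins back onto the input; the
join consistency of the two `combine` modes is tested.

## The shipped catalog

The exemplar catalog (`example_catalog_path()`) covers three instruments:
the parent family-environment cohesion and conflict subscales (9 items
each, mean kernel, `max_na = 1` per the instrument's scoring convention),
the youth blood-pressure measure (3 replicate readings each of systolic,
diastolic, heart rate), and a parent-report emotion-regulation attunement
exemplar. Two values there are this package's own choices, since no
published default exists at this granularity: the blood-pressure means use
`max_na = 2` (a mean of even a single replicate reading is conventionally
reported, and `_nm` preserves how many were missing), and the attunement
exemplar carries 6 items (a typical subscale size; it exists to exercise a
second domain, not to reproduce a specific instrument).

## Synthetic data: what it emulates and what it does not

The generators exist so every behavior is testable without access to
restricted cohort data:

* `simulate_items()` emulates a questionnaire subscale's raw input:
  id columns plus `<prefix>_001..NNN` items drawn uniformly from a level
  set (default binary 0/1, true/false-style items), with missingness
  placed either as *exact per-row counts* (so tests can pin `_nm`
  outcomes) or as a per-cell probability (checked to its rate within 3
  standard errors).
* `simulate_bp()` draws three replicate readings per vital sign around
  per-participant means plausible for early adolescents (systolic ~110
  mmHg (SD 9), diastolic ~65 mmHg (SD 7), heart rate ~80 bpm (SD 9), with
  ~3-unit within-person replicate noise).
* `simulate_longitudinal()` produces one row per participant x event with
  a drifting, intermittently missing variable — the input shape
  `make_static()` is for.

All randomness is scoped through explicit integer seeds (`withr`), so
identical seeds give identical tables and the global RNG state is left
untouched. The generators deliberately do **not** emulate real cohort
marginal distributions, item covariance, informative missingness, or
attrition; passing tests demonstrate the *contracts* (missingness gates,
proration algebra, grouping, IO round-trips), not distributional realism.

## Transforms for curation

Four column-level utilities cover the recurring curation steps around
scoring: `recode_levels()` (value recoding, with unmapped values kept or
set missing), `combine_cols()` (first-wins coalescing of mutually
exclusive branching-logic columns; rows where both sides disagree are
counted and logged, not fatal), `combine_levels()` (collapsing categories,
groups required to be disjoint), and `make_static()` (propagating one
per-participant value across events). `make_static()` defaults to the
earliest event with an observed value — for a stable trait this uses all
information — with `rule = "baseline"` available when strict
baseline-ascertainment semantics are wanted; either way the operation is
idempotent and its output constant within participant.

## Numerical and degenerate-input choices

* Event labels outside `event_order`, overlapping level groups, and
  selection-mode conflicts in the CLI are configuration errors, caught
  before any data is touched.
* An empty catalog group computes zero columns with a warning rather than
  erroring, so catalog-wide runs don't fail on a placeholder group.
* Determinism: identical inputs and definitions produce identical outputs
  (no time, locale, or row-order dependence; transforms never reorder
  rows), and the CLI and programmatic API produce byte-identical files.

## Problem sizes

The test-suite and acceptance computations use deliberately small
problems — hundreds to a few thousand simulated rows, item counts up to
20, property suites of 500+ randomized cases — chosen because every
contract here is exact (counts, gates, algebraic identities) and holds
independently of scale; the kernels are vectorized and score thousands of
rows in well under a second.

## Known limitations

* The shipped catalog is an exemplar, not a full release inventory;
  proprietary instruments (e.g. scales whose raw-to-t conversion tables
  are licensed) are out of scope by design.
* `ss_tscore` supports exact lookup only; continuous-norming models are
  not implemented.
* `combine_cols()` precedence is positional; it does not attempt to
  reconcile conflicting observed values.
* Catalogs are validated structurally; the package cannot know whether a
  declared item list is scientifically the right one for an instrument.
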