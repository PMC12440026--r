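# cohortscores

Catalog-driven summary scores for cohort-study tabulated data.

Longitudinal cohort studies release rectangular tables of item-level
responses — questionnaire items, replicate physiological readings — keyed
by participant and study event. What analyses actually use are *summary
scores* over defined item sets, and those scores are only reproducible if
two things are explicit: which items feed each score, and how missing
items are handled. cohortscores makes both declarative. A YAML **catalog**
names every score with a hierarchical grammar
(`<domain>_<respondent>_<table>(__<scale>)*_<suffix>`, e.g.
`fc_p_fes__cohes_mean`, the mean of the parent family-environment cohesion
subscale) and declares its items, scoring kernel, and parameters; the
engine validates, computes, and returns, emitting an `_nm`
(number-missing) companion column alongside most scores.

It is written for data teams curating cohort releases and for researchers
who want to recompute or customize released scores.

## The model

Each score is a row-wise reduction of its item columns with an explicit
missingness gate. Writing `nm` for the number of missing items in a row,
`n` for the item count, and `max_na` for the score's missing-item
tolerance, the mean/sum/max kernels return their statistic over the
observed items when `nm <= max_na` and at least one item is observed, and
`NA` otherwise; the prorated sum estimates the full-scale sum as

```
prsum = sum(observed) * n / (n - nm)
```

Counting kernels count observed items in a target level set or satisfied
row-level predicates, and `ss_tscore` maps a raw score to a normative
t-score (mean 50, SD 10) by exact stratified table lookup. Thirteen
generic utilities are exported: nine scoring kernels (`ss_mean`, `ss_sum`,
`ss_nm`, `ss_count`, `ss_count_cond`, `ss_max`, `ss_prsum`, `ss_mean_pos`,
`ss_tscore`) and four curation transforms (`recode_levels`,
`combine_cols`, `combine_levels`, `make_static`).

## Worked example

Score a simulated nine-item cohesion subscale with the shipped catalog
(default `max_na = 1`), then relax the tolerance to 2:

```r
library(cohortscores)

cat_obj <- read_catalog(example_catalog_path())
d <- simulate_items(
  n_rows = 5, n_items = 9,
  pattern = missingness_pattern(per_row = c(0, 1, 2, 0, 1), seed = 7),
  prefix = "fc_p_fes__cohes", seed = 7
)
defn <- cat_obj$definitions$fc_p_fes__cohes_mean
compute_score(d, defn, combine = FALSE)
#> # A tibble: 5 × 4
#>   participant_id session_id fc_p_fes__cohes_mean fc_p_fes__cohes_nm
#>   <chr>          <chr>                     <dbl>              <int>
#> 1 sub0001        event_01                  0.333                  0
#> 2 sub0002        event_01                  0.75                   1
#> 3 sub0003        event_01                 NA                      2
#> 4 sub0004        event_01                  0.889                  0
#> 5 sub0005        event_01                  0.625                  1

compute_score(d, defn, combine = FALSE, max_na = 2)
#> # A tibble: 5 × 4
#>   participant_id session_id fc_p_fes__cohes_mean fc_p_fes__cohes_nm
#>   <chr>          <chr>                     <dbl>              <int>
#> 1 sub0001        event_01                  0.333                  0
#> 2 sub0002        event_01                  0.75                   1
#> 3 sub0003        event_01                  0.714                  2
#> 4 sub0004        event_01                  0.889                  0
#> 5 sub0005        event_01                  0.625                  1
```

Row 3 has two missing items: under the catalog default (`max_na = 1`) its
mean is `NA`; raising the tolerance to 2 computes the mean of its seven
observed items (0.714) while every other row — and the `_nm` bookkeeping —
is unchanged.

Group scoring computes a whole measure at once. The youth blood-pressure
group yields six scores (mean and number-missing for systolic, diastolic,
and heart rate, each over three replicate readings):

```r
bp <- simulate_bp(n_rows = 3, seed = 1)
compute_group(bp, cat_obj, "ph_y_bp", combine = FALSE)
#> # A tibble: 3 × 8
#>   participant_id session_id ph_y_bp__sys_mean ph_y_bp__sys_nm ph_y_bp__dia_mean
#>   <chr>          <chr>                  <dbl>           <int>             <dbl>
#> 1 sub0001        event_01                 103               0              78.7
#> 2 sub0002        event_01                 111               0              68
#> 3 sub0003        event_01                 105               0              58
#> # ℹ 3 more variables: ph_y_bp__dia_nm <int>, ph_y_bp__hrate_mean <dbl>,
#> #   ph_y_bp__hrate_nm <int>
```

The same pipeline is available from a shell via the installed
`exec/cohortscores` script (`compute`, `validate`, `simulate`, `list`
subcommands), producing byte-identical output to the programmatic API.

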