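# sgains

Identify **sudden gains** — large, stable session-to-session improvements —
and their mirror image, sudden losses, in longitudinal outcome data such as
weekly symptom questionnaires collected during a psychological intervention.
The package is aimed at clinical researchers analysing repeated-measures
trial or routine-care data who want a reproducible, fully specified
implementation of the standard identification criteria rather than
error-prone spreadsheet arithmetic.

## The method

An interval from session *N* (pre-gain) to session *N+1* (post-gain) is a
sudden gain when three criteria hold:

1. **Absolute magnitude** — the drop is at least a cutoff in score units,
   `x_N − x_{N+1} ≥ c₁` (classically 7 points on the 0–63 Beck Depression
   Inventory). For other scales the cutoff can be derived from the
   Jacobson–Truax reliable-change chain:
   `S_E = s·√(1 − r)`, `S_diff = √(2·S_E²)`, reliable change `= 1.96·S_diff`,
   with either `S_diff` or the reliable change value used as `c₁`.
2. **Relative magnitude** — the drop is at least 25% of the pre-gain score,
   `x_N − x_{N+1} ≥ 0.25·x_N`.
3. **Stability relative to fluctuation** — the mean of the three
   measurements before the gain exceeds the mean of the three after it by
   more than a critical value times their pooled standard deviation:

   `M_pre − M_post > t_crit · √( ((n_pre−1)·SD²_pre + (n_post−1)·SD²_post) / (n_pre+n_post−2) )`

   where `t_crit` is the two-tailed Student-t quantile with
   `df = n_pre + n_post − 2`: 2.776 with full windows, 3.182 with one point
   missing on one side, 4.303 with one missing on each side (α = 0.05).

An interval can only be examined at all when the pre- and post-gain points
are present and at least two of the three points on each side are observed
(minimum four of the six window points); otherwise its verdict is `NA`.
A gain has **reversed** when a later score reaches the midpoint of the
pre-/post-gain scores or more (a 40 → 30 gain reverses at 35 or more).

## Worked example

The bundled synthetic demo dataset emulates a 12-session depression
intervention: 43 subjects, weekly BDI-like scores (`bdi_s1 … bdi_s12`,
range 0–63), a parallel rumination-like measure (`rq_s1 … rq_s12`), planted
gains with known ground truth, and realistic missingness.

```r
library(sgains)

demo <- sg_demo_data()
vars <- expand_var_range("bdi_s1:bdi_s12")

flags <- identify_sg(demo, id_var_name = "id", sg_var_list = vars,
                     sg_crit1_cutoff = 7, crit123_details = TRUE)
flags[flags$id %in% c(3, 7, 42),
      c("id", "sg_crit1_2to3", "sg_crit2_2to3", "sg_crit3_2to3", "sg_2to3")]
#>      id sg_crit1_2to3 sg_crit2_2to3 sg_crit3_2to3 sg_2to3
#> 1     3 TRUE          TRUE          TRUE                1
#> 2     7 FALSE         FALSE         FALSE               0
#> 3    42 NA            NA            NA                 NA
```

Subject 3 gains between sessions 2 and 3; subject 7 does not; subject 42 is
too sparsely observed for the interval to be classified (`NA`). The
one-row-per-gain and one-row-per-person datasets and the summary:

```r
bysg <- create_bysg(demo, "id", vars, "bdi_s1", "bdi_s12",
                    sg_crit1_cutoff = 7, sg_measure_name = "bdi")
bysg[1:3, c("id_sg", "sg_session_n", "sg_magnitude",
            "sg_change_proportion", "sg_reversal_value", "sg_reversal")]
#>   id_sg sg_session_n sg_magnitude sg_change_proportion sg_reversal_value sg_reversal
#> 1 3_sg2            2           19                0.422              44.5           0
#> 2 3_sg5            5           13                0.289              27.5           0
#> 3 3_sg9            9           12                0.267              14             0

byperson <- create_byperson(demo, "id", vars, "bdi_s1", "bdi_s12",
                            sg_crit1_cutoff = 7, sg_measure_name = "bdi")
describe_sg(bysg, byperson)
#>   n_subjects n_gainers pct_gainers n_multigainers total_gains mean_magnitude sd_magnitude
#> 1         43        16       0.372              9          26           14.9         2.68
#>   n_reversed pct_reversed mean_session_n
#> 1          3        0.115           5.81
```

16 of 43 subjects (37.2%) experienced a sudden gain, 9 more than one, for
26 gains in total, with a mean magnitude of 14.9 points; 3 gains (11.5%)
later reversed — exactly the structure planted by the generator. Deriving a
criterion-1 cutoff for a new measure:

```r
define_crit1_cutoff(sd_baseline = 10.5, reliability = 0.93)
#>   standard_error_measurement standard_error_difference reliable_change_value suggested_cutoff
#> 1                       2.78                      3.93                  7.70             7.70
```

Secondary-measure extraction (`extract_values()`), sudden losses
(`identify_sl()`), case selection (`select_cases()`), plot-ready aggregates
(`average_gain_profile()`, `trajectory_data()`) and plots (`plot_sg()`,
`plot_sg_trajectories()`) are documented in the vignette
(`vignettes/sudden-gains-methodology.Rmd`) and the function help pages.
Datasets export to `.csv`, `.tsv`, `.sav` and `.dta` via `write_bysg()` /
`write_byperson()`.

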