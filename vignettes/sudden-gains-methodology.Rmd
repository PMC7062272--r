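---
title: "Identifying sudden gains: methodology and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying sudden gains: methodology and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgains)
```

## The phenomenon and the model

A *sudden gain* is a large improvement in an outcome variable between two
consecutive measurements that is stable within the surrounding series —
classically studied in session-by-session depression scores during
psychotherapy, but applicable to any bounded repeated-measures outcome.
The session immediately before the gain is session *N* (pre-gain), the one
after is *N+1* (post-gain); other sessions are indexed relative to *N*.

Three criteria must hold for the interval *N* → *N+1*:

1. **Absolute:** `x_N − x_{N+1} ≥ c₁`, a cutoff in score units.
2. **Relative:** `x_N − x_{N+1} ≥ p · x_N`, a fraction of the pre-gain
   score.
3. **Stability:** the mean of the up-to-three measurements before the gain
   must exceed the mean of the up-to-three after it by more than a
   critical value times the pooled sample standard deviation of the two
   windows. This is *not* a literal two-sample t test — the critical value
   multiplies the pooled SD directly, without the `√(1/n₁ + 1/n₂)` factor —
   but it is algebraically equivalent to comparing the pooled t statistic
   against `t_crit / √(1/n₁ + 1/n₂)`, which is how the test suite
   cross-checks it through `stats::t.test()`.

Sudden *losses* are the mirrored phenomenon (large, stable deteriorations);
`identify_sl()` flips every direction-sensitive comparison. Some studies
raise the criterion-2 percentage for losses (e.g. 0.33); the argument is
exposed for that purpose.

## Tunable parameters

| Argument | Default | Units / range | Meaning |
|---|---|---|---|
| `sg_crit1_cutoff` | 7 | score units | absolute drop required (7 is the classic BDI value) |
| `sg_crit2_pct` | 0.25 | fraction in [0, 1) | relative drop required |
| `sg_crit2` | `TRUE` | — | apply criterion 2 at all (some studies omit it) |
| `sg_crit3` | `TRUE` | — | apply the stability criterion |
| `sg_crit3_alpha` | 0.05 | (0, 1) | alpha behind the adjusted critical value |
| `sg_crit3_adjust` | `TRUE` | — | adjust the critical value to the available data |
| `sg_crit3_critical_value` | 2.776 | — | fixed critical value when adjustment is off |

With adjustment on, the critical value is the two-tailed Student-t quantile
with `df = n_pre + n_post − 2`: 2.776 (3+3 points), 3.182 (3+2), 4.303
(2+2). With adjustment off, the fixed value is applied to every interval —
the other convention found in the literature.

`define_crit1_cutoff()` supports deriving `sg_crit1_cutoff` for a new
measure from a standard deviation and a reliability coefficient. Both
published conventions (the standard error of the difference `S_diff`, or
the reliable change value `1.96 · S_diff`) are computed and reported side
by side, because studies differ and the choice materially changes the
cutoff; the default recommendation is the reliable change value, and the
output always carries every intermediate quantity so reports can state the
convention used.

## Missing data and the tri-state verdict

No imputation is performed at the identification stage: carrying
observations forward or imputing could manufacture gains from data the
subject never provided. Instead every interval gets a tri-state verdict.

An interval is *evaluable* only if the pre- and post-gain points are
present and at least two of the three points on each side of the interval
are observed — at minimum four of the six window points. Sessions before
the first or after the last measured session count as missing, so for `S`
sessions the evaluable pre-gain indices are `2 … S−2` and the flag table
has `S−3` interval columns; columns for structurally impossible intervals
are omitted rather than emitted as all-`NA`.

Per-criterion columns report `TRUE`/`FALSE`/`NA` independently, but the
combined flag follows a strict rule: **if the interval is not evaluable the
combined verdict is `NA`**, even when some criteria could be computed (a
definite `FALSE` on criterion 1 does not rescue an untestable criterion 3,
because the interval as a whole could not have been classified under the
method); if the interval is evaluable, every enabled criterion is
computable and the verdict is 1 exactly when all are met. Each run also
attaches a log (`attr(x, "sg_missing_log")`) naming, for every
unclassifiable interval, which mandatory points were missing.

Criterion 2 with a non-positive pre-gain score is treated as not met, with
a warning: symptom scales are non-negative and a percentage drop from a
non-positive score is undefined.

## Degenerate inputs and numerical choices

* Criteria 1 and 2 are inclusive (`≥`, "at least"); criterion 3 is a
  strict `>`; the reversal test is inclusive ("or more"). These boundary
  semantics are the only ones applied — comparisons run at native double
  precision with no epsilon slack.
* A zero pooled SD (two flat windows) is legal; criterion 3 then reduces
  to a strict comparison of the window means, so two identical flat
  windows fail.
* `sg_change_proportion` is `NA` (with a warning), never a division error,
  when the total treatment change is zero or in the unexpected direction —
  the share of a non-improvement is not meaningful.

## Multiple gains, reversals, datasets

All gains of a subject are reported; adjacent or overlapping flagged
intervals are not suppressed, since no published exclusion rule exists.
The person-level dataset picks one gain per multi-gain subject via
`multiple_sg_select` (`first`, the default and the least
outcome-dependent; `last`; `smallest`; `largest` — ties broken by the
earlier session), and the choice is recorded in the dataset's attributes.

A gain reverses when a score at session `N+2` or later reaches
`x_{N+1} + 0.5 · (x_N − x_{N+1})` (the midpoint) or more; for losses the
rule mirrors (at or below the midpoint). "Stable reversals" (reversals
that are themselves sudden losses) are a further refinement described in
the literature and deliberately not operationalised here.

The gain-level dataset keys each record as `<id>_sg<N>` and stores the
around-gain scores, magnitude, total treatment change (signed so the
clinically expected direction is positive: start − end for gains,
end − start for losses), change proportion, reversal threshold and flag,
plus the raw session scores. `extract_values()` pulls a parallel secondary
measure at the same absolute sessions as each gain and refuses secondary
series whose length differs from the primary one, since misaligned
timepoints would silently shift the extraction window.

## The synthetic generator and what passing tests show

`sg_generate()` emulates the structure the method operates on: bounded
integer scores (0–63 by default), a gently declining background
(0.4 points/session by default) with AR(1) session noise (stationary SD
`noise_sd`, coefficient 0.3), optional random or monotone-dropout
missingness, an optional correlated secondary measure, and *planted* gains
as persistent downward steps whose positions and magnitudes are returned
as ground truth. The AR(1) background makes criterion 3 non-trivial:
uncorrelated white noise would understate the serial dependence real
symptom series show. Plants are validated on the noise-free skeleton
(range feasibility, three-session spacing so criterion-3 windows never
overlap, magnitude at least the cutoff and the criterion-2 fraction), so
with `noise_sd = 0` every planted gain is recovered exactly and nothing
else is flagged — a property the test suite checks over 100 random
generation specs, alongside a 10,000-window comparison of criterion 3
against an independent pooled-t oracle.

`sg_demo_data()` is a fixed-seed 43 × 12 instance designed as a
known-truth fixture: 16 gainers (9 with more than one gain; 26 gains
total), three planted reversals implemented as single-session rebounds
pinned just above the realised reversal threshold, and six curated
missing-data subjects including one too sparse for any interval to be
classified. It is synthetic: a stand-in with the right structure, not real
patient data.

What the generator does **not** emulate — therapist or site effects,
item-level measurement, floor effects from treatment responders, informative
dropout — bounds what passing tests show about real data: they demonstrate
that the criteria are implemented exactly and recover planted structure
under the stated noise model, not that sudden gains identified in any real
dataset reflect meaningful change processes.

## Problem sizes

The property suites run at sizes chosen to exercise the combinatorics
while keeping the default test run quick: 10,000 random windows for the
criterion-3 oracle, 100 random noise-free generation specs for exact
recovery, 200–1,000 repetitions for the symmetry and reliable-change
identities, and five moderately sized noisy datasets for the dataset
identities.

## Known limitations

* Only the three-criteria definition is implemented; no change-point or
  regression-based alternatives.
* Reliability estimation is the caller's job; `define_crit1_cutoff()`
  assumes a unidimensional scale with time-constant reliability.
* Long-format data must be reshaped to wide by the caller.
* Exports cover CSV/TSV/SPSS/Stata; spreadsheets are read but not written.
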