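---
title: "Methods: estimating when cardiovascular mortality overtakes cancer mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating when cardiovascular mortality overtakes cancer mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mortcross` estimates the time since cancer diagnosis at which the
cardiovascular mortality rate curve overtakes a cancer mortality rate curve
in a survivor cohort, together with a percentile-bootstrap confidence
interval, and ships a competing-risks simulator whose analytic ground truth
validates every stage. This vignette is the package's account of the
science: the model and its assumptions, the tunable parameters, what the
simulator does and does not emulate, the numerical choices, and the known
limitations.

## Model and assumptions

Follow-up runs on the time-since-diagnosis scale, beginning 1 year after
diagnosis (survivorship rather than the initial treatment period) and
ending at all-cause death or administrative censoring, at most 25 years
out. Censoring follow-up at death from any cause makes the estimands
*cause-specific hazards*: the mortality rate from one cause among people
still alive at that time. This describes the risk landscape faced by a
survivor who has reached a given point in survivorship. It is deliberately
not a subdistribution (Fine–Gray) analysis, which would instead describe
cumulative incidence from the moment of diagnosis.

Each person's follow-up is split over half-open time bands
$[a_i, b_i)$ — by default 1–<2, 2–<3, 3–<4, 4–<5, 5–<10, 10–<15 and 15–25
years — and deaths are attributed to the band containing the exit time.
Within one cancer site and one cause of death $c$, the death count in cell
$(g, i)$ (age group $g$, band $i$) is modelled as
$$d_{gi} \sim \text{Poisson}(\lambda_{gi} \cdot PY_{gi}),$$
a log-linear model in categorical age and band effects. Two variants are
implemented:

* **age-stratified (default, `age_interaction = TRUE`)** — one parameter
  per age × band cell. The model is saturated, so the maximum-likelihood
  predicted rate is the closed form $d_{gi}/PY_{gi}$. This is the variant
  used for crossover estimation, because the scientific question concerns
  the *shape* of each age group's curves and nothing is borrowed across
  ages.
* **main-effects (`age_interaction = FALSE`)** — common band effects plus
  a multiplicative age effect, fitted by iteratively reweighted least
  squares (`stats::glm`, Poisson family, `log(PY)` offset, convergence at
  relative deviance change $10^{-10}$ within 100 iterations;
  non-convergence is an error, never silently accepted). The description
  of the modelling as categorical age and time effects is ambiguous about
  interactions, so both readings are available; the default is stratified.

Predicted rates are reported per 1,000 person-years at the band midpoint
$m_i = (a_i+b_i)/2$ (the 10–<15 band at 12.5 years, etc.).

The crossover point between the cardiovascular curve $v$ and a cancer curve
$c$ is found by scanning consecutive midpoints where both are defined for
the first sign change of $v - c$ from negative to non-negative, and
intersecting the straight lines joining the two points:
$$t^* = m_i + (m_{i+1} - m_i)\,
  \frac{c_i - v_i}{(c_i - v_i) + (v_{i+1} - c_{i+1})}.$$
Exact equality at a midpoint yields that midpoint. Interpolation is on the
natural rate scale — the plainest reading of interpolating "between points
on either side" — with a log-scale variant available as a sensitivity
switch (`find_crossover(..., scale = "log")`); the two agree on which
bands bracket the crossing and differ only in where $t^*$ falls within
the bracket. Later re-crossings are
ignored: the estimand is the *first sustained overtaking*. Crossovers later
than the 20-year reporting horizon are reported as `never_within_horizon`
even though bands extend to 25 years, matching the convention of not
reporting crossovers beyond 20 years; both horizons are configurable.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `band_scheme()` breaks | 1,2,3,4,5,10,15,25 | years since diagnosis | annual resolution early (rates change fast), 5–10-year bands late (events thin out) |
| `horizon` (crossover) | 20 | years | reporting convention; late crossings sit in the widest band and are poorly identified |
| `level` | 0.95 | — | conventional two-sided coverage |
| `max_ci_width` | 50 | per 1,000 person-years | figure-truncation rule: suppress curves from the earliest band whose CI is wider than this |
| `B` | 200 | replicates | percentile bootstrap with 2.5th/97.5th percentiles |
| `cause_field` | `"underlying"` | — | `"immediate"` switches to the death-certificate sensitivity analysis |
| `p_disagree` | 0.05 | probability | immediate-vs-underlying certificate discordance in the simulator |
| `cens_window` | (5, 24) | years of potential follow-up | staggered entry against a fixed study end (below) |

## What the simulator emulates — and what it does not

`simulate_cohort()` draws, for each person, a latent all-cause event time
by exact inversion of the cumulative total hazard. Hazards are
piecewise-linear or piecewise-constant in time since diagnosis; both have
closed-form (piecewise-quadratic) cumulative hazards, so sampling is exact
— no discretisation, no rejection. The cause of death is drawn at the
realised time $t$ with probability $\lambda_c(t)/\sum_k \lambda_k(t)$,
which is the exact factorisation of a competing-risks process into total
intensity and cause allocation. Administrative censoring is a per-person
uniform draw of potential follow-up from `cens_window` after entry
(default 5–24 years, capping exits at the 25-year horizon), emulating
staggered diagnosis dates against a fixed study end; the joint
distribution of diagnosis dates and study end is not otherwise specified
anywhere, so this uniform window is a package design choice, exposed in
configuration. The immediate cause equals the underlying cause except with
probability `p_disagree`, when a uniformly random different cause is
recorded — a deliberately mechanism-free symmetric relabelling, since only
the existence of certificate discordance is established, not its
structure.

The `multisite` preset covers nine cancer sites × three age strata with
primary-cancer hazards declining in time (steeply for lung, colorectal,
bladder and uterus, gently for breast and prostate), cardiovascular
hazards rising with time and age, and second-cancer and other-cause
competing hazards. Stratum sizes and female fractions come from the
shipped study-population fixture (~104k survivors in total at scale 1).
The hazard *values* are illustrative: they reproduce the qualitative
pattern — crossovers within 20 years for most sites in the older strata,
essentially none in the 40–59 stratum — not any site's real rates.

What passing tests on these cohorts shows: the pipeline recovers known
crossing times from band-aggregated count data at realistic cohort sizes,
conserves person-time exactly, and attributes causes correctly. What it
does not show: anything about calendar-period or attained-age effects
(the simulator has a single time scale), treatment, stage or recurrence
structure, non-administrative loss to follow-up, or real cause-of-death
coding error — none of which the generator models. The shipped
denominator fixture pins only the *margins* of the real cohort (counts by
site × age), not its rate structure.

## Numerical choices

* **Inversion sampling.** Within a grid piece with total hazard
  $\lambda(t) = \lambda_s + a_1 (t - s)$, the event-time increment solves
  $\tfrac{a_1}{2}u^2 + \lambda_s u = r$; the root is computed as
  $u = 2r / (\lambda_s + \sqrt{\lambda_s^2 + 2 a_1 r})$, stable for
  $a_1$ of either sign and degrading gracefully to $r/\lambda_s$ as
  $a_1 \to 0$. Zero-hazard pieces are skipped exactly (ties in the
  cumulative-hazard lookup resolve rightward).
* **Band boundaries.** Bands are half-open $[a, b)$: follow-up ending at
  an interior boundary contributes no time to the right band, while a
  death at that instant belongs to the right band (the band the person
  was entering). The terminal boundary is closed for event assignment, so
  an exit at exactly 25 years is representable. Person-years are overlap
  lengths; their per-person sum equals exit − entry to well under
  $10^{-9}$ years.
* **Zero cells.** Cells with zero person-years yield `defined = FALSE`
  and `NA` rates — never zero, which would masquerade as a real rate and
  corrupt crossover detection. Zero-death cells have rate 0 with an exact
  Poisson upper bound $-\ln(\alpha/2)/PY$, and are treated as exceeding
  any precision-truncation threshold.
* **Crossover ties.** Exact equality of the two curves at a midpoint
  gives $t^*$ at that midpoint (the interpolation formula produces this
  automatically when the second gap is zero). Equality at the *first*
  usable midpoint counts as a crossover there only if the cardiovascular
  curve is strictly above at the next midpoint; otherwise the stratum is
  `already_overtaken_at_first_midpoint`.
* **Analytic ground truth.** `true_crossover()` works piece by piece on
  the merged breakpoint grid, where the hazard difference is linear, so
  roots are closed-form; a jump of the difference from negative (left
  limit) to non-negative across a step-function breakpoint counts as a
  crossover at the breakpoint, consistent with a fine-grid scan.
* **Bootstrap reproducibility.** Resampling uses one `set.seed(seed)`
  followed by `B` draws; quantiles use type 7 (linear interpolation
  between order statistics), so CI endpoints are bit-for-bit reproducible
  at a fixed seed. The fast path aggregates precomputed person × band
  contributions under multiplicity weights; a test verifies it equals
  explicit resample-and-refit through the public pipeline exactly.
* **Non-crossed replicates** are excluded from the percentiles but always
  counted and reported (`n_not_crossed`), and the CI is flagged unstable
  when they exceed 5% of `B`. Silently dropping them would bias the CI
  invisibly; there is no established convention to defer to here.
* **Bootstrap resampling unit** is the individual, within site,
  unstratified by age (the cohort is a simple random quantity at site
  level); age-stratified resampling is available (`stratify_age = TRUE`)
  and recorded in the estimate's metadata.

## Accuracy of the interpolation estimator

Band-midpoint interpolation carries two systematic errors worth knowing
about. First, a band's crude rate estimates the *person-time-weighted*
mean hazard over the band, which sits slightly before the midpoint
whenever mortality or censoring thins the cohort within the band; both
curves shift the same way, so the induced crossover bias is small (of
order 0.05–0.1 years at the default hazard scales). Second, and larger:
if a hazard is *not* linear within a band — for example a steeply falling
cancer hazard that floors at zero mid-band — the band average is not the
midpoint value, and the interpolated crossing can be displaced by several
tenths of a year. The parameter-recovery study therefore uses
configurations whose hazards are genuinely linear across the bands
bracketing the crossing (`linear_crossing_hazards(t, rate_at_cross = 16,
cvd_at_entry = 2, cancer_at_entry = 30)`, no administrative censoring):
under those conditions the median absolute error across 20 true crossings
spread over 3–18 years is about 0.1 years at $n = 10^5$ per stratum, and
the 50-replicate bootstrap CI covers the truth. Under the preset's
nonlinear (floored) hazards and default censoring, the same estimator
shows a deterministic bias of roughly +0.2 to +0.4 years around an 8-year
crossing — a property of coarse-band interpolation itself, visible in the
package because the simulator's truth is analytic, and worth remembering
when interpreting real-data crossovers to one decimal place.

## Problem sizes used by the tests

Unit tests run on cohorts of 200–50,000 persons; the deeper verification
suite uses $10^5$ persons per stratum for the sampler's distributional
checks (cause split and truncated-exponential law within 3 standard
errors), 1,000 randomised curve pairs against a $10^{-5}$-step brute-force
intersection (agreement within $10^{-4}$ years), 10,000 randomised
records for exact person-time conservation, and the 20-configuration
recovery sweep described above. The full suite completes in about a
minute on one CPU; the end-to-end analysis scripts under `analysis/` use
the full ~104k-person preset cohort and 200 bootstrap replicates.

## Interfaces

The package surface is functional: `simulate_cohort()` /
`write_cohort()` / `read_cohort()`, `split_followup()` /
`tabulate_person_time()` / `validate_margins()`, `fit_rates()` /
`rate_ci()` / `truncate_curve()`, `find_crossover()` /
`bootstrap_crossover()` / `crossover_table()`, and `run_pipeline()` over
a YAML config. The numbered scripts under `analysis/` are the
command-line entry points: simulate, person-time, rates, crossover and
fixture validation, in order, writing delimited-text tables under
`results/` and a JSON manifest via `run_pipeline()` — a deliberate
analysis-workflow layout rather than a separate CLI binary, since the
product of the method is a sequence of tables over one cohort.

## Known limitations

* Crossover precision is limited by band width; late crossings (in the
  5- and 10-year bands) are intrinsically coarse, and the reporting
  horizon of 20 years acknowledges that.
* The saturated model provides no smoothing: sparse cells give wide CIs
  and, past the truncation threshold, suppressed curves. The main-effects
  model borrows strength across ages at the cost of assuming a common
  band shape.
* The simulator's single time scale cannot represent age–period–cohort
  structure, and its censoring window is a stylised stand-in for real
  staggered entry.
* The shipped denominator fixture validates transcription totals, not
  rates; no real individual-level data are included or reproduced.
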