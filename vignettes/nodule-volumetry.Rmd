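---
title: "Methods: measured versus estimated nodule volume"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measured versus estimated nodule volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulevol)
```

## The comparison this package implements

Volumetric lung cancer screening assigns each solid pulmonary nodule an
outcome category from its volume, and each category an interval to the
next scan. `nodulevol` asks what happens to those assignments when the
software-measured volume (MV) is replaced by the estimated volume (EV)
obtained from the maximal diameter under a spherical assumption,
$EV = \tfrac{\pi}{6} D^3$. The pipeline is:

1. **Eligibility.** Baseline nodules with maximal diameter $\ge$ 3 mm
   (inclusive) enter the analysis.
2. **Classification.** Each eligible nodule is categorised twice:
   negative ($V < 113$ mm³), indeterminate ($113 \le V \le 260$ mm³) or
   positive ($V > 260$ mm³), once with $V = MV$ and once with $V = EV$.
3. **Growth.** For nodules re-measured at follow-up, the volume
   doubling time $VDT = \ln 2 \cdot \Delta T / \ln(V_2/V_1)$ is
   categorised as probably malignant ($< 400$ d), indeterminate
   ($[400, 600]$ d) or probably benign ($> 600$ d), again under both
   measures; the EV-based VDT uses EV at *both* timepoints, simulating
   a purely diameter-driven programme.
4. **Cross-tabulation.** MV (rows) versus EV (columns) categories are
   tallied twice over: per nodule (PN-based) and per screenee, the
   latter on the dominant nodule.
5. **Agreement.** Percent agreement and weighted Cohen's kappa
   summarise each table; the severity-shift fraction reports how many
   discordant items moved toward a more severe EV category.
6. **Recall burden.** Screenees are rescanned at the interval attached
   to their category (36 / 12 / 3 months for negative / indeterminate /
   positive) until a horizon, and the scheduled scans are totalled
   under each measure.

## Decisions made where the procedure was under-specified

**Band boundaries.** The outer categories are defined by strict
inequalities ($< 113$, $> 260$; $< 400$, $> 600$), which forces both
indeterminate bands to be closed on both ends. `classify_outcome(113)`
and `classify_outcome(260)` are therefore indeterminate, and likewise
VDTs of exactly 400 or 600 days.

**Shrinking and stable nodules.** The VDT of a shrinking nodule is
negative and that of an unchanged nodule undefined (the denominator of
the formula vanishes; `compute_vdt()` returns `NA`). Neither is growth,
so both default to *probably benign*. The alternative literal reading
of the "$< 400$ d" rule — under which a negative VDT would be probably
malignant — is available as
`screening_thresholds(nongrowth_rule = "literal")`.

**Dominant nodule.** The selection criterion at screenee level is a
design choice. The default (`by_MV`) takes the nodule with the largest
measured volume — volume being the programme's primary metric — with
ties broken by larger diameter, then smallest nodule id, so selection
is deterministic. `by_EV` keys on the diameter instead, and
`worst_category` assigns each screenee, per measure, the most severe
category among all their nodules (the representing nodule may then
differ between measures).

**Severity direction.** Outcome labels are ordered
negative < indeterminate < positive, so a shift toward severity lies
above the table diagonal. VDT labels are ordered by increasing doubling
time — probably_malignant first — so there the severe side is *below*
the diagonal. `severity_shift_fraction()` exposes this as its
`increasing_severity` flag, and the cohort pipeline sets it per metric.

**Recall schedule.** With interval $m$ months and horizon $H$ months a
screenee receives $\lfloor H/m \rfloor$ scans (the baseline scan is not
counted; a scan falling exactly on the horizon is). The positive-
category interval is not part of the published threshold set; 3 months
is the package default and is configurable. Calendar conversion, where
needed, uses 1 month = 30.44 days.

## The kappa weight scheme

Weighted Cohen's kappa is
$\kappa = (P_o - P_e)/(1 - P_e)$ with
$P_o = \sum_{ij} w_{ij} n_{ij}/N$ and
$P_e = \sum_{ij} w_{ij} r_i c_j/N^2$. The weight scheme the original
analysis used is not stated, so the package identifies it empirically:
on the four fixture tables,

```{r kappa-schemes}
sapply(c("unweighted", "linear", "quadratic"), function(s)
  round(sapply(fixture_tables(), function(t) weighted_kappa(t, s)$kappa), 2))
```

only the quadratic (Fleiss–Cohen) column reproduces the published
coefficients (0.49, 0.37, 0.52, 0.34) on all four tables
simultaneously, so quadratic weights are the package default; linear
and unweighted schemes remain selectable. Reported coefficients are
rounded half-up to two decimals; full precision is retained in all
objects and machine-readable output.

## The synthetic cohort generator

The generator emulates the *statistical structure* the analyses
consume, not the imaging process:

| parameter | default | role |
|---|---|---|
| `n_screenees` | 1583 | cohort size |
| `mean_nodules` | 1.72 | zero-truncated Poisson nodule count per screenee |
| `mv_log_median_mm3` | 30 | median of the lognormal true-volume distribution, mm³ |
| `mv_log_sigma` | 1.3 | log-sd of the true-volume distribution |
| `shape_alpha`, `shape_beta`, `shape_max` | 5, 3, 1.05 | shape ratio $s = MV/EV \sim 1.05\,\mathrm{Beta}(5,3)$ |
| `followup_fraction` | 2311/2715 | fraction of nodules re-measured |
| `delta_days` | 365 | scan interval, days |
| `malignant_fraction` | 0.02 | nodules with true exponential growth |
| `true_vdt_median_days`, `true_vdt_log_sd` | 150, 0.5 | lognormal true doubling time of growing nodules |
| `measurement_cv` | 0.15 | multiplicative volume measurement noise, both scans |
| `min_diameter_mm` | 3 | eligibility floor; undersized draws are rejected and redrawn |

Each nodule receives a true volume, a persistent shape ratio $s$, and
independent median-unbiased lognormal measurement noise at each scan;
the recorded diameter is that of the EV sphere, $EV = MV/s$. Growing
nodules evolve as $V(t) = V_0 \cdot 2^{\Delta t/VDT}$. All sampling is
vectorised inverse-CDF or standard R generators under a single config
seed (follow-up generation uses the `seed + 1` substream), so identical
configurations give bit-identical cohorts.

Calibration: the defaults were fixed once, by simulation, to match the
published cohort shape — 1583 screenees with ~2715 nodules, ~85 % of
nodules re-measured, and baseline MV category marginals near
81.1/12.1/6.8 %. The volume median of 30 mm³ is a *post-truncation*
calibration: the 3 mm diameter floor removes predominantly small
(negative-category) nodules, so the median of the accepted sample sits
well above the median of the parent lognormal, and a parent median
chosen to match the marginals before truncation would miss them after
it. For the same reason, checks that the generator recovers its own
lognormal parameters (median within 2 % at $n \ge 10^5$) are run with
`min_diameter_mm = 0`: they test the sampler, and left truncation would
bias the empirical statistics by construction.

Two deliberate structural properties: with `shape_max = 1.05` about
0.4 % of nodules have $s > 1$ (MV exceeding EV), mirroring the handful
of below-diagonal entries in the published tables, and `shape_max = 1`
makes the below-diagonal exactly empty. And because the default shape
ratio persists between scans, it cancels in $V_2/V_1$: EV-based and
MV-based VDTs agree *exactly* on default synthetic cohorts. Setting
`refresh_shape_ratio = TRUE` redraws the ratio at follow-up — modelling
independent diameter re-measurement — which is what generates VDT
discordance between the measures.

What passing tests on synthetic cohorts do **not** show: the generator
draws volumes and shape ratios independently, has one follow-up round,
no nodule morphology, no reader or scanner effects, and its measurement
noise is a single multiplicative lognormal. Agreement statistics
measured on synthetic cohorts therefore need not match the published
coefficients — those are reproduced from the packaged fixture tables,
which are the authoritative record of the real cohort.

## Numerical choices and degenerate inputs

* `compute_vdt()` flags the zero-growth case ($V_2 = V_1$) as `NA`
  rather than ±Inf; classification then applies the non-growth rule.
* `weighted_kappa()` refuses empty tables and tables with degenerate
  marginals ($P_e = 1$, e.g. all mass in one cell), where kappa is
  undefined.
* `severity_shift_fraction()` on a perfectly concordant table warns and
  returns `NA` — the fraction has an empty denominator — so fully
  concordant cohorts still flow through `run_report()`.
* The volume/diameter conversion round-trips to within $10^{-9}$
  relative error across $(0, 10^4]$ mm³; equality thresholds in
  classification are exact floating-point comparisons against the
  configured cut-offs (the defaults are integers, so 113 and 260 mm³
  classify reproducibly).
* Test and example problem sizes: property loops use hundreds of random
  cases; generator checks use 20 seeded default-size cohorts
  (~2.7k nodules each) and one $10^5$-nodule cohort for parameter
  recovery. The whole suite runs in well under a minute.

## Known limitations

* MV is always an input; the package neither segments images nor
  models segmentation error structure beyond multiplicative noise.
* Sub-solid nodules, multi-round longitudinal trajectories, malignancy
  outcomes and mortality are out of scope.
* Kappa is reported without standard errors or confidence intervals.
* The recall simulation holds each screenee's category fixed over the
  horizon; it counts scheduled scans, not diagnostic cascades.
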