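---
title: "Valid-day compliance analysis for perioperative step-count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valid-day compliance analysis for perioperative step-count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periwear)
library(data.table)
```

## The problem

When patients recovering from ambulatory surgery — the motivating case is
total knee arthroplasty (TKA) — wear a consumer step tracker, the first
analytical step is deciding which days of data to trust. A *valid-day
(compliance) criterion* is a deterministic rule mapping one day's step
record to valid/invalid; days failing the rule are discarded before any
activity analysis. The trouble is that the literature uses many such
rules, they are not interchangeable, and surgery itself—by temporarily
suppressing mobility—interacts with the strictness of the rule: a patient
can be wearing the tracker faithfully while taking too few steps to
satisfy a strict threshold.

periwear implements the full analysis: ingest of minute- or
hour-resolution step tables, alignment on a fixed 57-day perioperative
grid (day −14 through day 42, surgery at day 0), five built-in valid-day
criteria, patient/day/stage summaries of compliance and between-criteria
deviation, correlation and mixed-model association analyses, the standard
figures, and a synthetic cohort generator that makes every stage of the
pipeline testable without patient data.

## The day grid and stages

A timeline is a 57 × 24 matrix of hourly step counts. A calendar day is
local midnight-to-midnight, and an hour bin is the clock-hour label
(00:00–00:59 → bin 0); timestamps are treated as naive local time, so
daylight-saving bookkeeping is out of scope by design. Days with no
records are materialised as all-zero days rather than omitted: a gap is
evidence of non-wear and must score invalid under *every* criterion, and
period compliance always divides by the full window size.

Four two-week stages partition the window minus the surgery day:
presurgery (−14..−1), weeks 0–2 (1..14), weeks 2–4 (15..28) and
weeks 4–6 (29..42). Day 0 belongs to no stage; whole-period (57-day)
summaries include it. Both conventions are exposed (`include_day0` in the
CLI) because reasonable analyses differ on whether the surgery day itself
should count.

## The five criteria

| id | rule |
|----|------|
| `gt0_steps` | ≥ 1 step anywhere in the day |
| `gt500_steps` | strictly more than 500 steps |
| `ge10_hours` | ≥ 1 step in ≥ 10 distinct clock hours |
| `three_a_day` | ≥ 1 step in each of 3 am–11 am, 11 am–3 pm, 3 pm–3 am |
| `three_of_four` | ≥ 1 step in ≥ 3 of the four six-hour windows |

Window bounds are half-open on hour labels, so "3 am–11 am" is hours
3–10; this partitions the day without double counting. Two readings are
deliberate and literal: ">500" is strict (exactly 500 is invalid) and
">0" means any single step. Hour windows are fixed clock hours, not
sliding 60-minute windows, which is the conventional reading of
"different 1-hour windows" and the only one computable from hourly data.

The 3-a-day evening window (3 pm–3 am) crosses midnight. The source
definitions do not say which day owns the borrowed hours, so both
behaviours are implemented: by default hours 0–2 of the *next* day count
toward the current day's evening window (wrap), truncating at midnight on
the final day; `three_a_day_wrap = FALSE` truncates always. Every
predicate is cross-validated against an independent minute-level
brute-force oracle (in the test suite) that encodes the same wrap choice
in minute arithmetic.

Two structural facts are worth stating because the test suite leans on
them: **dominance** (any day valid under any criterion is valid under
`gt0_steps`, so every `gt0_steps` summary is an upper bound) and
**monotonicity** (adding steps can never invalidate a day).

## Deviation statistics and models

Between-criteria deviation — the SD across the five compliance values,
per day over sample rates or per patient over period outcomes — measures
how sensitive a reported compliance figure is to criterion choice. The SD
uses the sample (n−1) denominator by default, matching the default of the
desktop statistics environments this analysis style comes from; a
population-denominator switch is provided.

Associations use the point-biserial correlation (identical to Pearson on
a 0/1 coding; device clip = 0, wrist = 1) with the two-sided t-based
p-value on n − 2 df. Stage-wise analyses fit a linear mixed model with a
patient random intercept via `lme4::lmer` (REML by default). Because
denominator-df approximations (Satterthwaite/Kenward–Roger) are not
available in this dependency set, coefficient p-values are Wald-z and
per-term omnibus tests are ML likelihood ratios (`drop1` on an ML refit);
treatment contrasts against the first factor level are recorded in the
report. Coefficient estimates and SEs — the quantities the parameter
recovery acceptance layer checks — are unaffected by that choice; exact
published mixed-model test statistics from other software are explicitly
not reproduction targets, since their contrast coding and df method are
unreported. No multiplicity correction is applied.

## The synthetic cohort

The generator's defaults describe one fixed world chosen to match the
motivating study's setting, not tuning knobs:

* **Cohort**: 20 patients, 60% wrist devices; age ~ N(64.5, 8.94²)
  truncated to 37–85, 65% female, BMI ~ N(30, 4²), ASA mostly class 2.
* **Wear behaviour**: presurgery wear probability 0.9 with mean-preserving
  Beta(conc = 60) patient heterogeneity (so the expected presurgery
  `gt0_steps` compliance equals the configured probability — a recovery
  test target); a day-0 bump (hospital staff remind patients), a dip to
  0.8 just after surgery and linear return by day 28. Clip devices carry
  an extra 0.12 daily forget probability.
* **Activity**: 4,000 mean daily steps on a fully worn presurgery day — a
  low-mobility pre-TKA population — spread over a waking-hours diurnal
  template (07:00–22:00 wear window draws), with a surgery dip to 15% of
  baseline at day 0 recovering linearly over 35 days. Published
  calibration narrative (documented, not asserted): roughly a
  quarter-of-the-sample drop in mean compliance after surgery with
  recovery over the following weeks; the 20-patient default makes the
  realised drop noticeably seed-dependent, which is faithful to a cohort
  of that size.
* **Counts**: zero-inflated negative binomial per hour. An hour with
  target mean *μ* is active with probability 1 − exp(−μ/150) (activity
  bouts), and active hours draw NB(size = 0.3) with the mean rescaled to
  conserve the daily total. Burstiness matters: it is what makes
  low-intensity recovery days concentrate steps into few clock hours, so
  the hour- and window-based criteria diverge from the step-count ones
  after surgery. Poisson is recovered as size → ∞.
* **Device placement effect**: wrist devices register 1.5 incidental
  steps per worn hour (arm movement) versus 0.2 for clip devices, and
  incidental registration does *not* dip with surgery. Clip wearers also
  lose 6 evening wear hours in weeks 0–2 (3 in weeks 2–4) — the
  forget-to-unclip behaviour reported anecdotally. Together these
  reproduce the qualitative finding the deviation analyses target: clip
  wearers' between-criteria deviation exceeds wrist wearers', most
  strongly in the first two postoperative weeks, while the wrist group's
  criteria stay in close agreement throughout recovery.

What the generator does **not** emulate: within-minute step
microstructure (it writes hour-level records; criteria are provably
hour-sufficient), realistic gait, weekday/weekend rhythm, device battery
failure, or informative dropout. A green pipeline test therefore
establishes correctness of the *computation* on data with the assumed
structure, not that real Fitbit data have that structure.

## Numerical and degenerate-input choices

* Ties/boundaries: all thresholds are read literally (≥1, >500, ≥10
  hours, ≥3 windows).
* Empty cohorts and empty device groups warn and produce empty/skipped
  outputs instead of erroring; an empty day range or unknown stage name
  errors.
* Constant-response mixed models return point estimates with NA
  standard errors (the information matrix is singular); the random
  intercept variance is reported as 0.
* Correlations refuse zero-variance inputs and n < 3 explicitly rather
  than returning NaN.
* Determinism: a cohort is a pure function of its config (including
  seed); the CLI writes a manifest (config hash, seed, row counts)
  sufficient to reproduce a run.

## Known limitations

* The heatmap's grayscale is linear white→black clamped at 500 steps/h;
  the original figures' exact interpolation is unknown.
* Partial first/last days (device delivered mid-day) are kept as-is; no
  wear-time imputation is attempted anywhere, by design.
* The mixed-model omnibus tests are asymptotic LRTs; with 20 patients
  they are anti-conservative relative to small-sample F approximations.
  Parameter estimates, not p-values, are the validated quantities.
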