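# periwear

Compliance analysis for perioperative activity-tracker data.

When surgical patients (the motivating case is total knee arthroplasty)
wear a consumer step tracker through the perioperative period, analysts
must first decide which patient-days are *valid days of wear*. periwear
implements five standard valid-day criteria and quantifies how much the
choice among them changes the story — per patient, per day, per two-week
recovery stage, and as a function of device placement (clip vs wrist) and
demographics. Because post-surgical mobility is temporarily suppressed,
strict criteria silently discard recovery-period data; this package makes
that sensitivity measurable.

## What it computes

For each patient-day (a 24-hour vector of hourly step counts on the
57-day grid, day −14 … 42 with surgery at day 0) the five criteria are:

* **>0 steps** — ≥ 1 step anywhere (most lenient; an upper bound on every
  other criterion);
* **>500 steps** — strictly more than 500 steps;
* **≥10 hours** — ≥ 1 step in at least 10 distinct clock hours;
* **3-a-day** — ≥ 1 step in each of 3 am–11 am, 11 am–3 pm, 3 pm–3 am
  (the evening window wraps past midnight by default);
* **3-of-4 windows** — ≥ 1 step in at least 3 of the four six-hour
  windows.

Days without data count as non-compliant under every criterion (a gap is
evidence of non-wear), and compliance over a window is
`valid days / window size` ∈ [0, 1]. Between-criteria deviation is the
standard deviation across the five compliance values — per day over
cohort rates, or per patient over whole-period outcomes — and is related
to device placement via point-biserial correlation
(r = Pearson on a 0/1 coding, two-sided t test on n − 2 df) and to
stage × covariates via a linear mixed model with a patient random
intercept (`lme4`).

A synthetic cohort generator (wear behaviour × wear window ×
zero-inflated negative-binomial hourly counts with a surgery
dip-and-recovery multiplier) makes the entire pipeline testable without
patient data; see `vignettes/compliance-methods.Rmd` for the model and
every default.

## Worked example

```r
library(periwear); library(data.table)

sim <- simulate_cohort(sim_config(n_patients = 20, seed = 42))
m   <- evaluate_matrix(sim$cohort)            # patient x day x criterion
pc  <- period_compliance(m)                   # whole 57-day window

as.data.table(pc)[, .(mean = round(mean(value), 2), sd = round(sd(value), 2),
                      min = round(min(value), 2), max = round(max(value), 2)),
                  by = criterion]
#>        criterion  mean    sd   min   max
#> 1:    ge10_hours  0.58  0.28  0.21  0.95
#> 2:     gt0_steps  0.80  0.12  0.58  0.96
#> 3:   gt500_steps  0.72  0.12  0.54  0.91
#> 4:   three_a_day  0.75  0.14  0.51  0.96
#> 5: three_of_four  0.68  0.19  0.44  0.96
```

Mean reported compliance ranges from 0.80 under the most lenient
criterion to 0.58 under the strictest — a 22-point swing from the
filtering rule alone, on identical data. Is a patient's sensitivity to
criterion choice associated with wearing the tracker as a clip rather
than on the wrist?

```r
feats <- patient_features(pc, sim$cohort$meta)   # per-patient SD + covariates
point_biserial(feats$device01, feats$sd_compliance)
#> Point-biserial correlation: r = -0.841, t(18) = -6.597, p = 3.399e-06 (n = 20)
```

With wrist coded 1, the negative correlation says wrist wearers have
systematically *lower* between-criteria deviation: their five compliance
figures agree; clip wearers' do not. The stage-wise mixed model
quantifies where criteria separate:

```r
tab <- build_stage_table(stage_compliance(m), sim$cohort$meta)
rep <- stage_effect_model(tab, compliance ~ criterion + stage + device + age)
rep$coefficients[1:8, ]
#>                     term estimate     se statistic        p
#> 1            (Intercept)  1.12144 0.1672    6.7082 1.97e-11
#> 2   criteriongt500_steps -0.06964 0.0244   -2.8567 4.28e-03
#> 3    criterionge10_hours -0.21250 0.0244   -8.7166 2.87e-18
#> 4   criterionthree_a_day -0.05089 0.0244   -2.0876 3.68e-02
#> 5 criterionthree_of_four -0.10982 0.0244   -4.5048 6.64e-06
#> 6         stageweeks_0_2 -0.29643 0.0218  -13.5945 4.32e-42
#> 7         stageweeks_2_4 -0.12143 0.0218   -5.5688 2.56e-08
#> 8         stageweeks_4_6 -0.00143 0.0218   -0.0655 9.48e-01
```

Relative to the `gt0_steps` reference, every stricter criterion lowers
two-week compliance (≥10 hours by 21 points); relative to presurgery,
weeks 0–2 cost 30 points of compliance while weeks 4–6 have fully
recovered. Figures mirror the published analysis style:
`activity_heatmap()` (hour × day grid, white→black clamped at 500
steps/h, red rule at surgery), `daily_compliance_plot()` (mean ± SD
band), `criteria_overlay_plot()` and `device_panels()`.

## Command line

```sh
Rscript inst/cli/periwear.R simulate --seed 7 --outdir out/sim
Rscript inst/cli/periwear.R analyze --config run.cfg --outdir out/analysis
```

where `run.cfg` is flat `key: value` text (e.g. `simulate: true`,
`n_patients: 20`, `three_a_day_wrap: true`). `analyze` writes
`validity.csv`, `period_compliance.csv`, `stage_compliance.csv`,
`daily_rates.csv`, `deviation_series.csv`, `retention.csv`, correlation
and mixed-model reports, the figures, and a `manifest.json` (config
hash, seed, row counts) that makes the run reproducible.

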