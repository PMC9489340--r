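# hfmarkov

Long-term outcome analysis for two-arm heart-failure cohorts followed at
6-month intervals: baseline characterization with derived echocardiographic
indices, a Kaplan–Meier / log-rank / nested Cox survival pipeline, and a
five-state absorbing discrete-time Markov cohort model that projects NYHA
functional class and composite cardiovascular events (CVE) to 60 months.

## Who this is for

Clinical researchers comparing two treatment modalities (here labelled
*integrative* vs *conventional* therapy) on time-to-CVE in heart-failure
patients, where follow-up is short (6–36 months, staggered entry) but a
longer-horizon projection of functional status is wanted. Because such
cohorts are typically confidential, the package ships a synthetic-cohort
generator with a truth ledger so every estimator can be exercised and
validated against known ground truth.

## The models

**Derived indices.** Left ventricular mass by the Devereux formula,
LVM (g) = 0.8 · 1.04 · \[(LVIDd + PWTd + SWTd)³ − LVIDd³\] + 0.6 (dimensions
in cm), BSA (m²) = 0.0061·height + 0.0128·weight − 0.1529, LVMI = LVM/BSA.

**Survival stage.** Kaplan–Meier product-limit curves per arm with Greenwood
CIs; "average survival" as the restricted mean survival time (RMST) over
\[0, max observed time\]; log-rank comparison; three nested Cox
proportional-hazards tiers (I: age + gender; II: + BMI, medications,
comorbidities, smoking, admission NYHA class; III: + labs, LVEF, LVMI), Efron
tie handling (events sit on the 6-month visit grid), Harrell's C and an IPCW
cumulative/dynamic time-dependent ROC at 12 months; subgroup sensitivity
refits of the tier-III model.

**Markov stage.** States {NYHA I, II, III, IV, CVE}, CVE absorbing. The
6-month transition matrix is the row-normalised count matrix of paired
discharge → 6-month observations, P̂ᵢⱼ = nᵢⱼ/nᵢ. The discharge-state
distribution v₀ (in-hospital deaths excluded) is cycled v_{k+1} = v_k P for
10 cycles (60 months); state distributions are reported at 1/3/5 years and
validated against the observed 12-month distribution with a chi-square
goodness-of-fit test, Σ(O − Np)²/(Np), df = k − 1.

## Worked example

```r
library(hfmarkov)

out <- tempfile()
full_pipeline(run_config(out = out, seed = 1L))   # simulates 181 + 213 patients

read.csv(file.path(out, "km_table.csv"))[, c("group", "n", "events", "rmean", "median")]
#>          group   n events rmean median
#> 1          all 392    200 18.16     18
#> 2 conventional 213    124 16.29     12
#> 3  integrative 179     76 20.34     24
```

392 of 394 simulated patients enter the survival analysis (two in-hospital
deaths have no follow-up); the integrative arm survives longer (RMST 20.3 vs
16.3 months; log-rank χ² = 13.59, p = 2.3e-4). The fully adjusted Cox model:

```r
jsonlite::read_json(file.path(out, "cox_results.json"))$model_III[c("hr", "p")]
#> HR 0.565 (0.400, 0.799), p = 0.0012
```

i.e. a lower adjusted CVE hazard in the integrative arm of this synthetic
world. The Markov projection for the integrative arm:

```r
read.csv(file.path(out, "predictions_integrative.csv"))
#>     year   I   II  III   IV  CVE
#> 1 year_1 6.0 21.8 23.6 10.6 38.0
#> 2 year_3 3.3  8.8  8.3  3.2 76.5
#> 3 year_5 1.3  3.3  3.1  1.1 91.1
```

Percentages per state (rows sum to 100): by 5 years 91.1% of the integrative
cohort is projected to have had a CVE vs 98.5% conventional, mirroring the
qualitative pattern such cohorts show. The 12-month goodness-of-fit test
(`gof.json`: integrative p = 0.46, conventional p = 0.59) accepts the model:
predicted and observed 12-month distributions agree.

A command-line interface wraps the same stages:

```sh
Rscript inst/cli/hfmarkov.R simulate --out data --seed 7
Rscript inst/cli/hfmarkov.R survival --patients data/patients.csv --followup data/followup.csv --out results
Rscript inst/cli/hfmarkov.R markov   --patients data/patients.csv --followup data/followup.csv --out results
Rscript inst/cli/hfmarkov.R full-pipeline --out results --seed 7 --format markdown
```

Pre-tabulated transfer-frequency tables (CSV `from_state,to_state,count`) can
be fed to the Markov stage directly with `--transitions counts.csv`,
bypassing patient-level estimation.

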