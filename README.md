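# cimipkpd

PK/PD dose determination for cimicoxib, a COX-2 selective NSAID, in the
dog — implemented as a reusable pharmacometric pipeline with a synthetic
cohort generator so every stage is testable without animal data.

## Who this is for

Pharmacometricians and veterinary-pharmacology researchers who need to:

- fit a one-compartment oral absorption model (Bateman curve with lag) to
  per-subject plasma concentration profiles, with inverse-squared-fitted
  (1/ŷ²) weighting and AIC selection between 2- and 3-exponential shapes;
- run non-compartmental analysis on IV profiles (linear-up/log-down AUC,
  automatic λz selection, CL, Vz, half-life) and log-linear sparse-sampling
  half-lives;
- fit indirect-response (turnover) models — `dR/dt = Kin − Kout·R` with a
  sigmoid Hill drug term `H(C) = Cⁿ/(C50ⁿ + Cⁿ)` stimulating or inhibiting
  `Kin` or `Kout` — sequentially driven by each subject's fitted PK curve;
- simulate effect–time profiles over an oral dose grid and pick the
  smallest dose giving a near-maximal effect on every endpoint;
- detect extensive/poor-metabolizer (EM/PM) subpopulations from terminal
  half-lives, compare them (Welch t-test), and summarize breed half-life
  differences (one-way ANOVA + Tukey letter groups, CV%).

The core models, in the field's notation:

```
oral PK:    C(t) = D·k01 / [(V/F)(k01 − k10)] · (e^{−k10(t−tlag)} − e^{−k01(t−tlag)})
turnover:   dR/dt = Kin − Kout·(1 + Emax·H(C))·R      (stimulate loss: body temperature)
            dR/dt = Kin − Kout·(1 − Imax·H(C))·R      (inhibit loss: speed, vertical force)
            dR/dt = Kin·(1 − H(C)) − Kout·R           (inhibit production: lameness, cap fixed at 1)
```

with `R(0) = Kin/Kout` (the inflamed steady state at treatment time).

## Worked example

Generate a 12-dog crossover cohort (2 mg/kg oral, bimodal clearance), fit
one dog's PK, classify metabolizers, compare clearances, fit one turnover
model, and select a dose:

```r
library(cimipkpd)

spec   <- cohort_spec(n_subjects = 12, seed = 7)
cohort <- generate_cohort(spec)
oral   <- generate_concentration_data(cohort, "oral_study1", dose = 2)

fit <- fit_oral_pk(oral[[2]])
fit
#> Oral PK fit (2-exponential selected by AIC, AIC = -33.13)
#> Oral one-compartment PK parameters (Bateman with lag)
#>   V/F  = 0.948 L/kg
#>   k01  = 2.537 1/h
#>   k10  = 0.1547 1/h
#>   tlag = 0.3352 h
#>   terminal half-life = 4.48 h

hl  <- sapply(oral, function(p) log(2) / fit_oral_pk(p)$params$k10)
names(hl) <- sapply(oral, `[[`, "subject_id")
cls <- classify_metabolizers(hl)
table(cls$assignments$label)   # EM 7, PM 5 in this cohort draw
cls$bimodal                    # TRUE; cluster centers 2.43 h and 5.16 h

iv  <- generate_concentration_data(cohort, "iv_study1", dose = 2, seed = 18)
nca <- lapply(iv, nca_iv)
lab <- setNames(cls$assignments$label, cls$assignments$subject_id)
compare_subgroups(split(sapply(nca, `[[`, "clearance"), lab[names(hl)]),
                  "clearance")
#> clearance EM 0.29 vs PM 0.11 L/h/kg, fold 2.65, p = 4.6e-05

eff <- generate_effect_data(cohort, "creeping_speed", dose = 2)
fit_turnover(eff[[2]], conc_oral(fit$params, 2))
#> Turnover fit (creeping_speed, inhibit_kout)
#>   Kin = 0.6575, Kout = 0.8948 (baseline R0 = 0.7348)
#>   cap = 0.66, C50 = 430.5 ug/L, n = 3.09
```

The fitted half-life, clearance fold ratio (~3-fold EM/PM) and turnover
parameters are estimates of that virtual dog's known truth; the test suite
quantifies recovery error systematically. Dose selection with typical
extensive-metabolizer parameters (terminal half-life 2.9 h):

```r
pk_em <- oral_pk_parameters(1.12, 2, log(2) / 2.9, 0.3)
pd_bt <- indirect_response_parameters(41.30, 1.04, 0.04, 193.2, 5.09)
grid  <- simulate_dose_grid(pk_em, pd_bt, "stimulate_kout")
grid$near_maximal_dose
#> [1] 1   # mg/kg: smallest grid dose reaching 90% of the reference peak
```

`run_study1_pipeline(run_config(...))` chains all stages and writes tidy
CSV reports plus a JSON run log. A command-line front end covers each
stage (`fit-pk`, `nca`, `halflife-sparse`, `fit-pkpd`, `simulate-dose`,
`classify-metabolizers`, `breed-anova`, `simulate-cohort`, `run-study1`):

```sh
Rscript inst/cli/cimipkpd simulate-cohort --n-subjects 12 --seed 1 --out cohort/
Rscript inst/cli/cimipkpd fit-pk --input cohort/concentrations_oral.csv --out pk.csv
```

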