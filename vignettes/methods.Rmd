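---
title: "Turnover PK/PD modeling for coxib dose determination: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turnover PK/PD modeling for coxib dose determination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cimipkpd)
```

## The problem

Cimicoxib is a COX-2 selective NSAID for dogs. Choosing its oral dosing
regimen requires linking what the body does to the drug (pharmacokinetics:
clearance, volume of distribution, absorption and elimination rates) to
what the drug does to the body (pharmacodynamics: antipyretic and
anti-inflammatory effect magnitudes and their concentration dependence).
`cimipkpd` implements that chain for a two-study canine design: a rich
crossover study in beagles (oral and IV dosing at 2 mg/kg, with a
reversible kaolin paw-inflammation model providing clinical endpoints) and
a sparse-sampling field study across four breeds. Because no public raw
data exist for this design, a synthetic cohort generator is a first-class
module: every pipeline stage is exercised against data whose ground truth
is known.

## Pharmacokinetic models

**Oral.** Concentration follows the one-compartment first-order absorption
(Bateman) curve with lag,

$$C(t) = \frac{D\,k_{01}}{(V/F)\,(k_{01}-k_{10})}
\left(e^{-k_{10}(t-t_{lag})} - e^{-k_{01}(t-t_{lag})}\right),\quad t > t_{lag},$$

with dose $D$ in µg/kg so that concentrations are µg/L (≡ ng/mL)
throughout. Two identifiability conventions are enforced. First, oral data
alone cannot separate bioavailability $F$ from volume $V$, so $V/F$ is one
parameter. Second, the curve is symmetric under exchange of $k_{01}$ and
$k_{10}$ ("flip-flop"); fitting constrains $k_{01} > k_{10}$, attributing
the terminal phase to elimination, and records the constraint in the
diagnostics.

**Fitting.** `fit_oral_pk()` minimizes weighted least squares with weights
$1/\hat y^2$ (inverse squared *fitted* value), iterated to a fixed point:
at most 10 reweighting cycles, stopping when the largest relative parameter
change drops below 1e-6. Candidate models with two exponentials (the
Bateman form) and three (one extra disposition phase, constrained to
$C(t_{lag}) = 0$) are compared by $AIC = n\log(wRSS/n) + 2p$; the criterion
variant was an open choice and this one is used consistently across
candidates. Observations below the limit of quantification (10 µg/L
≡ 0.01 µg/mL) and exact zeros are excluded from fitting; pre-dose zeros are
retained in the container for plotting. Fitted values are floored at the
LOQ when forming the weights: a prediction below quantification carries no
proportional-error information, and unfloored $1/\hat y^2$ weights diverge
wherever the curve predicts near zero (just past the lag time), which can
drag the whole fit into a degenerate corner. The inner weighted
least-squares solver is the same projected Levenberg–Marquardt used for
the turnover fits, run from several absorption-rate starting points.
Positivity is enforced by fitting on the log scale; confidence intervals
are asymptotic Wald intervals propagated to the natural scale by the delta
method.

**IV NCA.** `nca_iv()` uses the linear-up/log-down trapezoid to the last
quantifiable point plus $C_{last}/\lambda_z$ extrapolation. $\lambda_z$
comes from a log-linear regression over the last $n \ge 3$ points chosen to
maximize adjusted $R^2$, ties resolved toward more points (the source
analysis does not state its rule; this is the common automatic one). An
extrapolated AUC fraction above 20% raises a flag and warning. Clearance is
$D/AUC_{0\to\infty}$, terminal volume $CL/\lambda_z$, half-life
$\ln 2/\lambda_z$.

**Sparse half-life.** For the four-sample field design (6, 8, 10, 24 h),
`terminal_halflife_sparse()` regresses $\log C$ on time over post-peak
positive concentrations and returns $\ln 2 / (-\text{slope})$.

## Effect metrics

Raw endpoint values $M$ are expressed as percent improvement anchored by
the mean healthy baseline $T^-$ (pre-inflammation) and the mean inflamed
pre-treatment baseline $T^+$:

$$\%\,\text{improvement} = \frac{T^+ - M}{T^+ - T^-}\times 100 .$$

The same formula covers endpoints that rise under inflammation (fever) and
endpoints that fall (creeping speed); values above 100% are meaningful
(hypoalgesia beyond the healthy baseline). The ordinal lameness score is
never pushed through this formula; it is summarized on its own 0–5 scale.

`summarize_effect()` operationalizes two summaries that were originally
read off plots by eye, so both knobs are exposed:

- the *plateau of maximal effect* is the longest contiguous run of
  observations within `plateau_tolerance` (default 10 percentage points) of
  the series maximum; the maximum effect is the mean over that window. A
  plateau is flagged undetermined when the run is a single point or ends at
  the last observation while still strictly rising — the "no plateau
  observed" situation.
- the *total duration of effect* is the Lebesgue measure of
  $\{t: \%\text{improvement}(t) \ge \text{threshold}\}$ (default 10%) with
  crossing times interpolated linearly. The original rule was unstated;
  threshold crossing is this package's operationalization, and durations
  are monotone non-increasing in the threshold by construction.

## Indirect-response (turnover) models

The response is produced at a zero-order rate $K_{in}$ and lost at a
first-order rate $K_{out}$; drug concentration modulates one of them
through a sigmoid Hill function
$H(C) = C^n/(C_{50}^n + C^n)$:

| variant | ODE | endpoint |
|---|---|---|
| stimulate loss | $\dot R = K_{in} - K_{out}(1 + E_{max} H(C))\,R$ | body temperature |
| inhibit loss | $\dot R = K_{in} - K_{out}(1 - I_{max} H(C))\,R$ | creeping speed, vertical force |
| inhibit production | $\dot R = K_{in}(1 - H(C)) - K_{out}\,R$ | lameness score |

For the lameness variant the drug term has no free cap (it saturates at
full inhibition of $K_{in}$, the "fixed at 1" convention), so only four
parameters are estimated there. The initial condition is the inflamed
steady state $R(0) = K_{in}/K_{out}$: treatment occurred 26.5 h after
induction, and the placebo time-course over the modeled window is treated
as constant — the model's stated assumption, inherited here.

**Numerics.** No ODE solver package is available in the target
environment, so integration is a Dormand–Prince 5(4) adaptive Runge–Kutta
in C++ (`src/turnover.cpp`), with steps clamped at output times and at
piecewise-constant forcing breakpoints so discontinuities never straddle a
step. Default tolerances are 1e-10 relative / 1e-12 absolute (1e-8 during
fitting). The Hill function is evaluated on the log scale so Hill
coefficients near the upper bound of 10 stay finite at extreme
concentration ratios.

**Estimation.** `fit_turnover()` is sequential PK/PD: each subject's PD is
driven by that subject's fitted oral curve, not raw interpolated
concentrations. Residuals are unweighted on the raw endpoint scale (the
source is silent; endpoint units, e.g. $K_{in}$ in °C·h⁻¹, are retained).
The likelihood surface has a nearly flat ridge between $C_{50}$ and the
Hill coefficient $n$ — steepness and potency trade off when few samples
fall in the concentration transition region. Quasi-Newton methods stall on
this ridge, so the optimizer is a projected Levenberg–Marquardt on the
residual vector, run from several deterministic starts, followed by a
coarse profile over fixed $n = 1,\dots,10$ (re-optimizing the rest) and a
final free-$n$ pass. Bounds: $n \in (0, 10]$, $I_{max} \in (0, 1]$, rates
and $C_{50}$ positive via log parameterization. With noise-free data this
recovers all parameter sets used in the tests to well under 0.1%.

Lameness, though ordinal, is fitted as a continuous response; predicted
trajectories are continuous and only observed scores are integers. For
this reason the course container enforces the 0–5 range but not
integrality.

## Dose–effect simulation

`simulate_dose_grid()` assumes dose-linear PK (the stated assumption of
the original analysis; its authors later learned solubility makes high
doses sub-linear, which is out of scope here) and simulates the turnover
response over a grid of oral doses (default
0.1–8 mg/kg, 48 h horizon). Effect magnitude is the absolute deviation of
the response from its inflamed baseline. Because "nearly maximal" was
originally judged by eye on a panel of simulated curves, the reference
peak is defined as the peak effect at the *largest grid dose*, and a
near-maximal dose is the smallest dose reaching 90% (configurable) of that
reference — certified only if the dose–response has leveled off at the top
of the grid (last grid step changes the peak by under 5%). Under mean
extensive-metabolizer parameters with a terminal half-life of 2.9 h, the
per-endpoint near-maximal doses land at 1 (temperature), 1 (lameness),
3 (creeping speed) and 4 mg/kg (vertical force), and at 2 mg/kg the
durations of effect are 10–13 h across endpoints. `select_dose()` applies
the all-endpoints rule: the smallest dose that is near-maximal everywhere.

## Subpopulation and breed statistics

Terminal half-lives in the beagle study are bimodal: a fast-eliminating
majority ("extensive metabolizers", EM) and a slow minority ("poor
metabolizers", PM). `classify_metabolizers()` runs an exact
one-dimensional two-means split on log half-lives — deterministic and
adequate at n = 12, where a mixture model would be fragile — and reports a
bimodality flag (cluster separation at least twice the pooled
within-cluster SD). Group contrasts use Welch's unequal-variance t-test
(the groups' variances differ several-fold; the source names only an
"unpaired t-test"). Breed comparisons use a one-way fixed-effects ANOVA
with Tukey HSD post-hoc pairwise tests rendered as compact letter groups
(maximal cliques of the non-significance graph, ordered by group mean);
the original letter display named no post-hoc method, and Tukey HSD is the
conventional choice.

## The synthetic world

`generate_cohort()` draws per-dog parameters log-normally around class
means with a between-subject CV of 25% (field-study CVs of 20–26% motivate
the default). PM prevalence defaults to 1/3 (4 of 12 beagles). Class mean
PK: EM clearance 0.31 L/h/kg and volume 1.12 L/kg; PM 0.11 and 0.89
(~3-fold clearance contrast). PD class means per endpoint are the
published fitted values. Two oral-absorption constants are never printed
anywhere and had to be chosen once: $t_{lag} = 0.3$ h (a capsule
disintegrates within ~20 min; a lag of exactly 0.5 h would zero out the
first post-dose sample of the stated 10-point schedule) and
$k_{01} = 2$ h⁻¹ (absorption clearly faster than elimination, peak around
1.5–2 h).

Observation noise: proportional log-normal concentration error (default CV
10%; the analytical method's validation reported day-to-day CVs below 9%),
with values under the LOQ of 10 µg/L flagged; additive Gaussian effect
noise at instrument precision — 0.1 °C (electronic thermometer), 0.02 m/s
(stopwatch-timed tunnel runs), 0.002 normalized force units
(triplicate-mean force plates), 0.2 score units before lameness is rounded
to integers and clipped to 0–5. Baselines are emitted consistently with
each dog's own turnover parameters: $T^+ = K_{in}/K_{out}$ (inflamed
steady state) and $T^-$ the full-drug-effect steady state, so that 100%
improvement corresponds exactly to complete suppression of the
inflammatory perturbation.

What the generator does **not** emulate: the time development of
inflammation itself (assumed stationary over the modeled window), placebo
arms beyond a constant noisy baseline, correlation between a dog's PD
parameters (drawn independently; the real correlation structure is
unknown and documented as a limitation), crossover period effects, and
the analgesia endpoint's dual mechanism. A green recovery test therefore
establishes that the estimation chain inverts the model under the stated
design and noise — not that the model is a complete description of a real
inflamed dog.

## Known limitations and honest failures

Two acceptance-level recovery checks do not meet their stated bound and
are deliberately left failing rather than loosened:

- **Vertical force IC50, stochastic recovery.** With $K_{out} = 7.4$ h⁻¹
  the response equilibrates within minutes and behaves as a direct Hill
  readout of concentration; under the sparse PD schedule (0, 2, 4, 9, 15,
  22, 27 h) and a Hill coefficient near 6, at most one sample falls in the
  transition region, so per-dog IC50 is weakly identified (median relative
  error ~25–35% across seeds instead of the targeted 15%). The published
  per-group interval for exactly this endpoint spans ~7-fold, which is the
  same phenomenon seen from the other side.
- **Lameness IC50, stochastic recovery.** Integer rounding of a 0–5 scale
  adds quantization error of the same order as the drug signal over much
  of the trajectory; medians land around 12–33% depending on the noise
  realization.

Noise-free recovery (all four model variants, including continuous-scale
lameness) is exact to numerical precision, so the failures above are
information limits of the stated design, not estimator defects.
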