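---
title: "Modelling long-term continuity-of-care trajectories in claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling long-term continuity-of-care trajectories in claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coctraj)
```

This vignette is the package's account of its methods: the models it fits,
the assumptions and parameter choices behind them, what the synthetic data
generator does and does not emulate, and the numerical decisions that a
maintainer or reviewer would want stated explicitly.

## The measurement problem

Administrative claims record every reimbursed visit: who, when, at which
institution, with what primary diagnosis, and at what cost. For a chronic
condition like hypertension, a patient's *continuity of care* — how
concentrated their visits are at one provider — is believed to influence
both outcomes and spending, but a single-period snapshot hides the dynamics:
a patient drifting away from a stable care relationship and a patient
consolidating one can have the same cross-sectional index. The package
therefore measures continuity per patient-year, models its multi-year
trajectory, and only then relates trajectory membership to spending.

## From claim lines to patient-years

A *visit* is a unique (patient, date, institution) triple; claim lines that
share the triple are one visit whose expense is the line sum. This is the
standard convention for concentration indices and is robust to line-item
billing. Calendar years (Jan 1–Dec 31) partition the window, year index
$t = \text{year} - \text{baseline}$, and every patient-year gets a visit
count, a per-provider tally and an expense total (zero where no visits
occurred). Expense totals include all reimbursement lines for the
patient-year regardless of diagnosis, since total medical spending is the
outcome of interest.

Cohort rules, applied in this order with the first failure recorded per
patient: adults (≥ 18 at the baseline date; a bare birth year is compared as
baseline year minus birth year), at least 3 years in the window with ≥ 3
visits, and a hypertension primary diagnosis (ICD-10 prefix I10–I13, I15,
after normalizing codes to uppercase without dots). The visit minimum
operates *per year*: a year with fewer than 3 visits contributes a missing
continuity value, but the patient may still qualify through other years.

## The Continuity of Care Index

With $N = \sum_i n_i$ visits spread over providers $i$,
$$\mathrm{COCI} \;=\; \frac{\sum_i n_i (n_i - 1)}{N (N - 1)},$$
the probability that two distinct visits drawn without replacement share a
provider. It is 1 exactly for single-provider years, 0 exactly when every
visit is to a different provider, and invariant to provider relabelling.
The test suite checks it against an exhaustive pair-enumeration oracle on
random tallies. Below $N = 3$ the index is undefined by convention here
(`NA`), matching the qualifying-year rule. A provider is a health
*institution*; physician-level continuity is not observable in
institution-level claims and is out of scope.

## The trajectory model

### Likelihood

Patient $i$ carries the COCI series $y_{it}$, $t = 0..T-1$ (missing years
simply drop out). The model is a finite mixture over $K$ latent groups.
Group $g$ has mixing weight $\pi_g$ and a polynomial mean trajectory
$\mu_{gt} = x_t'\beta_g$ on *scaled time* $s = t/(T-1) \in [0,1]$
(numerical conditioning; coefficients on the calendar basis are a linear
transform away). Because the index lives on $[0,1]$ with genuine mass at
both bounds (all-one-provider years are common), the outcome is
censored-normal: a latent $y^*_{it} \sim N(\mu_{gt}, \sigma^2)$ observed
only inside the unit interval, with
$P(y=0) = \Phi((0-\mu)/\sigma)$ and $P(y=1) = 1 - \Phi((1-\mu)/\sigma)$.
This is the canonical trajectory-modelling choice for bounded continuous
outcomes. $\sigma$ is shared across groups — the convention of the
trajectory software this design follows, and a meaningful parameter saving
at $K = 6$.

### Estimation

The EM algorithm treats *two* layers as missing data: the group label and,
for censored observations, the latent outcome. The E-step computes
responsibilities in log space (log-sum-exp) and truncated-normal first and
second moments for censored cells; the M-step is then a closed-form joint
update — weighted least squares per group for $\beta_g$, the weighted
residual moment for $\sigma^2$, responsibilities' means for $\pi$ — so each
iteration increases the observed-data log-likelihood (asserted to $10^{-8}$
in the tests). Convergence is declared at a relative log-likelihood change
below $10^{-6}$, capped at 500 iterations; $\sigma$ is floored at $10^{-4}$
with a warning rather than being allowed to collapse.

Starting values: patients are ranked by mean observed COCI and split into
$K$ equal blocks, each block gets a polynomial least-squares fit, and every
start jitters those coefficients by $N(0, 0.05^2)$; 20 starts by default,
all seeds explicit and derived from one user seed. The best *converged*
start wins; if none converges the error carries the best non-converged
state. On fully interior data with $K=1$ the first M-step reproduces
ordinary polynomial least squares exactly, which the suite checks to
$10^{-6}$ against an independent normal-equations solve.

Two determinism conventions: groups are relabelled in ascending order of
their time-averaged fitted trajectory, so labels are stable across starts
and initial orderings (G1 = lowest continuity, GK = highest); posterior
ties in assignment go to the lowest group index.

### Model selection

Candidates are enumerated as ordered tuples of per-group polynomial orders
from {1, 2, 3} — $3^K$ per $K$, e.g. 81 four-group models — accepting that
some tuples are relabel-duplicates; this matches how trajectory grids are
conventionally counted and costs only redundant computation. Selection
applies, in this order of logic: convergence; every assigned group share
≥ 5%; every AvePP > 0.7; then maximal BIC, computed as
$\log L - (k/2)\log n$ with $n$ = patients and
$k = \sum_g(\text{order}_g+1) + (K-1) + 1$, a negative quantity read as
"closest to zero wins". Ties break to smaller $K$, then lexicographically
smaller orders. The remaining, inherently qualitative criterion — whether
the trajectory shapes are practically meaningful — is deliberately *not*
automated: the candidate ledger and `plot_trajectories()` exist so an
analyst can apply it.

## Comorbidity scoring

The updated (2011) Charlson index sums recalibrated integer weights over
condition categories matched by ICD-10 prefix, with three severity
hierarchies (metastatic tumour over any malignancy, moderate/severe over
mild liver disease, complicated over uncomplicated diabetes) and each
category counted once. The category–prefix–weight table is *data, not
code* — `inst/extdata/upcci_weights.csv`, replaceable by any file with the
same columns — because prefix mappings legitimately vary across coding
practice. Hypertension itself carries weight 0 in this index, so the cohort
definition does not mechanically inflate the score. The score is computed
once per patient from all primary diagnoses observed in the window; which
years feed it is configurable in principle, and whole-window is the default
because one score per patient is the covariate the expense model expects.

## The expense model

The response is the patient's mean annual total expense over the horizon
(CNY). A pooled patient-year option exists behind `pooled = TRUE`, but
patient-level means are the default: they avoid within-patient correlation
without inventing a panel standard-error scheme. The design is fixed:
intercept; dummies for all but the highest-continuity group (G4 reference
in the four-group case); male (female reference); age groups 19–59 and
60–74 (75+ reference; 18-year-olds fall in the first band); employee
insurance (resident reference); the comorbidity score continuous. Classical
(non-robust) standard errors, two-sided t tests, 95% CIs via
$t_{0.975,\,n-p}$. Reported percentages and growth rates round half-up to
two decimals, matching the table conventions of the field (base R's
round-half-even would disagree in the last digit). Year-on-year growth is
$(\bar c_t/\bar c_{t-1} - 1)\cdot 100$ with the first year undefined.

## The synthetic cohort generator

The generator exists so that every stage has data with known truth. Its
defaults describe the study conditions the package targets: four trajectory
groups with shares (0.52, 0.17, 0.19, 0.12); flat-low (≈0.4–0.5), rising
(≈0.5→0.8), falling (≈0.9→0.5) and flat-high (≈0.85) mean trajectories over
six years; residual SD 0.10; 10% missing-COCI years; 3 + Poisson(5) visits
in observed years and 1–2 in missing years (a missing-COCI year is one
below the visit minimum, not a visit-free year); group base expenses
(7300, 5300, 6100, 4300) CNY — ordered G1 > G3 > G2 > G4 with a
G1-vs-G4 gap of 3,000 CNY — plus covariate effects (male +450,
19–59 −4000, 60–74 −2200, employee +3500, +2300 per comorbidity point) and
mean-preserving multiplicative lognormal noise (sdlog 0.5); demographic
mix 51.4% male, ages 28.8/45.5/25.7% across the three bands, 44.1%
employee-insured; comorbidity scores 0–4 with probabilities
(0.53, 0.37, 0.055, 0.036, 0.007). The rising and falling trajectories were
given slightly different time-averaged means so that the ascending-mean
relabelling rule orders them deterministically.

Claims-level generation inverts the continuity index: for a target COCI and
visit count $N$, it picks the tally "$n_1$ visits to one provider, the rest
singletons" whose index is closest to the target — the achieved value is
exact for targets in the achievable set and otherwise off by at most the
largest gap between adjacent achievable values (about $2/N$), and the
ground-truth tables record both target and achieved. Comorbidity codes are
planted as primary diagnoses on later visits in code bundles whose
recovered score equals the drawn score exactly; every eligible patient has
a hypertension code, so ingest → indices → filter recovers the generator's
eligibility flags and achieved COCI values exactly, which the suite asserts.

What the generator does **not** emulate: realistic ICD-10 code frequencies,
provider-market structure (providers are per-patient labels, not a shared
market), seasonal visit timing, cost inflation, or informative missingness —
missing years are missing completely at random, matching the model's
missing-at-random assumption rather than stress-testing it. Green tests on
synthetic data therefore demonstrate correctness of the *computations*, not
robustness of the scientific conclusions to violations of these
assumptions on real claims.

## Problem sizes and test design

The suite fits recovery experiments at 500–1,000 patients (where the
3-group, $\sigma = 0.08$, well-separated design recovers $\pi$ within
±0.03, coefficients within 0.05 sup-norm, AvePP > 0.9 and 99%+ assignment
accuracy), runs the chosen-$K$ replication at 800 patients over a
quadratic-shape grid for $K \in \{2,3,4\}$ (the full $3^K$ product is
exercised separately through the enumeration tests and the worked
five-candidate selection example), and validates the expense regression at
1,500–4,000 patients, where the planted +3,000 CNY group effect is
recovered within two standard errors. These sizes were chosen as the
smallest at which the Monte-Carlo tolerances above are meaningful.

## Known limitations

Institution-level continuity overstates physician-level continuity. The
index needs ≥ 3 visits, so low utilizers are under-observed by
construction. Shared $\sigma$ can misfit cohorts where group dispersions
truly differ. BIC with the 5%-share and AvePP rules can prefer fewer groups
than the data contain when groups are thin or overlapping. The expense
regression is associational — no matching, weighting or panel-robust
inference — and assumes homoskedastic errors that the lognormal cost
distribution only approximately satisfies. None of these are software
defects; they are properties of the method family the package implements.
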