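# coctraj

Long-term continuity-of-care trajectories from health-insurance claims, and
their association with medical spending.

Chronic-disease patients — hypertensive patients in particular — differ not
only in *how* concentrated their care is at any moment, but in how that
concentration evolves over years. `coctraj` is an R toolkit for the full
analysis chain on visit-level claims data: it measures provider concentration
per patient-year, classifies patients into latent trajectory subgroups of
that measure over a multi-year window, and quantifies how subgroup membership
relates to annual medical expenses after adjusting for demographics and
comorbidity. It is aimed at health-services researchers working with
administrative claims; a built-in synthetic claims generator with known group
structure makes every stage testable without access to protected data.

## The methods in brief

**Continuity of Care Index (Bice–Boxerman).** For a patient-year with
N visits, of which n_i went to provider i (a provider is a health
institution),

    COCI = Σ_i n_i (n_i − 1) / ( N (N − 1) ),

the probability that two distinct visits that year were to the same
provider: 1 = a single provider, 0 = every visit somewhere new. Years with
fewer than 3 visits give no meaningful estimate and are treated as missing.

**Group-based trajectory model, censored-normal outcome.** Each patient
belongs to one of K latent groups; group g has a polynomial mean trajectory
x_t'β_g on scaled time s = t/(T−1), a shared residual SD σ, and the COCI
outcome is modelled as a normal variable censored at the index bounds 0 and
1. The mixture likelihood

    L_i = Σ_g π_g Π_t f_cnorm( y_it | x_t'β_g , σ )

is maximized by a multi-start EM algorithm written for this model (both the
group labels and the censored latent outcome are treated as missing data, so
each M-step is a closed-form weighted least-squares update and the
log-likelihood ascends monotonically). Candidate models — every combination
of per-group polynomial orders 1–3 for each K — are compared by
BIC = logL − (k/2)·log n (negative; closer to 0 is better), subject to every
assigned group holding ≥ 5% of patients and every group's average posterior
probability (AvePP) exceeding 0.7. Patients are assigned to their
highest-posterior group.

**Comorbidity and expenses.** The updated (2011) Charlson Comorbidity Index
is computed from ICD-10 prefixes with severity hierarchies (weight table
shipped as an editable CSV), and a covariate-adjusted OLS regression relates
each patient's mean annual expense to trajectory group, sex, age group,
insurance type and comorbidity score.

## Worked example

Simulate a four-group cohort of 600 patients (2016–2021), ingest it as
claims, and run the stages:

```r
library(coctraj)
cfg    <- sim_config(n_patients = 600, seed = 42)
sim    <- simulate_claims(cfg, dir = "demo")
visits <- read_claims("demo/claims.csv")
panels <- build_panels(visits, sim$demographics, baseline_year = 2016, horizon = 6)
panels <- add_upcci(cohort_filter(panels))
fit    <- fit_gbtm(panels, trajectory_spec(c(2, 3, 3, 3)), n_starts = 10, seed = 1)
print(fit)
```

```
Censored-normal group-based trajectory model
  4 groups (2,3,3,3), n = 597, T = 6
  logLik 749.55323  BIC 688.83002  (k = 19)
  sigma 0.135
 group order    pi share AvePP
     1     2 0.561 0.563 0.981
     2     3 0.160 0.157 0.922
     3     3 0.160 0.161 0.946
     4     3 0.119 0.119 0.958
```

Three of 600 simulated patients fail the cohort filters (fewer than three
qualifying years); the fit recovers the generator's mixing proportions
(0.52/0.17/0.19/0.12), all four groups are comfortably above the 5% share
and 0.7 AvePP thresholds, and groups are labelled G1→G4 in ascending order
of mean continuity. The expense regression against the highest-continuity
group G4:

```r
reg <- expense_regression(panels,
  tibble::tibble(patient_id = fit$patient_id, group = fit$assignment))
print(reg)
```

```
Expense regression (OLS), n = 597, R^2 = 0.954
        term  estimate       se         t            p     ci_lo     ci_hi
 (Intercept)  4233.240 275.0310  15.39190  3.62781e-45  3693.080  4773.400
          G1  2961.630 233.8440  12.66500  1.12262e-32  2502.360  3420.900
          G2  1045.210 281.9580   3.70695  2.29603e-04   491.438  1598.970
          G3  1684.240 279.6640   6.02238  3.02969e-09  1134.980  2233.500
        male   453.416 147.9490   3.06468  2.27888e-03   162.844   743.989
    age19-59 -3789.700 194.9910 -19.43520  2.34048e-65 -4172.660 -3406.730
    age60-74 -2065.200 185.5050 -11.13280  2.96327e-26 -2429.530 -1700.870
    employee  3470.340 147.8430  23.47320  1.79538e-86  3179.970  3760.700
       upcci  2304.660  85.8623  26.84140 3.27731e-104  2136.030  2473.290
```

The G1 coefficient estimates the extra annual spending (CNY) of the
low-continuity-maintenance group relative to sustained high continuity; the
generator's true gap is +3,000 CNY, and every covariate estimate sits within
sampling error of its configured effect. `run_pipeline(run_config(...))`
chains all of these stages (including the model grid and selection) into one
seeded run that writes the tables, the chosen model, a trajectory plot and a
manifest.

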