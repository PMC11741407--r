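# habitiron

Simulation and analysis toolkit for studying how habit-like (perseverative)
decision-making relates to developmental trajectories of striatal tissue iron.

## The scientific problem

In the two-stage sequential decision-making task, a first-stage choice between
two options leads probabilistically (70% common / 30% rare) to one of two
second-stage states, where a second choice is rewarded according to slowly
drifting probabilities. The task dissociates decision strategies through the
probability of repeating ("staying with") the previous first-stage choice:

* **model-free** control appears as a main effect of the previous reward,
* **model-based** control as a reward × transition interaction,
* **habitual / perseverative** responding as an outcome-insensitive overall
  stay tendency (the **first-stage stay** index, *fss*).

Normalized T2\*-weighted imaging (nT2\*w) provides an indirect index of
striatal tissue iron — and thereby of dopaminergic neurophysiology — with
*lower* nT2\*w meaning *more* iron. Iron accumulates across adolescence. The
analysis this package implements asks whether individual differences in
habitual behavior track putamen iron, and whether that coupling is
age-dependent (present in adolescence, fading by adulthood).

Because no human data ship with the package, every analysis runs on synthetic
cohorts with known ground truth, and validation is by parameter and structure
recovery.

## What is inside

| Layer | Functions |
|---|---|
| Task generative model | `task_config()`, `simulate_session()`, `step_reward_walk()`, `stay_indicator()` |
| Hybrid RL agents | `agent_params()`, `make_policy()`, `session_loglik()` (SARSA(λ) + model-based mixture + perseveration bonus; compiled likelihood) |
| Behavioral indices | `build_stay_table()`, `fit_stay_mlm()` (hierarchical logistic stay model), `extract_indices()` |
| RL fitting | `fit_map()`, `fit_map_cohort()`, `compare_variants()`, `validate_fss_vs_perseveration()` |
| nT2\*w preprocessing | `censor_volumes()` (FD > 0.3 mm), `compute_nt2w_map()` (coverage-map z-scoring + voxelwise median), `extract_roi()`, `harmonize_batches()` |
| Trajectory models | `fit_gamm()` (penalized splines, k = 3, subject random intercepts), `smooth_significance()`, `residualize_age()`, `compare_model_ladder()`, `fit_varying_coefficient()`, `derivative_windows()`, `marginal_trajectories()`, `bonferroni()` |
| Synthetic cohort | `cohort_config()`, `generate_cohort()`, `coupling_beta()`, `make_volume_phantoms()` |
| Orchestration | `run_pipeline()`, `summarize_descriptives()`, `expt_*()` validation experiments |

The core stay-probability model is

```
logit P(stay) = (β₀+b₀ⱼ) + (β₁+b₁ⱼ)·reward + (β₂+b₂ⱼ)·transition + (β₃+b₃ⱼ)·reward·transition
```

with ±1 codings and session-level random effects; the three indices are
`fss = β₀+b₀ⱼ`, `mf = β₁+b₁ⱼ`, `mb = β₃+b₃ⱼ`. Tissue-iron trajectories are
modeled as

```
nT2*wᵢₜ = β₀ + β₁·sexᵢ + β₂·visitᵢₜ + f(ageᵢₜ) [+ f(age)·Behaviorᵢₜ] + b₀ᵢ + εᵢₜ
```

with penalized cubic regression splines, and age windows where the
behavior–iron coupling is significant are found by simulating 10,000
coefficient vectors from the Gaussian posterior of the fit.

## Worked example

```r
library(habitiron)

# a small cohort with the default age-varying fss-iron coupling on putamen
cfg    <- cohort_config(n_subjects = 60)
cohort <- generate_cohort(cfg, seed = 2, simulate_trials = FALSE)

d  <- cohort$iron |>
  dplyr::select(session, region, nT2w) |>
  tidyr::pivot_wider(names_from = region, values_from = nT2w) |>
  dplyr::inner_join(cohort$design, by = "session") |>
  dplyr::inner_join(cohort$indices[, c("session", "fss", "mb", "mf")],
                    by = "session")
d$fss_resid <- residualize_age(d$fss, d$age)

vc <- fit_varying_coefficient(d, "putamen", "fss_resid")
smooth_significance(vc, "age", by = "fss_resid")
#> # A tibble: 1 × 4
#>   term               edf     F p_value
#> 1 s(age):fss_resid  2.36  2.69  0.0502

derivative_windows(vc, n_sims = 1000, seed = 3)
#> Windows of significance (coefficient, pointwise 95% CI) for s(age):fss_resid:
#>  start   end
#>  13.95 24.12
```

The smooth test asks whether the fss–putamen association varies with age (at
78 sessions it is only marginal; at the full cohort size of ~320 sessions it
is decisive). The window says the coupling is distinguishable from zero from
early adolescence into the early twenties — the planted coupling ramps to
zero at age 23, and at ~320 sessions the recovered endpoint lands within
about a year of it in the median (see the vignette and
`expt_window_recovery()`).

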