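---
title: "Models and methods: habit indices and striatal iron trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: habit indices and striatal iron trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the models it implements, the
assumptions behind them, the tunable parameters that matter, and the design
choices made where the design was genuinely open. Everything empirical
stated here is computed by the test suite or by `scripts/acceptance.R`;
nothing is quoted from external data.

```{r setup, message = FALSE}
library(habitiron)
```

## 1. The two-stage task and its generative model

A session has 200 trials in three blocks. A first-stage choice between two
options leads to one of two second-stage states — to "its own" state with
probability `p_common = 0.7` (a *common* transition), otherwise to the other
(*rare*). A second-stage choice between two options is rewarded with
probability given by one of four independent reward walks.

* **Reward walks.** Each of the four probabilities takes a Gaussian step
  (mean 0, SD `walk_sd = 0.025`) per trial, constrained to
  `walk_bounds = c(0.25, 0.75)`. Task dialects differ on the bound pair
  (0.2–0.8 also circulates) and on boundary handling; both are config
  fields. We default to **reflection** at the bounds: reflection preserves
  near-uniform long-run coverage of the interval, whereas clamping piles
  mass at the bounds. The tests verify boundedness over 10,000 steps and
  the symmetry of the stationary mean.
* **Blocks.** 200 is not divisible by 3; blocks are contiguous and
  near-equal (66/67/67). By default the lagged stay regressors *cross*
  block breaks (a config option resets them), since the break is a pause,
  not a context change.
* **Missed responses.** A missed response voids the trial from that stage
  onward, and the following trial's lagged regressors are undefined; both
  trials drop from the stay table. Inside the agent, a missed trial clears
  the one-trial perseveration memory and leaves values untouched.

## 2. Hybrid agents

The agent family is the canonical hybrid two-step learner: a SARSA(λ)
model-free branch, a model-based branch computed from the (known, not
learned) transition probabilities, a softmax mixture with weight `w`, and a
perseveration bonus `pi_persev` added to the value of repeating the previous
first-stage choice. Stage-2 choices are softmax in the second-stage values.
Three nested variants are fitted: `hybrid4` (tied learning rates and
temperatures, λ = 1), `hybrid6` (frees λ and unties the learning rates),
`hybrid7` (all seven parameters). The exact per-trial recursions are in
`?agent_update`; the compiled likelihood (`session_loglik()`) is verified in
the tests against an independent pure-R re-computation to 1e-10, against
the closed-form uniform-policy value, and for invariance under joint
relabeling of choices and states.

**Fitting** is per-session MAP: Beta(2, 2) priors on unit-interval
parameters, Gamma(shape 1, rate 0.2) on temperatures, Normal(0, 1) on the
perseveration weight, maximized by BFGS over a transformed (logit/log)
parameterization from 10 Latin-hypercube starts. The Gamma shape-1 prior
has its mode at zero, so a flat likelihood returns a zero temperature and
exactly the uniform-policy log-likelihood — a useful contract for
degenerate sessions. MAP replaces the hierarchical MCMC machinery often
used for such models: orderings and correlations are expected to agree,
point values are not; the shrinkage direction differs (toward the fixed
prior rather than the group). With 200 trials and seven free parameters the
perseveration weight trades off against other parameters, so validation
experiments that only need a perseveration estimate fit the matched
lower-dimensional variant.

## 3. Behavioral indices

The stay table codes, per analyzable trial, `stay` ∈ {0, 1} and the
previous trial's reward and transition as ±1 (codings kept exactly as
conventional; no re-centering). The hierarchical logistic model

`stay ~ prev_reward * prev_transition + (1 + prev_reward * prev_transition | session)`

is fitted by Laplace-approximate ML with `lme4::glmer` (the field-standard
fitter for this model; its random-effect shrinkage also tames separation,
so no extra fixed-effect ridge is applied). Random effects are grouped by
**session** (subject-visit), so each visit gets its own index — an
unstructured 4×4 covariance when ≥ 30 sessions, diagonal otherwise. The
indices are sums of fixed effect and session BLUP: `mb` from the
interaction, `mf` from the reward effect, `fss` from the intercept. With
±1 codings, `fss` is the session's predicted stay log-odds averaged over
the four previous-outcome conditions — the outcome-insensitive stay
tendency, our habit measure.

Property tests verify the definitional sums, the coding symmetry (flipping
the transition sign flips exactly the transition and interaction effects),
convergence of BLUPs to independent per-session ML fits at 2,000 trials,
and monotone recovery of generative perseveration by `fss`.

## 4. nT2\*w preprocessing

The quantification rules operate on 4D arrays: (i) volumes with framewise
displacement strictly greater than 0.3 mm are censored; (ii) each retained
volume is z-scored over the coverage mask (voxels non-zero in every
volume), which makes the map exactly invariant to per-volume positive-
affine intensity drift; (iii) voxelwise median over retained volumes
(lower median for even counts, so the output is always an observed value);
(iv) ROI means pool both hemispheres' labels. Stored nT2\*w is never
sign-flipped; plotting helpers offer a reversed y-axis as a display-only
convention (lower nT2\*w = more iron).

Batch (scanner) harmonization is a deliberately simple location-scale
method with empirical shrinkage: per region, covariate-adjusted batch
offsets and residual-SD ratios are estimated by linear regression, shrunk
toward their across-region means with normal-normal weights, and removed.
It preserves age and sex relationships by construction and removes exactly
an additive offset in the two-batch limit; it is *not* a re-implementation
of full empirical-Bayes harmonizers, and batches with fewer than five
observations are adjusted without shrinkage.

Volume phantoms (`make_volume_phantoms()`) are built by a fixed-point
construction so that the planted ROI z-levels survive the full pipeline to
1e-6, with affine drift and high-motion junk volumes planted to exercise
the invariances. They are synthetic by construction and carry no anatomy.

## 5. Trajectory models

All trajectory models are Gaussian penalized-spline mixed models fitted
with `mgcv::gam`: cubic regression splines with basis dimension **k = 3**
(so smooth trajectories can be at most gently curved; the centered age
smooth has at most 2 effective degrees of freedom), sex and visit as linear
covariates, and a subject random intercept as a ridge-penalized smooth.
REML selects smoothing parameters for single-model summaries; ML is used
whenever models are compared. Smooth significance is reported as
(edf, F, p) from the Wald-type test on the Bayesian coefficient
covariance. A basis dimension of 3 is a modeling commitment, not an
estimate: it reflects the expectation that iron accumulates monotonically
with a decelerating rate.

Because every behavioral index rises with age, the index smooths would be
concurved with the age smooth; indices are therefore **age-residualized**
(exact linear orthogonalization) before entering iron models.

**The four-model ladder.** Model 1 contains only the age smooth; Models
2–4 add smooths of the residualized fss, mb, and mf indices in that order.
A more complex model is retained only when *both* an analysis-of-deviance
test and AIC favor it. Comparisons use the **marginal** (mixed-model)
likelihood — the ML criterion of the fit, in which penalized coefficients
and random intercepts are integrated out — with LRT df equal to the added
smooth's basis dimension. The conditional likelihood of the fitted model is
not usable here: with ~217 subjects and ~1.5 visits each, the random
intercept carries ~190 effective degrees of freedom, and conditional
AIC/deviance comparisons are dominated by how that term trades off against
any between-subject covariate; in synthetic checks they select the null
model even under strong planted couplings, while the marginal criterion
selects correctly (see `expt_ladder_recovery()`).

**Varying-coefficient models** add `f(age)·Behavior`, letting the linear
behavior–iron association change smoothly with age. The implied β(age)
curve per unit of behavior and its covariance come from the fitted
coefficients.

**Windows of significance.** `derivative_windows()` simulates 10,000
coefficient vectors from the Gaussian posterior of the fit, evaluates
β(age) — or its first derivative by central finite differences with step
equal to the spacing of a 200-point age grid — and returns maximal age
intervals where the pointwise 95% interval excludes zero. Both monitored
quantities are available: *coefficient* mode answers "where is the
association non-zero" and is the reporting default; *derivative* mode
answers "where is it changing". Pointwise bands do not control the
family-wise rate across the grid: under a zero-coupling generator the
chance of detecting at least one window somewhere is about 3–6× the
nominal pointwise rate in our measurements (a k = 3 curve has ~2–3
effectively independent segments, and the sparse old-age edge occasionally
produces a short spurious window). The `simultaneous = TRUE` option uses a
max-t critical value over the same simulations and brings the family-wise
rate near nominal; window-recovery summaries read the window anchored at
the young end of the age range, where the hypothesized coupling lives.

**Marginal trajectories** report predicted iron-versus-age curves at the
behavior mean and ±1/±2 SD, with subject effects excluded — purely a
visualization of the fitted interaction, linear in the behavior level by
construction.

Bonferroni families follow the analysis structure: 4 primary ROIs
(α = 0.0125), 3 behavioral indices (α = 0.0167), 4 putamen subdivisions
(α = 0.0125).

## 6. The synthetic cohort

`cohort_config()` emulates an accelerated-longitudinal two-study design:
217 subjects, a 156-subject longitudinal batch (1–3 visits ~1.5 y apart)
and a 61-subject cross-sectional batch, ages 10.17–33.22, 53% female,
~320 sessions. Ground truth is stored alongside every cohort and the whole
generation is reproducible from one seed.

* **Agent maps.** The model-based weight and the perseveration weight both
  increase with age through logistic maps (midpoint 16 y, scale 3 y) plus
  stable subject deviations (SDs 0.12 and 0.2); learning rates ~N(0.5,
  0.1²), temperatures log-normal around 4. Slopes were chosen once so that
  cohort-level age effects are detectable at this sample size — values in
  the range reported for this task family — not to match any printed
  statistic.
* **Iron trajectories.** Exponential-approach curves
  `asymptote + amplitude·exp(−rate·(age − 10))` per ROI — the simplest
  family with decelerating accumulation — with subject random intercepts
  (SD 0.12), residual noise (SD 0.10), and a batch B offset (+0.05) and
  residual-scale factor (×1.1) to exercise the harmonizer. The caudate
  gets a deliberately shallow trajectory, emulating its weak age
  association.
* **Coupling.** The behavior–iron coupling acts on the *subject residual*
  of the relevant generative parameter (perseveration for fss, the
  model-based weight for mb), scaled by `coupling_beta(age)`: constant
  amplitude −0.4 below age 14, ramping linearly to zero at 23, zero above
  (negative: more perseveration for one's age → lower nT2\*w → more iron).
  `a0 = a1 = Inf` gives a constant coupling for ladder experiments;
  an empty coupling table gives null cohorts.
* **Index-level mode.** `generate_cohort(..., simulate_trials = FALSE)`
  draws indices from the latent maps plus measurement noise (SD 0.25)
  instead of simulating 200 trials and refitting the stay model. The
  replicate-cohort experiments (ladder, windows) use this mode: they test
  the index→iron stages, and trial-level simulation would only prepend an
  estimation step those experiments do not examine. Trial-level mode is
  the default and is what the index-recovery and signature experiments use.

What the generator does **not** emulate: real MRI noise physics and
registration error, practice effects and attrition, reward-walk
nonstationarities beyond the Gaussian walk, age-varying learning rates, or
any demographic structure. Passing recovery tests therefore demonstrates
that the estimators recover the stated generative structure at the stated
sizes — not that real data satisfy that structure.

## 7. Problem sizes and numerical choices

The standing experiments (`expt_*`, also run by `scripts/acceptance.R`)
use: 100-session cohorts for agent signatures and index validity; 500
replicates of n = 500 for spline calibration; 20 replicate ~320-session
cohorts per condition for ladder and window recovery; 3 phantom sessions
for preprocessing invariances; a 40-subject double run for determinism.
These sizes give Monte-Carlo error comfortably below the effect sizes under
test while keeping a full validation run under ten minutes on one CPU.

Numerical details: reward-walk reflection handles arbitrarily large steps
by modular folding; softmaxes subtract the max before exponentiating; the
MAP objective returns a large finite penalty where the posterior is
degenerate so quasi-Newton steps stay finite; optimizer seeds are isolated
so fitting does not perturb the caller's random stream; varying-coefficient
terms with a constant covariate are dropped explicitly (an inert penalized
block would otherwise make the smoothing-parameter problem singular);
windows at grid ends use one-sided differences.

## 8. Known limitations

* MAP point estimates are shrunken relative to hierarchical posterior
  means; only orderings should be compared across fitting frameworks.
* The deviance-test df for an added smooth (its basis dimension) is an
  approximation; with k = 3 the ladder's selections are driven mainly by
  the conjunction with AIC and are well-calibrated in the recovery
  experiments.
* Pointwise windows are anti-conservative under the null (documented
  above); simultaneous bands are the controlled option.
* The harmonizer assumes location-scale batch effects; batch-by-age
  interactions would pass through it.
* k = 3 smooths cannot represent sharp developmental transitions; a true
  piecewise coupling is recovered as a smooth decline whose detected
  endpoint carries a modest, size-dependent attenuation.
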