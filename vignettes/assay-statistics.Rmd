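---
title: "Models and design choices behind the larvastat pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind the larvastat pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvastat)
```

This vignette explains the statistical models the package implements, the
choices made where the methodology was genuinely open, and what the
synthetic-data generators do and do not emulate.

## The light–dark transition model

Larval zebrafish stereotypically increase swimming in darkness; exposure
effects show up as phase-specific shifts in activity. The assay records
distance moved per second through a 62-minute protocol: 20 min dark
acclimation (0 lux), 20 min light (13,238 lux; phases L1 and L2 of 600 s),
and 22 min dark (phases D1 and D2 of 600 s plus a trailing 120 s).

**Binning.** Each phase contributes exactly five 2-minute sums per larva.
That arithmetic fixes the phase windows: D1 and D2 are the first two 600-s
blocks of the dark period and the final 120 s are recorded but not binned —
five 2-min sums per phase cannot cover 1320 s. Binning is plain summation,
so it is tested against direct summation oracles and conserves per-phase
totals exactly.

**Scaling.** Two-minute sums are bounded below by zero and above by a
physical maximum, which motivates a beta rather than Gaussian response.
Bins are divided by `M = 1.001 ×` the maximum bin. Two readings of "maximum
per larva within an experiment" are possible; we scale by **one constant
per experiment** (the maximum across larvae), because per-larva constants
would put each larva on its own scale and break the cross-group
comparability of marginal means. The per-larva alternative remains
available via `compute_scale(per_larva = TRUE)`. The 1.001 factor keeps the
maximum at `1/1.001 ≈ 0.999001`, strictly inside the unit interval; exact
zeros (a larva that never moved in a bin) are nudged to a configurable
`epsilon = 1e-6`, far below any observable activity fraction.

**The beta GAMM.** Scaled bins are modeled as

$$\mathrm{logit}(\mu_{it}) = \beta_0 + f(t) + \alpha_{c(i)} + \gamma_{p(t)}
  + (\alpha\gamma)_{c(i),p(t)} + b_i,\qquad
  y_{it} \sim \mathrm{Beta}(\mu_{it}\varphi, (1-\mu_{it})\varphi),$$

with $f$ a cubic P-spline (basis size 10, second-order difference penalty),
treatment (concentration) and phase as categorical fixed effects with
their two-way interaction, and per-larva random intercepts
$b_i \sim N(0, \sigma_b^2)$ implemented as ridge-penalized coefficients —
the smooth-as-random-effect equivalence — so the whole model is one
penalized likelihood. Smoothing and variance parameters are selected by
the outer restricted marginal-likelihood criterion; the engine is
`mgcv::gam(..., family = betar, method = "REML")`. The precision
$\varphi$ is reported as `precision`; $\sigma_b$ as `random_sd`. Because
phase is a step function of time, the time smooth and the phase main
effects compete for between-phase level differences; the penalty resolves
this in favor of the factor (the smooth prefers smoothness), and the
treatment-by-phase interaction — the scientifically interesting term — is
unaffected because the smooth is shared across treatments. Parameter
recovery of a +1 logit dark-phase interaction is verified by simulation.

Responses on the boundary are rejected (scale first); non-convergence is
flagged on the fit object and blocks the post hoc stage, never silently.

**Autocorrelation.** Consecutive 2-min bins of one larva are serially
dependent. The package estimates the pooled lag-1 autocorrelation of
within-larva working residuals and records it in the fit metadata; with
`ar1 = TRUE` the coefficient covariance is inflated by
$(1+\hat\rho)/(1-\hat\rho)$, a working-correlation correction. The switch
defaults to OFF because the penalized smooth already absorbs most serial
trend and because a full AR(1) beta-family fit is not available in the
penalized-likelihood machinery used here; the estimated $\hat\rho$ is
always reported so users can judge.

**EMMs and multiplicity.** Estimated marginal means are the fitted linear
predictor per treatment × phase cell with the time smooth averaged over
the observed time grid and the random intercept at zero; standard errors
come from the delta method on the penalized-coefficient covariance, and
inference uses the normal approximation (penalized fits do not admit a
clean finite residual df). The contrast family is **all between-treatment
pairs within the same phase, adjusted jointly**: the adjusted p-value is
the null probability that the maximum absolute standardized contrast in
the whole family exceeds the observed one, computed by Monte-Carlo
integration (1e5 draws, fixed internal seed, caller's RNG untouched) over
the estimated contrast correlation. This single-step max-|z| construction
is the multivariate-normal generalization of Tukey's procedure and stays
valid for unbalanced families; with a single pair it reduces exactly to
the unadjusted two-sided z test. Pure phase contrasts (dark vs light
within one treatment) are not part of the family — the assay's questions
are between treatments — which also means a single-treatment run simply
has no contrasts. Compact letters are assigned per phase by
insert-and-absorb so that two treatments share a letter exactly when
their adjusted p ≥ α = 0.05.

**Startle response.** The VSR is the summed distance in the first three
full seconds after each transition (1200–1202 s and 2400–2402 s; the
recording has no sub-second convention, so windows are closed 3-s blocks
starting at the transition second). It is modeled on its raw scale as
`value ~ treatment + startle_phase + (1 | animal)` by REML (`lme4`),
without an interaction, and post-processed by the same EMM/adjustment/
letters chain. A rank-deficient fixed design is an error naming the
aliased columns.

## The MEA concentration–response pipeline

Sorted units from BrainSphere-derived networks are recorded for 15 min per
segment across 11 segments: baseline, GABA 10 µM, antagonist (bicuculline
10 µM or saclofen 5 µM depending on the well), a post-washout baseline
that serves as the 0 µM reference, and seven increasing PFOS
concentrations (7.78–120 µM).

* **Activity filter:** units with zero spikes in either baseline carry no
  information and are dropped (`seg1 > 0 & seg4 > 0`).
* **Inclusion window:** the 2.5th and 97.5th percentiles of each
  baseline's counts (computed on the activity-filtered population, in
  that order) define a nonparametric 95% inclusion window; counts are
  compared to the interpolated bounds inclusively and without rounding.
  The percentile estimator is the linear-interpolation type with plotting
  position $(k-1)/(n-1)$ (R's type 7) — the convention is stated because
  integer counts near a bound depend on it.
* **Classification:** a unit is GABA_A if spiking strictly decreased
  under the agonist and strictly increased under bicuculline; GABA_B
  likewise under saclofen. Ties fail: the rule is deterministic and
  conservative. Note the rule is purely directional — a unit whose
  spontaneous fluctuations happen to dip and rebound will be classified,
  so specificity against active-but-nonresponsive units is limited by
  chance (about 1/3 of exchangeable triples dip-then-rebound); the
  simulation suite quantifies this honestly rather than hiding it.
* **Normalization:** counts are divided by the unit's total over the
  *analyzed* segments, read as segments 4–11 — the segments entering the
  statistical comparison; segments 1–3 exist for classification only.
  The alternative (1–11) is available via the `segments` argument. Units
  with a zero analyzed total are excluded with their ids logged.
* **Testing:** a Friedman test (within-unit midranks, tie-corrected
  chi-square, df = k−1) across the eight paired conditions, then Conover
  many-to-one statistics comparing each concentration's rank sum to the
  0 µM control with pooled tie-corrected variance and df = (n−1)(k−1),
  two-sided, and Benjamini–Hochberg adjustment over the seven control
  comparisons. Fully tied blocks define a zero statistic with p = 1.
  Both tests also offer `exact = TRUE`, which replaces the asymptotic
  tail with the exact within-block permutation null — enumerable for the
  small designs used in verification, where the asymptotic p-values are
  checked to agree with the exact ones in rank order.

## Synthetic data: what it does and does not emulate

`simulate_bins` draws directly from the beta mixed model above (trend +
phase + treatment-by-phase + larva intercept), so model-recovery tests are
exact generative round trips. Defaults are the conditions a typical
experiment presents: 24 larvae per group (replicate counts in such assays
run roughly 21–45), precision φ = 20 and intercept SD 0.5 on the logit
scale (activity fractions mostly 0.1–0.6 with clear between-larva
spread), markedly higher dark-phase activity (+1 and +0.8 logits), and a
mild sinusoidal drift. `simulate_trace` exists to exercise binning,
scaling, startle extraction and IO: per-second distances are gamma draws
(shape 0.6, capturing intermittent beat-and-glide swimming) with
phase-dependent means and a startle burst spread over the 3 s after each
transition, plus viability flags at a 5% exclusion rate. Its second-level
marginals are *not* calibrated to aggregate exactly to the beta bin
model — bins are the modeling level, seconds only feed the plumbing.

`simulate_paradigm` draws negative-binomial counts
(`Var = μ + μ²/θ`, θ = `nb_dispersion`, default 5; `Inf` gives the
Poisson limit) around lognormal per-unit baseline rates (median 200
spikes/segment), with multiplicative agonist suppression (0.3),
antagonist rebound (2.5), washout return to baseline, and per-segment
PFOS factors (default 1 = null). Responsive units sit in wells carrying
their matching antagonist; inactive units emit a zero first baseline to
exercise the activity filter. What passing tests show is that the
*statistical machinery* behaves — filters select exactly the defined
sets, effects injected at these magnitudes are recovered, null rates are
controlled. They do not show robustness to features real MEA data can
have (bursting, non-stationary drift, within-well correlation between
units, rate-dependent sorting artifacts), which the generator does not
model.

## Numerical conventions

* Iterative fits use the engines' defaults with REML selection and
  deterministic initialization; convergence flags are propagated, and a
  non-converged beta fit blocks post hoc analysis explicitly.
* The Monte-Carlo multiplicity adjustment uses 1e5 draws under a fixed
  internal seed (results are reproducible and identical across repeated
  calls); the caller's RNG state is saved and restored. Adjusted
  p-values are clamped to `[raw_p, 1]`.
* Degenerate inputs have defined answers: all-tied Friedman blocks give
  statistic 0 and p = 1; a zero-variance Mann–Whitney comparison gives
  p = 1; an all-zero experiment has no defined scaling constant and is
  an error.
* Exact Mann–Whitney p-values are computed from the null distribution of
  U — equivalently, the proportion of label permutations at least as
  extreme — whenever the pooled sample has no ties and n₁ + n₂ ≤ 20;
  otherwise the midrank normal approximation with tie and continuity
  correction is used and labeled as such in the result.
* Problem sizes in the verification suite (50 simulated experiments for
  interaction recovery, 200 for familywise error, 1000 units for
  classification, 1000/2000 null recordings for FDR and test size) were
  chosen to give Monte-Carlo standard errors comfortably below the
  margins being checked while keeping a full run in the minutes range.

## Known limitations

* The beta GAMM supports the terms this assay needs (one smooth,
  categorical fixed effects, one random-intercept factor) — it is not a
  general GAMM toolkit, and there is no Bayesian mode.
* The AR(1) switch is a variance inflation, not a full correlated-error
  likelihood.
* EMM inference is z-based; for very small experiments a
  degrees-of-freedom correction would be more conservative.
* The pharmacological classification rule is directional by design
  (matching the assay's definition) and inherits that rule's false
  positive rate among active nonresponsive units; treat class
  counts as estimates, not ground truth.
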