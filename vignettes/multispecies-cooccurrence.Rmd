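---
title: "Multispecies co-occurrence and activity overlap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispecies co-occurrence and activity overlap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the occurrence
and intensity-of-use model, the sampler, model ranking, the circular
activity machinery, the synthetic-data generator, and the numerical and
design choices behind each. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The occurrence model

For `S` interacting categories (wildlife species and human recreation
types are treated identically, each with its own occurrence and use
process), the latent presence vector `z` at a site follows a multivariate
Bernoulli distribution written in log-linear form:

$$P(z) \propto \exp\Big(\sum_i z_i f_i + \sum_{i<j} z_i z_j f_{ij}\Big),$$

with first-order natural parameters $f_i = x_\alpha'\alpha_i$ and pairwise
parameters $f_{ij} = x_\gamma'\gamma_{ij}$, each linear in site
covariates. $f_{ij}$ is the log odds-ratio of co-occurrence: zero means
independence, negative means avoidance. Third- and higher-order terms are
fixed at zero; with four categories the 16-state distribution is then
parameterised by at most 4 first-order and 6 pairwise terms, which keeps
every term interpretable as a pairwise association and matches the
hypotheses the candidate grammar encodes. Closed forms follow from the
state table: marginals are sums over states, conditionals are ratios, and
for two species `P(z1 = 1 | z2 = 1) = plogis((alpha_0 + gamma_0) +
alpha_1 x)`.

**State encoding.** States are enumerated with species `i` as bit `i`
(state index $1 + \sum_i z_i 2^{i-1}$), so state 1 is all-absent and the
two-species order is `00, 10, 01, 11`. The `psi_11`-style notation common
for two species does not generalise unambiguously to `S > 2`; the bit
encoding in `state_space()` is the package-wide convention and every
function that consumes a `psi` vector assumes it.

**Detection as intensity of use.** On human-use trails the per-occasion
"detection probability" of a continuously moving animal is better read as
the intensity with which it uses the trail, and it is a quantity of
interest rather than a nuisance. It is modelled on the logit scale as
covariate terms plus named *modifiers*, one per conditioning species,
added when that species is **latently** present. Whether such conditioning
should key on latent or on observed presence is genuinely open; latent
presence was chosen because the occurrence model supplies it coherently
(an unobserved but present competitor still affects behaviour), and
because it makes the two-parameter present/absent formulation
(`p(z = 1)`, `p(z = 0)`) exact within the likelihood.

**Site likelihood.** The likelihood marginalises `z` exactly over all
$2^S$ states; a species with $z_i = 0$ contributes only when it was never
detected at the site, missing occasions contribute a factor of one, and
everything is accumulated in log space with log-sum-exp. Occasions are
assumed exchangeable given the state (use probabilities are constant
within a season), sites independent given covariates.

## Data preparation

* **Occasions** default to 4 days — long enough to keep per-occasion use
  probabilities moderate for wide-ranging species, short enough to retain
  ~18 occasions over a ~10-week summer window. Windows are anchored at the
  global study start so occasion `t` means the same calendar window at
  every site (deterministic, comparable binning); per-camera anchoring is
  available via `anchor = "camera"`.
* A window counts as **surveyed** if the camera was active for any part of
  it; only fully inactive windows are missing. This is conservative
  against data loss and matches presence-absence semantics: one active day
  with a detection is a legitimate presence.
* Sites with fewer than 4 surveyed occasions are dropped
  (`filter_min_surveys()`): such records carry almost no information about
  occurrence and destabilise fitting.
* **Independent events** for activity analysis use a 30-minute gap rule
  (linear scan within site and category), a common camera-trap convention;
  the threshold is a parameter because no single value is canonical. Burst
  photography (3–5 frames per trigger) collapses to one event regardless
  of burst size.
* The `unknown` category (animals not identifiable to species) is excluded
  from histories and activity analysis.
* Continuous covariates are standardised to mean 0, sd 1 before fitting
  (binary 0/1 columns are left alone); scalers are stored on the fit and
  applied to `newdata` in `predict()`. This puts the logistic prior on a
  comparable scale for every slope.

## Priors, sampler, diagnostics

All coefficients get independent logistic(0, 1) priors — density 1/4 at
zero, variance $\pi^2/3$ — which are weakly informative on the logit scale
and keep the posterior proper even with no data (the property the
prior-recovery test exercises for every parameter type).

The sampler is adaptive random-walk Metropolis: proposal scale adapted by
Robbins–Monro toward acceptance 0.234, proposal shape adapted to the
empirical covariance of the warmup draws (plus a `1e-6` diagonal ridge),
both frozen at the end of warmup so the post-warmup chain targets the
exact posterior. The contract is distributional correctness, not a named
algorithm; the defaults (3 chains × 2,000 iterations, 1,000 warmup)
mirror the study design the package emulates, and every entry point
requires a seed (chain `c` is seeded `seed + (c-1) * 100003`). Initial
values are mildly overdispersed draws around the prior mode.

Convergence is summarised by split-chain Rhat; "close to 1" is
operationalised as a flag at 1.1, attached to fits and rankings rather
than silently enforced (`run_pipeline()` turns an unacknowledged flag into
a non-zero exit). Zero-variance parameters define Rhat as 1 with a
warning.

## WAIC and the candidate set

WAIC uses the pointwise per-site log-likelihood over all post-warmup
draws, with the variance form of the effective-parameter penalty
(`p_waic = sum of per-site posterior variances`), the standard choice for
fully Bayesian comparison. Weights are `exp(-ΔWAIC/2)` normalised over the
set, with deltas taken to the minimum for numerical stability (weights are
invariant to adding a constant to all WAICs). Non-convergent fits stay in
the ranking with a flag; excluding them from the weights is an option, not
the default, so the table always accounts for every candidate.

The shipping grammar (`candidate_grammar()`) enumerates 4 × 2 × 3 × 2 = 48
models over the four structural axes such a study varies: bear–recreation
co-occurrence (none / motorised / non-motorised / both), bear–bear
co-occurrence, recreation effects on bear intensity of use (none /
motorised only / both forms), and the grizzly-presence modifier on black
bear use. The historical 48-model list this approximates is not fully
recoverable, so the preset is documented as an approximation with the same
axes; the grammar machinery accepts any user-defined base model and axes
and deduplicates structurally identical variants with a warning.

## Diel activity and overlap

Event clock times map to angles (`time/24h · 2π`). Densities are von
Mises kernel density estimates with the plug-in concentration rule
$\nu = \big(3 n \hat\kappa^2 I_2(2\hat\kappa) / (4\sqrt{\pi}
I_0(\hat\kappa)^2)\big)^{2/5}$, where $\hat\kappa$ comes from the
trigonometric-moment (mean resultant length) estimator; a user multiplier
(default 1) scales the result. Densities are evaluated on a 513-point
periodic grid (512 intervals — finer than typical package defaults because
the grid is cheap and the trapezoid error negligible for periodic smooth
functions) and renormalised so the trapezoidal integral is exactly one.

Overlap uses the small-sample nonparametric estimator
$\hat\Delta_1 = \int \min(\hat f_a, \hat f_b)$ for **all** comparisons,
regardless of sample size: the study sizes here are mostly below the
conventional n = 75 threshold, and using one estimator throughout keeps
present/absent cells comparable. $\hat\Delta_4$/$\hat\Delta_5$ are
deliberately not implemented.

Confidence intervals are smoothed bootstrap (resample events from each
fitted density by perturbing data points with kernel noise, refit
bandwidths, recompute $\hat\Delta_1$; 1,000 resamples by default) with the
**basic (reflected percentile)** interval $[2\hat\Delta - q_{1-\alpha/2},
\, 2\hat\Delta - q_{\alpha/2}]$, clipped to $[0,1]$ and widened if
necessary to bracket the point estimate. The variant matters:
$\hat\Delta_1$ carries a positive smoothing bias for separated densities,
and the bootstrap mean sits above the point estimate by roughly that bias,
so the raw percentile interval is centred about two biases away from the
truth. The reflection subtracts the bias estimate, and in the package's
own coverage study (200 replicates of von Mises pairs at n = 75, run in
the test suite) restores empirical coverage close to the nominal 95%.

`conditional_overlap()` partitions sites by whether the conditioning
species was ever detected there and compares the focal species' activity
in each subset against the full reference series of the `versus` category,
reporting $\hat\Delta_1$, its interval, and the subset event count; cells
with fewer than 2 events are reported as missing with their `n`.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is checked.

* `simulate_covariates()` emulates a mountain/foothill trail network over
  a June–August window: distances to road and stream are lognormal in
  metres (median 800 m and 300 m) and enter as natural logs; elevation is
  a 50/50 mixture of N(1350, 120²) and N(1900, 180²) m; NDVI is
  Beta(12, 4); half the sites are in a protected area; 10% of cameras fail
  early at a uniform time. Defaults were chosen once as plausible field
  values and are exposed as arguments, so the moment checks in the test
  suite test the code, not the choice.
* `simulate_dataset()` draws the latent state from the model's own state
  probabilities, then occasion detections Bernoulli given the state, over
  the deployment calendar (default 182 sites × 18 four-day occasions).
  Event-level expansion places 1 + Poisson(0.5) timestamped events per
  detected occasion at clock times drawn from each species' von Mises
  activity mixture, linking the occupancy and activity surfaces.
* `example_truth()` ships a study-like preset: habitat effects on bear
  occurrence, a protected-area effect on recreation, a negative
  grizzly–black pairwise term, and use modifiers (recreation on both
  bears, grizzly presence on black bear use). Bear coefficients are set to
  published posterior means from such a system for realism — illustrative,
  not ground truth — and recreation coefficients and activity mixtures are
  invented but plausible.

What the generator does **not** emulate, and what passing tests therefore
do not establish about real data: spatial autocorrelation between sites,
animal movement and home-range structure (detections are exchangeable
given the state), classification error, seasonal trends in activity or
use, and unequal per-site effort beyond early camera failure.

## Problem sizes and numerical choices

The test suite's simulation studies use sizes chosen to make their checks
informative while keeping the suite quick to run: parameter recovery uses
10 replicates of 300 sites × 18 occasions with a true pairwise term of
−0.5 (posterior sd ≈ 0.24 at that size, so systematic errors would be
visible); selection power uses 10 replicates of 150 sites with a strong
(−2) pairwise term; the bootstrap coverage study uses 200 replicates of
von Mises pairs at n = 75 with 150 resamples on a 128-interval grid; the
generator frequency checks use 50,000 sites.

Numerical conventions throughout: all state sums and site likelihoods in
log space via log-sum-exp; `n log p` terms evaluated through
`plogis(eta, log.p = TRUE)` so extreme logits stay finite; a species with
detections contributes `-Inf` to absent states (exact zeros survive the
log-sum-exp); degenerate inputs error early with the offending field or
term named (unknown sites, mismatched parameter vectors, conditioning
events of probability zero, all sites filtered out).

## Known limitations

Pairwise-only dependence (no third-order terms); single-season, closed
occurrence (no colonisation/extinction dynamics); no spatial random
effects; no abundance (N-mixture) interpretation; WAIC only (no
cross-validation criteria); random-walk MCMC mixes slowly for models far
larger than the shipping candidate set, in which case longer chains and
the convergence flags are the guard rails.
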