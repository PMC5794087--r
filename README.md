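# mvboccu

Multispecies co-occurrence and diel activity analysis for camera-trap data.

Trail cameras record which species use a site and when, but raw detections
confound two processes: whether a species occurs at a site at all, and how
intensively it uses the trail when it does. `mvboccu` implements a joint
model for both, designed for questions about interacting species — for
example, whether two competing bear species avoid each other in space, and
whether human recreation (motorised and non-motorised, treated as
"species" in their own right) changes how bears use trails and when they
are active.

## The model

Detections are collapsed into occasion-level histories (default 4-day
occasions). For `S` species the joint latent presence vector
`z = (z_1, ..., z_S)` at a site follows a multivariate Bernoulli
distribution with log-linear natural parameters

    f_i  = x_i' alpha_i          (first-order, one per species)
    f_ij = x_ij' gamma_ij        (pairwise log odds-ratio of co-occurrence)

so `P(z) ∝ exp( Σ_i z_i f_i + Σ_{i<j} z_i z_j f_ij )`. A negative `f_ij`
means spatial avoidance; `f_ij = 0` means independent occurrence, in which
case the marginal occurrence of species `i` is `plogis(f_i)`. Conditional
occurrence has a closed logistic form, e.g. for two species
`P(z1 = 1 | z2 = 1) = plogis((alpha_0 + gamma_0) + alpha_1 x)`.

Given presence, each surveyed occasion is a Bernoulli trial with
intensity of use `p_i` on the logit scale — an intercept, optional
covariates, and additive modifiers that switch on when another species is
latently present (e.g. black bear trail use shifting where grizzly bears
occur). The latent states are marginalised exactly over all `2^S`
combinations in the site likelihood.

Fitting is Bayesian: independent logistic(0, 1) priors on all
coefficients, adaptive random-walk MCMC (3 chains x 2,000 iterations,
1,000 warmup by default), split-chain Rhat convergence checks, and WAIC
with `exp(-ΔWAIC/2)` weights for ranking a structural candidate set
(`candidate_grammar()` ships a 48-model preset varying bear–recreation
co-occurrence, bear–bear co-occurrence, recreation effects on bear use,
and the grizzly-on-black use modifier).

Diel activity is handled on the 24-hour circle: von Mises kernel densities
with a plug-in concentration rule, the nonparametric coefficient of
overlapping `Δ̂1 = ∫ min(f̂_a, f̂_b)` (1 = identical schedules, 0 =
disjoint), smoothed-bootstrap confidence intervals, and present/absent
site-partition comparisons (`conditional_overlap()`).

A synthetic-data generator (`simulate_covariates()`, `example_truth()`,
`simulate_dataset()`) reproduces the statistical structure of a
two-bear/two-recreation camera study — 182 sites, ~18 four-day occasions —
so the whole pipeline is testable end to end.

## Worked example

```r
library(mvboccu)

spec <- mvb_spec(
  species    = c("grizzly", "black"),
  occurrence = list(grizzly = ~ elevation, black = ~ elevation),
  pairs      = list(c("grizzly", "black")),        # f_12 term
  modifiers  = list(black = "grizzly"))            # grizzly presence shifts black p

truth <- mvb_truth(spec, c(
  psi_grizzly_Intercept = 0.2, psi_grizzly_elevation = 0.5,
  psi_black_Intercept = 0.4,   psi_black_elevation = -1.0,
  f_grizzly.black_Intercept = -1.0,
  p_grizzly_Intercept = -1.2,  p_black_Intercept = -1.5,
  p_black_z.grizzly = 1.0))

sim <- simulate_dataset(truth, n_sites = 182, n_occasions = 18, seed = 11)
round(naive_summary(sim$history)$naive, 2)
#> grizzly   black
#>    0.45    0.52

fit <- mvb_occu(spec, sim$history, sim$deployments, seed = 11)
summary(fit)
#> Posterior summary (logit scale), model: 2sp pairs(grizzly~black) mods(black|grizzly)
#>                  parameter   mean    sd  lower  upper  rhat
#>      psi_grizzly_Intercept  0.457 0.242  0.044  0.995 1.009
#>      psi_grizzly_elevation  0.423 0.177  0.082  0.745 1.042
#>        psi_black_Intercept  0.776 0.247  0.370  1.291 1.034
#>        psi_black_elevation -1.106 0.204 -1.515 -0.714 1.026
#>  f_grizzly.black_Intercept -1.163 0.343 -1.780 -0.515 1.032
#>        p_grizzly_Intercept -1.386 0.066 -1.517 -1.262 1.038
#>          p_black_Intercept -1.539 0.080 -1.696 -1.393 1.005
#>          p_black_z.grizzly  1.135 0.122  0.902  1.362 1.038
```

The pairwise natural parameter is recovered clearly negative
(truth −1.0, posterior mean −1.16): the two species co-occur less than
their habitat preferences alone would predict. Posterior-mean predictions
make that concrete at the average elevation:

```r
newd <- data.frame(elevation = mean(sim$deployments$elevation))
predict(fit, newd, type = "conditional", species = "black", given = "grizzly", z = 1)
#> 0.404                       # P(black present | grizzly present)
predict(fit, newd, type = "conditional", species = "black", given = "grizzly", z = 0)
#> 0.685                       # P(black present | grizzly absent)
predict(fit, newd, type = "p", z = c(grizzly = 1))[, "black"]
#> 0.4                         # per-occasion use where grizzly bears occur
predict(fit, newd, type = "p", z = c(grizzly = 0))[, "black"]
#> 0.177                       # ... and where they do not
```

Activity overlap between a crepuscular species and midday recreation:

```r
set.seed(11)
bears  <- simulate_times(120, list(mu = c(6, 20) / 24 * 2 * pi, kappa = c(3, 3), w = c(.5, .5)))
hikers <- simulate_times(200, list(mu = 13 / 24 * 2 * pi, kappa = 3, w = 1))
bootstrap_ci(bears, hikers, n_boot = 1000, seed = 11)
#> Activity overlap Dhat1 = 0.404 [0.285, 0.404] (95% smoothed basic bootstrap,
#> 1000 resamples; n = 120, 200)
```

A config-driven pipeline (`run_pipeline()`, YAML config via
`read_config()`, thin CLI wrapper in `inst/cli/mvboccu.R`) chains
`simulate -> histories -> fit / rank -> overlap -> report` with
deterministic, hash-stamped CSV artifacts.

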