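spec2 <- mvb_spec(c("a", "b"), pairs = list(c("a", "b")),
                  modifiers = list(b = "a"))

test_that("log posterior is the likelihood plus logistic prior mass", {
  # empty data: prior only; logistic(0,1) density at 0 is 1/4
  expect_equal(log_posterior(rep(0, 6), spec2, NULL, NULL), 6 * log(1 / 4))
  set.seed(14)
  sites <- c("s1", "s2", "s3")
  covs <- data.frame(site_id = sites)
  y <- array(sample(c(0L, 1L, NA), 3 * 2 * 4, TRUE), c(3, 2, 4),
             dimnames = list(sites, c("a", "b"), NULL))
  for (rep in 1:5) {
    theta <- rnorm(6)
    want <- sum(pointwise_loglik(spec2, y, covs, theta)) +
      sum(dlogis(theta, log = TRUE))
    expect_equal(log_posterior(theta, spec2, y, covs), want, tolerance = 1e-10)
    expect_true(is.finite(log_posterior(theta * 5, spec2, y, covs)))
  }
})

test_that("posterior sampling is reproducible from its seed", {
  set.seed(999)  # should not matter
  tr <- mvb_truth(spec2, setNames(c(0, 0, -1, 0, 0, 1),
                                  c("psi_a_Intercept", "psi_b_Intercept",
                                    "f_a.b_Intercept", "p_a_Intercept",
                                    "p_b_Intercept", "p_b_z.a")))
  sim <- simulate_dataset(tr, n_sites = 30, n_occasions = 6, seed = 4)
  d1 <- sample_posterior(spec2, sim$history, sim$deployments, chains = 2,
                         iterations = 200, warmup = 100, seed = 11)
  d2 <- sample_posterior(spec2, sim$history, sim$deployments, chains = 2,
                         iterations = 200, warmup = 100, seed = 11)
  expect_identical(unclass(d1)[, , ], unclass(d2)[, , ])
})

test_that("split Rhat flags divergent chains and matches the formula", {
  set.seed(8)
  # chains from the same distribution: Rhat near 1
  x <- array(rnorm(4 * 500), c(4, 500, 1), dimnames = list(NULL, NULL, "t"))
  expect_lt(abs(rhat(x)["t"] - 1), 0.01)
  # chains with means 0 and 100: far above the 1.1 flag
  xx <- array(c(rnorm(200), rnorm(200, 100)), c(2, 200, 1),
              dimnames = list(NULL, NULL, "t"))
  xx[1, , 1] <- rnorm(200)
  xx[2, , 1] <- rnorm(200, 100)
  expect_gt(rhat(xx)["t"], 10)
  # fixed small array vs the hand-coded split formula
  m <- matrix(c(1.2, 0.4, -0.3, 0.9, 2.0, -1.1, 0.5, 0.8,
                0.1, -0.6, 1.4, 0.2, -0.9, 0.3, 1.1, -0.4), 2, 8, byrow = TRUE)
  arr <- array(m, c(2, 8, 1), dimnames = list(NULL, NULL, "p"))
  expect_equal(unname(rhat(arr)["p"]), oracle_split_rhat(m), tolerance = 1e-12)
  # constant draws: defined as 1 with a warning
  cst <- array(1, c(2, 8, 1), dimnames = list(NULL, NULL, "c"))
  expect_warning(r <- rhat(cst), "zero")
  expect_equal(unname(r), 1)
})

test_that("WAIC follows its defining formula", {
  # all draws identical: p_waic 0, WAIC = -2 * total log-lik
  ll <- matrix(rep(c(-1.5, -2.5), each = 4), 4, 2)
  w <- waic(ll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * (-1.5 - 2.5))
  # small fixture vs the direct formula
  m <- matrix(c(-1, -2, -1.5, -0.5, -3, -2), 3, 2)
  w2 <- waic(m)
  lppd <- sum(log(colMeans(exp(m))))
  p <- sum(apply(m, 2, var))
  expect_equal(w2$lppd, lppd, tolerance = 1e-12)
  expect_equal(w2$p_waic, p, tolerance = 1e-12)
  expect_equal(w2$waic, -2 * (lppd - p), tolerance = 1e-12)
  # adding an independent site adds its own contribution
  extra <- matrix(c(-2, -1, -1.5), 3, 1)
  expect_equal(waic(cbind(m, extra))$waic, w2$waic + waic(extra)$waic,
               tolerance = 1e-12)
})

test_that("WAIC weights normalise relative likelihoods", {
  expect_equal(waic_weights(c(10, 10, 10)), rep(1 / 3, 3))
  expect_equal(waic_weights(c(0, 1000)), c(1, 0))
  w <- waic_weights(c(100, 102))
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  # invariant to adding a constant
  expect_equal(waic_weights(c(3, 7, 9)), waic_weights(c(3, 7, 9) + 500),
               tolerance = 1e-12)
})

test_that("candidate grammars enumerate the product of their axes", {
  base <- mvb_spec(c("a", "b"))
  g1 <- list(base = base, axes = list(
    pair = list(no = list(), yes = list(pairs = list(c("a", "b"))))))
  expect_length(build_candidate_set(g1), 2)
  g2 <- list(base = base, axes = list(
    ax1 = list(v1 = list(), v2 = list(pairs = list(c("a", "b")))),
    ax2 = list(v1 = list(), v2 = list(modifiers = list(b = "a"))),
    ax3 = list(v1 = list(), v2 = list(modifiers = list(a = "b")),
               v3 = list(modifiers = list(a = "b", b = "a"))),
    ax4 = list(v1 = list(), v2 = list(modifiers = list(b = "a")))))
  # axis sizes (2, 2, 3, 2) = 24 raw models, some structurally identical
  expect_warning(specs <- build_candidate_set(g2), "duplicate")
  raw <- suppressWarnings(build_candidate_set(g2))
  expect_length(raw, length(unique(vapply(raw, mvboccu:::spec_signature, ""))))
  g3 <- list(base = base, axes = list(
    ax1 = list(v1 = list(), v2 = list(pairs = list(c("a", "b")))),
    ax2 = list(v1 = list(), v2 = list(modifiers = list(b = "a"))),
    ax3 = list(v1 = list(), v2 = list(modifiers = list(a = "b"))),
    ax4 = list(v1 = list())))
  expect_length(build_candidate_set(g3), 8)
  # shipping preset: 4 x 2 x 3 x 2 distinct structures
  expect_length(build_candidate_set(candidate_grammar()), 48)
})

test_that("model ranking orders by WAIC and a lone model gets weight one", {
  tr <- mvb_truth(spec2, setNames(c(0.3, 0.2, -1.5, 0, -0.3, 1),
                                  c("psi_a_Intercept", "psi_b_Intercept",
                                    "f_a.b_Intercept", "p_a_Intercept",
                                    "p_b_Intercept", "p_b_z.a")))
  sim <- simulate_dataset(tr, n_sites = 40, n_occasions = 8, seed = 2)
  indep <- mvb_spec(c("a", "b"), label = "independence")
  rk1 <- rank_models(list(indep), sim$history, sim$deployments, chains = 2,
                     iterations = 300, warmup = 150, seed = 5)
  expect_equal(rk1$weight, 1)
  rk2 <- rank_models(list(indep, spec2), sim$history, sim$deployments,
                     chains = 2, iterations = 300, warmup = 150, seed = 5)
  expect_equal(rk2$waic, sort(rk2$waic))
  expect_equal(sum(rk2$weight), 1, tolerance = 1e-12)
  expect_equal(rk2$delta_waic[1], 0)
})

test_that("spec YAML serialisation round-trips the model structure", {
  spec <- mvb_spec(c("grizzly", "black"),
                   occurrence = list(grizzly = ~ lndroad + elevation),
                   pairs = list(list(species = c("black", "grizzly"),
                                     formula = ~ ndvi)),
                   detection = list(black = ~ protected),
                   modifiers = list(black = "grizzly"), label = "demo")
  back <- spec_from_yaml(spec_to_yaml(spec))
  expect_identical(mvboccu:::spec_signature(back),
                   mvboccu:::spec_signature(spec))
  expect_identical(back$label, "demo")
})
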