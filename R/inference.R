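#' Log posterior density of a multispecies occurrence model
#'
#' Sum of the per-site marginal log-likelihoods and independent standard
#' logistic log prior densities, one per coefficient. The logistic(0, 1)
#' prior is weakly informative on the logit scale (density 1/4 at zero,
#' variance pi^2/3) and keeps every posterior proper even with no data.
#'
#' @inheritParams pointwise_loglik
#' @return a single finite log density (`-Inf` only if the likelihood is
#'   degenerate at `params`).
#' @export
log_posterior <- function(params, spec, history, sitecovs, standardize = TRUE) {
  stopifnot(all(is.finite(params)))
  ll <- if (is.null(history) || dim(history_array(history))[1] == 0) 0 else
    sum(pointwise_loglik(spec, history, sitecovs, params, standardize))
  ll + sum(stats::dlogis(params, log = TRUE))
}

# internal fast version against a prebuilt context
log_posterior_ctx <- function(theta, ctx) {
  par <- unpack_params(ctx$designs, theta)
  sum(ll_sites_internal(par, ctx$pair_idx, ctx$n1, ctx$n0, ctx$spec$species)) +
    sum(stats::dlogis(theta, log = TRUE))
}

#' Draw from the posterior by adaptive Markov chain Monte Carlo
#'
#' Random-walk Metropolis with Robbins-Monro adaptation of the proposal
#' scale (target acceptance 0.234) and empirical-covariance adaptation of
#' the proposal shape during warmup; after warmup the proposal is frozen so
#' the chain targets the exact posterior. The sampler contract is
#' distributional correctness, not a particular algorithm. Chains are
#' seeded deterministically from `seed`, so runs are reproducible.
#'
#' @inheritParams pointwise_loglik
#' @param chains number of chains (default 3; at least 2 for Rhat).
#' @param iterations total iterations per chain (default 2000).
#' @param warmup adaptation iterations discarded per chain (default 1000).
#' @param seed integer seed (mandatory for reproducibility).
#' @param init optional `[chains, params]` matrix of initial values;
#'   defaults to mildly overdispersed draws around the prior mode.
#' @return an `mvb_draws` object: array `[chain, iteration, parameter]` of
#'   post-warmup draws with parameter names, acceptance rates, seed and
#'   warmup recorded as attributes.
#' @export
sample_posterior <- function(spec, history, sitecovs, chains = 3,
                             iterations = 2000, warmup = 1000, seed,
                             standardize = TRUE, init = NULL) {
  stopifnot(chains >= 1, iterations > warmup, warmup >= 0)
  if (missing(seed)) stop("'seed' is required")
  empty <- is.null(history) || dim(history_array(history))[1] == 0
  if (empty) {
    sc <- data.frame(row.names = character(0))
    designs <- build_designs(spec, as.data.frame(sitecovs %||% sc)[0, , drop = FALSE])
    ctx <- list(spec = spec, designs = designs, pair_idx = pair_index(spec),
                n1 = matrix(0, 0, length(spec$species)),
                n0 = matrix(0, 0, length(spec$species)))
  } else {
    ctx <- build_context(spec, history, sitecovs, standardize)
  }
  d <- n_params(ctx$designs)
  lp_fun <- function(theta) log_posterior_ctx(theta, ctx)
  keep <- iterations - warmup
  draws <- array(NA_real_, c(chains, keep, d),
                 dimnames = list(NULL, NULL, ctx$designs$par_names))
  lp_keep <- matrix(NA_real_, chains, keep)
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + (ch - 1L) * 100003L)
    th0 <- if (is.null(init)) stats::rnorm(d, 0, 0.5) else init[ch, ]
    res <- am_chain(lp_fun, th0, iterations, warmup)
    draws[ch, , ] <- res$draws
    lp_keep[ch, ] <- res$lp
    accept[ch] <- res$accept
  }
  structure(draws, lp = lp_keep, accept = accept, seed = seed,
            warmup = warmup, scaling = ctx$scaling, class = "mvb_draws")
}

# one adaptive random-walk Metropolis chain; returns post-warmup draws
am_chain <- function(lp_fun, init, iterations, warmup) {
  d <- length(init)
  theta <- init
  cur <- lp_fun(theta)
  if (!is.finite(cur)) {
    theta <- rep(0, d)
    cur <- lp_fun(theta)
  }
  log_s <- log(2.38 / sqrt(d))
  L <- diag(d)
  mu <- theta
  Sxx <- matrix(0, d, d)
  n_acc <- 0L
  keep <- iterations - warmup
  out <- matrix(NA_real_, keep, d)
  lp_out <- numeric(keep)
  for (it in seq_len(iterations)) {
    prop <- theta + exp(log_s) * as.numeric(stats::rnorm(d) %*% L)
    lpp <- lp_fun(prop)
    a <- if (is.finite(lpp)) min(1, exp(lpp - cur)) else 0
    if (stats::runif(1) < a) {
      theta <- prop
      cur <- lpp
      if (it > warmup) n_acc <- n_acc + 1L
    }
    if (it <= warmup) {
      log_s <- log_s + (a - 0.234) / max(10, it)^0.6
      dl <- theta - mu
      mu <- mu + dl / (it + 1)
      Sxx <- Sxx + tcrossprod(dl, theta - mu)
      if (it >= 100 && it %% 50 == 0) {
        C <- Sxx / it + diag(1e-6, d)
        ch <- tryCatch(chol(C), error = function(e) NULL)
        if (!is.null(ch)) L <- ch
      }
    } else {
      out[it - warmup, ] <- theta
      lp_out[it - warmup] <- cur
    }
  }
  list(draws = out, lp = lp_out, accept = n_acc / keep)
}

#' @export
print.mvb_draws <- function(x, ...) {
  d <- dim(x)
  cat("Posterior draws: ", d[1], " chains x ", d[2], " iterations x ", d[3],
      " parameters (warmup ", attr(x, "warmup"), ", seed ", attr(x, "seed"),
      ")\n", sep = "")
  cat("  acceptance:", paste(sprintf("%.2f", attr(x, "accept")), collapse = ", "), "\n")
  invisible(x)
}

#' Split-chain potential scale reduction factor
#'
#' The Brooks-Gelman-Rubin diagnostic with each chain split in half, so
#' within-chain trends also inflate the statistic. Values close to 1
#' indicate convergence; 1.1 is the conventional flag threshold here.
#'
#' @param draws an `mvb_draws` array (or `[chain, iteration, parameter]`
#'   array) with at least 2 chains and 4 post-warmup iterations.
#' @return named numeric vector of Rhat values, one per parameter.
#' @export
rhat <- function(draws) {
  x <- unclass(draws)
  stopifnot(length(dim(x)) == 3, dim(x)[1] >= 2, dim(x)[2] >= 4)
  n_half <- floor(dim(x)[2] / 2)
  out <- numeric(dim(x)[3])
  names(out) <- dimnames(x)[[3]]
  for (p in seq_len(dim(x)[3])) {
    halves <- list()
    for (ch in seq_len(dim(x)[1])) {
      halves[[length(halves) + 1]] <- x[ch, seq_len(n_half), p]
      halves[[length(halves) + 1]] <- x[ch, n_half + seq_len(n_half), p]
    }
    m <- length(halves)
    n <- n_half
    means <- vapply(halves, mean, 0)
    vars <- vapply(halves, stats::var, 0)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W == 0) {
      warning("zero within-chain variance for parameter ",
              names(out)[p] %||% p, "; Rhat set to 1")
      out[p] <- 1
    } else {
      var_plus <- (n - 1) / n * W + B / n
      out[p] <- sqrt(var_plus / W)
    }
  }
  out
}

#' Watanabe-Akaike information criterion
#'
#' Fully Bayesian predictive criterion from the per-site pointwise
#' log-likelihood over posterior draws: `lppd = sum_s log mean_d
#' exp(ll[d, s])`, effective parameters `p_waic = sum_s var_d(ll[d, s])`
#' (the variance form), and `WAIC = -2 (lppd - p_waic)`. Lower is better.
#'
#' @param pointwise matrix `[draws, sites]` of log-likelihood values.
#' @return list with elements `waic`, `p_waic`, `lppd`.
#' @export
waic <- function(pointwise) {
  pointwise <- as.matrix(pointwise)
  stopifnot(all(is.finite(pointwise)))
  nd <- nrow(pointwise)
  lppd_s <- apply(pointwise, 2, log_sum_exp) - log(nd)
  p_s <- apply(pointwise, 2, stats::var)
  if (nd == 1) p_s <- rep(0, ncol(pointwise))
  lppd <- sum(lppd_s)
  p_waic <- sum(p_s)
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd)
}

#' WAIC model weights
#'
#' Relative likelihood weights `exp(-0.5 * dWAIC_i)` normalised over the
#' candidate set, with differences taken to the minimum WAIC for numerical
#' stability; invariant to adding a constant to every WAIC.
#'
#' @param waics numeric vector of WAIC values (at least one model).
#' @return numeric weights summing to 1.
#' @export
waic_weights <- function(waics) {
  stopifnot(length(waics) >= 1, all(is.finite(waics)))
  rel <- exp(-0.5 * (waics - min(waics)))
  rel / sum(rel)
}
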