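#' Fit a multispecies occurrence model to a detection history
#'
#' The central fitting function. Joint species occurrence follows a
#' multivariate Bernoulli distribution whose first-order and pairwise
#' natural parameters are linear in site covariates; per-occasion intensity
#' of use is Bernoulli on the logit scale with optional shifts keyed to the
#' latent presence of other species. All coefficients get standard logistic
#' priors and the posterior is explored by adaptive MCMC
#' (see [sample_posterior()]). Continuous covariates are standardised to
#' mean 0, sd 1 before fitting (scalers are stored on the fit).
#'
#' @inheritParams sample_posterior
#' @param compute_waic evaluate the pointwise log-likelihood for every draw
#'   and attach WAIC (needed for model ranking).
#' @param rhat_threshold convergence flag threshold on the maximum
#'   split-chain Rhat (default 1.1).
#' @return an object of class `mvb_fit` with components `spec`, `draws`,
#'   `rhat`, `waic`, `pointwise` (draws x sites log-likelihood matrix when
#'   `compute_waic`), `converged`, `sites`, `scaling`; supports `print`,
#'   `summary`, `coef`, `logLik` and `predict`.
#' @examples
#' \donttest{
#' truth <- example_truth(species = c("grizzly", "black"))
#' sim <- simulate_dataset(truth, n_sites = 60, seed = 1)
#' fit <- mvb_occu(truth$spec, sim$history, sim$deployments,
#'                 iterations = 400, warmup = 200, seed = 1)
#' summary(fit)
#' }
#' @export
mvb_occu <- function(spec, history, sitecovs, chains = 3, iterations = 2000,
                     warmup = 1000, seed, standardize = TRUE,
                     compute_waic = TRUE, rhat_threshold = 1.1) {
  if (missing(seed)) stop("'seed' is required")
  ctx <- build_context(spec, history, sitecovs, standardize)
  if (nrow(ctx$n1) == 0) stop("no sites remain in the detection history")
  draws <- sample_posterior(spec, history, sitecovs, chains = chains,
                            iterations = iterations, warmup = warmup,
                            seed = seed, standardize = standardize)
  rh <- rhat(draws)
  converged <- max(rh) <= rhat_threshold
  if (!converged) {
    warning("convergence flag: max Rhat = ", round(max(rh), 3), " > ",
            rhat_threshold, " (", names(which.max(rh)), ")")
  }
  pw <- NULL
  wa <- NULL
  if (compute_waic) {
    pw <- pointwise_matrix(ctx, draws)
    wa <- waic(pw)
  }
  structure(list(spec = spec, draws = draws, rhat = rh, waic = wa,
                 pointwise = pw, converged = converged,
                 rhat_threshold = rhat_threshold, sites = ctx$sites,
                 scaling = ctx$scaling, n_sites = nrow(ctx$n1),
                 seed = attr(draws, "seed"),
                 sampler = list(chains = chains, iterations = iterations,
                                warmup = warmup)),
            class = "mvb_fit")
}

# [draws, sites] log-likelihood matrix from a prebuilt context
pointwise_matrix <- function(ctx, draws) {
  x <- unclass(draws)
  nd <- dim(x)[1] * dim(x)[2]
  th <- matrix(aperm(x, c(2, 1, 3)), nd, dim(x)[3])
  out <- matrix(NA_real_, nd, nrow(ctx$n1))
  for (r in seq_len(nd)) {
    par <- unpack_params(ctx$designs, th[r, ])
    out[r, ] <- ll_sites_internal(par, ctx$pair_idx, ctx$n1, ctx$n0,
                                  ctx$spec$species)
  }
  colnames(out) <- ctx$sites
  out
}

flat_draws <- function(fit) {
  x <- unclass(fit$draws)
  matrix(aperm(x, c(2, 1, 3)), dim(x)[1] * dim(x)[2], dim(x)[3],
         dimnames = list(NULL, dimnames(x)[[3]]))
}

#' @export
print.mvb_fit <- function(x, ...) {
  cat("Multispecies occurrence model fit:", x$spec$label, "\n")
  cat("  sites: ", x$n_sites, "; sampler: ", x$sampler$chains, " chains x ",
      x$sampler$iterations, " iterations (", x$sampler$warmup,
      " warmup), seed ", x$seed, "\n", sep = "")
  cat("  max Rhat: ", round(max(x$rhat), 3),
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  if (!is.null(x$waic)) {
    cat("  WAIC: ", round(x$waic$waic, 1), " (p_waic ",
        round(x$waic$p_waic, 1), ")\n", sep = "")
  }
  invisible(x)
}

#' Posterior summary table of a fitted model
#'
#' One row per coefficient (logit scale): posterior mean, sd, central 95%
#' credible interval and split-chain Rhat.
#'
#' @param object an `mvb_fit`.
#' @param prob credible interval mass (default 0.95).
#' @param ... unused.
#' @return data frame of class `summary.mvb_fit`.
#' @export
summary.mvb_fit <- function(object, prob = 0.95, ...) {
  th <- flat_draws(object)
  a <- (1 - prob) / 2
  out <- data.frame(
    parameter = colnames(th),
    mean = colMeans(th),
    sd = apply(th, 2, stats::sd),
    lower = apply(th, 2, stats::quantile, probs = a),
    upper = apply(th, 2, stats::quantile, probs = 1 - a),
    rhat = object$rhat[colnames(th)],
    row.names = NULL)
  attr(out, "label") <- object$spec$label
  attr(out, "prob") <- prob
  class(out) <- c("summary.mvb_fit", "data.frame")
  out
}

#' @export
print.summary.mvb_fit <- function(x, digits = 3, ...) {
  cat("Posterior summary (logit scale), model:", attr(x, "label"), "\n")
  df <- x
  class(df) <- "data.frame"
  df[-1] <- lapply(df[-1], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mvb_fit <- function(object, ...) {
  colMeans(flat_draws(object))
}

#' @export
logLik.mvb_fit <- function(object, ...) {
  if (is.null(object$waic)) stop("fit was run with compute_waic = FALSE")
  structure(object$waic$lppd, df = object$waic$p_waic, class = "logLik")
}

#' Posterior-mean occurrence and use predictions
#'
#' Evaluates the fitted model at the posterior mean coefficients for new (or
#' the original) site covariates. Continuous covariates are transformed with
#' the scalers stored at fitting time.
#'
#' @param object an `mvb_fit`.
#' @param newdata data frame of site covariates; required.
#' @param type `"psi"` for the full joint state probability matrix
#'   (sites x 2^S), `"marginal"` for per-species marginal occurrence,
#'   `"conditional"` for `P(z_species = 1 | z_given = z)`, or `"p"` for
#'   per-species intensity of use given the other-species latent state `z`.
#' @param species,given species names for `type = "conditional"`.
#' @param z latent-state value of `given` (`type = "conditional"`), or a
#'   named 0/1 vector of conditioning-species states (`type = "p"`,
#'   default all absent).
#' @param ... unused.
#' @return matrix or vector of probabilities, one row/element per site.
#' @export
predict.mvb_fit <- function(object, newdata, type = c("psi", "marginal",
                            "conditional", "p"), species = NULL, given = NULL,
                            z = 1, ...) {
  type <- match.arg(type)
  spec <- object$spec
  newdata <- as.data.frame(newdata)
  for (nm in intersect(names(object$scaling$center), names(newdata))) {
    newdata[[nm]] <- (newdata[[nm]] - object$scaling$center[nm]) /
      object$scaling$scale[nm]
  }
  designs <- build_designs(spec, newdata)
  par <- unpack_params(designs, coef(object))
  S <- length(spec$species)
  Z <- state_space(S)
  pidx <- pair_index(spec)
  psi <- t(vapply(seq_len(nrow(newdata)), function(s) {
    f2 <- matrix(0, S, S)
    if (nrow(pidx)) for (q in seq_len(nrow(pidx))) {
      f2[pidx[q, 1], pidx[q, 2]] <- par$G[s, q]
    }
    state_probs(par$F[s, ], f2)
  }, numeric(2^S)))
  rownames(psi) <- rownames(newdata)
  if (type == "psi") return(psi)
  if (type == "marginal") {
    out <- matrix(NA_real_, nrow(newdata), S,
                  dimnames = list(rownames(newdata), spec$species))
    for (i in seq_len(S)) out[, i] <- psi %*% (Z[, i] == 1)
    return(out)
  }
  if (type == "conditional") {
    i <- match(species, spec$species)
    j <- match(given, spec$species)
    if (is.na(i) || is.na(j)) stop("'species' and 'given' must name species in the model")
    return(apply(psi, 1, conditional_prob, i = i, j = j, z_j = z))
  }
  # type == "p": intensity of use given a named latent state of the others
  zvec <- stats::setNames(rep(0, S), spec$species)
  if (!is.null(names(z))) zvec[names(z)] <- z
  out <- matrix(NA_real_, nrow(newdata), S,
                dimnames = list(rownames(newdata), spec$species))
  for (i in seq_len(S)) {
    sp <- spec$species[i]
    eta <- par$Eta[, i]
    m <- par$M[[sp]]
    if (length(m)) eta <- eta + sum(m * zvec[names(m)])
    out[, i] <- stats::plogis(eta)
  }
  out
}
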