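#' Enumerate the joint presence-absence state space
#'
#' For `S` species the latent occurrence state is a binary vector
#' `z = (z_1, ..., z_S)`. States are enumerated in a fixed binary order:
#' species `i` is bit `i`, so state index `k` (1-based) encodes
#' `k - 1 = sum(z_i * 2^(i-1))`. State 1 is therefore all-absent and the
#' ordering for two species is `00, 10, 01, 11` (first character = species 1).
#'
#' @param S number of species (>= 1).
#' @return integer matrix with `2^S` rows and `S` columns of 0/1.
#' @examples
#' state_space(2)
#' @export
state_space <- function(S) {
  stopifnot(is.numeric(S), length(S) == 1, S >= 1)
  S <- as.integer(S)
  K <- 2L^S
  Z <- matrix(0L, K, S)
  for (i in seq_len(S)) {
    Z[, i] <- bitwAnd(seq_len(K) - 1L, bitwShiftL(1L, i - 1L)) > 0L
  }
  storage.mode(Z) <- "integer"
  rownames(Z) <- apply(Z, 1, paste, collapse = "")
  Z
}

#' Joint occurrence probabilities from natural parameters
#'
#' The multivariate Bernoulli occurrence model places log-linear natural
#' parameters on the joint presence-absence distribution: first-order terms
#' `f_i` (one per species) and pairwise terms `f_ij` (log odds-ratios of
#' co-occurrence). The probability of state `z` is proportional to
#' `exp(sum_i z_i f_i + sum_{i<j} z_i z_j f_ij)`; third- and higher-order
#' terms are fixed at zero. Normalisation uses log-sum-exp for stability.
#'
#' With all parameters zero the distribution is uniform over states; with
#' all `f_ij = 0` species occur independently with marginal `plogis(f_i)`.
#'
#' @param f numeric vector of first-order natural parameters, length `S`.
#' @param f2 optional pairwise terms: an `S x S` matrix (upper triangle used,
#'   treated as symmetric) or `NULL` for independence.
#' @return numeric probability vector of length `2^S`, named by state pattern
#'   (see [state_space()]), summing to 1.
#' @examples
#' state_probs(c(0, 0))                       # uniform over 4 states
#' state_probs(c(0, 0), matrix(c(0, -1, -1, 0), 2))  # co-occurrence avoided
#' @export
state_probs <- function(f, f2 = NULL) {
  if (!all(is.finite(f))) stop("non-finite natural parameters 'f'")
  S <- length(f)
  Z <- state_space(S)
  lp <- as.numeric(Z %*% f)
  if (!is.null(f2)) {
    f2 <- as.matrix(f2)
    stopifnot(nrow(f2) == S, ncol(f2) == S)
    if (!all(is.finite(f2[upper.tri(f2)]))) stop("non-finite pairwise term in 'f2'")
    for (i in seq_len(S - 1)) {
      for (j in seq((i + 1), S)) {
        lp <- lp + Z[, i] * Z[, j] * f2[i, j]
      }
    }
  }
  lp <- lp - log_sum_exp(lp)
  psi <- exp(lp)
  names(psi) <- rownames(Z)
  psi
}

#' Marginal occurrence probability of one species
#'
#' Sums the joint state probabilities over all states in which species `i`
#' is present, e.g. `P(z1 = 1) = psi_11 + psi_10` for two species.
#'
#' @param psi probability vector over `2^S` joint states (see [state_probs()]).
#' @param i species index (bit position in the state encoding).
#' @return a single probability.
#' @export
marginal_prob <- function(psi, i) {
  Z <- psi_states(psi)
  stopifnot(i >= 1, i <= ncol(Z))
  sum(psi[Z[, i] == 1L])
}

#' Conditional occurrence probability given another species' latent state
#'
#' `conditional_prob(psi, i, j, 1)` is `P(z_i = 1 | z_j = 1)`, the occurrence
#' probability of species `i` at sites where species `j` is (latently)
#' present; e.g. for two species `P(z1 = 1 | z2 = 1) = psi_11 / (psi_11 +
#' psi_01)`. When all pairwise natural parameters are zero this reduces to
#' the marginal probability.
#'
#' @inheritParams marginal_prob
#' @param j conditioning species index.
#' @param z_j conditioning state, 0 or 1.
#' @return a single probability.
#' @export
conditional_prob <- function(psi, i, j, z_j = 1) {
  Z <- psi_states(psi)
  stopifnot(i >= 1, i <= ncol(Z), j >= 1, j <= ncol(Z), z_j %in% c(0, 1))
  denom <- sum(psi[Z[, j] == z_j])
  if (denom <= 0) {
    stop("conditioning event z_", j, " = ", z_j, " has probability zero")
  }
  sum(psi[Z[, i] == 1L & Z[, j] == z_j]) / denom
}

#' Per-occasion intensity of use on the probability scale
#'
#' For camera traps on trails the classical "detection probability" is better
#' read as intensity of use: how heavily an occupied site's trail is used per
#' occasion. It is modelled on the logit scale as an intercept plus covariate
#' terms plus additive modifiers that switch on when a conditioning species
#' is latently present.
#'
#' @param coef numeric coefficient vector over detection covariates; the
#'   first element is the intercept when `x` is left `NULL`.
#' @param x covariate values matching `coef` (defaults to intercept-only:
#'   `c(1, 0, 0, ...)`).
#' @param modifiers named numeric vector of logit shifts, one per
#'   conditioning species.
#' @param z named 0/1 vector giving the latent presence of the conditioning
#'   species named in `modifiers`.
#' @return probability of use per occasion.
#' @examples
#' # black bear use when grizzly bears are present vs absent
#' intensity_of_use(-6.81, modifiers = c(grizzly = 4.47), z = c(grizzly = 1))
#' intensity_of_use(-6.81, modifiers = c(grizzly = 4.47), z = c(grizzly = 0))
#' @export
intensity_of_use <- function(coef, x = NULL, modifiers = NULL, z = NULL) {
  stopifnot(all(is.finite(coef)))
  if (is.null(x)) x <- c(1, rep(0, length(coef) - 1))
  stopifnot(length(x) == length(coef))
  eta <- sum(coef * x)
  if (!is.null(modifiers) && length(modifiers)) {
    if (is.null(z)) stop("'z' must give latent presence for each named modifier")
    miss <- setdiff(names(modifiers), names(z))
    if (length(miss)) stop("missing latent state for modifier(s): ",
                           paste(miss, collapse = ", "))
    eta <- eta + sum(modifiers * z[names(modifiers)])
  }
  stats::plogis(eta)
}

#' Marginal log-likelihood of one site's detection history
#'
#' The detection history of a site is a species-by-occasion matrix of 0/1
#' with `NA` for occasions the camera did not survey. The latent joint state
#' `z` is marginalised: the likelihood is `sum_z psi_z * prod_i prod_t
#' Bernoulli(y[i, t] | z_i * p[i](z))`, where a species with `z_i = 0`
#' contributes only if it was never detected, missing occasions contribute a
#' factor of 1, and `p[i](z)` may depend on the state through modifiers.
#' Computation is in log space with log-sum-exp over states.
#'
#' @param y matrix `[species, occasion]` of 0/1/NA detections.
#' @param psi joint state probability vector of length `2^S`.
#' @param p per-occasion use probabilities: either a numeric vector of length
#'   `S` (state-independent) or a `2^S x S` matrix giving each species' use
#'   probability under each joint state.
#' @return the site log-likelihood (a scalar).
#' @export
site_loglik <- function(y, psi, p) {
  y <- as.matrix(y)
  S <- nrow(y)
  K <- 2L^S
  stopifnot(length(psi) == K)
  if (is.null(dim(p))) {
    stopifnot(length(p) == S)
    p <- matrix(p, K, S, byrow = TRUE)
  }
  stopifnot(nrow(p) == K, ncol(p) == S)
  Z <- state_space(S)
  n1 <- rowSums(y == 1, na.rm = TRUE)
  n0 <- rowSums(y == 0, na.rm = TRUE)
  lp <- log(psi)
  for (k in seq_len(K)) {
    for (i in seq_len(S)) {
      if (Z[k, i] == 1L) {
        lp[k] <- lp[k] + bern_terms(n1[i], n0[i], p[k, i])
      } else if (n1[i] > 0) {
        lp[k] <- -Inf
      }
    }
  }
  log_sum_exp(lp)
}

# n1 * log(p) + n0 * log(1 - p) with 0 * log(0) treated as 0
bern_terms <- function(n1, n0, p) {
  out <- 0
  if (n1 > 0) out <- out + n1 * log(p)
  if (n0 > 0) out <- out + n0 * log1p(-p)
  out
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp for a matrix with few columns
row_log_sum_exp <- function(X) {
  m <- X[, 1]
  K <- ncol(X)
  if (K > 1) for (k in 2:K) m <- pmax(m, X[, k])
  ok <- is.finite(m)
  out <- m
  if (any(ok)) {
    acc <- numeric(sum(ok))
    for (k in seq_len(K)) acc <- acc + exp(X[ok, k] - m[ok])
    out[ok] <- m[ok] + log(acc)
  }
  out
}

psi_states <- function(psi) {
  S <- round(log2(length(psi)))
  if (2^S != length(psi)) stop("'psi' length must be a power of two")
  state_space(S)
}
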