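#' Simulate camera deployments and site covariates
#'
#' Generates a deployment table with the covariate structure of a
#' mountain-and-foothills trail-camera study: log distances to the nearest
#' road and stream (logs of lognormal positive distances in metres),
#' elevation from a bimodal mountain/foothill normal mixture, NDVI from a
#' beta distribution on `[0, 1]`, and a protected-area indicator. Cameras
#' are active over a common summer window, with a configurable fraction
#' failing early.
#'
#' @param n_sites number of camera sites (>= 1).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers can embed this in a larger seeded simulation).
#' @param start,end study window dates.
#' @param road_meanlog,road_sdlog lognormal parameters of distance-to-road (m).
#' @param stream_meanlog,stream_sdlog lognormal parameters of
#'   distance-to-stream (m).
#' @param elev_means,elev_sds,elev_mix two-component elevation mixture (m);
#'   `elev_mix` is the weight of the first (foothill) component.
#' @param ndvi_shape beta shape parameters for NDVI.
#' @param p_protected probability a site lies in a protected area.
#' @param dropout probability a camera fails before the window ends (its end
#'   date is then uniform over the window).
#' @return deployment data frame: `site_id`, `start`, `end`, `lndroad`,
#'   `lndstream`, `elevation`, `ndvi`, `protected`.
#' @export
simulate_covariates <- function(n_sites, seed = NULL,
                                start = "2014-06-15", end = "2014-08-25",
                                road_meanlog = log(800), road_sdlog = 0.9,
                                stream_meanlog = log(300), stream_sdlog = 0.8,
                                elev_means = c(1350, 1900),
                                elev_sds = c(120, 180), elev_mix = 0.5,
                                ndvi_shape = c(12, 4), p_protected = 0.5,
                                dropout = 0.1) {
  stopifnot(n_sites >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  start <- as.Date(start)
  end <- as.Date(end)
  droad <- stats::rlnorm(n_sites, road_meanlog, road_sdlog)
  dstream <- stats::rlnorm(n_sites, stream_meanlog, stream_sdlog)
  comp <- stats::rbinom(n_sites, 1, 1 - elev_mix) + 1
  elev <- stats::rnorm(n_sites, elev_means[comp], elev_sds[comp])
  ndvi <- stats::rbeta(n_sites, ndvi_shape[1], ndvi_shape[2])
  protected <- stats::rbinom(n_sites, 1, p_protected)
  n_days <- as.numeric(end - start)
  fails <- stats::runif(n_sites) < dropout
  end_i <- rep(end, n_sites)
  end_i[fails] <- start + floor(stats::runif(sum(fails), 7, n_days))
  data.frame(site_id = sprintf("S%03d", seq_len(n_sites)),
             start = rep(start, n_sites), end = end_i,
             lndroad = log(droad), lndstream = log(dstream),
             elevation = elev, ndvi = ndvi, protected = protected)
}

#' Bundle a model specification with true parameter values
#'
#' A truth object carries everything needed to regenerate a dataset
#' bit-identically given a seed: the model structure, the named coefficient
#' vector (in the layout [build_designs()] reports), and a diel activity
#' density (von Mises mixture) per species for event-level expansion.
#'
#' @param spec an [mvb_spec()].
#' @param coef named numeric coefficient vector.
#' @param activity named list per species: `list(mu = , kappa = , w = )`
#'   von Mises mixture components (angles in radians).
#' @return object of class `mvb_truth`.
#' @export
mvb_truth <- function(spec, coef, activity = NULL) {
  stopifnot(inherits(spec, "mvb_spec"), !is.null(names(coef)))
  if (!is.null(activity)) {
    stopifnot(all(names(activity) %in% spec$species))
  }
  structure(list(spec = spec, coef = coef, activity = activity),
            class = "mvb_truth")
}

#' @export
print.mvb_truth <- function(x, ...) {
  cat("Synthetic truth for model:", x$spec$label, "\n")
  print(round(x$coef, 3))
  invisible(x)
}

#' Study-like synthetic truth
#'
#' A shipping preset emulating a two-bear, two-recreation trail-camera
#' system: habitat covariates on bear occurrence, a protected-area covariate
#' on recreation, a negative grizzly-black pairwise occurrence term, and
#' intensity-of-use modifiers (recreation on both bears; grizzly presence on
#' black bear use). Bear coefficients are set to published posterior means
#' for such a system for realism; recreation coefficients and diel activity
#' mixtures are illustrative. The preset is a plausible generating model for
#' testing and power analysis, not ground truth for any real landscape.
#'
#' @param species subset of
#'   `c("grizzly", "black", "motorised", "non-motorised")` to keep (terms
#'   referencing dropped species are dropped with them).
#' @return an [mvb_truth()].
#' @export
example_truth <- function(species = c("grizzly", "black", "motorised",
                                      "non-motorised")) {
  all_sp <- c("grizzly", "black", "motorised", "non-motorised")
  stopifnot(all(species %in% all_sp), length(species) >= 1)
  species <- all_sp[all_sp %in% species]
  habitat <- ~ lndroad + lndstream + elevation + ndvi
  occurrence <- list(grizzly = habitat, black = habitat,
                     motorised = ~ protected, `non-motorised` = ~ protected)
  detection <- list(grizzly = ~1, black = ~1,
                    motorised = ~ protected, `non-motorised` = ~ protected)
  pairs <- if (all(c("grizzly", "black") %in% species)) {
    list(c("grizzly", "black"))
  }
  modifiers <- list(
    grizzly = intersect(c("motorised", "non-motorised"), species),
    black = intersect(c("grizzly", "motorised", "non-motorised"), species))
  modifiers <- Filter(length, modifiers[intersect(names(modifiers), species)])
  spec <- mvb_spec(species, occurrence = occurrence[species], pairs = pairs,
                   detection = detection[species], modifiers = modifiers,
                   label = paste0("study-like (", length(species), " species)"))
  coef <- c(
    psi_grizzly_Intercept = 0.61, psi_grizzly_lndroad = 0.29,
    psi_grizzly_lndstream = -0.14, psi_grizzly_elevation = -0.27,
    psi_grizzly_ndvi = 0.11,
    psi_black_Intercept = 2.40, psi_black_lndroad = -0.14,
    psi_black_lndstream = 0.23, psi_black_elevation = -1.76,
    psi_black_ndvi = -0.12,
    psi_motorised_Intercept = -0.4, psi_motorised_protected = -2.5,
    `psi_non-motorised_Intercept` = 0.0, `psi_non-motorised_protected` = 1.0,
    f_grizzly.black_Intercept = -2.63,
    p_grizzly_Intercept = -2.09,
    p_black_Intercept = -6.81,
    p_motorised_Intercept = 0.5, p_motorised_protected = -1.5,
    `p_non-motorised_Intercept` = 0.9, `p_non-motorised_protected` = 0.5,
    p_grizzly_z.motorised = -0.67, `p_grizzly_z.non-motorised` = 0.49,
    p_black_z.grizzly = 4.47, p_black_z.motorised = -0.65,
    `p_black_z.non-motorised` = 0.82)
  h <- function(hh) hh / 24 * 2 * pi
  activity <- list(
    grizzly = list(mu = h(c(6, 20)), kappa = c(3, 3), w = c(0.5, 0.5)),
    black = list(mu = h(c(8, 17)), kappa = c(2, 2), w = c(0.5, 0.5)),
    motorised = list(mu = h(13), kappa = 2.5, w = 1),
    `non-motorised` = list(mu = h(12), kappa = 3, w = 1))
  keep <- keep_coef_names(spec)
  mvb_truth(spec, coef[keep], activity[species])
}

# names a spec's coefficient layout without data (intercept/known covariates)
keep_coef_names <- function(spec) {
  fake <- data.frame(lndroad = 0, lndstream = 0, elevation = 0, ndvi = 0,
                     protected = 0)
  build_designs(spec, fake)$par_names
}

#' Simulate a multispecies detection dataset from a truth object
#'
#' The generative direction of the occurrence model: for each site, joint
#' latent presence `z` is drawn from the multivariate Bernoulli state
#' probabilities implied by the (standardised) covariates; then each
#' species' occasion-level detections are Bernoulli with its intensity of
#' use given `z` (zero when absent). Occasions a camera did not survey are
#' `NA`. Optionally detections are expanded to timestamped events whose
#' clock times follow each species' diel activity mixture, linking the
#' occupancy and activity analyses.
#'
#' @param truth an [mvb_truth()].
#' @param n_sites number of sites (ignored when `deployments` is given).
#' @param n_occasions maximum number of sampling occasions.
#' @param occasion_days days per occasion.
#' @param seed optional integer seed (the whole dataset is reproducible).
#' @param deployments optional deployment table; default
#'   [simulate_covariates()] under the same RNG stream.
#' @param events also generate a timestamped event table (requires
#'   `truth$activity`).
#' @param mean_extra_events mean number of additional events per detected
#'   occasion (events per detection = 1 + Poisson).
#' @return list of class `mvb_sim`: `history` (a `detection_history`),
#'   `deployments`, `z` (site x species latent truth), `state` (state
#'   index per site), `events` (data frame or `NULL`), `truth`, `seed`.
#' @export
simulate_dataset <- function(truth, n_sites = 182, n_occasions = 18,
                             occasion_days = 4, seed = NULL,
                             deployments = NULL, events = FALSE,
                             mean_extra_events = 0.5) {
  stopifnot(inherits(truth, "mvb_truth"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(deployments)) deployments <- simulate_covariates(n_sites)
  n <- nrow(deployments)
  spec <- truth$spec
  S <- length(spec$species)
  sc <- standardize_covs(deployments[setdiff(names(deployments),
                                             c("site_id", "start", "end"))])
  designs <- build_designs(spec, sc$data)
  if (!identical(designs$par_names, names(truth$coef))) {
    stop("truth coefficients do not match the spec layout; expected: ",
         paste(designs$par_names, collapse = ", "))
  }
  par <- unpack_params(designs, as.numeric(truth$coef))
  Z <- state_space(S)
  K <- 2L^S
  pidx <- pair_index(spec)
  LP <- matrix(0, n, K)
  for (k in seq_len(K)) {
    lp <- numeric(n)
    for (i in seq_len(S)) if (Z[k, i] == 1L) lp <- lp + par$F[, i]
    if (nrow(pidx)) for (q in seq_len(nrow(pidx))) {
      if (Z[k, pidx[q, 1]] == 1L && Z[k, pidx[q, 2]] == 1L) lp <- lp + par$G[, q]
    }
    LP[, k] <- lp
  }
  PSI <- exp(LP - row_log_sum_exp(LP))
  state <- vapply(seq_len(n), function(s)
    sample.int(K, 1, prob = PSI[s, ]), 0L)
  z <- Z[state, , drop = FALSE]
  rownames(z) <- deployments$site_id
  # per-site, per-species use probability given the drawn state
  P <- matrix(0, n, S)
  for (i in seq_len(S)) {
    eta <- par$Eta[, i]
    m <- par$M[[spec$species[i]]]
    if (length(m)) {
      zc <- z[, match(names(m), spec$species), drop = FALSE]
      eta <- eta + as.numeric(zc %*% m)
    }
    P[, i] <- stats::plogis(eta)
  }
  start <- min(deployments$start)
  y <- array(NA_integer_, c(n, S, n_occasions),
             dimnames = list(deployments$site_id, spec$species,
                             paste0("occ", seq_len(n_occasions))))
  w_start <- start + (seq_len(n_occasions) - 1) * occasion_days
  w_end <- w_start + occasion_days - 1
  for (s in seq_len(n)) {
    surveyed <- w_end >= deployments$start[s] & w_start <= deployments$end[s]
    for (i in seq_len(S)) {
      if (z[s, i] == 1L) {
        y[s, i, surveyed] <- stats::rbinom(sum(surveyed), 1, P[s, i])
      } else {
        y[s, i, surveyed] <- 0L
      }
    }
  }
  history <- structure(y, occasion_days = occasion_days, start = start,
                       anchor = "study", class = "detection_history")
  ev <- NULL
  if (events) {
    if (is.null(truth$activity)) stop("truth has no activity densities")
    ev <- expand_events(y, deployments, truth, w_start, w_end,
                        mean_extra_events)
  }
  structure(list(history = history, deployments = deployments, z = z,
                 state = state, events = ev, truth = truth, seed = seed),
            class = "mvb_sim")
}

expand_events <- function(y, deployments, truth, w_start, w_end,
                          mean_extra_events) {
  spec <- truth$spec
  rows <- list()
  hits <- which(y == 1, arr.ind = TRUE)
  if (nrow(hits)) hits <- hits[order(hits[, 1], hits[, 2], hits[, 3]), ,
                               drop = FALSE]
  for (r in seq_len(nrow(hits))) {
    s <- hits[r, 1]; i <- hits[r, 2]; t <- hits[r, 3]
    sp <- spec$species[i]
    n_ev <- 1L + stats::rpois(1, mean_extra_events)
    d0 <- max(w_start[t], deployments$start[s])
    d1 <- min(w_end[t], deployments$end[s])
    days <- d0 + sample.int(as.numeric(d1 - d0) + 1, n_ev, replace = TRUE) - 1
    ang <- simulate_times(n_ev, truth$activity[[sp]])
    secs <- round(ang / (2 * pi) * 86400)
    rows[[length(rows) + 1]] <- data.frame(
      site_id = deployments$site_id[s], category = sp,
      timestamp = as.POSIXct(days, tz = "UTC") + secs)
  }
  if (!length(rows)) {
    return(data.frame(site_id = character(0), category = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC")))
  }
  out <- do.call(rbind, rows)
  out[order(out$site_id, out$category, out$timestamp), , drop = FALSE]
}

#' Draw event times from a von Mises mixture on the diel circle
#'
#' @param n number of draws (>= 1).
#' @param mixture list with `mu` (radians), `kappa`, `w` (weights, summing
#'   to 1), one entry per component.
#' @param seed optional integer seed.
#' @return angles in `[0, 2 pi)`.
#' @export
simulate_times <- function(n, mixture, seed = NULL) {
  stopifnot(n >= 1, length(mixture$mu) == length(mixture$kappa))
  if (!is.null(seed)) set.seed(as.integer(seed))
  w <- mixture$w %||% rep(1 / length(mixture$mu), length(mixture$mu))
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  out <- numeric(n)
  for (k in unique(comp)) {
    sel <- comp == k
    out[sel] <- rvonmises(sum(sel), mixture$mu[k], mixture$kappa[k])
  }
  out
}
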