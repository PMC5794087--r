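# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorised code paths: plain loops and direct formulas.

# direct enumeration of state probabilities: exp / sum over all 2^S states
oracle_state_probs <- function(f, f2 = NULL) {
  S <- length(f)
  K <- 2^S
  w <- numeric(K)
  for (k in seq_len(K)) {
    z <- as.integer(intToBits(k - 1))[seq_len(S)]
    e <- sum(z * f)
    if (!is.null(f2)) {
      for (i in seq_len(S - 1)) for (j in (i + 1):S) {
        e <- e + z[i] * z[j] * f2[i, j]
      }
    }
    w[k] <- exp(e)
  }
  w / sum(w)
}

# site likelihood by explicit products over states, species and occasions
oracle_site_loglik <- function(y, psi, pmat) {
  S <- nrow(y)
  tot <- 0
  for (k in seq_len(2^S)) {
    z <- as.integer(intToBits(k - 1))[seq_len(S)]
    lk <- psi[k]
    for (i in seq_len(S)) for (t in seq_len(ncol(y))) {
      if (is.na(y[i, t])) next
      pp <- z[i] * pmat[k, i]
      lk <- lk * if (y[i, t] == 1) pp else (1 - pp)
    }
    tot <- tot + unname(lk)
  }
  log(tot)
}

# per-state use probabilities for a 2-species model with a single modifier
# of species 2 keyed to species 1
oracle_pmat_2sp <- function(p_eta, mod21) {
  Z <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  cbind(plogis(p_eta[1]),
        plogis(p_eta[2] + mod21 * Z[, 1]))
}

# event-to-occasion binning by explicit loops over events and windows
oracle_bin_events <- function(events, deployments, occasion_days, categories,
                              start) {
  start <- as.Date(start)
  n_occ <- max(ceiling((as.numeric(deployments$end - start) + 1) / occasion_days))
  y <- array(NA_integer_,
             c(nrow(deployments), length(categories), n_occ),
             dimnames = list(deployments$site_id, categories, NULL))
  for (s in seq_len(nrow(deployments))) {
    for (t in seq_len(n_occ)) {
      w0 <- start + (t - 1) * occasion_days
      w1 <- w0 + occasion_days - 1
      if (w1 < deployments$start[s] || w0 > deployments$end[s]) next
      y[s, , t] <- 0L
      for (r in seq_len(nrow(events))) {
        d <- as.Date(events$timestamp[r], tz = "UTC")
        if (events$site_id[r] == deployments$site_id[s] &&
            d >= w0 && d <= w1 && events$category[r] %in% categories) {
          y[s, match(events$category[r], categories), t] <- 1L
        }
      }
    }
  }
  y
}

# linear scan over a sorted photo stream, one (site, category) at a time
oracle_independent <- function(events, gap_minutes) {
  keep <- logical(nrow(events))
  for (key in unique(paste(events$site_id, events$category))) {
    idx <- which(paste(events$site_id, events$category) == key)
    idx <- idx[order(events$timestamp[idx])]
    last <- -Inf
    for (r in idx) {
      if (as.numeric(events$timestamp[r]) - last >= gap_minutes * 60) {
        keep[r] <- TRUE
        last <- as.numeric(events$timestamp[r])
      }
    }
  }
  events[keep, , drop = FALSE]
}

# numeric overlap of two true von Mises densities on a fine grid
oracle_vm_overlap <- function(mu1, k1, mu2, k2, n_grid = 4096) {
  g <- seq(0, 2 * pi, length.out = n_grid + 1)
  f1 <- exp(k1 * cos(g - mu1)) / (2 * pi * besselI(k1, 0))
  f2 <- exp(k2 * cos(g - mu2)) / (2 * pi * besselI(k2, 0))
  m <- pmin(f1, f2)
  h <- diff(g)
  sum((m[-length(m)] + m[-1]) / 2 * h)
}

# split-chain potential scale reduction, written straight from the formula
oracle_split_rhat <- function(mat) {
  # mat: [chain, iteration]
  n <- floor(ncol(mat) / 2)
  seqs <- list()
  for (ch in seq_len(nrow(mat))) {
    seqs[[length(seqs) + 1]] <- mat[ch, 1:n]
    seqs[[length(seqs) + 1]] <- mat[ch, (n + 1):(2 * n)]
  }
  means <- sapply(seqs, mean)
  W <- mean(sapply(seqs, var))
  B <- n * var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# minimal random event table on a handful of sites
random_events <- function(n, sites, categories, start, days,
                          tz = "UTC") {
  data.frame(
    site_id = sample(sites, n, replace = TRUE),
    category = sample(categories, n, replace = TRUE),
    timestamp = as.POSIXct(as.Date(start), tz = tz) +
      runif(n, 0, days * 86400))
}
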