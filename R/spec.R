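#' Specify a multispecies occurrence model
#'
#' A model specification names the species (camera-trap "species" may include
#' human activity categories), the covariates driving each species'
#' first-order occurrence term, which species pairs carry a pairwise
#' natural parameter (and on which covariates), the covariates of each
#' species' per-occasion intensity of use, and which conditioning species
#' shift a species' use on the logit scale when latently present.
#'
#' @param species character vector of species names; the order fixes the bit
#'   encoding of joint states (see [state_space()]).
#' @param occurrence named list of one-sided formulas over site covariates,
#'   one per species; species not named get `~ 1`.
#' @param pairs list of pairwise terms; each element either a length-2
#'   character vector (intercept-only pair) or a list with elements
#'   `species` (length-2 character) and `formula`.
#' @param detection named list of one-sided formulas for intensity of use;
#'   default `~ 1` per species.
#' @param modifiers named list mapping a species to the character vector of
#'   conditioning species whose latent presence adds a coefficient to its
#'   use logit.
#' @param label optional model label used in rankings.
#' @return an object of class `mvb_spec`.
#' @examples
#' mvb_spec(c("grizzly", "black"),
#'          occurrence = list(grizzly = ~ lndroad + elevation),
#'          pairs = list(c("grizzly", "black")),
#'          modifiers = list(black = "grizzly"))
#' @export
mvb_spec <- function(species, occurrence = NULL, pairs = NULL,
                     detection = NULL, modifiers = NULL, label = NULL) {
  stopifnot(is.character(species), length(species) >= 1,
            !anyDuplicated(species))
  occurrence <- complete_formulas(occurrence, species, "occurrence")
  detection <- complete_formulas(detection, species, "detection")
  pairs <- lapply(pairs, function(pr) {
    if (is.character(pr)) pr <- list(species = pr, formula = ~1)
    stopifnot(length(pr$species) == 2, all(pr$species %in% species),
              pr$species[1] != pr$species[2])
    # canonical order = species order, so f_ij is symmetric by construction
    pr$species <- species[sort(match(pr$species, species))]
    if (is.null(pr$formula)) pr$formula <- ~1
    pr
  })
  keys <- vapply(pairs, function(pr) paste(pr$species, collapse = ":"), "")
  if (anyDuplicated(keys)) stop("duplicate species pair in 'pairs'")
  modifiers <- modifiers %||% list()
  for (sp in names(modifiers)) {
    stopifnot(sp %in% species, all(modifiers[[sp]] %in% species),
              !sp %in% modifiers[[sp]])
  }
  structure(list(species = species, occurrence = occurrence, pairs = pairs,
                 detection = detection, modifiers = modifiers,
                 label = label %||% spec_signature_short(species, pairs, modifiers)),
            class = "mvb_spec")
}

complete_formulas <- function(x, species, what) {
  x <- x %||% list()
  bad <- setdiff(names(x), species)
  if (length(bad)) stop("unknown species in '", what, "': ", paste(bad, collapse = ", "))
  out <- stats::setNames(rep(list(~1), length(species)), species)
  for (sp in names(x)) {
    stopifnot(inherits(x[[sp]], "formula"))
    out[[sp]] <- x[[sp]]
  }
  out
}

spec_signature_short <- function(species, pairs, modifiers) {
  pk <- vapply(pairs, function(pr) paste(pr$species, collapse = "~"), "")
  mk <- unlist(lapply(names(modifiers), function(sp)
    paste0(sp, "|", paste(modifiers[[sp]], collapse = "+"))))
  paste0(length(species), "sp",
         if (length(pk)) paste0(" pairs(", paste(pk, collapse = ","), ")") else "",
         if (length(mk)) paste0(" mods(", paste(mk, collapse = ","), ")") else "")
}

#' @export
print.mvb_spec <- function(x, ...) {
  cat("Multispecies occurrence model spec:", x$label, "\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  for (sp in x$species) {
    cat("  psi[", sp, "] ", deparse(x$occurrence[[sp]]),
        "   p[", sp, "] ", deparse(x$detection[[sp]]), "\n", sep = "")
  }
  for (pr in x$pairs) {
    cat("  f[", paste(pr$species, collapse = ","), "] ",
        deparse(pr$formula), "\n", sep = "")
  }
  for (sp in names(x$modifiers)) {
    cat("  p[", sp, "] += modifier(z ", paste(x$modifiers[[sp]], collapse = ", z "),
        ")\n", sep = "")
  }
  invisible(x)
}

# canonical signature used for deduplication of candidate sets
spec_signature <- function(spec) {
  fml <- function(f) paste(sort(labels(stats::terms(f))), collapse = "+")
  pair_sig <- vapply(spec$pairs, function(pr)
    paste0(paste(pr$species, collapse = ":"), "~", fml(pr$formula)), character(1))
  mod_sig <- vapply(names(spec$modifiers), function(sp)
    paste0(sp, "<-", paste(sort(spec$modifiers[[sp]]), collapse = "+")), character(1))
  paste(
    paste(spec$species, collapse = ","),
    paste(vapply(spec$species, function(sp) fml(spec$occurrence[[sp]]), ""),
          collapse = ";"),
    paste(sort(pair_sig), collapse = ";"),
    paste(vapply(spec$species, function(sp) fml(spec$detection[[sp]]), ""),
          collapse = ";"),
    paste(sort(mod_sig), collapse = ";"),
    sep = " || ")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- design construction and parameter packing -------------------------------

# Builds model matrices for every term of a spec against a site covariate
# table and lays the free coefficients out in one named vector.
build_designs <- function(spec, sitecovs) {
  sitecovs <- as.data.frame(sitecovs)
  occ <- lapply(spec$occurrence, term_matrix, data = sitecovs)
  det <- lapply(spec$detection, term_matrix, data = sitecovs)
  pair <- lapply(spec$pairs, function(pr) term_matrix(pr$formula, sitecovs))
  nm <- c(
    unlist(lapply(spec$species, function(sp)
      paste0("psi_", sp, "_", colnames(occ[[sp]])))),
    unlist(lapply(seq_along(spec$pairs), function(k)
      paste0("f_", paste(spec$pairs[[k]]$species, collapse = "."), "_",
             colnames(pair[[k]])))),
    unlist(lapply(spec$species, function(sp)
      paste0("p_", sp, "_", colnames(det[[sp]])))),
    unlist(lapply(names(spec$modifiers), function(sp)
      paste0("p_", sp, "_z.", spec$modifiers[[sp]])))
  )
  structure(list(spec = spec, occ = occ, det = det, pair = pair,
                 n_sites = nrow(sitecovs), par_names = nm), class = "mvb_designs")
}

term_matrix <- function(formula, data) {
  mm <- stats::model.matrix(formula, data)
  colnames(mm) <- gsub("[()]", "", colnames(mm))
  mm
}

n_params <- function(designs) length(designs$par_names)

# theta -> site-level natural parameters, detection logits and modifier coefs
unpack_params <- function(designs, theta) {
  spec <- designs$spec
  S <- length(spec$species)
  n <- designs$n_sites
  stopifnot(length(theta) == n_params(designs))
  pos <- 0L
  take <- function(k) {
    out <- theta[pos + seq_len(k)]
    pos <<- pos + k
    out
  }
  F <- matrix(0, n, S)
  for (i in seq_len(S)) {
    X <- designs$occ[[spec$species[i]]]
    F[, i] <- X %*% take(ncol(X))
  }
  G <- if (length(spec$pairs)) {
    g <- matrix(0, n, length(spec$pairs))
    for (k in seq_along(spec$pairs)) {
      X <- designs$pair[[k]]
      g[, k] <- X %*% take(ncol(X))
    }
    g
  } else matrix(0, n, 0)
  Eta <- matrix(0, n, S)
  for (i in seq_len(S)) {
    X <- designs$det[[spec$species[i]]]
    Eta[, i] <- X %*% take(ncol(X))
  }
  M <- lapply(spec$species, function(sp) {
    conds <- spec$modifiers[[sp]]
    if (is.null(conds)) return(numeric(0))
    stats::setNames(take(length(conds)), conds)
  })
  names(M) <- spec$species
  list(F = F, G = G, Eta = Eta, M = M)
}

pair_index <- function(spec) {
  t(vapply(spec$pairs, function(pr) match(pr$species, spec$species), integer(2)))
}

# Per-site marginal log-likelihood, vectorised over sites.
# n1, n0: [site, species] counts of detected / surveyed-undetected occasions.
ll_sites_internal <- function(par, pair_idx, n1, n0, species) {
  S <- ncol(n1)
  n <- nrow(n1)
  K <- 2L^S
  Z <- state_space(S)
  LP <- matrix(0, n, K)   # unnormalised log psi
  LD <- matrix(0, n, K)   # detection log-likelihood given state
  for (k in seq_len(K)) {
    z <- Z[k, ]
    lp <- numeric(n)
    for (i in seq_len(S)) if (z[i] == 1L) lp <- lp + par$F[, i]
    if (nrow(pair_idx)) {
      for (q in seq_len(nrow(pair_idx))) {
        if (z[pair_idx[q, 1]] == 1L && z[pair_idx[q, 2]] == 1L) {
          lp <- lp + par$G[, q]
        }
      }
    }
    LP[, k] <- lp
    ld <- numeric(n)
    for (i in seq_len(S)) {
      if (z[i] == 1L) {
        eta <- par$Eta[, i]
        m <- par$M[[species[i]]]
        if (length(m)) {
          on <- z[match(names(m), species)] == 1L
          if (any(on)) eta <- eta + sum(m[on])
        }
        ld <- ld + n1[, i] * stats::plogis(eta, log.p = TRUE) +
          n0[, i] * stats::plogis(-eta, log.p = TRUE)
      } else {
        ld <- ld + ifelse(n1[, i] > 0, -Inf, 0)
      }
    }
    LD[, k] <- ld
  }
  LP <- LP - row_log_sum_exp(LP)
  row_log_sum_exp(LP + LD)
}

detection_counts <- function(history, species) {
  y <- history_array(history)
  have <- dimnames(y)[[2]]
  miss <- setdiff(species, have)
  if (length(miss)) stop("species absent from history: ", paste(miss, collapse = ", "))
  y <- y[, species, , drop = FALSE]
  n1 <- apply(y == 1, c(1, 2), sum, na.rm = TRUE)
  n0 <- apply(y == 0, c(1, 2), sum, na.rm = TRUE)
  list(n1 = matrix(n1, nrow = dim(y)[1]), n0 = matrix(n0, nrow = dim(y)[1]),
       sites = dimnames(y)[[1]])
}

history_array <- function(history) {
  if (inherits(history, "detection_history")) return(unclass(history))
  stopifnot(is.array(history), length(dim(history)) == 3)
  history
}

# Context object: everything site_loglik evaluation needs, built once per fit.
build_context <- function(spec, history, sitecovs, standardize = TRUE) {
  y <- history_array(history)
  sitecovs <- as.data.frame(sitecovs)
  if (!is.null(sitecovs$site_id)) {
    rownames(sitecovs) <- sitecovs$site_id
  }
  sites <- dimnames(y)[[1]]
  if (!is.null(sites) && all(sites %in% rownames(sitecovs))) {
    sitecovs <- sitecovs[sites, , drop = FALSE]
  } else if (nrow(sitecovs) != dim(y)[1]) {
    stop("site covariate table does not match history sites")
  }
  sc <- if (standardize) standardize_covs(sitecovs) else
    list(data = sitecovs, center = NULL, scale = NULL)
  designs <- build_designs(spec, sc$data)
  counts <- detection_counts(y, spec$species)
  list(spec = spec, designs = designs, pair_idx = pair_index(spec),
       n1 = counts$n1, n0 = counts$n0, sites = counts$sites,
       scaling = sc[c("center", "scale")], sitecovs = sc$data)
}

# z-score numeric, non-binary covariate columns; keep scalers for reporting
standardize_covs <- function(sitecovs) {
  center <- scale <- numeric(0)
  out <- sitecovs
  for (nm in names(sitecovs)) {
    v <- sitecovs[[nm]]
    if (!is.numeric(v)) next
    vals <- unique(v[is.finite(v)])
    if (length(vals) <= 2 && all(vals %in% c(0, 1))) next
    mu <- mean(v)
    sd <- stats::sd(v)
    if (!is.finite(sd) || sd == 0) sd <- 1
    out[[nm]] <- (v - mu) / sd
    center[nm] <- mu
    scale[nm] <- sd
  }
  list(data = out, center = center, scale = scale)
}

#' Per-site marginal log-likelihood under a model specification
#'
#' Evaluates the latent-state-marginalised log-likelihood of every site in a
#' detection history at a given coefficient vector. The sum of the returned
#' vector is the model log-likelihood; the per-site decomposition is what
#' WAIC needs.
#'
#' @param spec an [mvb_spec()].
#' @param history a `detection_history` (or `[site, species, occasion]`
#'   array with 0/1/NA entries) containing all species in `spec`.
#' @param sitecovs data frame of site covariates, one row per site (matched
#'   by `site_id` column or rownames when present, otherwise by order).
#' @param params named or plain numeric coefficient vector laid out as the
#'   fit reports it (occurrence blocks, pair blocks, detection blocks,
#'   modifier coefficients).
#' @param standardize standardise continuous covariates before building
#'   design matrices (the default matches fitting).
#' @return numeric vector of per-site log-likelihoods.
#' @export
pointwise_loglik <- function(spec, history, sitecovs, params, standardize = TRUE) {
  ctx <- build_context(spec, history, sitecovs, standardize)
  if (length(params) != n_params(ctx$designs)) {
    stop("parameter vector has length ", length(params), " but the model '",
         spec$label, "' needs ", n_params(ctx$designs), " (",
         paste(utils::head(ctx$designs$par_names, 5), collapse = ", "), ", ...)")
  }
  par <- unpack_params(ctx$designs, params)
  ll <- ll_sites_internal(par, ctx$pair_idx, ctx$n1, ctx$n0, spec$species)
  names(ll) <- ctx$sites
  ll
}
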