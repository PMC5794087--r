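#' Enumerate a candidate model set from a structural grammar
#'
#' A grammar is a base [mvb_spec()] plus named axes; each axis is a named
#' list of variants and each variant a fragment, i.e. a list with optional
#' elements `pairs` (pairwise occurrence terms to add) and `modifiers`
#' (latent-presence shifts of intensity of use to add). The candidate set is
#' the Cartesian product over axes, applied to the base spec; duplicate
#' model structures are dropped with a warning. Enumeration order is
#' deterministic (row-major over the axes as given).
#'
#' @param grammar list with elements `base` (an `mvb_spec`) and `axes`.
#' @return list of `mvb_spec` objects with labels `axis=variant; ...`.
#' @seealso [candidate_grammar()] for the shipping preset.
#' @export
build_candidate_set <- function(grammar) {
  stopifnot(inherits(grammar$base, "mvb_spec"), is.list(grammar$axes),
            length(grammar$axes) >= 1)
  axes <- grammar$axes
  idx <- expand.grid(lapply(axes, seq_along), KEEP.OUT.ATTRS = FALSE)
  specs <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    sp <- grammar$base
    labels <- character(0)
    for (a in seq_along(axes)) {
      variant <- axes[[a]][[idx[r, a]]]
      labels <- c(labels, paste0(names(axes)[a], "=", names(axes[[a]])[idx[r, a]]))
      sp <- apply_fragment(sp, variant)
    }
    sp$label <- paste(labels, collapse = "; ")
    specs[[r]] <- sp
  }
  sig <- vapply(specs, spec_signature, "")
  if (anyDuplicated(sig)) {
    warning("dropped ", sum(duplicated(sig)), " duplicate model structure(s)")
    specs <- specs[!duplicated(sig)]
  }
  specs
}

apply_fragment <- function(spec, fragment) {
  if (is.null(fragment) || identical(fragment, list())) return(spec)
  pairs <- spec$pairs
  for (pr in fragment$pairs %||% list()) {
    if (is.character(pr)) pr <- list(species = pr, formula = ~1)
    pairs[[length(pairs) + 1]] <- pr
  }
  mods <- spec$modifiers
  for (sp in names(fragment$modifiers %||% list())) {
    mods[[sp]] <- union(mods[[sp]], fragment$modifiers[[sp]])
  }
  mvb_spec(spec$species, occurrence = spec$occurrence, pairs = pairs,
           detection = spec$detection, modifiers = mods, label = spec$label)
}

#' Shipping candidate grammar for the bear-recreation system
#'
#' Builds the default 48-model grammar for a four-category system (two bear
#' species plus motorised and non-motorised recreation treated as species).
#' The base model carries habitat covariates on bear occurrence and a
#' protected-area covariate on recreation. The four structural axes vary
#' (a) bear-recreation co-occurrence (none / with motorised / with
#' non-motorised / both), (b) bear-bear co-occurrence (no / yes),
#' (c) recreation effects on bear intensity of use (none / motorised only /
#' both forms), and (d) the effect of grizzly presence on black bear
#' intensity of use (no / yes): 4 x 2 x 3 x 2 = 48 models. The exact
#' historical candidate list is not recoverable, so this preset is a
#' documented approximation with the same structural axes.
#'
#' @param habitat one-sided formula of habitat covariates for bear
#'   occurrence.
#' @param recreation one-sided formula for recreation occurrence and use.
#' @return a grammar list for [build_candidate_set()].
#' @export
candidate_grammar <- function(habitat = ~ lndroad + lndstream + elevation + ndvi,
                              recreation = ~ protected) {
  bears <- c("grizzly", "black")
  recs <- c("motorised", "non-motorised")
  base <- mvb_spec(
    species = c(bears, recs),
    occurrence = c(stats::setNames(rep(list(habitat), 2), bears),
                   stats::setNames(rep(list(recreation), 2), recs)),
    detection = stats::setNames(rep(list(recreation), 2), recs))
  bear_rec_pairs <- function(which_recs) {
    unlist(lapply(which_recs, function(r) lapply(bears, function(b) c(b, r))),
           recursive = FALSE)
  }
  list(base = base, axes = list(
    bear_rec_occ = list(
      none = list(),
      motorised = list(pairs = bear_rec_pairs("motorised")),
      nonmotorised = list(pairs = bear_rec_pairs("non-motorised")),
      both = list(pairs = bear_rec_pairs(recs))),
    bear_bear_occ = list(
      no = list(),
      yes = list(pairs = list(c("grizzly", "black")))),
    rec_on_bear_use = list(
      none = list(),
      motorised = list(modifiers = list(grizzly = "motorised",
                                        black = "motorised")),
      both = list(modifiers = list(grizzly = recs, black = recs))),
    grizzly_on_black_use = list(
      no = list(),
      yes = list(modifiers = list(black = "grizzly")))
  ))
}

#' Fit and rank a candidate model set by WAIC
#'
#' Fits every specification with the same sampler settings (each model gets
#' a distinct deterministic seed derived from `seed`), computes WAIC and
#' WAIC weights, and returns the set ordered by ascending WAIC. Models
#' whose maximum Rhat exceeds the threshold are flagged; they stay in the
#' table and, unless `exclude_nonconverged`, in the weights.
#'
#' @inheritParams mvb_occu
#' @param specs list of `mvb_spec` objects.
#' @param exclude_nonconverged drop flagged models from the weight
#'   normalisation (their weight is reported as `NA`).
#' @param verbose print one progress line per model.
#' @return `mvb_ranking`: a data frame with columns `model`, `waic`,
#'   `p_waic`, `lppd`, `delta_waic`, `weight`, `max_rhat`, `converged`, and
#'   the fits stored in `attr(, "fits")`.
#' @export
rank_models <- function(specs, history, sitecovs, chains = 3,
                        iterations = 2000, warmup = 1000, seed,
                        exclude_nonconverged = FALSE, verbose = FALSE) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(length(specs) >= 1)
  fits <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    if (verbose) message("fitting [", k, "/", length(specs), "] ", specs[[k]]$label)
    fits[[k]] <- withCallingHandlers(
      mvb_occu(specs[[k]], history, sitecovs, chains = chains,
               iterations = iterations, warmup = warmup,
               seed = as.integer(seed) + 17L * k, compute_waic = TRUE),
      warning = function(w) {
        if (grepl("convergence flag", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  tab <- data.frame(
    model = vapply(specs, function(s) s$label, ""),
    waic = vapply(fits, function(f) f$waic$waic, 0),
    p_waic = vapply(fits, function(f) f$waic$p_waic, 0),
    lppd = vapply(fits, function(f) f$waic$lppd, 0),
    max_rhat = vapply(fits, function(f) max(f$rhat), 0),
    converged = vapply(fits, function(f) f$converged, TRUE))
  tab$delta_waic <- tab$waic - min(tab$waic)
  tab$weight <- NA_real_
  use <- if (exclude_nonconverged) tab$converged else rep(TRUE, nrow(tab))
  if (any(use)) tab$weight[use] <- waic_weights(tab$waic[use])
  ord <- order(tab$waic)
  tab <- tab[ord, c("model", "waic", "p_waic", "lppd", "delta_waic",
                    "weight", "max_rhat", "converged")]
  rownames(tab) <- NULL
  structure(tab, fits = fits[ord], class = c("mvb_ranking", "data.frame"))
}

#' @export
print.mvb_ranking <- function(x, digits = 2, ...) {
  cat("Candidate model ranking by WAIC (", nrow(x), " models)\n", sep = "")
  df <- x
  attr(df, "fits") <- NULL
  class(df) <- "data.frame"
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
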