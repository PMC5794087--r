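#' Read camera-trap event records
#'
#' Expects a delimited file with columns `site_id`, `category` and
#' `timestamp` (ISO 8601, local time). Categories are free text; histories
#' are built only for the categories requested there, and the `unknown`
#' category (bears that could not be identified to species) is always
#' excluded from analysis.
#'
#' @param path CSV file path.
#' @param tz timezone the timestamps are interpreted in (one local zone for
#'   the whole study; no DST adjustment is applied within a summer window).
#' @return data frame with columns `site_id`, `category`, `timestamp`.
#' @export
read_events <- function(path, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("site_id", "category", "timestamp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("events file missing column(s): ", paste(miss, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp, tz = tz,
                             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                            "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (anyNA(df$timestamp)) stop("unparseable timestamps in ", path)
  df[need]
}

#' Read camera deployments and site covariates
#'
#' One row per camera site: `site_id`, activity window `start`/`end`
#' (dates), and site covariates (e.g. `lndroad`, `lndstream`, `elevation`,
#' `ndvi`, `protected`).
#'
#' @param path CSV file path.
#' @return data frame with `start`/`end` as `Date`.
#' @export
read_deployments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("site_id", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("deployments file missing column(s): ", paste(miss, collapse = ", "))
  df$start <- as.Date(df$start)
  df$end <- as.Date(df$end)
  if (any(df$start > df$end)) stop("deployment with start after end")
  if (anyDuplicated(df$site_id)) stop("duplicate site_id in deployments")
  df
}

#' Collapse events into occasion-level detection histories
#'
#' Daily records are collapsed into presence-absence sampling occasions of
#' `occasion_days` days (default 4, which keeps per-occasion detection
#' probabilities moderate for wide-ranging species). Occasion windows are
#' anchored at the global study start by default so occasions are comparable
#' across sites; `anchor = "camera"` anchors each site's windows at its own
#' deployment start instead.
#'
#' An occasion is `NA` (not surveyed) for a site only when the camera was
#' inactive for the entire window; a partially active window counts as
#' surveyed. Within a surveyed window, `1` records at least one event of the
#' category and `0` none.
#'
#' @param events event data frame (see [read_events()]).
#' @param deployments deployment data frame (see [read_deployments()]).
#' @param occasion_days length of one sampling occasion in days.
#' @param categories the species/categories to build rows for, in the order
#'   that fixes the latent-state bit encoding. Events of other categories
#'   (e.g. `unknown`) are ignored.
#' @param start study start date; defaults to the earliest deployment start.
#' @param anchor `"study"` (global windows) or `"camera"` (per-site windows).
#' @return a `detection_history`: a 0/1/NA array `[site, species, occasion]`
#'   with attributes `occasion_days`, `start` and `anchor`.
#' @export
build_histories <- function(events, deployments, occasion_days = 4,
                            categories = c("grizzly", "black", "motorised",
                                           "non-motorised"),
                            start = NULL, anchor = c("study", "camera")) {
  stopifnot(occasion_days >= 1)
  anchor <- match.arg(anchor)
  dep <- deployments
  start <- as.Date(start %||% min(dep$start))
  bad_site <- setdiff(unique(events$site_id), dep$site_id)
  if (length(bad_site)) stop("events reference unknown site_id: ",
                             paste(bad_site, collapse = ", "))
  events <- events[events$category %in% categories, , drop = FALSE]
  ev_date <- as.Date(events$timestamp, tz = attr(events$timestamp, "tzone") %||% "UTC")
  dep_start <- stats::setNames(dep$start, dep$site_id)
  dep_end <- stats::setNames(dep$end, dep$site_id)
  outside <- ev_date < dep_start[events$site_id] | ev_date > dep_end[events$site_id]
  if (any(outside)) {
    warning(sum(outside), " event(s) outside their site's deployment window dropped")
    events <- events[!outside, , drop = FALSE]
    ev_date <- ev_date[!outside]
  }
  site_anchor <- if (anchor == "study") {
    stats::setNames(rep(start, nrow(dep)), dep$site_id)
  } else dep_start
  n_occ <- max(ceiling((as.numeric(dep$end - site_anchor[dep$site_id]) + 1) /
                         occasion_days))
  sites <- dep$site_id
  y <- array(NA_integer_, dim = c(length(sites), length(categories), n_occ),
             dimnames = list(sites, categories, paste0("occ", seq_len(n_occ))))
  for (s in seq_along(sites)) {
    a <- site_anchor[sites[s]]
    w_start <- a + (seq_len(n_occ) - 1) * occasion_days
    w_end <- w_start + occasion_days - 1
    surveyed <- w_end >= dep_start[sites[s]] & w_start <= dep_end[sites[s]]
    y[s, , surveyed] <- 0L
  }
  if (nrow(events)) {
    a <- site_anchor[events$site_id]
    occ <- floor(as.numeric(ev_date - a) / occasion_days) + 1
    in_range <- occ >= 1 & occ <= n_occ
    idx <- cbind(match(events$site_id, sites)[in_range],
                 match(events$category, categories)[in_range],
                 occ[in_range])
    surveyed <- !is.na(y[idx])
    y[idx[surveyed, , drop = FALSE]] <- 1L
  }
  structure(y, occasion_days = occasion_days, start = start, anchor = anchor,
            class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  d <- dim(x)
  cat("Detection history: ", d[1], " sites x ", d[2], " species x ", d[3],
      " occasions (", attr(x, "occasion_days"), "-day, anchor = ",
      attr(x, "anchor"), ")\n", sep = "")
  surv <- apply(!is.na(unclass(x)[, 1, , drop = FALSE]), 1, sum)
  cat("  surveyed occasions per site: median ", stats::median(surv),
      " [", min(surv), ", ", max(surv), "]\n", sep = "")
  det <- apply(unclass(x) == 1, 2, sum, na.rm = TRUE)
  cat("  detections:", paste(paste0(names(det), "=", det), collapse = ", "), "\n")
  invisible(x)
}

#' Drop sites with too few surveyed occasions
#'
#' Sites whose cameras yielded fewer than `min_occasions` surveyed (non-`NA`)
#' occasions are removed, preserving site order. Short records carry little
#' information on occurrence and can destabilise model fitting.
#'
#' @param history a `detection_history`.
#' @param min_occasions minimum number of surveyed occasions to retain a
#'   site (default 4).
#' @return the filtered `detection_history`.
#' @export
filter_min_surveys <- function(history, min_occasions = 4) {
  stopifnot(min_occasions >= 1)
  y <- history_array(history)
  surveyed <- apply(!is.na(y), c(1, 3), any)
  keep <- rowSums(surveyed) >= min_occasions
  if (!any(keep)) stop("no site has at least ", min_occasions,
                       " surveyed occasions; nothing left to analyse")
  out <- y[keep, , , drop = FALSE]
  attributes(out)[c("occasion_days", "start", "anchor")] <-
    attributes(history)[c("occasion_days", "start", "anchor")]
  class(out) <- "detection_history"
  out
}

#' Thin photo bursts into independent events
#'
#' Cameras fire 3-5 frames per trigger, and an animal lingering on a trail
#' produces runs of near-duplicate records. Within each site and category,
#' an event is kept only if it is at least `gap_minutes` after the last kept
#' event (linear scan), so bursts collapse to their first timestamp.
#'
#' @param events event data frame.
#' @param gap_minutes minimum separation in minutes (default 30, a common
#'   camera-trap independence rule).
#' @return the thinned event data frame.
#' @export
independent_events <- function(events, gap_minutes = 30) {
  stopifnot(gap_minutes > 0)
  if (!nrow(events)) return(events)
  ord <- order(events$site_id, events$category, events$timestamp)
  ev <- events[ord, , drop = FALSE]
  keep <- logical(nrow(ev))
  last_key <- ""
  last_t <- -Inf
  tt <- as.numeric(ev$timestamp)
  key <- paste(ev$site_id, ev$category, sep = "\r")
  for (r in seq_len(nrow(ev))) {
    if (key[r] != last_key || tt[r] - last_t >= gap_minutes * 60) {
      keep[r] <- TRUE
      last_key <- key[r]
      last_t <- tt[r]
    }
  }
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Naive occurrence and co-detection summary
#'
#' Naive occurrence is the fraction of sites with at least one detection,
#' uncorrected for imperfect detection; the co-detection matrix counts sites
#' where both members of a pair were detected at least once.
#'
#' @param history a `detection_history` with at least one site.
#' @return list with `n_sites`, `detected_sites` (count per species),
#'   `naive` (proportion per species) and `codetections` (species x species
#'   count matrix, diagonal = detected site count).
#' @export
naive_summary <- function(history) {
  y <- history_array(history)
  if (dim(y)[1] < 1) stop("history has no sites")
  det <- apply(y == 1, c(1, 2), any)
  det[is.na(det)] <- FALSE
  co <- crossprod(det)
  list(n_sites = nrow(det),
       detected_sites = colSums(det),
       naive = colSums(det) / nrow(det),
       codetections = co)
}

#' Write / read a detection history as a wide CSV
#'
#' One row per site-species combination, occasion values in columns
#' `occ1, occ2, ...` with `NA` for occasions not surveyed. `read_history`
#' inverts the format.
#'
#' @param history a `detection_history`.
#' @param path CSV file path.
#' @param comment optional comment lines (prefixed `#`) written above the
#'   header, e.g. a config hash.
#' @return `write_history` returns `path` invisibly; `read_history` returns
#'   a `detection_history`.
#' @export
write_history <- function(history, path, comment = character(0)) {
  y <- history_array(history)
  d <- dim(y)
  wide <- data.frame(site_id = rep(dimnames(y)[[1]], times = d[2]),
                     species = rep(dimnames(y)[[2]], each = d[1]),
                     matrix(as.integer(y), d[1] * d[2], d[3],
                            dimnames = list(NULL, dimnames(y)[[3]])),
                     check.names = FALSE)
  wide <- wide[order(match(wide$site_id, dimnames(y)[[1]])), ]
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste0("# occasion_days ", attr(history, "occasion_days"),
                    " start ", attr(history, "start"),
                    " anchor ", attr(history, "anchor")), con)
  utils::write.csv(wide, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  meta <- grep("^# occasion_days", readLines(path, n = 10), value = TRUE)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  sites <- unique(df$site_id)
  species <- unique(df$species)
  occ_cols <- grep("^occ", names(df), value = TRUE)
  y <- array(NA_integer_, c(length(sites), length(species), length(occ_cols)),
             dimnames = list(sites, species, occ_cols))
  for (r in seq_len(nrow(df))) {
    y[df$site_id[r], df$species[r], ] <- as.integer(df[r, occ_cols])
  }
  od <- 4L
  start <- NA
  anchor <- "study"
  if (length(meta)) {
    parts <- strsplit(sub("^# ", "", meta[1]), " ")[[1]]
    od <- as.integer(parts[2])
    start <- as.Date(parts[4])
    anchor <- parts[6]
  }
  structure(y, occasion_days = od, start = start, anchor = anchor,
            class = "detection_history")
}
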