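#' Default pipeline configuration
#'
#' All defaults match the study design the package emulates: 4-day
#' occasions, a minimum of 4 surveyed occasions per retained site, a
#' 30-minute event-independence gap, 3 chains of 2,000 MCMC iterations with
#' 1,000 warmup, and 1,000 bootstrap resamples on a 512-point activity grid.
#'
#' @param out_dir directory the pipeline writes artifacts into.
#' @return nested configuration list (see [run_pipeline()]).
#' @export
default_config <- function(out_dir = "mvboccu-run") {
  list(
    out_dir = out_dir,
    paths = list(events = NULL, deployments = NULL, history = NULL,
                 truth = NULL),
    study = list(start = "2014-06-15", end = "2014-08-25", tz = "UTC"),
    species = c("grizzly", "black", "motorised", "non-motorised"),
    occasions = list(occasion_days = 4, min_occasions = 4, anchor = "study"),
    independence = list(gap_minutes = 30),
    sampler = list(chains = 3, iterations = 2000, warmup = 1000, seed = 1),
    simulate = list(n_sites = 182, n_occasions = 18, events = TRUE),
    candidates = list(preset = "default", specs = NULL),
    activity = list(grid_n = 512, n_boot = 1000,
                    comparisons = list(
                      list(focal = "grizzly", conditioning = "black",
                           versus = "black"),
                      list(focal = "black", conditioning = "grizzly",
                           versus = "grizzly")))
  )
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML file, overlays it on [default_config()] and validates field
#' types and ranges; validation failures name the offending field.
#'
#' @param path YAML configuration file.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modify_list(default_config(), user)
  validate_config(cfg)
  cfg
}

modify_list <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- modify_list(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  check <- function(ok, field, msg) {
    if (!ok) stop("invalid config field '", field, "': ", msg, call. = FALSE)
  }
  check(is.character(cfg$out_dir) && length(cfg$out_dir) == 1,
        "out_dir", "must be a single path")
  check(cfg$occasions$occasion_days >= 1, "occasions.occasion_days", ">= 1")
  check(cfg$occasions$min_occasions >= 1, "occasions.min_occasions", ">= 1")
  check(cfg$independence$gap_minutes > 0, "independence.gap_minutes", "> 0")
  check(cfg$sampler$chains >= 2, "sampler.chains", ">= 2 (needed for Rhat)")
  check(cfg$sampler$iterations > cfg$sampler$warmup,
        "sampler.iterations", "must exceed sampler.warmup")
  check(is.numeric(cfg$sampler$seed), "sampler.seed", "must be numeric")
  check(cfg$activity$n_boot >= 100, "activity.n_boot", ">= 100")
  check(!is.na(as.Date(cfg$study$start)) && !is.na(as.Date(cfg$study$end)),
        "study.start/end", "must be dates")
  invisible(cfg)
}

# deterministic 32-bit FNV-1a-style hash of the config's YAML rendering
config_hash <- function(cfg) {
  bytes <- utf8ToInt(yaml::as.yaml(cfg))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 31 + 17) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_artifact <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

read_artifact <- function(path) {
  first <- readLines(path, n = 1)
  hash <- if (grepl("^# config_hash ", first)) sub("^# config_hash ", "", first)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  attr(df, "config_hash") <- hash
  df
}

#' Run one stage of the camera-trap co-occurrence pipeline
#'
#' Config-driven entry point tying the stages together with deterministic
#' outputs. Commands:
#' \describe{
#'   \item{simulate}{write synthetic `events.csv`, `deployments.csv` and
#'     `truth.yaml` from the study-like generator.}
#'   \item{histories}{build, filter and write the occasion-level
#'     `history.csv` plus `naive_summary.csv`.}
#'   \item{fit}{fit the configured (default: study-like) model; write
#'     `posterior_summary.csv`.}
#'   \item{rank}{fit and rank the candidate set; write `ranking.csv`.}
#'   \item{overlap}{write the conditional activity-overlap table
#'     `overlap.csv`.}
#'   \item{report}{collate the artifacts above into `report.txt`, refusing
#'     inputs whose embedded config hash does not match.}
#' }
#' Every CSV artifact embeds the config hash in a leading comment line, and
#' a `log.txt` records seeds and convergence flags. Reruns with the same
#' config are byte-identical.
#'
#' @param command one of `simulate`, `histories`, `fit`, `rank`, `overlap`,
#'   `report`.
#' @param config configuration list from [default_config()]/[read_config()].
#' @param allow_nonconverged do not error when a fit fails the Rhat flag.
#' @return invisible named list of artifact paths written.
#' @export
run_pipeline <- function(command = c("simulate", "histories", "fit", "rank",
                                     "overlap", "report"),
                         config = default_config(),
                         allow_nonconverged = FALSE) {
  command <- match.arg(command)
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  p <- function(f) file.path(config$out_dir, f)
  log_lines <- c(paste("command:", command),
                 paste("config_hash:", hash),
                 paste("seed:", config$sampler$seed),
                 paste("mvboccu:", as.character(utils::packageVersion("mvboccu"))))
  out <- switch(command,
    simulate = pipe_simulate(config, hash, p),
    histories = pipe_histories(config, hash, p),
    fit = pipe_fit(config, hash, p, allow_nonconverged,
                   function(l) log_lines <<- c(log_lines, l)),
    rank = pipe_rank(config, hash, p, allow_nonconverged,
                     function(l) log_lines <<- c(log_lines, l)),
    overlap = pipe_overlap(config, hash, p),
    report = pipe_report(config, hash, p))
  writeLines(c(log_lines, paste("artifacts:", paste(unlist(out), collapse = " "))),
             p(paste0("log_", command, ".txt")))
  invisible(out)
}

pipe_simulate <- function(config, hash, p) {
  truth <- if (!is.null(config$paths$truth)) truth_from_yaml(config$paths$truth)
           else example_truth(config$species)
  sim <- simulate_dataset(truth,
                          n_sites = config$simulate$n_sites,
                          n_occasions = config$simulate$n_occasions,
                          occasion_days = config$occasions$occasion_days,
                          seed = config$sampler$seed,
                          events = isTRUE(config$simulate$events))
  ev <- sim$events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%S")
  list(events = write_artifact(ev, p("events.csv"), hash),
       deployments = write_artifact(sim$deployments, p("deployments.csv"), hash),
       truth = truth_to_yaml(truth, p("truth.yaml")))
}

pipe_histories <- function(config, hash, p) {
  events <- read_events(config$paths$events %||% p("events.csv"),
                        tz = config$study$tz)
  dep <- read_deployments(config$paths$deployments %||% p("deployments.csv"))
  hist <- build_histories(events, dep,
                          occasion_days = config$occasions$occasion_days,
                          categories = config$species,
                          start = config$study$start,
                          anchor = config$occasions$anchor)
  hist <- filter_min_surveys(hist, config$occasions$min_occasions)
  ns <- naive_summary(hist)
  naive_df <- data.frame(species = names(ns$naive),
                         detected_sites = as.integer(ns$detected_sites),
                         n_sites = ns$n_sites,
                         naive_occurrence = round(ns$naive, 4))
  list(history = write_history(hist, p("history.csv"),
                               comment = paste("config_hash", hash)),
       naive = write_artifact(naive_df, p("naive_summary.csv"), hash))
}

pipeline_inputs <- function(config, p) {
  hist <- read_history(config$paths$history %||% p("history.csv"))
  dep <- read_deployments(config$paths$deployments %||% p("deployments.csv"))
  dep <- dep[dep$site_id %in% dimnames(hist)[[1]], , drop = FALSE]
  list(history = hist, deployments = dep)
}

pipe_spec <- function(config) {
  if (!is.null(config$paths$spec)) return(spec_from_yaml(config$paths$spec))
  example_truth(config$species)$spec
}

pipe_fit <- function(config, hash, p, allow_nonconverged, add_log) {
  inp <- pipeline_inputs(config, p)
  fit <- mvb_occu(pipe_spec(config), inp$history, inp$deployments,
                  chains = config$sampler$chains,
                  iterations = config$sampler$iterations,
                  warmup = config$sampler$warmup,
                  seed = config$sampler$seed)
  add_log(c(paste("max_rhat:", round(max(fit$rhat), 4)),
            paste("converged:", fit$converged),
            paste("waic:", round(fit$waic$waic, 2))))
  if (!fit$converged && !allow_nonconverged) {
    stop("model did not pass the convergence flag (max Rhat = ",
         round(max(fit$rhat), 3), "); rerun with allow_nonconverged = TRUE ",
         "or increase iterations")
  }
  s <- summary(fit)
  s$mean <- round(s$mean, 6); s$sd <- round(s$sd, 6)
  s$lower <- round(s$lower, 6); s$upper <- round(s$upper, 6)
  s$rhat <- round(s$rhat, 4)
  list(posterior = write_artifact(as.data.frame(s), p("posterior_summary.csv"),
                                  hash))
}

pipe_rank <- function(config, hash, p, allow_nonconverged, add_log) {
  inp <- pipeline_inputs(config, p)
  specs <- if (!is.null(config$candidates$specs)) {
    lapply(config$candidates$specs, spec_from_yaml)
  } else if (identical(config$candidates$preset, "default")) {
    build_candidate_set(candidate_grammar())
  } else {
    stop("invalid config field 'candidates.preset': unknown preset '",
         config$candidates$preset, "'")
  }
  rk <- rank_models(specs, inp$history, inp$deployments,
                    chains = config$sampler$chains,
                    iterations = config$sampler$iterations,
                    warmup = config$sampler$warmup,
                    seed = config$sampler$seed,
                    exclude_nonconverged = FALSE)
  add_log(paste("nonconverged_models:", sum(!rk$converged)))
  if (any(!rk$converged) && !allow_nonconverged) {
    stop(sum(!rk$converged), " candidate fit(s) failed the convergence flag; ",
         "rerun with allow_nonconverged = TRUE or increase iterations")
  }
  df <- as.data.frame(rk)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = 6)
  list(ranking = write_artifact(df, p("ranking.csv"), hash))
}

pipe_overlap <- function(config, hash, p) {
  events <- read_events(config$paths$events %||% p("events.csv"),
                        tz = config$study$tz)
  events <- independent_events(events, config$independence$gap_minutes)
  hist <- read_history(config$paths$history %||% p("history.csv"))
  rows <- lapply(config$activity$comparisons, function(cmp) {
    conditional_overlap(events, hist, cmp$focal, cmp$conditioning,
                        cmp$versus, n_boot = config$activity$n_boot,
                        grid_n = config$activity$grid_n,
                        seed = config$sampler$seed)
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df$delta <- round(df$delta, 4)
  df$ci_low <- round(df$ci_low, 4)
  df$ci_high <- round(df$ci_high, 4)
  list(overlap = write_artifact(df, p("overlap.csv"), hash))
}

pipe_report <- function(config, hash, p) {
  parts <- c(naive = "naive_summary.csv", ranking = "ranking.csv",
             posterior = "posterior_summary.csv", overlap = "overlap.csv")
  lines <- c("Multispecies co-occurrence analysis report",
             paste("config hash:", hash), "")
  for (nm in names(parts)) {
    f <- p(parts[nm])
    if (!file.exists(f)) next
    df <- read_artifact(f)
    got <- attr(df, "config_hash")
    if (!is.null(got) && !identical(got, hash)) {
      stop("artifact ", parts[nm], " was produced under config hash ", got,
           " but the current config hashes to ", hash,
           "; refusing to collate mismatched inputs")
    }
    lines <- c(lines, paste0("== ", nm, " (", parts[nm], ") =="),
               utils::capture.output(print(df)), "")
  }
  writeLines(lines, p("report.txt"))
  list(report = p("report.txt"))
}
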