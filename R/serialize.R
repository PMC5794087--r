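#' Serialize a model specification to YAML
#'
#' The YAML layout mirrors the spec structure: per-species occurrence and
#' detection formulas (as strings), the pair list, and the modifier map.
#'
#' @param spec an [mvb_spec()].
#' @param path optional file to write; when `NULL` the YAML string is
#'   returned.
#' @return `path` (invisibly) or the YAML string.
#' @export
spec_to_yaml <- function(spec, path = NULL) {
  x <- list(
    species = spec$species,
    label = spec$label,
    occurrence = lapply(spec$occurrence, formula_chr),
    detection = lapply(spec$detection, formula_chr),
    pairs = lapply(spec$pairs, function(pr)
      list(species = pr$species, formula = formula_chr(pr$formula))),
    modifiers = lapply(spec$modifiers, as.list))
  if (is.null(path)) return(yaml::as.yaml(x))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname spec_to_yaml
#' @param x a YAML file path or string produced by [spec_to_yaml()].
#' @export
spec_from_yaml <- function(x) {
  y <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  mvb_spec(unlist(y$species),
           occurrence = lapply(y$occurrence, stats::as.formula),
           pairs = lapply(y$pairs, function(pr)
             list(species = unlist(pr$species),
                  formula = stats::as.formula(pr$formula))),
           detection = lapply(y$detection, stats::as.formula),
           modifiers = lapply(y$modifiers, unlist),
           label = y$label)
}

formula_chr <- function(f) paste(deparse(f), collapse = " ")

#' Serialize a synthetic truth (spec + coefficients + activity) to YAML
#'
#' @param truth an [mvb_truth()].
#' @inheritParams spec_to_yaml
#' @return `path` (invisibly) or the YAML string.
#' @export
truth_to_yaml <- function(truth, path = NULL) {
  x <- list(spec = yaml::yaml.load(spec_to_yaml(truth$spec)),
            coef = as.list(truth$coef),
            activity = truth$activity)
  if (is.null(path)) return(yaml::as.yaml(x))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname truth_to_yaml
#' @param x a YAML file path or string produced by [truth_to_yaml()].
#' @export
truth_from_yaml <- function(x) {
  y <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  spec <- spec_from_yaml(yaml::as.yaml(y$spec))
  activity <- lapply(y$activity, function(a) lapply(a, unlist))
  mvb_truth(spec, unlist(y$coef), if (length(activity)) activity)
}
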