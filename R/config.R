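# Pipeline configuration.
#
# Every analysis constant is a named key with the study's value as the
# default, so a run is fully determined by (inputs, config, seed).

#' Default analysis configuration
#'
#' @return Nested named list: `alpha` (screening significance, 0.05),
#'   `fold` (linear fold-change filter, 1.5), `window` (moving-average
#'   width in days, 3), `thresholds` (fold-change sensitivity sweep),
#'   `lowess_span` and `lowess_iterations`, `qc_percentiles`,
#'   `flag_policy`, `kw_p_method`, `tie_rule` (dynamic-type magnitude
#'   ties), `t10_include_baseline`, and `seed`.
#' @export
default_config <- function() {
  list(
    alpha = 0.05,
    fold = 1.5,
    window = 3,
    thresholds = c(1.5, 1.75, 2.0),
    lowess_span = 0.3,
    lowess_iterations = 3,
    qc_percentiles = c(25, 50, 75),
    flag_policy = "any",
    kw_p_method = "chisq",
    tie_rule = "day5",
    t10_include_baseline = FALSE,
    seed = 1
  )
}

#' Read or write a configuration file
#'
#' JSON natively; YAML when the `yaml` package is available. Unknown
#' keys are rejected so typos fail loudly; missing keys fall back to
#' [default_config()].
#'
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_input("the yaml package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else stop_input("unsupported config format: .%s", ext)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) stop_input("unknown config key(s): %s",
                                  paste(unknown, collapse = ", "))
  utils::modifyList(base, user)
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_input("the yaml package is required for YAML configs")
    }
    yaml::write_yaml(config, path)
  } else stop_input("unsupported config format: .%s", ext)
  invisible(path)
}
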