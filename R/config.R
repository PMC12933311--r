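# Run configuration: one YAML/JSON document holding the registration
# hyperparameters, the phantom simulator block, the seed and the output
# directory; fully validated before any stage runs.

#' Default run configuration
#'
#' @return Nested list with blocks `registration` (the [coreg_config()]
#'   fields), `phantom` (the [phantom_config()] fields), plus `seed` and
#'   `out_dir`. These defaults reproduce the CLI `demo`.
#' @export
default_run_config <- function() {
  list(
    registration = unclass(coreg_config()),
    phantom = unclass(phantom_config()),
    seed = 1L,
    out_dir = "."
  )
}

#' Read and validate a run configuration file
#'
#' Accepts YAML (or JSON, a YAML subset). Keys missing from the file keep
#' their defaults; unknown keys are an error naming the key; every value is
#' validated through [coreg_config()] / [phantom_config()] before any
#' pipeline stage runs.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @return Validated run configuration list with a `"run_config"` class.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config file must be a mapping", call. = FALSE)
    for (top in names(user)) {
      if (!top %in% names(cfg)) {
        stop(sprintf("unknown config key: %s", top), call. = FALSE)
      }
      if (top %in% c("registration", "phantom")) {
        for (key in names(user[[top]])) {
          if (!key %in% names(cfg[[top]])) {
            stop(sprintf("unknown config key: %s.%s", top, key), call. = FALSE)
          }
          cfg[[top]][[key]] <- user[[top]][[key]]
        }
      } else {
        cfg[[top]] <- user[[top]]
      }
    }
  }
  # re-validate through the constructors
  cfg$registration <- unclass(do.call(coreg_config, cfg$registration))
  cfg$phantom <- unclass(do.call(phantom_config, cfg$phantom))
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || !is.finite(cfg$seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

run_config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_recursive(unclass(cfg)), tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
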