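cli_known_keys <- c(
  "out", "cells", "bin-width", "wgd", "founder-events", "missegregation",
  "segmental", "seed", "binmap", "population", "counts", "mean-reads",
  "dispersion", "gc-bias", "replicates", "background-mean", "effect-mean",
  "groups", "means", "concordance", "min-reads", "euploid", "anchor",
  "delta", "table", "compare", "bonferroni", "config", "verbose")

#' Read a run configuration file
#'
#' Configurations are flat key/value maps in YAML (`.yaml`/`.yml`, requires
#' the yaml package) or JSON. Keys use the CLI flag names (e.g. `min-reads`,
#' `seed`); unknown keys are rejected so typos fail loudly. On the command
#' line, `--config file` supplies defaults that explicit flags override.
#'
#' @param path config file path.
#' @return Named list of parameter values.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path))
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  assert_that(is.list(cfg) && !is.null(names(cfg)) && all(nzchar(names(cfg))),
              "config must be a named key/value map")
  unknown <- setdiff(names(cfg), cli_known_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  lapply(cfg, function(v) if (is.logical(v)) v else as.character(v))
}
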