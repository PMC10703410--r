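## Declarative run configuration (YAML/JSON), override validation, result
## persistence, and a thin command-line front end over the package functions.

#' Load and validate a run configuration
#'
#' A configuration is a YAML (or JSON) document with optional fields:
#' `overrides` (named dotted parameter keys), `mechanisms` (list of
#' `{mechanism, severity}`), `protocol` (`settle` or `remodel` with its
#' options), `sobol` (`N`, `days`, `replicates`), `seed`, and `days`.
#' Every override key must match a known parameter symbol; unknown keys are
#' errors, not warnings.
#'
#' @param path file path
#' @return validated configuration list of class `cr_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}

#' Validate a configuration list
#' @param cfg configuration list
#' @return the configuration, classed `cr_config`; errors name the offending key
#' @export
validate_config <- function(cfg) {
  known <- c("overrides", "mechanisms", "protocol", "sobol", "seed", "days",
             "output", "label")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  }
  if (!is.null(cfg$overrides)) {
    # surfaces unknown parameter keys with the key named
    set_parameters(default_parameters(), cfg$overrides)
  }
  if (!is.null(cfg$mechanisms)) {
    for (m in cfg$mechanisms) {
      if (is.null(m$mechanism) || is.null(m$severity)) {
        stop("each mechanism entry needs 'mechanism' and 'severity'")
      }
      mechanism_spec(m$mechanism, m$severity)
    }
  }
  structure(cfg, class = "cr_config")
}

#' @keywords internal
config_params <- function(cfg) {
  p <- default_parameters()
  if (!is.null(cfg$overrides)) p <- set_parameters(p, cfg$overrides)
  if (!is.null(cfg$mechanisms)) {
    specs <- lapply(cfg$mechanisms, function(m)
      mechanism_spec(m$mechanism, m$severity))
    p <- apply_mechanisms(p, specs)
  }
  p
}

#' Write a run manifest
#'
#' Records the configuration hash, seed, and package version next to the run
#' outputs so results are attributable and reproducible.
#'
#' @param dir output directory
#' @param cfg_path configuration path (hashed); may be NA
#' @param seed seed used
#' @param extra named list merged into the manifest
#' @return manifest path, invisibly
#' @export
write_manifest <- function(dir, cfg_path = NA, seed = NA, extra = list()) {
  man <- c(list(
    package = "cardiorenal",
    version = as.character(utils::packageVersion("cardiorenal")),
    config = if (is.na(cfg_path)) NA else basename(cfg_path),
    config_md5 = if (is.na(cfg_path)) NA else unname(tools::md5sum(cfg_path)),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC")
  ), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Command-line entry point
#'
#' Verbs: `simulate` (settling run from a config), `remodel` (1-year
#' remodeling protocol), `sobol` (sensitivity study), `validate-config`.
#' Intended to be called from the thin launcher script shipped under
#' `inst/cli/`.
#'
#' @param args character vector, e.g. `c("simulate", "--config", "run.yaml",
#'   "--out", "results")`
#' @return exit status (0 on success), invisibly
#' @export
cr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cardiorenal <verb> [--config FILE] [--out DIR] [--seed N]",
    "verbs: simulate | remodel | sobol | validate-config", sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  verb <- args[[1]]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[[i + 1]] else default
  }
  out_dir <- opt("--out", "results")
  seed <- as.integer(opt("--seed", "1"))
  cfg_path <- opt("--config")
  cfg <- if (!is.null(cfg_path)) load_config(cfg_path) else
    validate_config(list())
  if (identical(verb, "validate-config")) {
    message("config OK")
    return(invisible(0L))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  status <- 0L
  if (identical(verb, "simulate")) {
    p <- config_params(cfg)
    days <- if (!is.null(cfg$days)) cfg$days else 60
    res <- run_settling(p, days = days)
    write.csv(res$trajectory, file.path(out_dir, "trajectory.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      c(res$metrics[c("EF", "LVEDP", "EDV", "ESV", "SV", "CO", "MAP", "SBP",
                      "DBP", "IVRT", "tau")],
        list(hf_state = res$hf_state, settled = res$settled)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  } else if (identical(verb, "remodel")) {
    p <- default_parameters()
    mech <- if (!is.null(cfg$mechanisms)) {
      lapply(cfg$mechanisms, function(m) mechanism_spec(m$mechanism, m$severity))
    } else list(mechanism_spec("lv_stiffness", 0.8))
    law <- if (!is.null(cfg$protocol$law)) cfg$protocol$law else "strain"
    days <- if (!is.null(cfg$days)) cfg$days else 365
    res <- run_remodeling_protocol(p, mech, law_mode = law, duration = days)
    write.csv(res$trajectory, file.path(out_dir, "trajectory.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      c(res$final[c("EF", "LVEDP", "EDV")], list(hf_state = res$hf_state)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  } else if (identical(verb, "sobol")) {
    N <- if (!is.null(cfg$sobol$N)) cfg$sobol$N else 2^5
    days <- if (!is.null(cfg$sobol$days)) cfg$sobol$days else 60
    st <- sobol_study(N = N, seed = seed, days = days)
    write.csv(cbind(as.data.frame(st$design$X), st$outputs),
              file.path(out_dir, "design_outputs.csv"), row.names = FALSE)
    jsonlite::write_json(list(LVEDP = st$LVEDP, EF = st$EF),
                         file.path(out_dir, "indices.json"),
                         dataframe = "rows", digits = NA)
  } else {
    message(usage)
    status <- 1L
  }
  if (status == 0L) write_manifest(out_dir, cfg_path %||% NA, seed)
  invisible(status)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
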