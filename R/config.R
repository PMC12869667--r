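.config_defaults <- list(
  seed = NULL, dt = 1, preset = "td_child", params = NULL,
  cohorts = "TD", n_epochs = 3000, cap_at_td = FALSE,
  mix = NULL, rates = NULL, output_dir = ".", verbosity = 1)

# cheap FNV-1a style hash of the canonical config text, for run logs
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(txt)) h <- ((bitwXor(h, b)) * 16777619) %% 2^32
  sprintf("%08x", h)
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON; YAML is a superset) configuration, rejects unknown
#' keys, validates the fields and fills documented defaults.  Recognized
#' keys: \code{seed} (mandatory, integer), \code{dt}, \code{preset} or
#' inline \code{params} overrides, \code{cohorts} (vector of
#' [cohort_names]), \code{n_epochs}, \code{cap_at_td}, \code{mix}
#' (\code{p_av/p_a/p_v}, optional override of the cohort mix), \code{rates}
#' (optional: \code{preset} plus [learning_rates()] overrides),
#' \code{output_dir}, \code{verbosity}.
#'
#' @param path Path to the configuration file.
#' @return Object of class \code{msidev_config} (named list, all defaults
#'   filled).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a mapping")
  bad <- setdiff(names(raw), names(.config_defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- .config_defaults
  cfg[names(raw)] <- raw
  if (is.null(cfg$seed)) stop("config key 'seed' is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  if (!is.numeric(cfg$dt) || cfg$dt <= 0) stop("config key 'dt' must be > 0")
  if (!is.numeric(cfg$n_epochs) || cfg$n_epochs < 1)
    stop("config key 'n_epochs' must be >= 1")
  cfg$cohorts <- as.character(cfg$cohorts)
  bad <- setdiff(cfg$cohorts, cohort_names)
  if (length(bad)) stop("unknown cohort(s) in config: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$params)) {
    p <- do.call(network_params, c(list(preset = cfg$preset), cfg$params))
    validate_params(p)
  } else {
    network_params(cfg$preset)
  }
  if (!is.null(cfg$mix))
    do.call(mix_spec, cfg$mix[c("p_av", "p_a", "p_v")])
  if (!is.null(cfg$rates)) {
    preset <- if (is.null(cfg$rates$preset)) "td" else cfg$rates$preset
    do.call(learning_rates,
            c(list(preset = preset),
              cfg$rates[setdiff(names(cfg$rates), "preset")]))
  }
  structure(cfg, class = "msidev_config")
}

#' Write a run configuration to YAML
#'
#' @param cfg An \code{msidev_config} (round-trips losslessly through
#'   [load_config()]).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  if (!inherits(cfg, "msidev_config")) stop("not an msidev_config")
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Execute the cohort runs described by a configuration
#'
#' Runs each configured cohort with [run_cohort()], writes one trajectory
#' CSV per cohort into \code{output_dir} and logs the config hash, seed,
#' step size and package version to standard error.
#'
#' @param cfg An \code{msidev_config} from [load_config()].
#' @return Named list of \code{rt_trajectory} objects, invisibly.
#' @export
run_config <- function(cfg) {
  if (!inherits(cfg, "msidev_config")) stop("not an msidev_config")
  log <- function(...) if (cfg$verbosity > 0) message(...)
  log(sprintf("msidev %s | config %s | seed %d | dt %g ms",
              as.character(utils::packageVersion("msidev")),
              config_hash(cfg), cfg$seed, cfg$dt))
  if (!dir.exists(cfg$output_dir))
    dir.create(cfg$output_dir, recursive = TRUE)
  rates <- if (is.null(cfg$rates)) NULL else {
    preset <- if (is.null(cfg$rates$preset)) "td" else cfg$rates$preset
    do.call(learning_rates,
            c(list(preset = preset),
              cfg$rates[setdiff(names(cfg$rates), "preset")]))
  }
  out <- lapply(cfg$cohorts, function(nm) {
    log("running cohort ", nm)
    traj <- run_cohort(nm, seed = cfg$seed, dt = cfg$dt,
                       n_epochs = cfg$n_epochs, cap_at_td = cfg$cap_at_td,
                       rates = rates)
    path <- file.path(cfg$output_dir, paste0("trajectory_", nm, ".csv"))
    write_trajectory(traj, path)
    log("wrote ", path)
    traj
  })
  names(out) <- cfg$cohorts
  invisible(out)
}
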