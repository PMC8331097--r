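#' Load and resolve a structured text configuration
#'
#' Configurations are YAML with up to five sections, all optional:
#'
#' * `parameters:` named circuit-coefficient overrides (names as in
#'   [default_parameters()]; applied on top of the calibrated set).
#' * `simulation:` `duration` (s), `dt` (s), `method` (`euler`/`rk4`),
#'   `clamp` (logical), `seed`.
#' * `schedule:` list of `{time, parameter, multiplier}` entries.
#' * `cohort:` `n_subjects`, `noise_low`, `noise_high`, `seed`.
#' * `ga:` any [ga_config()] argument.
#' * `arm:` `anchor` (`zero`/`range`), `interp` (`zoh`/`linear`); joint
#'   angles in degrees are accepted via `shoulder_limits`/`elbow_limits`
#'   and stored in radians.
#'
#' Defaults are merged under explicit overrides; unknown keys are rejected
#' with an error naming the key.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A list with class `"serotrem_config"`: resolved `params`,
#'   `schedule`, `simulation`, `cohort`, `ga`, `arm`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("parameters", "simulation", "schedule", "cohort", "ga", "arm")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "serotrem_config_error")
  }

  params <- do.call(circuit_parameters,
                    c(raw$parameters %||% list(),
                      list(.base = calibrated_parameters())))

  sim_defaults <- list(duration = 300, dt = 0.1, method = "euler",
                       clamp = FALSE, seed = 1L)
  sim_unknown <- setdiff(names(raw$simulation %||% list()), names(sim_defaults))
  if (length(sim_unknown)) {
    abort(paste0("unknown simulation key(s): ", paste(sim_unknown, collapse = ", ")),
          class = "serotrem_config_error")
  }
  simulation <- modifyList(sim_defaults, raw$simulation %||% list())
  check_time_grid(simulation$duration, simulation$dt)
  if (!simulation$method %in% c("euler", "rk4")) {
    abort("simulation method must be 'euler' or 'rk4'",
          class = "serotrem_config_error")
  }

  schedule <- if (is.null(raw$schedule)) empty_schedule() else {
    entries <- raw$schedule
    bad <- !vapply(entries, function(e) {
      all(c("time", "parameter", "multiplier") %in% names(e))
    }, logical(1))
    if (any(bad)) {
      abort("malformed schedule entry: need time, parameter, multiplier",
            class = "serotrem_config_error")
    }
    intervention_schedule(
      time = vapply(entries, function(e) as.numeric(e$time), numeric(1)),
      parameter = vapply(entries, function(e) as.character(e$parameter), character(1)),
      multiplier = vapply(entries, function(e) as.numeric(e$multiplier), numeric(1))
    )
  }

  coh_defaults <- list(n_subjects = 20L, noise_low = 0.01, noise_high = 0.02, seed = 1L)
  coh_unknown <- setdiff(names(raw$cohort %||% list()), names(coh_defaults))
  if (length(coh_unknown)) {
    abort(paste0("unknown cohort key(s): ", paste(coh_unknown, collapse = ", ")),
          class = "serotrem_config_error")
  }
  coh <- modifyList(coh_defaults, raw$cohort %||% list())
  cohort <- cohort_spec(coh$n_subjects, c(coh$noise_low, coh$noise_high), coh$seed)

  ga_args <- raw$ga %||% list()
  ga_unknown <- setdiff(names(ga_args), names(formals(ga_config)))
  if (length(ga_unknown)) {
    abort(paste0("unknown ga key(s): ", paste(ga_unknown, collapse = ", ")),
          class = "serotrem_config_error")
  }
  ga <- do.call(ga_config, ga_args)

  arm_defaults <- list(anchor = "zero", interp = "zoh",
                       shoulder_limits = c(-60, 150), elbow_limits = c(0, 180))
  arm_unknown <- setdiff(names(raw$arm %||% list()), names(arm_defaults))
  if (length(arm_unknown)) {
    abort(paste0("unknown arm key(s): ", paste(arm_unknown, collapse = ", ")),
          class = "serotrem_config_error")
  }
  arm_raw <- modifyList(arm_defaults, raw$arm %||% list())
  arm <- list(
    anchor = arm_raw$anchor, interp = arm_raw$interp,
    params = arm_parameters(
      shoulder_limits = as.numeric(arm_raw$shoulder_limits) * pi / 180,
      elbow_limits = as.numeric(arm_raw$elbow_limits) * pi / 180
    )
  )

  structure(list(params = params, simulation = simulation, schedule = schedule,
                 cohort = cohort, ga = ga, arm = arm),
            class = "serotrem_config")
}

#' Write a resolved configuration back to YAML
#'
#' Writing then reloading a configuration yields an identical resolved
#' configuration (round trip).
#'
#' @param config A `"serotrem_config"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list(
    parameters = as.list(setNames(as.numeric(config$params), .param_names)),
    simulation = config$simulation,
    cohort = list(n_subjects = config$cohort$n,
                  noise_low = config$cohort$noise_range[1],
                  noise_high = config$cohort$noise_range[2],
                  seed = config$cohort$seed),
    ga = unclass(config$ga),
    arm = list(anchor = config$arm$anchor, interp = config$arm$interp,
               shoulder_limits = config$arm$params$shoulder_limits * 180 / pi,
               elbow_limits = config$arm$params$elbow_limits * 180 / pi)
  )
  if (nrow(config$schedule)) {
    out$schedule <- purrr::pmap(config$schedule, function(time, parameter, multiplier) {
      list(time = time, parameter = parameter, multiplier = multiplier)
    })
  }
  out$ga$weights <- as.list(out$ga$weights)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

# run manifest: everything needed to reproduce a CLI run bit-identically
write_manifest <- function(out_dir, command, config, seed, files) {
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(
    tool = "serotrem",
    version = as.character(packageVersion("serotrem")),
    command = command,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = seed,
    config = jsonlite::fromJSON(jsonlite::toJSON(
      list(parameters = as.list(setNames(as.numeric(config$params), .param_names)),
           simulation = config$simulation,
           cohort = list(n_subjects = config$cohort$n,
                         noise_range = config$cohort$noise_range,
                         seed = config$cohort$seed)),
      auto_unbox = TRUE, digits = NA)),
    outputs = checksums
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(out_dir, "manifest.json"))
}
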