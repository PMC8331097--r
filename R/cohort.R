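#' Cohort specification for in-silico experiments
#'
#' A simulated cohort of `n` subjects. Subject `i` receives additive
#' Gaussian noise on every circuit coefficient and every initial-state value
#' with standard deviation `s_i` times the base value, where the noise
#' scales `s_i` are evenly spaced over `noise_range` (defaults: 0.01 for
#' subject 1 up to 0.02 for subject `n`).
#'
#' @param n Number of subjects.
#' @param noise_range Length-2 numeric, low and high noise scale.
#' @param seed Master seed; subject draws are deterministic given the master
#'   seed and the subject index.
#' @return A list with class `"cohort_spec"`.
#' @export
cohort_spec <- function(n = 20, noise_range = c(0.01, 0.02), seed = 1) {
  if (n < 1) abort("cohort needs at least one subject", class = "serotrem_config_error")
  if (any(noise_range < 0) || noise_range[1] > noise_range[2]) {
    abort("noise_range must be 0 <= low <= high", class = "serotrem_config_error")
  }
  structure(list(n = as.integer(n), noise_range = as.numeric(noise_range),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# run code under a given seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

.subject_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1009 + index) %% 2147483647)
}

# additive Gaussian noise, SD = scale * |base|; negative or zero draws are
# resampled so the perturbed values stay positive
.perturb_positive <- function(base, scale) {
  if (scale == 0) return(base)
  out <- base + rnorm(length(base), 0, scale * abs(base))
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- base[bad] + rnorm(length(bad), 0, scale * abs(base[bad]))
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Draw one simulated subject
#'
#' @param base_params Base [circuit_parameters()].
#' @param base_state Base initial [circuit_state()].
#' @param index Subject index, `1..spec$n`.
#' @param spec A [cohort_spec()].
#' @return A list with class `"subject"`: `index`, `noise_scale`, `seed`,
#'   perturbed `params` and `init`.
#' @export
make_subject <- function(base_params, base_state, index, spec = cohort_spec()) {
  if (index < 1 || index > spec$n) {
    abort("subject index out of range", class = "serotrem_config_error")
  }
  scales <- if (spec$n == 1) spec$noise_range[1] else {
    seq(spec$noise_range[1], spec$noise_range[2], length.out = spec$n)
  }
  s_i <- scales[index]
  seed_i <- .subject_seed(spec$seed, index)
  base_params <- as_circuit_parameters(base_params)
  base_state <- as_circuit_state(base_state)
  drawn <- .with_seed(seed_i, {
    p <- .perturb_positive(as.numeric(base_params), s_i)
    s <- .perturb_positive(as.numeric(base_state), s_i)
    list(p = p, s = s)
  })
  structure(list(index = index, noise_scale = s_i, seed = seed_i,
                 params = as_circuit_parameters(setNames(drawn$p, .param_names)),
                 init = as_circuit_state(setNames(drawn$s, .state_names))),
            class = "subject")
}

# condition windows per scenario (s); drn-damage conditions are separate
# runs, so its windows all span the full horizon
.scenario_windows <- function(scenario, duration = 300, damages = c(1.4, 1.6, 1.8)) {
  switch(scenario,
    "ssri" = tibble(condition = c("HEALTH", "SNC DAMAGE", "TRMT1", "TRMT2", "TRMT3"),
                    t0 = c(0, 75, 125, 175, 225),
                    t1 = c(75, 125, 175, 225, duration)),
    "snc-lesion" = tibble(condition = c("HEALTH", "LESION"),
                          t0 = c(0, 75), t1 = c(75, duration)),
    "drn-damage" = tibble(condition = c("HEALTH", paste0("DAMAGE", seq_along(damages))),
                          t0 = 0, t1 = duration),
    abort(paste0("unknown scenario: ", scenario), class = "serotrem_config_error")
  )
}

# per-window summaries of one subject's circuit trajectory + arm trace.
# settle: seconds dropped at the start of each window (transient after the
# intervention that opens the window, or the initial reach of the arm)
.measure_windows <- function(time, states, arm, windows, settle = 10) {
  purrr::pmap_dfr(windows, function(condition, t0, t1) {
    i <- which(time >= t0 + settle & time < t1)
    tr <- if (is.null(arm)) NA_real_ else {
      as.numeric(tremor_amplitude(arm, window = c(t0 + settle, t1)))
    }
    tibble(condition = condition,
           da_mean = mean(states[i, 6]),
           fiveht_mean = mean(states[i, 4]),
           drn_mean = mean(states[i, 3]),
           snc_mean = mean(states[i, 5]),
           thal_mean = mean(states[i, 2]),
           m1_mean = mean(states[i, 1]),
           tremor = tr)
  })
}

#' Run a cohort scenario experiment
#'
#' Simulates a noisy cohort through one of the three experiments and
#' summarises each condition per subject:
#'
#' * `"snc-lesion"`: moderate dopaminergic lesion at 75 s
#'   (`tauSNc` +25%, `alphaIP` +11%); conditions HEALTH / LESION. Probes the
#'   serotonergic compensation chain (SNc and DA fall, DRN and serotonin
#'   rise, thalamus and M1 fall, DA partially recovers).
#' * `"drn-damage"`: graded serotonergic lesions; one 300 s run per damage
#'   level with `tauDRN` multiplied at 75 s, plus a healthy run. The
#'   per-condition dopamine level is the mean over the condition's full run
#'   (`da_mean`); `da_steady` is the post-onset quasi-steady mean (last 50 s).
#' * `"ssri"`: strong dopaminergic lesion at 75 s (`tauSNc` +70%,
#'   `alphaIP` +333%) followed by three escalating serotonin-reuptake-blocker
#'   doses (125/175/225 s); five condition windows tiling the 300 s run.
#'
#' For windowed scenarios each condition window drops its first 10 s
#' (intervention transient; for the first window this also removes the arm's
#' initial reach) before averaging dopamine or measuring tremor.
#' Integration failures of individual subjects are recorded (`ok = FALSE`)
#' without aborting the cohort.
#'
#' @param scenario `"snc-lesion"`, `"drn-damage"` or `"ssri"`.
#' @param cohort A [cohort_spec()].
#' @param params Base circuit parameters (default: calibrated set).
#' @param base_state Base initial state (default: [reference_state()]).
#' @param damages `tauDRN` multipliers for `"drn-damage"`.
#' @param schedule Override the preset intervention schedule (windowed
#'   scenarios only); `NULL` uses the preset. Pass an empty schedule for a
#'   null-intervention control run.
#' @param arm If `TRUE` (default) the two-link arm is driven by each
#'   subject's M1 trace and tremor amplitudes are measured per window.
#' @param duration,dt Circuit horizon and step (s).
#' @param arm_params,gains,arm_dt,anchor Arm model settings, see
#'   [simulate_arm()].
#' @param keep_trajectories If `TRUE`, the per-subject circuit trajectories
#'   are returned in a long tibble (memory permitting).
#' @return A list with class `"scenario_result"`: `scenario`, `windows`,
#'   `subjects`, per-subject-per-condition `measurements`, and the cohort
#'   specification. See [condition_summary()], [tidy.scenario_result()].
#' @export
run_scenario <- function(scenario = c("ssri", "snc-lesion", "drn-damage"),
                         cohort = cohort_spec(),
                         params = calibrated_parameters(),
                         base_state = reference_state(),
                         damages = c(1.4, 1.6, 1.8),
                         schedule = NULL, arm = TRUE,
                         duration = 300, dt = 0.1,
                         arm_params = arm_parameters(),
                         gains = controller_gains(),
                         arm_dt = 0.01, anchor = "zero",
                         keep_trajectories = FALSE) {
  scenario <- match.arg(scenario)
  params <- as_circuit_parameters(params)
  base_state <- as_circuit_state(base_state)
  subjects <- purrr::map(seq_len(cohort$n), function(i) {
    make_subject(params, base_state, i, cohort)
  })
  P <- vapply(subjects, function(s) as.numeric(s$params), numeric(24))
  P <- matrix(P, nrow = 24, dimnames = list(.param_names, NULL))
  S0 <- vapply(subjects, function(s) as.numeric(s$init), numeric(8))
  S0 <- matrix(S0, nrow = 8)

  windows <- .scenario_windows(scenario, duration, damages)
  runs <- if (scenario == "drn-damage") {
    c(list(empty_schedule()), purrr::map(damages, schedule_drn_damage))
  } else {
    preset <- switch(scenario, "ssri" = schedule_ssri(), "snc-lesion" = schedule_snc_lesion())
    list(if (is.null(schedule)) preset else check_schedule(schedule))
  }

  ok <- rep(TRUE, cohort$n)
  meas <- list()
  trajs <- list()
  for (r in seq_along(runs)) {
    res <- .integrate_schedule(P, S0, runs[[r]], duration, dt,
                               method = "euler", clamp = FALSE)
    ok <- ok & res$alive
    arm_runs <- NULL
    if (arm) {
      des_sh <- matrix(NA_real_, length(res$time), cohort$n)
      des_el <- des_sh
      for (j in seq_len(cohort$n)) {
        if (!res$alive[j]) { des_sh[, j] <- 0; des_el[, j] <- 0; next }
        d <- m1_to_desired_angles(res$states[, 1, j], arm_params, anchor)
        des_sh[, j] <- d$shoulder; des_el[, j] <- d$elbow
      }
      arm_runs <- .simulate_arm_batch(des_sh, des_el, dt, duration,
                                      arm_params, gains, arm_dt)
    }
    w_r <- if (scenario == "drn-damage") windows[r, ] else windows
    for (j in seq_len(cohort$n)) {
      if (!res$alive[j]) next
      atr <- if (is.null(arm_runs)) NULL else {
        tibble(time = arm_runs$time, x = arm_runs$x[, j], y = arm_runs$y[, j])
      }
      m <- .measure_windows(res$time, res$states[, , j], atr, w_r)
      m$subject <- subjects[[j]]$index
      if (scenario == "drn-damage") {
        # condition level = mean over the condition's full run; also report
        # the post-onset quasi-steady level and measure tremor after onset
        i_full <- seq_along(res$time)
        i_steady <- which(res$time >= duration - 50)
        m$da_mean <- mean(res$states[i_full, 6, j])
        m$da_steady <- mean(res$states[i_steady, 6, j])
        if (!is.null(atr)) {
          m$tremor <- as.numeric(tremor_amplitude(atr, window = c(85, duration)))
        }
      }
      meas[[length(meas) + 1]] <- m
    }
    if (keep_trajectories) {
      for (j in seq_len(cohort$n)) {
        tj <- tibble(time = res$time)
        for (v in seq_along(.state_names)) tj[[.state_names[v]]] <- res$states[, v, j]
        tj$subject <- subjects[[j]]$index
        tj$run <- if (scenario == "drn-damage") windows$condition[r] else scenario
        trajs[[length(trajs) + 1]] <- tj
      }
    }
  }

  measurements <- dplyr::bind_rows(meas)
  measurements <- dplyr::select(measurements, "subject", "condition",
                                dplyr::everything())
  structure(list(
    scenario = scenario,
    windows = windows,
    cohort = cohort,
    params = params,
    subjects = tibble(
      subject = purrr::map_int(subjects, "index"),
      noise_scale = purrr::map_dbl(subjects, "noise_scale"),
      seed = purrr::map_int(subjects, "seed"),
      ok = ok
    ),
    measurements = measurements,
    trajectories = if (keep_trajectories) dplyr::bind_rows(trajs) else NULL,
    arm = arm
  ), class = "scenario_result")
}

#' @rdname run_scenario
#' @export
run_snc_lesion_scenario <- function(cohort = cohort_spec(), ...) {
  run_scenario("snc-lesion", cohort = cohort, ...)
}

#' @rdname run_scenario
#' @export
run_drn_damage_scenario <- function(cohort = cohort_spec(),
                                    damages = c(1.4, 1.6, 1.8), ...) {
  run_scenario("drn-damage", cohort = cohort, damages = damages, ...)
}

#' @rdname run_scenario
#' @export
run_ssri_scenario <- function(cohort = cohort_spec(), ...) {
  run_scenario("ssri", cohort = cohort, ...)
}

#' Per-condition cohort summary
#'
#' Cohort means and standard deviations of the dopamine level and tremor
#' amplitude for each condition, over the subjects that integrated
#' successfully. The summary mean is the arithmetic mean of the per-subject
#' values (the per-subject table that a repeated-measures test would be fed
#' is available via [tidy.scenario_result()]).
#'
#' @param result A `"scenario_result"`.
#' @return A tibble: condition, n, da_mean, da_sd, tremor_mean, tremor_sd.
#' @export
condition_summary <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  ok_subjects <- result$subjects$subject[result$subjects$ok]
  m <- dplyr::filter(result$measurements, .data$subject %in% ok_subjects)
  out <- dplyr::summarise(
    dplyr::group_by(m, .data$condition),
    n = dplyr::n(),
    da_sd = sd(.data$da_mean),        # sd before the mean shadows the column
    da_mean = mean(.data$da_mean),
    tremor_sd = sd(.data$tremor),
    tremor_mean = mean(.data$tremor),
    .groups = "drop"
  )
  out <- dplyr::select(out, "condition", "n", "da_mean", "da_sd",
                       "tremor_mean", "tremor_sd")
  # preserve scenario condition order
  out[match(result$windows$condition, out$condition), , drop = FALSE]
}
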