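#' Timed multiplicative parameter interventions
#'
#' An intervention schedule is a tibble with columns `time` (s), `parameter`
#' (a circuit coefficient name) and `multiplier` (> 0). At each listed time
#' the named coefficient is multiplied by the multiplier before the
#' integration step at that time; multipliers at later times compose
#' multiplicatively on the already-modified value. A lesion that raises a
#' decay coefficient by 25% is `multiplier = 1.25`; a drug that lowers one by
#' 40% is `multiplier = 0.6`.
#'
#' @param time Numeric vector of intervention times (s).
#' @param parameter Character vector of coefficient names.
#' @param multiplier Positive numeric vector.
#' @return A tibble with class `"intervention_schedule"`, sorted by time.
#' @examples
#' intervention_schedule(time = c(75, 75), parameter = c("tauSNc", "alphaIP"),
#'                       multiplier = c(1.25, 1.11))
#' @export
intervention_schedule <- function(time = numeric(), parameter = character(),
                                  multiplier = numeric()) {
  if (length(time) != length(parameter) || length(time) != length(multiplier)) {
    abort("time, parameter and multiplier must have equal length",
          class = "serotrem_config_error")
  }
  unknown <- setdiff(parameter, .param_names)
  if (length(unknown)) {
    abort(paste0("unknown parameter in schedule: ", paste(unique(unknown), collapse = ", ")),
          class = "serotrem_config_error")
  }
  if (any(!is.finite(multiplier) | multiplier <= 0)) {
    abort("intervention multipliers must be finite and > 0",
          class = "serotrem_config_error")
  }
  if (any(!is.finite(time) | time < 0)) {
    abort("intervention times must be finite and >= 0",
          class = "serotrem_config_error")
  }
  sched <- tibble(time = as.numeric(time), parameter = as.character(parameter),
                  multiplier = as.numeric(multiplier))
  sched <- dplyr::arrange(sched, .data$time)
  class(sched) <- c("intervention_schedule", class(sched))
  sched
}

empty_schedule <- function() intervention_schedule()

#' Scenario preset schedules
#'
#' Preset intervention schedules for the three in-silico experiments:
#'
#' * `schedule_snc_lesion()`: a moderate dopaminergic lesion at 75 s --
#'   the SNc decay coefficient `tauSNc` is raised by 25% (cell loss) and the
#'   indirect-pathway oscillation gain `alphaIP` by 11% (reduced efficacy of
#'   the D2 receptors damping the oscillation).
#' * `schedule_drn_damage(damage)`: a serotonergic lesion at 75 s -- the
#'   raphe decay coefficient `tauDRN` is multiplied by `damage`
#'   (1.4, 1.6 or 1.8 for the three graded damage levels).
#' * `schedule_ssri()`: a strong dopaminergic lesion at 75 s
#'   (`tauSNc` +70%, `alphaIP` +333%) followed by three escalating doses of a
#'   serotonin-reuptake blocker at 125, 175 and 225 s that bring the
#'   serotonin decay coefficient `tau5HT` to 80%, 70% and 60% of its
#'   baseline value (dose steps compose on the already-reduced value).
#'
#' @param damage Multiplier (> 1) applied to `tauDRN` at the lesion time.
#' @param t_lesion Lesion onset time (s).
#' @return An [intervention_schedule()].
#' @name schedule_presets
NULL

#' @rdname schedule_presets
#' @export
schedule_snc_lesion <- function(t_lesion = 75) {
  intervention_schedule(time = c(t_lesion, t_lesion),
                        parameter = c("tauSNc", "alphaIP"),
                        multiplier = c(1.25, 1.11))
}

#' @rdname schedule_presets
#' @export
schedule_drn_damage <- function(damage = 1.8, t_lesion = 75) {
  stopifnot(is.numeric(damage), length(damage) == 1, damage >= 1)
  if (damage == 1) return(empty_schedule())
  intervention_schedule(time = t_lesion, parameter = "tauDRN", multiplier = damage)
}

#' @rdname schedule_presets
#' @export
schedule_ssri <- function(t_lesion = 75) {
  doses <- c(0.8, 0.7, 0.6)                      # of baseline tau5HT
  steps <- doses / c(1, doses[-length(doses)])   # compose on current value
  intervention_schedule(
    time = c(t_lesion, t_lesion, 125, 175, 225),
    parameter = c("tauSNc", "alphaIP", "tau5HT", "tau5HT", "tau5HT"),
    multiplier = c(1.70, 4.33, steps)
  )
}
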