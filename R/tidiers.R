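#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration: the per-generation trace
#'
#' @param x A `"circuit_calibration"`.
#' @param ... Unused.
#' @return Tibble with one row per generation: best/mean score, best
#'   fitness, best meanAPE, number of divergent candidates.
#' @method tidy circuit_calibration
#' @export
tidy.circuit_calibration <- function(x, ...) {
  x$trace
}

#' One-row summary of a calibration
#'
#' @param x A `"circuit_calibration"`.
#' @param ... Unused.
#' @return One-row tibble: meanAPE, meanPhys, meanPark, aggregate fitness,
#'   GA settings, and whether the 0.003 meanAPE calibration criterion is met.
#' @method glance circuit_calibration
#' @export
glance.circuit_calibration <- function(x, ...) {
  tibble(
    meanAPE = x$components$meanAPE,
    meanPhys = x$components$meanPhys,
    meanPark = x$components$meanPark,
    fitness = x$components$fitness,
    generations = x$config$generations,
    pop_size = x$config$pop_size,
    converged = x$components$meanAPE <= 0.003
  )
}

#' Tidy a scenario result: per-subject, per-condition measurements
#'
#' The long table a repeated-measures analysis would be fed: one row per
#' subject and condition with the dopamine level (nM), the windowed means
#' of the other circuit variables, and the tremor amplitude (m).
#'
#' @param x A `"scenario_result"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) {
  x$measurements
}

#' One-row summary of a scenario run
#'
#' @param x A `"scenario_result"`.
#' @param ... Unused.
#' @return One-row tibble: scenario, subjects (total and integrated), number
#'   of conditions, master seed.
#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  tibble(
    scenario = x$scenario,
    n_subjects = x$cohort$n,
    n_ok = sum(x$subjects$ok),
    n_conditions = nrow(x$windows),
    seed = x$cohort$seed
  )
}
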