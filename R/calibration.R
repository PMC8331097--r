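#' Parameter search space for calibration
#'
#' Per-coefficient box bounds around a seed vector. The default search
#' explores `[0.2, 5]` times the literature seed values. Collapsing a
#' coefficient's bounds onto its seed (`lower = upper = 1`) fixes it, which
#' is how reduced searches are expressed.
#'
#' @param seed Seed parameter vector (default: [default_parameters()]).
#' @param lower,upper Either scalars (multiples of the seed applied to every
#'   coefficient) or full named vectors of absolute bounds.
#' @param fix Optional character vector of coefficient names to fix at their
#'   seed value.
#' @return A list with class `"search_space"`: `seed`, `lower`, `upper`.
#' @export
search_space <- function(seed = default_parameters(), lower = 0.2, upper = 5,
                         fix = NULL) {
  seed <- as_circuit_parameters(seed)
  lo <- if (length(lower) == 1) as.numeric(seed) * lower else as.numeric(as_circuit_parameters(lower))
  hi <- if (length(upper) == 1) as.numeric(seed) * upper else as.numeric(as_circuit_parameters(upper))
  lo <- setNames(lo, .param_names); hi <- setNames(hi, .param_names)
  if (!is.null(fix)) {
    unknown <- setdiff(fix, .param_names)
    if (length(unknown)) {
      abort(paste0("unknown parameter(s) in fix: ", paste(unknown, collapse = ", ")),
            class = "serotrem_config_error")
    }
    lo[fix] <- seed[fix]; hi[fix] <- seed[fix]
  }
  if (any(lo <= 0) || any(hi < lo)) {
    abort("search bounds must be positive with lower <= upper",
          class = "serotrem_config_error")
  }
  if (any(seed < lo - 1e-12) || any(seed > hi + 1e-12)) {
    abort("seed vector must lie within the search bounds",
          class = "serotrem_config_error")
  }
  structure(list(seed = seed, lower = lo, upper = hi), class = "search_space")
}

#' Genetic-algorithm configuration
#'
#' Generational GA with tournament selection, per-gene blend (BLX-alpha)
#' crossover, annealed per-gene lognormal mutation, and single-individual
#' elitism. The aggregate objective combines three components: the
#' steady-state mean absolute percentage error against the reference
#' (minimised), the healthy-model dopamine oscillation amplitude
#' (minimised) and the lesioned-model oscillation amplitude (rewarded),
#' weighted by `weights` and normalised by their sum:
#' `(w_ape (1 - meanAPE) + w_phys (1 - meanPhys) + w_park min(meanPark, 1)) / sum(w)`.
#' A proximity regulariser `proximity_weight * mean(|log(p / seed)|)`
#' (subtracted from the objective) keeps parameter directions that the
#' steady states cannot identify at their seed values; set
#' `proximity_weight = 0` to disable it.
#'
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param tournament Tournament size for parent selection.
#' @param blend_alpha BLX-alpha crossover expansion factor.
#' @param mutation_rate Per-gene mutation probability.
#' @param mutation_sd Initial SD of the lognormal mutation factor.
#' @param mutation_decay Per-generation multiplicative decay of the mutation
#'   SD (annealing); `1` keeps it constant.
#' @param proximity_weight Weight of the proximity regulariser.
#' @param weights Named weights `c(ape=, phys=, park=)` of the objective
#'   components.
#' @param eval_duration Horizon (s) of each candidate evaluation run.
#' @param osc_window Trailing window (s) over which the oscillation
#'   amplitude components are measured.
#' @param seed RNG seed; the whole calibration is deterministic given it.
#' @return A list with class `"ga_config"`.
#' @export
ga_config <- function(pop_size = 30, generations = 300, tournament = 3,
                      blend_alpha = 0.5, mutation_rate = 0.2,
                      mutation_sd = 0.10, mutation_decay = 0.98,
                      proximity_weight = 0.2,
                      weights = c(ape = 1, phys = 1, park = 0.5),
                      eval_duration = 150, osc_window = 50, seed = 1) {
  if (pop_size < 2 || generations < 1) {
    abort("pop_size >= 2 and generations >= 1 required",
          class = "serotrem_config_error")
  }
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament),
                 blend_alpha = blend_alpha, mutation_rate = mutation_rate,
                 mutation_sd = mutation_sd, mutation_decay = mutation_decay,
                 proximity_weight = proximity_weight,
                 weights = weights, eval_duration = eval_duration,
                 osc_window = osc_window, seed = as.integer(seed)),
            class = "ga_config")
}

# lesion used for the "parkinsonian oscillation" component of the objective
.park_lesion <- c(tauSNc = 1.25, alphaIP = 1.11)

# evaluate a 24 x n population: healthy steady state + oscillation, and
# oscillation under the reference dopaminergic lesion
.evaluate_population <- function(P, reference, config) {
  n <- ncol(P)
  S0 <- matrix(as.numeric(reference), 8, n)
  dt <- 0.1
  dur <- config$eval_duration
  h <- .integrate_segment(P, S0, round(dur / dt), dt, 0, "euler", FALSE)
  Pl <- P
  for (nm in names(.park_lesion)) Pl[nm, ] <- Pl[nm, ] * .park_lesion[[nm]]
  l <- .integrate_segment(Pl, S0, round(dur / dt), dt, 0, "euler", FALSE)
  nt <- round(dur / dt) + 1
  i_ss <- (nt - round(10 / dt)):nt
  i_osc <- (nt - round(config$osc_window / dt)):nt
  ref <- as.numeric(reference)
  meanAPE <- rep(1, n); phys <- rep(1, n); park <- numeric(n)
  alive <- h$alive & l$alive
  for (j in which(alive)) {
    ss <- colMeans(h$states[i_ss, , j])
    meanAPE[j] <- mean(abs(ss - ref) / abs(ref))
    phys[j] <- oscillation_amplitude(h$states[i_osc, 6, j])
    park[j] <- oscillation_amplitude(l$states[i_osc, 6, j])
  }
  w <- config$weights
  fitness <- (w[["ape"]] * (1 - pmin(meanAPE, 1)) +
                w[["phys"]] * (1 - pmin(phys, 1)) +
                w[["park"]] * pmin(park, 1)) / sum(w)
  fitness[!alive] <- 0
  list(meanAPE = meanAPE, phys = phys, park = park,
       fitness = fitness, alive = alive)
}

.proximity_penalty <- function(P, seed_vec, weight) {
  if (weight == 0) return(numeric(ncol(P)))
  weight * colMeans(abs(log(P / as.numeric(seed_vec))))
}

#' Evaluate one candidate parameter vector
#'
#' Simulates the healthy model to a steady state and measures the mean
#' absolute percentage error against the reference (`meanAPE`), the
#' dopamine oscillation amplitude of the healthy model (`meanPhys`,
#' minimised) and of the model under the reference dopaminergic lesion
#' (`tauSNc` +25%, `alphaIP` +11%; `meanPark`, rewarded). Component
#' fitnesses are reported in their `1 - metric` form alongside the
#' aggregate objective (see [ga_config()]).
#'
#' @param params Candidate [circuit_parameters()].
#' @param reference Reference steady state.
#' @param config A [ga_config()] (weights and evaluation windows).
#' @param space A [search_space()]; needed only for the proximity term.
#' @return A one-row tibble with class `"fitness_components"`.
#' @export
evaluate_candidate <- function(params, reference = reference_state(),
                               config = ga_config(), space = search_space()) {
  params <- as_circuit_parameters(params)
  P <- matrix(params, 24, 1, dimnames = list(.param_names, NULL))
  ev <- .evaluate_population(P, as_circuit_state(reference), config)
  pen <- .proximity_penalty(P, space$seed, config$proximity_weight)
  out <- tibble(
    meanAPE = ev$meanAPE, meanPhys = ev$phys, meanPark = ev$park,
    fitness_ape = 1 - ev$meanAPE, fitness_phys = 1 - ev$phys,
    fitness_park = 1 - ev$park,
    fitness = ev$fitness, penalty = pen, score = ev$fitness - pen,
    diverged = !ev$alive
  )
  class(out) <- c("fitness_components", class(out))
  out
}

#' Calibrate the circuit with a genetic algorithm
#'
#' Generational GA over the 24 circuit coefficients, seeded at the
#' literature values, maximising the aggregate objective of
#' [evaluate_candidate()] minus the proximity regulariser. Selection is by
#' tournament; children are produced by per-gene BLX-alpha blend crossover,
#' then mutated per-gene by a lognormal factor whose spread anneals across
#' generations (coarse exploration early, fine refinement late); bounds are
#' enforced by clipping; the best individual survives unchanged (elitism),
#' so the best score is non-decreasing. Divergent candidates receive
#' worst-case fitness and are counted in the trace, not raised as errors.
#' The whole run is deterministic given `config$seed`.
#'
#' @param space A [search_space()].
#' @param config A [ga_config()].
#' @param reference Reference steady state to fit (default
#'   [reference_state()]).
#' @return An object of class `"circuit_calibration"`: `params` (best
#'   candidate), `components` (its [evaluate_candidate()] row), `trace`
#'   (per-generation tibble), plus the inputs. Supports [generics::tidy()]
#'   and [generics::glance()].
#' @examples
#' \donttest{
#' fit <- calibrate_circuit(config = ga_config(generations = 20))
#' glance(fit)
#' }
#' @export
calibrate_circuit <- function(space = search_space(), config = ga_config(),
                              reference = reference_state()) {
  reference <- as_circuit_state(reference)
  seed_vec <- as.numeric(space$seed)
  lo <- as.numeric(space$lower); hi <- as.numeric(space$upper)
  npar <- length(seed_vec)
  n <- config$pop_size

  .with_seed(config$seed, {
    P <- matrix(rep(seed_vec, n), npar, n, dimnames = list(.param_names, NULL))
    for (j in seq_len(n)[-1]) {
      P[, j] <- pmin(hi, pmax(lo, seed_vec * exp(rnorm(npar, 0, 0.1))))
    }
    ev <- .evaluate_population(P, reference, config)
    if (!any(ev$alive)) {
      abort("all candidates divergent in generation 0",
            class = "serotrem_config_error")
    }
    score <- ev$fitness - .proximity_penalty(P, space$seed, config$proximity_weight)
    score[!ev$alive] <- -Inf
    trace <- vector("list", config$generations)
    for (g in seq_len(config$generations)) {
      sdg <- config$mutation_sd * config$mutation_decay^g
      elite <- which.max(score)
      newP <- matrix(NA_real_, npar, n, dimnames = list(.param_names, NULL))
      newP[, 1] <- P[, elite]
      for (j in seq_len(n)[-1]) {
        i1 <- sample.int(n, config$tournament)
        i2 <- sample.int(n, config$tournament)
        a <- P[, i1[which.max(score[i1])]]
        b <- P[, i2[which.max(score[i2])]]
        blo <- pmin(a, b) - config$blend_alpha * abs(a - b)
        bhi <- pmax(a, b) + config$blend_alpha * abs(a - b)
        child <- blo + runif(npar) * (bhi - blo)
        mut <- runif(npar) < config$mutation_rate
        if (any(mut)) child[mut] <- child[mut] * exp(rnorm(sum(mut), 0, sdg))
        newP[, j] <- pmin(hi, pmax(lo, child))
      }
      P <- newP
      ev <- .evaluate_population(P, reference, config)
      score <- ev$fitness - .proximity_penalty(P, space$seed, config$proximity_weight)
      score[!ev$alive] <- -Inf
      b <- which.max(score)
      trace[[g]] <- tibble(generation = g, best_score = score[b],
                           best_fitness = ev$fitness[b],
                           best_meanAPE = ev$meanAPE[b],
                           mean_score = mean(score[is.finite(score)]),
                           n_divergent = sum(!ev$alive))
    }
    best <- which.max(score)
    best_params <- as_circuit_parameters(setNames(P[, best], .param_names))
    structure(list(
      params = best_params,
      components = evaluate_candidate(best_params, reference, config, space),
      trace = dplyr::bind_rows(trace),
      space = space, config = config, reference = reference
    ), class = "circuit_calibration")
  })
}

#' @export
print.circuit_calibration <- function(x, ...) {
  cat("<circuit_calibration>\n")
  cat(sprintf("  generations: %d  population: %d\n",
              x$config$generations, x$config$pop_size))
  cat(sprintf("  best meanAPE: %.5f  fitness: %.4f\n",
              x$components$meanAPE, x$components$fitness))
  invisible(x)
}
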