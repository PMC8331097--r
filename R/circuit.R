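#' Instantaneous derivatives of the circuit equations
#'
#' Evaluates the right-hand side of the eight coupled equations at a given
#' state and time. Each variable has a linear decay term; the thalamus is
#' excited by the direct pathway and inhibited by the indirect pathway; the
#' raphe nucleus (DRN) is inhibited by motor cortex and weakly excited by
#' SNc; striatal serotonin follows DRN activity; SNc is inhibited by DRN;
#' striatal dopamine release is proportional to the product of serotonin
#' concentration and SNc activity; and the indirect pathway carries a
#' sinusoidal drive of amplitude `alphaIP / max(DA, 1e-3)` whose
#' amplification under dopamine loss is the tremor source.
#'
#' @param state A [circuit_state()] (or named vector with the 8 variables).
#' @param params A [circuit_parameters()] set.
#' @param t Time (s), entering through the oscillatory term `sin(fIP * t)`.
#' @return Named numeric vector of derivatives (Hz/s or nM/s).
#' @examples
#' circuit_derivatives(reference_state(), default_parameters(), t = 0)
#' @export
circuit_derivatives <- function(state, params, t = 0) {
  params <- as_circuit_parameters(params)
  state <- unlist(state)[.state_names]
  if (any(!is.finite(state))) {
    abort(paste0("non-finite state variable: ",
                 paste(.state_names[!is.finite(state)], collapse = ", ")),
          class = "serotrem_integration_failure")
  }
  S <- matrix(state, nrow = 8)
  r <- .circuit_rate(S, as.list(params), t)
  setNames(as.numeric(r), .state_names)
}

# vectorised right-hand side: S is 8 x n, P a list of 24 scalars-or-n-vectors
.circuit_rate <- function(S, P, t) {
  DAg <- pmax(S[6, ], .eps_da)
  rbind(
    P$a1Thal * S[2, ] - P$tauM1 * S[1, ],
    P$a2Ex + P$a2DP * S[7, ] - P$a2IP * S[8, ] - P$tauThal * S[2, ],
    P$a3Ex - P$a3M1 * S[1, ] + P$a3SNc * S[5, ] - P$tauDRN * S[3, ],
    P$a4DRN * S[3, ] - P$tau5HT * S[4, ],
    P$a5Ex - P$a5DRN * S[3, ] - P$tauSNc * S[5, ],
    P$G * S[4, ] * S[5, ] - P$tauDA * S[6, ],
    P$a7Ex + P$a7DA * S[6, ] - P$tauDP * S[7, ],
    P$a8Ex - P$tauIP * S[8, ] + P$alphaIP * sin(P$fIP * t) / DAg
  )
}

.overflow_guard <- 1e8

# fixed-step integration of n parallel runs over one constant-parameter
# segment. P: 24 x n matrix (rows in .param_names order); S0: 8 x n.
# Euler is unrolled for speed (the cohort and GA loops live here);
# RK4 goes through .circuit_rate.
.integrate_segment <- function(P, S0, nstep, dt, t0, method = "euler",
                               clamp = FALSE) {
  n <- ncol(S0)
  out <- array(NA_real_, c(nstep + 1, 8, n))
  out[1, , ] <- S0
  S <- S0
  alive <- rep(TRUE, n)
  first_bad <- rep(NA_integer_, n)   # step index of first blow-up
  Pl <- lapply(seq_len(24), function(i) P[i, ])
  names(Pl) <- .param_names
  for (i in seq_len(nstep)) {
    t <- t0 + (i - 1) * dt
    if (method == "euler") {
      M1 <- S[1, ]; Th <- S[2, ]; DR <- S[3, ]; HT <- S[4, ]
      SN <- S[5, ]; DA <- S[6, ]; DP <- S[7, ]; IP <- S[8, ]
      DAg <- pmax(DA, .eps_da)
      S[1, ] <- M1 + dt * (Pl$a1Thal * Th - Pl$tauM1 * M1)
      S[2, ] <- Th + dt * (Pl$a2Ex + Pl$a2DP * DP - Pl$a2IP * IP - Pl$tauThal * Th)
      S[3, ] <- DR + dt * (Pl$a3Ex - Pl$a3M1 * M1 + Pl$a3SNc * SN - Pl$tauDRN * DR)
      S[4, ] <- HT + dt * (Pl$a4DRN * DR - Pl$tau5HT * HT)
      S[5, ] <- SN + dt * (Pl$a5Ex - Pl$a5DRN * DR - Pl$tauSNc * SN)
      S[6, ] <- DA + dt * (Pl$G * HT * SN - Pl$tauDA * DA)
      S[7, ] <- DP + dt * (Pl$a7Ex + Pl$a7DA * DA - Pl$tauDP * DP)
      S[8, ] <- IP + dt * (Pl$a8Ex - Pl$tauIP * IP + Pl$alphaIP * sin(Pl$fIP * t) / DAg)
    } else {
      k1 <- .circuit_rate(S, Pl, t)
      k2 <- .circuit_rate(S + dt / 2 * k1, Pl, t + dt / 2)
      k3 <- .circuit_rate(S + dt / 2 * k2, Pl, t + dt / 2)
      k4 <- .circuit_rate(S + dt * k3, Pl, t + dt)
      S <- S + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (clamp) S[S < 0] <- 0
    tot <- colSums(abs(S))
    bad <- (!is.finite(tot) | tot > .overflow_guard) & alive
    if (any(bad)) {
      first_bad[bad] <- i
      alive[bad] <- FALSE
      S[, bad] <- 0
    }
    out[i + 1, , ] <- S
  }
  list(states = out, final = S, alive = alive, first_bad = first_bad)
}

# run a full schedule for n parallel runs; P is 24 x n (per-run parameters
#  allowed); the schedule is shared. Intervention times are snapped to the
# step grid; multipliers compose on the current (possibly already modified)
# coefficient value.
.integrate_schedule <- function(P, S0, schedule, duration, dt, method, clamp) {
  n <- ncol(S0)
  ntot <- round(duration / dt)
  snap <- if (nrow(schedule)) round(schedule$time / dt) * dt else numeric()
  if (any(snap > duration)) {
    abort("intervention time beyond the simulation horizon",
          class = "serotrem_config_error")
  }
  bounds <- sort(unique(c(0, snap[snap < duration], duration)))
  states <- array(NA_real_, c(ntot + 1, 8, n))
  alive <- rep(TRUE, n)
  bad_at <- rep(NA_real_, n)
  Pcur <- P
  S <- S0
  row <- 1
  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]
    for (h in which(abs(snap - t0) < dt / 2)) {
      Pcur[schedule$parameter[h], ] <- Pcur[schedule$parameter[h], ] * schedule$multiplier[h]
    }
    nstep <- round((bounds[k + 1] - t0) / dt)
    res <- .integrate_segment(Pcur, S, nstep, dt, t0, method, clamp)
    newly_bad <- alive & !res$alive
    bad_at[newly_bad] <- t0 + (res$first_bad[newly_bad] - 1) * dt
    alive <- alive & res$alive
    states[row:(row + nstep), , ] <- res$states
    row <- row + nstep
    S <- res$final
  }
  list(time = seq(0, duration, by = dt), states = states, alive = alive,
       bad_at = bad_at, params_final = Pcur)
}

#' Simulate the circuit under an intervention schedule
#'
#' Fixed-step integration of the eight circuit equations over `[0, duration]`.
#' The default scheme is explicit Euler at `dt = 0.1` s; a classical
#' fourth-order Runge-Kutta scheme is available via `method = "rk4"`.
#' Interventions multiply the named coefficient at their scheduled time
#' (cumulatively on the current value) before the step at that time.
#'
#' @param params A [circuit_parameters()] set. Defaults to the calibrated set.
#' @param schedule An [intervention_schedule()] or `NULL`.
#' @param duration Simulation horizon (s).
#' @param dt Integration step (s); `duration / dt` must be integral.
#' @param init Initial [circuit_state()].
#' @param method `"euler"` (default) or `"rk4"`.
#' @param clamp If `TRUE`, clip state variables at zero after each step.
#'   The dopamine denominator guard (`max(DA, 1e-3)` nM) is always active,
#'   independent of this option.
#' @return A tibble with class `"circuit_trajectory"`: column `time` plus one
#'   column per circuit variable, one row per accepted step
#'   (`duration / dt + 1` rows).
#' @examples
#' traj <- simulate_circuit(duration = 20)
#' tail(traj, 3)
#' @export
simulate_circuit <- function(params = calibrated_parameters(), schedule = NULL,
                             duration = 300, dt = 0.1,
                             init = reference_state(),
                             method = c("euler", "rk4"), clamp = FALSE) {
  method <- match.arg(method)
  params <- validate_circuit_parameters(as_circuit_parameters(params))
  init <- as_circuit_state(init)
  check_time_grid(duration, dt)
  schedule <- check_schedule(schedule)
  res <- .integrate_schedule(matrix(params, 24, 1, dimnames = list(.param_names, NULL)),
                             matrix(init, 8, 1), schedule, duration, dt, method, clamp)
  if (!res$alive[1]) {
    # identify the variable that left the admissible range first
    idx <- which(res$time >= res$bad_at[1])[1] + 1
    snap <- res$states[min(idx, length(res$time)), , 1]
    v <- .state_names[which.max(abs(ifelse(is.finite(snap), snap, Inf)))]
    abort(sprintf("integration blew up at t = %.3f s (variable %s)",
                  res$bad_at[1], v),
          class = "serotrem_integration_failure")
  }
  traj <- tibble(time = res$time)
  for (j in seq_along(.state_names)) traj[[.state_names[j]]] <- res$states[, j, 1]
  structure(traj,
            class = c("circuit_trajectory", class(traj)),
            params = params, schedule = schedule, dt = dt, method = method)
}

check_time_grid <- function(duration, dt) {
  if (!is.numeric(dt) || dt <= 0) {
    abort("dt must be > 0", class = "serotrem_config_error")
  }
  if (!is.numeric(duration) || duration <= 0 ||
      abs(duration / dt - round(duration / dt)) > 1e-8) {
    abort("duration must be positive and an integer multiple of dt",
          class = "serotrem_config_error")
  }
  invisible(TRUE)
}

check_schedule <- function(schedule) {
  if (is.null(schedule)) return(empty_schedule())
  if (!inherits(schedule, "intervention_schedule")) {
    schedule <- intervention_schedule(schedule$time, schedule$parameter,
                                      schedule$multiplier)
  }
  schedule
}

#' Steady state of the circuit
#'
#' Integrates the circuit and returns the time-averaged state over a trailing
#' window once consecutive windowed means agree to within `tol` (maximum
#' relative change over the eight variables). Averaging over a 10 s window
#' removes the indirect-pathway oscillation (period about 1 s), so the value
#' reported for `IP` is its mean level.
#'
#' @inheritParams simulate_circuit
#' @param window Averaging window length (s).
#' @param tol Relative change between successive windowed means declared
#'   converged. The default (1%) sits above the irreducible wobble that the
#'   sinusoidal indirect-pathway component leaves in a 10 s windowed mean
#'   (about 0.5% of the IP level at the calibrated oscillation frequency),
#'   so convergence reflects the decay of the genuine transient.
#' @return A `"circuit_state"` vector of windowed means, with attributes
#'   `converged` (logical) and `t_converged` (end time of the accepted
#'   window, s). If the horizon ends before convergence a warning is issued
#'   and the last windowed mean is returned with `converged = FALSE`.
#' @examples
#' steady_state(calibrated_parameters())
#' @export
steady_state <- function(params = calibrated_parameters(), duration = 300,
                         dt = 0.1, init = reference_state(),
                         method = c("euler", "rk4"), clamp = FALSE,
                         window = 10, tol = 0.01) {
  method <- match.arg(method)
  traj <- simulate_circuit(params, NULL, duration, dt, init, method, clamp)
  M <- as.matrix(traj[, .state_names])
  wlen <- round(window / dt)
  nwin <- floor(nrow(M) / wlen)
  if (nwin < 2) {
    abort("horizon too short for two averaging windows",
          class = "serotrem_config_error")
  }
  prev <- NULL
  for (k in seq_len(nwin)) {
    idx <- ((k - 1) * wlen + 1):(k * wlen)
    cur <- colMeans(M[idx, , drop = FALSE])
    if (!is.null(prev)) {
      # absolute floor so states decaying to zero register as converged
      rel <- abs(cur - prev) / pmax(abs(prev), 1e-8)
      if (max(rel) < tol) {
        out <- as_circuit_state(cur)
        attr(out, "converged") <- TRUE
        attr(out, "t_converged") <- k * wlen * dt
        return(out)
      }
    }
    prev <- cur
  }
  warn(sprintf("steady state not converged within %g s; returning last windowed mean",
               duration),
       class = "serotrem_no_convergence")
  out <- as_circuit_state(prev)
  attr(out, "converged") <- FALSE
  attr(out, "t_converged") <- NA_real_
  out
}

#' Mean absolute percentage error between two circuit states
#'
#' The calibration loss: the mean over the eight variables of
#' `|estimate - reference| / |reference|`, as a fraction (0.01 = 1%).
#'
#' @param estimate,reference Circuit states (named vectors over the 8
#'   variables); every reference entry must be nonzero.
#' @return A single non-negative number.
#' @examples
#' mean_ape(reference_state(), reference_state())
#' @export
mean_ape <- function(estimate, reference) {
  e <- unlist(estimate)[.state_names]
  r <- unlist(reference)[.state_names]
  if (any(!is.finite(e))) return(Inf)
  if (any(r == 0 | !is.finite(r))) {
    abort("mean_ape undefined: reference contains zero or non-finite entries",
          class = "serotrem_metric_error")
  }
  mean(abs(e - r) / abs(r))
}

#' Write / read a circuit trajectory as CSV
#'
#' Column order is `time,M1,Thal,DRN,fiveHT,SNc,DA,DP,IP`; values carry at
#' least 9 significant digits so a round trip preserves the dynamics.
#'
#' @param traj A `"circuit_trajectory"` tibble.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns the trajectory tibble.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("time", .state_names)
  m <- vapply(cols, function(cl) sprintf("%.10g", traj[[cl]]), character(nrow(traj)))
  utils::write.table(m, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = cols)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  traj <- as_tibble(df)
  class(traj) <- c("circuit_trajectory", class(traj))
  traj
}
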