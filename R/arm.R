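#' Two-link arm physical parameters
#'
#' Planar, gravity-free two-link arm with canonical human upper-limb
#' constants: link lengths (m), masses (kg), centre-of-mass distances from
#' the proximal joint (m) and moments of inertia about the centre of mass
#' (kg m^2). The shoulder is anchored at the origin of the horizontal
#' workspace. Joint conventions: the shoulder angle is measured from the +x
#' axis (limits -60 to 150 degrees); the elbow angle is the interior angle
#' between upper arm and forearm, so 180 degrees is the fully extended arm
#' (limits 0 to 180 degrees).
#'
#' @param l1,l2 Link lengths (m): upper arm, forearm(+hand).
#' @param m1,m2 Link masses (kg).
#' @param lc1,lc2 Centre-of-mass distances (m).
#' @param i1,i2 Moments of inertia about the COM (kg m^2).
#' @param shoulder_limits,elbow_limits Joint limits in radians.
#' @return A list with class `"arm_parameters"`.
#' @export
arm_parameters <- function(l1 = 0.30, l2 = 0.35, m1 = 1.9, m2 = 1.1,
                           lc1 = 0.15, lc2 = 0.175,
                           i1 = 0.0141, i2 = 0.0120,
                           shoulder_limits = c(-60, 150) * pi / 180,
                           elbow_limits = c(0, 180) * pi / 180) {
  vals <- c(l1 = l1, l2 = l2, m1 = m1, m2 = m2, lc1 = lc1, lc2 = lc2,
            i1 = i1, i2 = i2)
  if (any(!is.finite(vals) | vals <= 0)) {
    abort("arm lengths, masses and inertias must be positive",
          class = "serotrem_config_error")
  }
  structure(list(l1 = l1, l2 = l2, m1 = m1, m2 = m2, lc1 = lc1, lc2 = lc2,
                 i1 = i1, i2 = i2, shoulder_limits = shoulder_limits,
                 elbow_limits = elbow_limits),
            class = "arm_parameters")
}

#' Proportional-derivative controller gains
#'
#' Defaults capture visco-elastic properties of the human arm:
#' stiffness 20 (shoulder) and 10 (elbow) Nm/rad, damping 1.5 and 1.0
#' Nm s/rad.
#'
#' @param kp,kd Length-2 vectors `(shoulder, elbow)`.
#' @return A list with class `"controller_gains"`.
#' @export
controller_gains <- function(kp = c(shoulder = 20, elbow = 10),
                             kd = c(shoulder = 1.5, elbow = 1.0)) {
  if (any(!is.finite(c(kp, kd)) | c(kp, kd) <= 0)) {
    abort("controller gains must be positive", class = "serotrem_config_error")
  }
  structure(list(kp = unname(kp), kd = unname(kd)), class = "controller_gains")
}

#' PD controller torque
#'
#' `T = Kp (A_des - A_cur) - Kd * velocity`, element-wise over the
#' `(shoulder, elbow)` pair.
#'
#' @param desired,current Angle pairs (rad).
#' @param velocity Angular velocity pair (rad/s).
#' @param gains A [controller_gains()] object.
#' @return Torque pair (Nm).
#' @examples
#' pd_torque(c(0.1, 0.2), c(0, 0), c(0, 0))
#' @export
pd_torque <- function(desired, current, velocity, gains = controller_gains()) {
  if (any(!is.finite(c(desired, current, velocity)))) {
    abort("non-finite input to pd_torque", class = "serotrem_state_error")
  }
  gains$kp * (desired - current) - gains$kd * velocity
}

#' Forward kinematics of the arm endpoint
#'
#' @param shoulder,elbow Angles in radians (elbow: interior angle).
#' @param params An [arm_parameters()] object.
#' @return A tibble with columns `x`, `y` (m).
#' @export
forward_kinematics <- function(shoulder, elbow, params = arm_parameters()) {
  q1 <- shoulder
  q2 <- pi - elbow   # relative rotation of the forearm
  tibble(x = params$l1 * cos(q1) + params$l2 * cos(q1 + q2),
         y = params$l1 * sin(q1) + params$l2 * sin(q1 + q2))
}

# rigid-body dynamics in rotation coordinates (q1 = shoulder, q2 = relative
# forearm rotation = pi - interior elbow angle); all arguments are length-n
# vectors, tau is a list(t1, t2). Returns accelerations list(a1, a2).
.arm_accel <- function(q2, qd1, qd2, tau, ap) {
  c2 <- cos(q2)
  h11 <- ap$i1 + ap$m1 * ap$lc1^2 + ap$i2 +
    ap$m2 * (ap$l1^2 + ap$lc2^2 + 2 * ap$l1 * ap$lc2 * c2)
  h12 <- ap$i2 + ap$m2 * (ap$lc2^2 + ap$l1 * ap$lc2 * c2)
  h22 <- ap$i2 + ap$m2 * ap$lc2^2
  h <- ap$m2 * ap$l1 * ap$lc2 * sin(q2)
  rhs1 <- tau[[1]] + h * qd2^2 + 2 * h * qd1 * qd2
  rhs2 <- tau[[2]] - h * qd1^2
  det <- h11 * h22 - h12^2
  if (any(det < 1e-12)) {
    abort("singular arm inertia matrix (degenerate parameters)",
          class = "serotrem_config_error")
  }
  list(a1 = (h22 * rhs1 - h12 * rhs2) / det,
       a2 = (h11 * rhs2 - h12 * rhs1) / det)
}

# one RK4 step in rotation coordinates for n parallel arms.
# torque_fn(t, q1, q2, qd1, qd2) -> list(t1, t2), evaluated at each stage.
.arm_rk4_step <- function(t, q1, q2, qd1, qd2, torque_fn, ap, dt) {
  st <- function(tt, p1, p2, v1, v2) {
    a <- .arm_accel(p2, v1, v2, torque_fn(tt, p1, p2, v1, v2), ap)
    list(v1 = v1, v2 = v2, a1 = a$a1, a2 = a$a2)
  }
  k1 <- st(t, q1, q2, qd1, qd2)
  k2 <- st(t + dt / 2, q1 + dt / 2 * k1$v1, q2 + dt / 2 * k1$v2,
           qd1 + dt / 2 * k1$a1, qd2 + dt / 2 * k1$a2)
  k3 <- st(t + dt / 2, q1 + dt / 2 * k2$v1, q2 + dt / 2 * k2$v2,
           qd1 + dt / 2 * k2$a1, qd2 + dt / 2 * k2$a2)
  k4 <- st(t + dt, q1 + dt * k3$v1, q2 + dt * k3$v2,
           qd1 + dt * k3$a1, qd2 + dt * k3$a2)
  list(q1 = q1 + dt / 6 * (k1$v1 + 2 * k2$v1 + 2 * k3$v1 + k4$v1),
       q2 = q2 + dt / 6 * (k1$v2 + 2 * k2$v2 + 2 * k3$v2 + k4$v2),
       qd1 = qd1 + dt / 6 * (k1$a1 + 2 * k2$a1 + 2 * k3$a1 + k4$a1),
       qd2 = qd2 + dt / 6 * (k1$a2 + 2 * k2$a2 + 2 * k3$a2 + k4$a2))
}

#' Advance the arm one integration step under a fixed torque
#'
#' One classical RK4 step of the planar two-link rigid-body dynamics
#' (inertia matrix plus Coriolis/centripetal terms, no gravity) under a
#' torque held constant over the step. Joint limits are enforced by clamping
#' the angle and zeroing the offending velocity component.
#'
#' @param state List with `angles = c(shoulder, elbow)` (rad, elbow interior)
#'   and `velocities = c(shoulder, elbow)` (rad/s).
#' @param torque Torque pair (Nm) in `(shoulder, elbow)` interior-angle
#'   coordinates.
#' @param params An [arm_parameters()] object.
#' @param dt Step (s).
#' @return Updated state list.
#' @export
step_arm <- function(state, torque, params = arm_parameters(), dt = 0.01) {
  q1 <- state$angles[1]; q2 <- pi - state$angles[2]
  qd1 <- state$velocities[1]; qd2 <- -state$velocities[2]
  tau_q <- list(torque[1], -torque[2])   # conjugate torque flips with q2 = pi - elbow
  s <- .arm_rk4_step(0, q1, q2, qd1, qd2,
                     function(tt, p1, p2, v1, v2) tau_q, params, dt)
  lim <- .apply_joint_limits(s$q1, s$q2, s$qd1, s$qd2, params)
  list(angles = c(lim$q1, pi - lim$q2), velocities = c(lim$qd1, -lim$qd2))
}

# joint limits in rotation coordinates: shoulder limits direct; elbow
# interior [lo, hi] maps to q2 in [pi - hi, pi - lo]
.apply_joint_limits <- function(q1, q2, qd1, qd2, ap) {
  s_lo <- ap$shoulder_limits[1]; s_hi <- ap$shoulder_limits[2]
  e_lo <- pi - ap$elbow_limits[2]; e_hi <- pi - ap$elbow_limits[1]
  low1 <- q1 < s_lo; high1 <- q1 > s_hi
  q1[low1] <- s_lo; q1[high1] <- s_hi
  qd1[low1 | high1] <- 0
  low2 <- q2 < e_lo; high2 <- q2 > e_hi
  q2[low2] <- e_lo; q2[high2] <- e_hi
  qd2[low2 | high2] <- 0
  list(q1 = q1, q2 = q2, qd1 = qd1, qd2 = qd2)
}

#' Map an M1 firing-rate series to desired joint angles
#'
#' The single scalar motor-cortex signal drives both joints through an
#' affine map onto their anatomical ranges. With `anchor = "zero"` (default)
#' the map sends a silent cortex (0 Hz, the firing-rate floor) to the joint
#' minima (shoulder -60 deg, elbow 0 deg) and the series maximum to the
#' joint maxima (150 deg, 180 deg). With `anchor = "range"` the observed
#' series minimum (rather than 0 Hz) is sent to the joint minima; this
#' stretches the observed excursion over the full anatomical range and
#' requires a non-constant series.
#'
#' @param m1 Numeric firing-rate series (Hz).
#' @param params An [arm_parameters()] object (for the joint limits).
#' @param anchor `"zero"` or `"range"`.
#' @return A tibble with columns `shoulder`, `elbow` (rad; elbow interior),
#'   one row per sample.
#' @export
m1_to_desired_angles <- function(m1, params = arm_parameters(),
                                 anchor = c("zero", "range")) {
  anchor <- match.arg(anchor)
  lo <- if (anchor == "zero") 0 else min(m1)
  span <- max(m1) - lo
  if (span <= 0) {
    abort("M1 series is constant (or all zero): angle scaling undefined",
          class = "serotrem_config_error")
  }
  frac <- (m1 - lo) / span
  tibble(
    shoulder = params$shoulder_limits[1] +
      frac * diff(params$shoulder_limits),
    elbow = params$elbow_limits[1] + frac * diff(params$elbow_limits)
  )
}

# vectorised PD-driven arm integration for n parallel runs.
# des_sh, des_el: (n_m1 x n) desired angle matrices (rad; elbow interior)
# sampled on the circuit grid dt_m1. Returns angle and endpoint arrays on
# the arm grid.
.simulate_arm_batch <- function(des_sh, des_el, dt_m1, duration, ap, gains,
                                dt = 0.01, init = c(0, 0),
                                interp = c("zoh", "linear")) {
  interp <- match.arg(interp)
  n <- ncol(des_sh)
  nstep <- round(duration / dt)
  q1 <- rep(init[1], n); q2 <- rep(pi - init[2], n)
  qd1 <- numeric(n); qd2 <- numeric(n)
  Q1 <- matrix(NA_real_, nstep + 1, n); Q2 <- matrix(NA_real_, nstep + 1, n)
  Q1[1, ] <- q1; Q2[1, ] <- q2
  kp1 <- gains$kp[1]; kp2 <- gains$kp[2]
  kd1 <- gains$kd[1]; kd2 <- gains$kd[2]
  nm1 <- nrow(des_sh)
  for (i in seq_len(nstep)) {
    t <- (i - 1) * dt
    if (interp == "zoh") {
      j <- min(floor(t / dt_m1 + 1e-9) + 1, nm1)
      dsh <- des_sh[j, ]; del <- des_el[j, ]
    } else {
      u <- t / dt_m1
      j0 <- min(floor(u) + 1, nm1 - 1); f <- u - (j0 - 1)
      dsh <- des_sh[j0, ] * (1 - f) + des_sh[j0 + 1, ] * f
      del <- des_el[j0, ] * (1 - f) + des_el[j0 + 1, ] * f
    }
    dq2 <- pi - del
    # PD feedback evaluated at every RK4 stage; desired held over the step
    torque_fn <- function(tt, p1, p2, v1, v2) {
      list(kp1 * (dsh - p1) - kd1 * v1,
           -(kp2 * (del - (pi - p2)) - kd2 * (-v2)))
    }
    s <- .arm_rk4_step(t, q1, q2, qd1, qd2, torque_fn, ap, dt)
    lim <- .apply_joint_limits(s$q1, s$q2, s$qd1, s$qd2, ap)
    q1 <- lim$q1; q2 <- lim$q2; qd1 <- lim$qd1; qd2 <- lim$qd2
    Q1[i + 1, ] <- q1; Q2[i + 1, ] <- q2
  }
  X <- ap$l1 * cos(Q1) + ap$l2 * cos(Q1 + Q2)
  Y <- ap$l1 * sin(Q1) + ap$l2 * sin(Q1 + Q2)
  list(time = seq(0, duration, by = dt), q1 = Q1, q2 = Q2, x = X, y = Y)
}

#' Simulate the PD-controlled arm from an M1 trace
#'
#' Maps the motor-cortex firing-rate series to desired joint angles (see
#' [m1_to_desired_angles()]), resamples the command from the circuit grid to
#' the arm grid (zero-order hold by default), and integrates the rigid-body
#' dynamics with RK4 at `dt = 0.01` s under the PD controller. The arm
#' starts at rest at shoulder 0, elbow 0 (folded) unless overridden.
#'
#' @param m1 M1 firing-rate series on the circuit time grid (Hz), e.g. the
#'   `M1` column of a [simulate_circuit()] trajectory.
#' @param dt_m1 Sampling step of `m1` (s).
#' @param params An [arm_parameters()] object.
#' @param gains A [controller_gains()] object.
#' @param dt Arm integration step (s).
#' @param anchor,interp Command mapping and resampling options; see
#'   [m1_to_desired_angles()].
#' @param init Initial `(shoulder, elbow)` angles (rad; elbow interior).
#' @return A tibble with class `"arm_trace"`: columns `time`,
#'   `shoulder_angle`, `elbow_angle` (rad), `x`, `y` (m).
#' @examples
#' traj <- simulate_circuit(duration = 30)
#' trace <- simulate_arm(traj$M1, duration = 30)
#' @export
simulate_arm <- function(m1, dt_m1 = 0.1, duration = (length(m1) - 1) * dt_m1,
                         params = arm_parameters(), gains = controller_gains(),
                         dt = 0.01, anchor = c("zero", "range"),
                         interp = c("zoh", "linear"), init = c(0, 0)) {
  anchor <- match.arg(anchor)
  des <- m1_to_desired_angles(m1, params, anchor)
  res <- .simulate_arm_batch(matrix(des$shoulder, ncol = 1),
                             matrix(des$elbow, ncol = 1),
                             dt_m1, duration, params, gains, dt, init, interp)
  trace <- tibble(time = res$time,
                  shoulder_angle = res$q1[, 1],
                  elbow_angle = pi - res$q2[, 1],
                  x = res$x[, 1], y = res$y[, 1])
  structure(trace, class = c("arm_trace", class(trace)),
            params = params, gains = gains, dt = dt, anchor = anchor)
}

#' Tremor amplitude of an endpoint trace
#'
#' Quantifies tremor as the oscillation amplitude of the endpoint within a
#' time window: the endpoint positions are centred on their window mean and
#' projected onto the principal axis of their spread (so the metric is
#' invariant to rigid translation and captures the dominant oscillation
#' direction); the amplitude is the cycle-based half mean peak-to-peak
#' excursion of that projection (see [oscillation_amplitude()]). Reported in
#' meters. If fewer than two complete cycles are found the amplitude is 0
#' and the result carries `no_cycles = TRUE`.
#'
#' @param trace An `"arm_trace"` tibble (or any tibble with `time`, `x`, `y`).
#' @param window Length-2 numeric: `c(t0, t1)`, with `t0 < t1`, inside the
#'   trace. The window should span several oscillation periods.
#' @return Amplitude (m) with attributes `n_cycles`, `no_cycles`.
#' @export
tremor_amplitude <- function(trace, window = range(trace$time)) {
  if (window[1] >= window[2] || window[1] < min(trace$time) - 1e-9 ||
      window[2] > max(trace$time) + 1e-9) {
    abort("window must lie within the trace and have positive length",
          class = "serotrem_config_error")
  }
  i <- which(trace$time >= window[1] & trace$time < window[2])
  e <- cbind(trace$x[i], trace$y[i])
  ec <- sweep(e, 2, colMeans(e))
  cv <- crossprod(ec) / nrow(ec)
  if (sum(diag(cv)) < .Machine$double.eps) {
    return(structure(0, n_cycles = 0L, no_cycles = TRUE))
  }
  pc1 <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  oscillation_amplitude(as.numeric(ec %*% pc1))
}

#' Write an arm trace as CSV
#'
#' Columns `time,shoulder_angle,elbow_angle,x,y` (radians / meters).
#'
#' @param trace An `"arm_trace"` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_arm_trace <- function(trace, path) {
  cols <- c("time", "shoulder_angle", "elbow_angle", "x", "y")
  m <- vapply(cols, function(cl) sprintf("%.10g", trace[[cl]]), character(nrow(trace)))
  utils::write.table(m, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = cols)
  invisible(path)
}
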