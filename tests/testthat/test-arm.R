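test_that("PD torque follows its definition", {
  expect_equal(pd_torque(c(0.5, 0.5), c(0.5, 0.5), c(0, 0)), c(0, 0))
  # pure position error (0.1, 0.2) rad: Kp * error
  expect_equal(pd_torque(c(0.6, 0.7), c(0.5, 0.5), c(0, 0)), c(2.0, 2.0))
  # pure damping at 1 rad/s: -Kd
  expect_equal(pd_torque(c(0.5, 0.5), c(0.5, 0.5), c(1, 1)), c(-1.5, -1.0))
  expect_error(pd_torque(c(NA, 0), c(0, 0), c(0, 0)),
               class = "serotrem_state_error")
})

test_that("a torque-free resting arm stays at rest", {
  st <- list(angles = c(0.4, 1.2), velocities = c(0, 0))
  out <- step_arm(st, c(0, 0))
  expect_equal(out$angles, st$angles, tolerance = 1e-12)
  expect_equal(out$velocities, c(0, 0), tolerance = 1e-12)
})

test_that("a constant torque on a single effective link gives T/I dynamics", {
  # forearm nearly massless: shoulder behaves as one rigid body with
  # inertia I = i1 + m1 lc1^2 + i2 (+ ~0 from m2)
  ap <- arm_parameters(m2 = 1e-9, i2 = 1e-6,
                       shoulder_limits = c(-10, 10), elbow_limits = c(0, pi))
  inertia <- ap$i1 + ap$m1 * ap$lc1^2 + ap$i2
  torque <- 0.02
  st <- list(angles = c(0, pi / 2), velocities = c(0, 0))
  t_end <- 0.2
  for (k in seq_len(20)) st <- step_arm(st, c(torque, 0), ap, dt = 0.01)
  expect_equal(st$angles[1], 0.5 * (torque / inertia) * t_end^2,
               tolerance = 1e-3)
  expect_equal(st$velocities[1], (torque / inertia) * t_end, tolerance = 1e-3)
})

test_that("the PD-controlled arm settles on a reachable target without residual oscillation", {
  ap <- arm_parameters()
  g <- controller_gains()
  target <- c(0.8, 1.9)     # shoulder, interior elbow (rad)
  st <- list(angles = c(0, pi / 2), velocities = c(0, 0))
  n <- 1500                 # 15 s
  ang <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    tau <- pd_torque(target, st$angles, st$velocities, g)
    st <- step_arm(st, tau, ap, dt = 0.01)
    ang[k, ] <- st$angles
  }
  expect_equal(st$angles, target, tolerance = 1e-6)
  late <- ang[(n - 200):n, ]
  expect_lt(max(apply(late, 2, function(x) diff(range(x)))), 1e-6)
})

test_that("the M1-to-angle map hits the stated endpoints", {
  m1 <- c(10, 15, 20)
  d2r <- pi / 180
  # observed-range anchor: min -> joint minima, max -> joint maxima
  d <- m1_to_desired_angles(m1, anchor = "range")
  expect_equal(d$shoulder, c(-60, 45, 150) * d2r)
  expect_equal(d$elbow, c(0, 90, 180) * d2r)
  # zero anchor: silent cortex -> joint minima, series max -> joint maxima
  dz <- m1_to_desired_angles(c(0, 10, 20), anchor = "zero")
  expect_equal(dz$shoulder, c(-60, 45, 150) * d2r)
  expect_equal(dz$elbow, c(0, 90, 180) * d2r)
  expect_error(m1_to_desired_angles(rep(5, 10), anchor = "range"),
               class = "serotrem_config_error")
  expect_error(m1_to_desired_angles(rep(0, 10), anchor = "zero"),
               class = "serotrem_config_error")
})

test_that("trace endpoints equal the forward kinematics of the stored angles", {
  traj <- simulate_circuit(duration = 20)
  trace <- simulate_arm(traj$M1, duration = 20)
  fk <- forward_kinematics(trace$shoulder_angle, trace$elbow_angle,
                           attr(trace, "params"))
  expect_equal(trace$x, fk$x, tolerance = 1e-12)
  expect_equal(trace$y, fk$y, tolerance = 1e-12)
  expect_equal(nrow(trace), 2001)
})

test_that("joint limits clamp the angle and stop the offending motion", {
  ap <- arm_parameters(shoulder_limits = c(-0.1, 0.1), elbow_limits = c(0, pi))
  st <- list(angles = c(0.09, pi / 2), velocities = c(2, 0))
  out <- st
  for (k in seq_len(50)) out <- step_arm(out, c(0.5, 0), ap, dt = 0.01)
  expect_equal(out$angles[1], 0.1, tolerance = 1e-12)
  expect_equal(out$velocities[1], 0)
})

test_that("tremor amplitude recovers known signals and its invariances", {
  t <- seq(0, 20, by = 0.01)
  flat <- tibble::tibble(time = t, x = 0.3, y = 0.2)
  a0 <- tremor_amplitude(flat)
  expect_equal(as.numeric(a0), 0)
  expect_true(attr(a0, "no_cycles"))

  sine <- tibble::tibble(time = t, x = 0.01 * sin(2 * pi * t), y = 0.25)
  expect_equal(as.numeric(tremor_amplitude(sine)), 0.01, tolerance = 1e-3)

  # rigid translation leaves the metric unchanged; scaling is linear
  shifted <- dplyr::mutate(sine, x = .data$x + 1.7, y = .data$y - 2.2)
  expect_equal(as.numeric(tremor_amplitude(shifted)),
               as.numeric(tremor_amplitude(sine)), tolerance = 1e-12)
  scaled <- dplyr::mutate(sine, x = 3 * .data$x, y = 3 * .data$y)
  expect_equal(as.numeric(tremor_amplitude(scaled)),
               3 * as.numeric(tremor_amplitude(sine)), tolerance = 1e-9)

  # oblique oscillation is captured along its principal axis
  obli <- tibble::tibble(time = t, x = 0.006 * sin(2 * pi * t),
                         y = 0.008 * sin(2 * pi * t))
  expect_equal(as.numeric(tremor_amplitude(obli)), 0.01, tolerance = 1e-3)

  expect_error(tremor_amplitude(sine, window = c(5, 3)),
               class = "serotrem_config_error")
  expect_error(tremor_amplitude(sine, window = c(0, 100)),
               class = "serotrem_config_error")
})

test_that("arm integration shows fourth-order convergence on a smooth torque", {
  ap <- arm_parameters()
  torque_fn <- function(tt, p1, p2, v1, v2) {
    list(0.3 * sin(2 * tt), 0.1 * cos(3 * tt))
  }
  run <- function(dt, t_end = 1) {
    q1 <- 0; q2 <- pi / 2; v1 <- 0; v2 <- 0
    for (k in seq_len(round(t_end / dt))) {
      s <- serotrem:::.arm_rk4_step((k - 1) * dt, q1, q2, v1, v2,
                                    torque_fn, ap, dt)
      q1 <- s$q1; q2 <- s$q2; v1 <- s$qd1; v2 <- s$qd2
    }
    c(q1, q2)
  }
  ref <- run(1e-4)
  e1 <- sqrt(sum((run(0.04) - ref)^2))
  e2 <- sqrt(sum((run(0.02) - ref)^2))
  expect_gt(e1 / e2, 8)    # ~16x for a fourth-order scheme
  expect_lt(e1 / e2, 40)
})

test_that("with a fixed target the mechanical plus controller energy dissipates", {
  ap <- arm_parameters()
  g <- controller_gains()
  target <- c(0.5, 2.0)
  q1 <- 0; q2 <- pi - 1.0; v1 <- 0; v2 <- 0
  torque_fn <- function(tt, p1, p2, w1, w2) {
    list(g$kp[1] * (target[1] - p1) - g$kd[1] * w1,
         -(g$kp[2] * (target[2] - (pi - p2)) - g$kd[2] * (-w2)))
  }
  energy <- function(q1, q2, v1, v2) {
    c2 <- cos(q2)
    h11 <- ap$i1 + ap$m1 * ap$lc1^2 + ap$i2 +
      ap$m2 * (ap$l1^2 + ap$lc2^2 + 2 * ap$l1 * ap$lc2 * c2)
    h12 <- ap$i2 + ap$m2 * (ap$lc2^2 + ap$l1 * ap$lc2 * c2)
    h22 <- ap$i2 + ap$m2 * ap$lc2^2
    kin <- 0.5 * (h11 * v1^2 + 2 * h12 * v1 * v2 + h22 * v2^2)
    err <- c(target[1] - q1, target[2] - (pi - q2))
    kin + 0.5 * sum(g$kp * err^2)
  }
  E <- numeric(800)
  for (k in seq_len(800)) {
    s <- serotrem:::.arm_rk4_step((k - 1) * 0.01, q1, q2, v1, v2,
                                  torque_fn, ap, 0.01)
    q1 <- s$q1; q2 <- s$q2; v1 <- s$qd1; v2 <- s$qd2
    E[k] <- energy(q1, q2, v1, v2)
  }
  expect_true(all(diff(E) < 1e-8))
})
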