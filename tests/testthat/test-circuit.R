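test_that("derivatives match hand evaluations at the reference point", {
  d <- circuit_derivatives(reference_state(), default_parameters(), t = 0)
  # serotonin release balance: 1.1951 * 1.41 - 1.9949 * 0.846
  expect_equal(d[["fiveHT"]], -0.0025944, tolerance = 1e-6)
  # nigral balance: 60.4428 - 13.6055 * 1.41 - 9.2357 * 4.47
  expect_equal(d[["SNc"]], -0.0245340, tolerance = 1e-6)
})

test_that("zero drives and zero state give a (near-)zero derivative", {
  p <- circuit_parameters(a2Ex = tiny, a3Ex = tiny, a5Ex = tiny,
                          a7Ex = tiny, a8Ex = tiny, alphaIP = tiny)
  z <- circuit_state(M1 = 0, Thal = 0, DRN = 0, fiveHT = 0, SNc = 0,
                     DA = 0, DP = 0, IP = 0)
  d <- circuit_derivatives(z, p, t = 1.3)
  expect_true(all(abs(d) < 1e-9))
  # and the zero state is then (numerically) the steady state
  ss <- steady_state(p, duration = 100, init = z)
  expect_true(all(abs(as.numeric(ss)) < 1e-9))
})

test_that("non-finite states are rejected with the offending variable named", {
  s <- reference_state()
  s[["DA"]] <- Inf
  expect_error(circuit_derivatives(s, default_parameters()),
               regexp = "DA", class = "serotrem_integration_failure")
})

test_that("an exact equilibrium is preserved under both schemes", {
  p <- consistent_parameters()   # reference state is the exact fixed point
  for (method in c("euler", "rk4")) {
    traj <- simulate_circuit(p, duration = 50, method = method)
    drift <- vapply(traj[, -1], function(x) max(abs(x - x[1])), numeric(1))
    expect_true(all(drift < 1e-8),
                label = paste0("equilibrium drift under ", method))
  }
})

test_that("an isolated decaying variable follows exp(-t) at the scheme's order", {
  # decouple M1: its only input a1Thal * Thal ~ 0, decay coefficient 1
  p <- circuit_parameters(a1Thal = tiny, tauM1 = 1,
                          .base = consistent_parameters())
  init <- reference_state()
  init[["M1"]] <- 1
  for (method in c("euler", "rk4")) {
    dt <- 0.05
    traj <- simulate_circuit(p, duration = 5, dt = dt, init = init, method = method)
    err <- max(abs(traj$M1 - exp(-traj$time)))
    # explicit Euler is first order, RK4 fourth order
    bound <- if (method == "euler") 2 * dt else 2 * dt^4
    expect_lt(err, bound)
  }
})

test_that("trajectories are deterministic and interventions act locally in time", {
  sch <- schedule_snc_lesion(t_lesion = 30)
  a <- simulate_circuit(calibrated_parameters(), sch, duration = 60)
  b <- simulate_circuit(calibrated_parameters(), sch, duration = 60)
  expect_identical(as.data.frame(a), as.data.frame(b))

  base <- simulate_circuit(calibrated_parameters(), NULL, duration = 60)
  pre <- a$time < 30
  expect_identical(as.matrix(a[pre, ]), as.matrix(base[pre, ]))
  expect_false(isTRUE(all.equal(a$SNc[!pre], base$SNc[!pre])))
})

test_that("the moderate nigral lesion triggers the serotonergic compensation chain", {
  traj <- simulate_circuit(calibrated_parameters(), schedule_snc_lesion(),
                           duration = 200)
  pre <- traj$time >= 50 & traj$time < 75
  post <- traj$time >= 150
  m <- function(v, w) mean(traj[[v]][w])
  expect_lt(m("SNc", post), m("SNc", pre))
  expect_lt(m("DA", post), m("DA", pre))
  expect_gt(m("DRN", post), m("DRN", pre))
  expect_gt(m("fiveHT", post), m("fiveHT", pre))
  expect_lt(m("Thal", post), m("Thal", pre))
  expect_lt(m("M1", post), m("M1", pre))
  # partial recovery: DA climbs back from its post-lesion trough but stays low
  trough <- min(traj$DA[traj$time >= 75 & traj$time < 100])
  expect_gt(m("DA", post), trough)
})

test_that("the published seed vector is not a stable operating point", {
  expect_error(simulate_circuit(default_parameters(), duration = 100),
               regexp = "blew up", class = "serotrem_integration_failure")
})

test_that("steady state matches closed-form fixed points as inputs vary", {
  # serotonin balance: 5HT* = a4DRN * DRN* / tau5HT for any operating point
  for (scale in c(0.6, 1, 1.5)) {
    st <- reference_state()
    st[["DRN"]] <- st[["DRN"]] * scale
    st[["fiveHT"]] <- st[["fiveHT"]] * scale   # consistent 5HT for this DRN
    p <- consistent_parameters(state = st)
    # no oscillatory component here, so a tight windowed tolerance is reachable
    ss <- steady_state(p, duration = 300, tol = 1e-8)
    expect_equal(ss[["fiveHT"]], p[["a4DRN"]] * ss[["DRN"]] / p[["tau5HT"]],
                 tolerance = 1e-6)
    # cortical balance: M1* = a1Thal * Thal* / tauM1
    expect_equal(ss[["M1"]], p[["a1Thal"]] * ss[["Thal"]] / p[["tauM1"]],
                 tolerance = 1e-6)
  }
})

test_that("halving the step leaves the steady state unchanged within tolerance", {
  s1 <- steady_state(calibrated_parameters(), duration = 200, dt = 0.1)
  s2 <- steady_state(calibrated_parameters(), duration = 200, dt = 0.05)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 5e-3)
})

test_that("IP oscillation amplitude matches the driven linear-filter closed form", {
  # dopamine frozen by making its release and decay negligible
  p <- circuit_parameters(G = tiny, tauDA = tiny, .base = consistent_parameters())
  p <- circuit_parameters(alphaIP = 7.3801, .base = p)
  da0 <- reference_state()[["DA"]]
  traj <- simulate_circuit(p, duration = 60, dt = 0.005, method = "rk4")
  expect_equal(mean(traj$DA), da0, tolerance = 1e-6)  # frozen
  keep <- traj$time >= 30
  ipd <- traj$IP[keep] - mean(traj$IP[keep])
  wt <- p[["fIP"]] * traj$time[keep]
  fitc <- coef(lm(ipd ~ sin(wt) + cos(wt) - 1))
  amp <- sqrt(sum(fitc^2))
  amp_theory <- (p[["alphaIP"]] / da0) / sqrt(p[["tauIP"]]^2 + p[["fIP"]]^2)
  expect_equal(amp, amp_theory, tolerance = 0.01)
  # and the oscillation rides on the mean a8Ex / tauIP
  expect_equal(mean(traj$IP[keep]), p[["a8Ex"]] / p[["tauIP"]], tolerance = 0.01)
})

test_that("mean_ape follows its definition and guards zero references", {
  expect_equal(mean_ape(reference_state(), reference_state()), 0)
  est <- reference_state(); ref <- reference_state()
  est[] <- c(1, 5, rep(1, 6)); ref[] <- c(2, 4, rep(1, 6))
  # restricted 2-variable case padded with exact entries: (0.5 + 0.25) / 8
  expect_equal(mean_ape(est, ref), 0.75 / 8)
  ref[["M1"]] <- 0
  expect_error(mean_ape(est, ref), class = "serotrem_metric_error")
})

test_that("trajectory CSV round trip preserves values and layout", {
  traj <- simulate_circuit(duration = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  header <- readLines(path, n = 1)
  expect_equal(header, "time,M1,Thal,DRN,fiveHT,SNc,DA,DP,IP")
  back <- read_trajectory(path)
  expect_equal(nrow(back), 51)
  expect_equal(back$DA, traj$DA, tolerance = 1e-9)
})

test_that("config validation rejects bad grids and horizon violations", {
  expect_error(simulate_circuit(duration = 10, dt = -0.1),
               class = "serotrem_config_error")
  expect_error(simulate_circuit(duration = 10, dt = 0.3),
               class = "serotrem_config_error")
  sch <- intervention_schedule(500, "tauSNc", 1.25)
  expect_error(simulate_circuit(schedule = sch, duration = 100),
               class = "serotrem_config_error")
})
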