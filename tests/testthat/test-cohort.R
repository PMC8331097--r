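test_that("subject noise scales span the stated range and zero noise is exact", {
  spec <- cohort_spec(n = 20, seed = 7)
  s1 <- make_subject(default_parameters(), reference_state(), 1, spec)
  s20 <- make_subject(default_parameters(), reference_state(), 20, spec)
  expect_equal(s1$noise_scale, 0.01)
  expect_equal(s20$noise_scale, 0.02)
  expect_error(make_subject(default_parameters(), reference_state(), 21, spec),
               class = "serotrem_config_error")

  null_spec <- cohort_spec(n = 3, noise_range = c(0, 0), seed = 7)
  s <- make_subject(default_parameters(), reference_state(), 2, null_spec)
  expect_equal(as.numeric(s$params), as.numeric(default_parameters()))
  expect_equal(as.numeric(s$init), as.numeric(reference_state()))

  # deterministic given master seed and index
  again <- make_subject(default_parameters(), reference_state(), 20, spec)
  expect_identical(as.numeric(again$params), as.numeric(s20$params))
})

test_that("the noise law has the stated spread and keeps values positive", {
  base <- default_parameters()
  draws <- serotrem:::.with_seed(42, {
    replicate(10000, serotrem:::.perturb_positive(as.numeric(base), 0.02))
  })
  expect_true(all(draws > 0))
  # empirical SD of each coefficient ~ 0.02 x its value (resampling of
  # negatives is negligible at these scales)
  rel_sd <- apply(draws, 1, sd) / as.numeric(base)
  expect_true(all(abs(rel_sd - 0.02) < 0.02 * 0.03))
})

test_that("scenario runs are reproducible and null interventions change nothing", {
  spec <- cohort_spec(n = 4, seed = 11)
  a <- run_ssri_scenario(spec, arm = FALSE)
  b <- run_ssri_scenario(spec, arm = FALSE)
  expect_identical(as.data.frame(tidy(a)), as.data.frame(tidy(b)))

  null_run <- run_scenario("ssri", cohort = spec, schedule = intervention_schedule(),
                           arm = FALSE)
  m <- tidy(null_run)
  per_subj <- split(m$da_mean, m$subject)
  for (v in per_subj) expect_lt(diff(range(v)) / mean(v), 1e-3)
})

test_that("ssri condition windows tile the horizon with the trial boundaries", {
  spec <- cohort_spec(n = 2, seed = 3)
  res <- run_ssri_scenario(spec, arm = FALSE)
  expect_equal(res$windows$t0, c(0, 75, 125, 175, 225))
  expect_equal(res$windows$t1, c(75, 125, 175, 225, 300))
  expect_equal(res$windows$t0[-1], res$windows$t1[-5])
  expect_equal(nrow(tidy(res)), 2 * 5)
})

test_that("condition summaries are the arithmetic cohort means", {
  spec <- cohort_spec(n = 3, seed = 5)
  res <- run_drn_damage_scenario(spec, arm = FALSE)
  cs <- condition_summary(res)
  expect_equal(nrow(cs), 4)
  expect_equal(cs$condition, c("HEALTH", "DAMAGE1", "DAMAGE2", "DAMAGE3"))
  m <- tidy(res)
  h <- m$da_mean[m$condition == "HEALTH"]
  expect_equal(cs$da_mean[1], mean(h))
  expect_equal(cs$da_sd[1], sd(h))

  single <- condition_summary(run_drn_damage_scenario(
    cohort_spec(n = 1, noise_range = c(0, 0)), damages = 1.8, arm = FALSE))
  expect_equal(nrow(single), 2)
  expect_equal(single$n, c(1, 1))
})

test_that("raphe damage lowers dopamine monotonically; unit damage is no damage", {
  spec <- cohort_spec(n = 5, seed = 2)
  res <- run_drn_damage_scenario(spec, arm = FALSE)
  cs <- condition_summary(res)
  expect_true(all(diff(cs$da_mean) < 0))   # HEALTH > D1 > D2 > D3

  null_res <- run_drn_damage_scenario(spec, damages = 1.0, arm = FALSE)
  ncs <- condition_summary(null_res)
  expect_equal(ncs$da_mean[ncs$condition == "DAMAGE1"],
               ncs$da_mean[ncs$condition == "HEALTH"], tolerance = 1e-12)
})

test_that("the lesion scenario records the compensation chain at cohort level", {
  spec <- cohort_spec(n = 4, seed = 9)
  res <- run_snc_lesion_scenario(spec, arm = FALSE)
  m <- tidy(res)
  h <- m[m$condition == "HEALTH", ]
  l <- m[m$condition == "LESION", ]
  expect_true(all(l$fiveht_mean > h$fiveht_mean))
  expect_true(all(l$drn_mean > h$drn_mean))
  expect_true(all(l$da_mean < h$da_mean))
  expect_true(all(l$m1_mean < h$m1_mean))
})

test_that("glance reports cohort bookkeeping", {
  res <- run_ssri_scenario(cohort_spec(n = 2, seed = 1), arm = FALSE)
  g <- glance(res)
  expect_equal(g$n_subjects, 2)
  expect_equal(g$n_ok, 2)
  expect_equal(g$n_conditions, 5)
})
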