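test_that("default pressure schedule matches the 24-level injection design", {
  sched <- default_pressure_schedule()
  expect_length(sched, 24L)
  expect_equal(sched[1], 0.0)
  expect_equal(sched[length(sched)], 6.0)
  expect_equal(unique(round(diff(sched[sched <= 4]), 10)), 0.2)
  expect_equal(tail(sched, 3), c(4.5, 5.0, 6.0))
  expect_false(is.unsorted(sched, strictly = TRUE))
})

test_that("noiseless observations lie exactly on the curve", {
  obs <- generate_vc_observations(paper_params(), n_samples = 2,
                                  noise_sd = 0)
  expect_equal(nrow(obs), 48L)
  expect_equal(obs$lc, weibull_lc(paper_params(), obs$psi))
})

test_that("observation generator is deterministic under a seed", {
  o1 <- generate_vc_observations(paper_params(), noise_sd = 0.02, seed = 77)
  o2 <- generate_vc_observations(paper_params(), noise_sd = 0.02, seed = 77)
  expect_identical(o1, o2)
  o3 <- generate_vc_observations(paper_params(), noise_sd = 0.02, seed = 78)
  expect_false(identical(o1$lc, o3$lc))
  expect_error(generate_vc_observations(paper_params(), noise_sd = 0.02),
               "seed")
})

test_that("LC noise has the configured spread away from the boundaries", {
  # empirical sd at psi = 2.0 MPa across 300 seeds, one draw each
  draws <- vapply(1:300, function(s) {
    generate_vc_observations(paper_params(), n_samples = 1,
                             pressure_schedule = 2.0, noise_sd = 0.02,
                             seed = s)$lc
  }, numeric(1))
  expect_equal(sd(draws), 0.02, tolerance = 0.15)
  expect_equal(mean(draws), weibull_lc(paper_params(), 2.0),
               tolerance = 0.005)
  # censoring keeps every draw inside [0, 1] at the boundaries too
  lo <- generate_vc_observations(paper_params(), n_samples = 50,
                                 pressure_schedule = c(0, 6),
                                 noise_sd = 0.1, seed = 1)
  expect_true(all(lo$lc >= 0 & lo$lc <= 1))
})

test_that("injection series invert the time-ratio identity", {
  # the final 6 MPa step of the reference curve exceeds the LC cap
  expect_message(
    ser <- generate_injection_series(paper_params(), reference_time_s = 120,
                                     noise_sd = 0),
    "capped")
  expect_s3_class(ser, "injection_series")
  expect_equal(ser$steps$step_index, 0:23)
  # psi = 0 gives the reference time itself
  expect_equal(ser$steps$time_s[1], 120)
  # LC = 0.75 corresponds to t = 4T
  p75 <- lc_quantile(paper_params(), 0.75)
  s75 <- generate_injection_series(paper_params(), reference_time_s = 120,
                                   pressure_schedule = p75, noise_sd = 0)
  expect_equal(s75$steps$time_s, 480, tolerance = 1e-9)
  # round trip through lc_from_times, exact below the cap
  lc <- lc_from_times(ser$steps$time_s, ser$reference_time_s)$lc
  truth <- weibull_lc(paper_params(), ser$steps$pressure_mpa)
  below <- truth <= 1 - 1e-4
  expect_equal(lc[below], truth[below], tolerance = 1e-12)
  expect_equal(lc[!below], rep(1 - 1e-4, sum(!below)), tolerance = 1e-12)
})

test_that("the LC cap keeps generated times finite and is reported", {
  expect_message(
    ser <- generate_injection_series(weibull_params(0.5, 2.5),
                                     reference_time_s = 120, noise_sd = 0),
    "capped")
  expect_true(all(is.finite(ser$steps$time_s)))
  expect_lte(max(lc_from_times(ser$steps$time_s, 120)$lc), 1 - 1e-4 + 1e-12)
})

test_that("group sample generator is seeded and centred", {
  g1 <- generate_group_samples(2.73, 0.03, n = 10, seed = 12)
  g2 <- generate_group_samples(2.73, 0.03, n = 10, seed = 12)
  expect_identical(g1, g2)
  expect_length(g1, 10L)
  g0 <- generate_group_samples(2.73, 0, n = 10)
  expect_true(all(g0 == 2.73))
  expect_identical(one_sample_t(g0, 2.73)$p_value, 1)
  # grand mean over 300 seeds stays at the centre
  means <- vapply(1:300, function(s)
    mean(generate_group_samples(2.73, 0.03, n = 10, seed = s)), numeric(1))
  expect_equal(mean(means), 2.73, tolerance = 0.005)
})

test_that("generated data drive the full pipeline back to the true key points", {
  obs <- generate_vc_observations(paper_params(), n_samples = 10,
                                  noise_sd = 0.02, seed = 2024)
  fit <- fit_weibull(obs)
  kp <- dm_key_points(fit$params)
  truth <- dm_key_points(paper_params())
  expect_equal(kp$psi_m, truth$psi_m, tolerance = 0.05)
  expect_equal(kp$psi_l, truth$psi_l, tolerance = 0.05)
  br <- bracket_test(generate_group_samples(2.73, 0.03, 10, seed = 1),
                     generate_group_samples(2.93, 0.03, 10, seed = 2),
                     kp$psi_l)
  expect_true(br$bracketed)
})
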