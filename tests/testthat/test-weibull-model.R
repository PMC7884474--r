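test_that("parameter validation rejects non-positive scale and shape", {
  expect_error(weibull_params(-1, 2), "must be > 0")
  expect_error(weibull_params(0, 2), "must be > 0")
  expect_error(weibull_params(2, 0), "must be > 0")
  expect_error(weibull_params(NA, 2), "finite")
})

test_that("weibull_lc matches its defining values and rejects negative psi", {
  p <- paper_params()
  expect_identical(weibull_lc(p, 0), 0)
  # at psi = a the CDF equals 1 - exp(-1) for any shape
  for (b in c(0.8, 1, 2.5, 6))
    expect_equal(weibull_lc(weibull_params(2.23, b), 2.23), 1 - exp(-1),
                 tolerance = 1e-12)
  expect_equal(weibull_lc(p, 2.77709), 0.822833, tolerance = 1e-5)
  expect_error(weibull_lc(p, -0.1), "tension")
  # strictly increasing
  psi <- seq(0.01, 6, length.out = 200)
  expect_true(all(diff(weibull_lc(p, psi)) > 0))
})

test_that("analytic derivatives agree with symbolic and finite-difference oracles", {
  grid <- expand.grid(a = c(0.5, 2.23, 5), b = c(1.3, 2.5, 4))
  for (i in seq_len(nrow(grid))) {
    p <- weibull_params(grid$a[i], grid$b[i])
    for (psi in c(0.5, 1, 2) * grid$a[i]) {
      got <- weibull_derivatives(p, psi)
      want <- sym_derivatives(p, psi)
      expect_equal(got$d1, want$d1, tolerance = 1e-10)
      expect_equal(got$d2, want$d2, tolerance = 1e-10)
      expect_equal(got$d3, want$d3, tolerance = 1e-10)
      expect_equal(got$d1, fd_first_derivative(p, psi), tolerance = 1e-6)
    }
  }
  expect_error(weibull_derivatives(paper_params(), 0), "> 0")
})

test_that("key points are roots of the derivatives by construction", {
  for (b in c(2.1, 2.5, 4)) {
    p <- weibull_params(2.23, b)
    kp <- dm_key_points(p)
    expect_lt(abs(weibull_derivatives(p, kp$psi_m)$d2), 1e-10)
    expect_lt(abs(weibull_derivatives(p, kp$psi_e)$d3), 1e-10)
    expect_lt(abs(weibull_derivatives(p, kp$psi_l)$d3), 1e-10)
  }
})

test_that("dm_key_points reproduces the reference fit's key points", {
  kp <- dm_key_points(paper_params())
  # lethal point as printed for the fitted curve, full-precision closed form
  expect_equal(kp$psi_l, 2.7771, tolerance = 1e-4)
  expect_equal(kp$lc_l, 0.8228, tolerance = 1e-4)
  # remaining points frozen from the root-finding oracle
  expect_equal(kp$psi_e, 0.76682, tolerance = 1e-5)
  expect_equal(kp$psi_m, 1.81788, tolerance = 1e-5)
  expect_equal(kp$lc_e, 0.06699, tolerance = 1e-4)
  expect_equal(kp$lc_m, 0.45119, tolerance = 1e-4)
})

test_that("air-entry point is absent for shape in (1, 2] and errors for b <= 1", {
  kp <- dm_key_points(weibull_params(1, 2))  # lower root exactly 0 at b = 2
  expect_true(is.na(kp$psi_e))
  expect_true(is.na(kp$lc_e))
  expect_equal(kp$psi_m, (1 / 2)^(1 / 2), tolerance = 1e-12)
  expect_false(is.na(dm_key_points(weibull_params(1, 2 + 1e-6))$psi_e))
  expect_error(dm_key_points(weibull_params(1, 1)), "b > 1")
  expect_error(dm_key_points(weibull_params(1, 0.9)), "b > 1")
})

test_that("traditional points are the 12/50/88 percent quantiles", {
  p <- paper_params()
  tm <- tm_points(p)
  expect_equal(tm$psi_12, bisect_quantile(p, 0.12), tolerance = 1e-8)
  expect_equal(tm$psi_50, bisect_quantile(p, 0.50), tolerance = 1e-8)
  expect_equal(tm$psi_88, bisect_quantile(p, 0.88), tolerance = 1e-8)
  # frozen oracle values at the reference parameters
  expect_equal(tm$psi_12, 0.97941, tolerance = 1e-5)
  expect_equal(tm$psi_50, 1.92591, tolerance = 1e-5)
  expect_equal(tm$psi_88, 3.01204, tolerance = 1e-5)
  expect_true(tm$psi_12 < tm$psi_50 && tm$psi_50 < tm$psi_88)
  # exponential special case b = 1: median at a*ln2
  expect_equal(tm_points(weibull_params(3, 1))$psi_50, 3 * log(2),
               tolerance = 1e-12)
})

test_that("lc_quantile round-trips through the curve and handles limits", {
  for (b in c(1.2, 2.5, 6)) {
    p <- weibull_params(2.23, b)
    expect_equal(lc_quantile(p, 1 - exp(-1)), 2.23, tolerance = 1e-10)
    for (q in c(1e-6, 0.12, 0.5, 0.88, 1 - 1e-6))
      expect_equal(weibull_lc(p, lc_quantile(p, q)), q, tolerance = 1e-10)
  }
  # quantile -> 0 monotonically as p -> 0
  ps <- 10^seq(-2, -10, by = -1)
  qs <- lc_quantile(paper_params(), ps)
  expect_true(all(diff(qs) < 0) && qs[length(qs)] < 1e-3)
  expect_error(lc_quantile(paper_params(), 0), "inside")
  expect_error(lc_quantile(paper_params(), 1), "inside")
})

test_that("closed-form key points match the root-finding oracle on a grid", {
  for (a in c(0.5, 1, 2.23, 5)) {
    for (b in c(2.1, 2.5, 3, 4, 6)) {
      kp <- dm_key_points(weibull_params(a, b))
      nk <- numeric_key_points(weibull_params(a, b))
      expect_lt(abs(kp$psi_e - nk$psi_e), 1e-8)
      expect_lt(abs(kp$psi_m - nk$psi_m), 1e-8)
      expect_lt(abs(kp$psi_l - nk$psi_l), 1e-8)
    }
  }
  # closed form for the inflection at (1, 3)
  expect_equal(numeric_key_points(weibull_params(1, 3))$psi_m,
               (2 / 3)^(1 / 3), tolerance = 1e-8)
  # no lower third-derivative root for b <= 2: oracle agrees with absence
  nk <- numeric_key_points(weibull_params(2, 1.5))
  expect_true(is.na(nk$psi_e))
  expect_false(is.na(nk$psi_m) || is.na(nk$psi_l))
})

test_that("key points are ordered, scale in a, and have shape-only LC values", {
  for (b in c(2.1, 3, 5)) {
    kp1 <- dm_key_points(weibull_params(1, b))
    kp3 <- dm_key_points(weibull_params(3, b))
    expect_true(kp1$psi_e < kp1$psi_m && kp1$psi_m < kp1$psi_l)
    expect_true(kp1$lc_e < kp1$lc_m && kp1$lc_m < kp1$lc_l)
    expect_true(kp1$lc_l < 1 && kp1$lc_e > 0)
    # scale equivariance
    expect_equal(3 * c(kp1$psi_e, kp1$psi_m, kp1$psi_l),
                 c(kp3$psi_e, kp3$psi_m, kp3$psi_l), tolerance = 1e-12)
    # LC values depend on shape only
    expect_equal(c(kp1$lc_e, kp1$lc_m, kp1$lc_l),
                 c(kp3$lc_e, kp3$lc_m, kp3$lc_l), tolerance = 1e-12)
    # inflection LC identity
    expect_equal(kp1$lc_m, 1 - exp(-(b - 1) / b), tolerance = 1e-12)
  }
  # large-shape limit of the inflection LC
  expect_equal(dm_key_points(weibull_params(1, 1e6))$lc_m, 1 - exp(-1),
               tolerance = 1e-5)
})

test_that("traditional points exceed differential points at the reference fit", {
  kp <- dm_key_points(paper_params())
  tm <- tm_points(paper_params())
  expect_gt(tm$psi_12, kp$psi_e)
  expect_gt(tm$psi_50, kp$psi_m)
  expect_gt(tm$psi_88, kp$psi_l)
})

test_that("period classification uses half-open intervals on the key points", {
  kp <- dm_key_points(paper_params())
  expect_equal(as.character(classify_period(kp, 0)), "stationary")
  expect_equal(as.character(classify_period(kp, 1.0)), "accelerated_decline")
  expect_equal(as.character(classify_period(kp, 3.5)), "platform")
  # boundaries belong to the higher period
  expect_equal(as.character(classify_period(kp, kp$psi_e)),
               "accelerated_decline")
  expect_equal(as.character(classify_period(kp, kp$psi_m)),
               "decelerated_decline")
  expect_equal(as.character(classify_period(kp, kp$psi_l)), "platform")
  expect_equal(as.character(classify_period(kp, kp$psi_m - 1e-9)),
               "accelerated_decline")
  # vectorised and exhaustive
  labs <- classify_period(kp, seq(0, 6, by = 0.1))
  expect_false(anyNA(labs))
  expect_setequal(levels(labs), c("stationary", "accelerated_decline",
                                  "decelerated_decline", "platform"))
  # without an air-entry point four periods are undefined
  expect_error(classify_period(dm_key_points(weibull_params(1, 1.8)), 1),
               "b > 2")
  expect_error(classify_period(kp, -1), "tension")
})
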