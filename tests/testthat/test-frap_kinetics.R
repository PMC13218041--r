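# FRAP normalization and recovery kinetics.

test_that("double normalization is the identity for a steady reference", {
  t <- seq(0.5, 20, by = 0.5)
  R1 <- 40 + 30 * (1 - 0.8^t)
  tr <- frap_trace(t, R1, I_R2 = rep(500, length(t)), I_R3 = rep(0, length(t)),
                   I_R1_pre = 100, I_R2_pre = 500, I_R3_pre = 0)
  expect_equal(frap_double_normalize(tr), R1)
})

test_that("a constant background added to all channels cancels exactly", {
  t <- seq(0.5, 20, by = 0.5)
  R1 <- 40 + 30 * (1 - 0.8^t)
  R2 <- rep(500, length(t))
  base <- frap_trace(t, R1, R2, rep(0, length(t)), 100, 500, 0)
  k <- 37.5
  shifted <- frap_trace(t, R1 + k, R2 + k, rep(k, length(t)),
                        100 + k, 500 + k, k)
  expect_equal(frap_double_normalize(shifted), frap_double_normalize(base))
})

test_that("linear reference photobleaching is corrected point by point", {
  # 20% linear reference decay; hand-computed correction
  tr <- gen_frap_trace(a = 80, b = 60, c = 0.9, reference_bleach_frac = 0.2)
  proc <- frap_double_normalize(tr)
  clean <- 80 - 60 * 0.9^tr$t
  expect_equal(proc, clean, tolerance = 1e-10)
  # spreadsheet-style direct evaluation at every point
  manual <- (tr$I_R1 - tr$I_R3) * (tr$I_R2_pre - tr$I_R3_pre) /
    (tr$I_R2 - tr$I_R3)
  expect_equal(proc, manual)
})

test_that("min-max normalization maps min to 0 and prebleach to 100", {
  series <- c(20, 35, 70, 90, 110)
  out <- frap_minmax_normalize(series, prebleach = 120)
  expect_equal(out[1], 0)
  expect_equal(out[3], 50)
  expect_equal(frap_minmax_normalize(c(20, 120), 120)[2], 100)
  expect_true(all(diff(out) > 0))
  expect_error(frap_minmax_normalize(c(5, 5, 5), 5), "degenerate")
})

test_that("fit_recovery is exact on noiseless model data", {
  t <- seq(0, 30, by = 0.5)
  y <- 100 - 60 * 0.5^t
  fit <- fit_recovery(t, y)
  expect_equal(fit$a, 100, tolerance = 1e-8)
  expect_equal(fit$b, 60, tolerance = 1e-8)
  expect_equal(fit$c, 0.5, tolerance = 1e-8)
  expect_equal(fit$mobile_fraction, 100, tolerance = 1e-8)
  expect_warning(flat <- fit_recovery(t, rep(50, length(t))), "flat")
  expect_lt(flat$b, 1e-6)
  expect_error(fit_recovery(t[1:5], y[1:5]), "at least 8")
})

test_that("mobile fraction recovers a synthetic plateau of 68.9", {
  tr <- gen_frap_trace(a = 68.9, b = 55, c = 0.95, noise_sd = 0.5,
                       n_points = 180, dt = 0.5, seed = 9)
  fit <- fit_recovery(tr$t, frap_double_normalize(tr))
  expect_equal(fit$mobile_fraction, 68.9, tolerance = 0.05)
})

test_that("half_time solves the half-recovery crossing", {
  fit <- list(a = 100, b = 60, c = 0.5)
  expect_equal(half_time(fit), log(50 / 60) / log(0.5), tolerance = 1e-12)
  expect_equal(half_time(fit), 0.2630344, tolerance = 1e-6)
  # fitted-curve consistency: y(t_half) = a/2
  th <- half_time(fit)
  expect_equal(100 - 60 * 0.5^th, 50, tolerance = 1e-10)
  # already above half at t = 0
  expect_warning(t0 <- half_time(list(a = 100, b = 50, c = 0.5)), "t_half = 0")
  expect_equal(t0, 0)
  # monotonicity: faster decay, smaller t_half
  expect_lt(half_time(list(a = 100, b = 60, c = 0.3)),
            half_time(list(a = 100, b = 60, c = 0.7)))
  # the printed closed form agrees with the numeric solve only when a = 1
  cf <- half_time(list(a = 1, b = 0.6, c = 0.5), method = "closed_form")
  expect_equal(cf, half_time(list(a = 1, b = 0.6, c = 0.5)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(half_time(fit, "closed_form"), half_time(fit))))
})

test_that("numeric t_half agrees with uniroot on the fitted curve", {
  withr::with_seed(77, {
    for (i in 1:10) {
      a <- runif(1, 50, 100); b <- runif(1, a / 2 + 1, a)
      cc <- runif(1, 0.3, 0.97)
      th <- half_time(list(a = a, b = b, c = cc))
      root <- uniroot(function(t) a - b * cc^t - a / 2, c(0, 1e4),
                      tol = 1e-12)$root
      expect_equal(th, root, tolerance = 1e-9)
    }
  })
})

test_that("end-to-end generator -> normalize -> fit recovers t_half within 5%", {
  rel_err <- vapply(1:60, function(s) {
    tr <- gen_frap_trace(a = 80, b = 60, c = 0.9, noise_sd = 2,
                         reference_bleach_frac = 0.15, n_points = 60,
                         dt = 0.5, seed = s)
    truth <- attr(tr, "truth")
    fit <- fit_recovery(tr$t, frap_double_normalize(tr))
    abs(fit$t_half - truth$t_half) / truth$t_half
  }, numeric(1))
  expect_lt(median(rel_err), 0.05)
})
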