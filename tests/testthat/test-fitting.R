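test_that("normalization scales to unit maximum and flags degenerate input", {
  expect_equal(normalize_signal(c(2, 4, 8)), c(0.25, 0.5, 1))
  v <- listing_curve() / max(listing_curve())
  expect_equal(normalize_signal(v), v)  # idempotent on unit-max data
  expect_error(normalize_signal(c(0, 0, 0)), "degenerate")
  expect_error(normalize_signal(c(1, 2)), "at least 3")
})

test_that("T1 readout has the closed form and guards its domain", {
  expect_equal(t1_readout(1, 1, 1), 1000)
  expect_equal(t1_readout(1, 1, 0.44444), 2250.0, tolerance = 0.1 / 2250)
  expect_true(is.na(t1_readout(0.5, 1, 1)))   # plateau below readout fraction
  expect_true(is.na(t1_readout(1, -1, 1)))
  expect_true(is.na(t1_readout(1, 1, 0)))
})

test_that("T1 fit recovers the worked example and noiseless ground truth", {
  f <- fit_t1(tr_schedule(), listing_curve())
  expect_true(f$valid)
  expect_equal(f$time_ms, 2250, tolerance = 0.01)
  expect_gt(f$r_squared, 0.999)

  # noiseless recovery across the physiologic range, < 0.5% error, R^2 ~ 1
  for (t1 in c(200, 500, 800, 1100, 2250, 3000)) {
    y <- signal_model(1, t1, 100, tr_schedule(), te_ms = 0)
    f <- fit_t1(tr_schedule(), y)
    expect_true(f$valid)
    expect_lt(abs(f$time_ms - t1) / t1, 0.005)
    expect_gt(f$r_squared, 1 - 1e-9)
  }

  expect_false(fit_t1(tr_schedule(), rep(0.5, 9))$valid)
  expect_equal(fit_t1(tr_schedule(), rep(0.5, 9))$time_ms, 0)
})

test_that("noisy T1 fits have small median relative error at SNR 50", {
  set.seed(101)
  clean <- signal_model(0.9, 1100, 171, tr_schedule(), te_ms = 3)
  sigma <- max(clean) / 50
  err <- replicate(1000, {
    f <- fit_t1(tr_schedule(), rician(clean, sigma))
    if (f$valid) abs(f$time_ms - 1100) / 1100 else NA_real_
  })
  expect_lt(median(err, na.rm = TRUE), 0.03)
})

test_that("T2 fit recovers decay constants and rejects non-decaying data", {
  y <- signal_model(1, 10000, 100, tr_ms = 10000, te_ms = te_schedule())
  f <- fit_t2(te_schedule(), y)
  expect_true(f$valid)
  expect_lt(abs(f$time_ms - 100) / 100, 0.005)
  expect_gt(f$r_squared, 1 - 1e-9)

  # exact model points including the idealized TE = 0 sample
  f2 <- fit_t2(c(0, 100, 200), c(1, exp(-1), exp(-2)))
  expect_true(f2$valid)
  expect_equal(f2$time_ms, 100, tolerance = 1e-6)

  expect_false(fit_t2(te_schedule(), rep(0.4, 10))$valid)
  rising <- seq(0.2, 0.9, length.out = 10)
  expect_false(fit_t2(te_schedule(), rising)$valid)
})

test_that("R^2 declines as noise grows", {
  clean <- signal_model(1, 1100, 171, tr_schedule(), te_ms = 3)
  mean_r2 <- vapply(c(0.005, 0.02, 0.05, 0.1), function(sg) {
    set.seed(77)
    mean(replicate(60, fit_t1(tr_schedule(), rician(clean, sg))$r_squared),
         na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
})

test_that("fits agree with the independent profile-search oracle", {
  set.seed(11)
  for (i in 1:12) {
    t1 <- runif(1, 300, 3000)
    y <- signal_model(runif(1, 0.5, 1), t1, 150, tr_schedule(), te_ms = 0)
    y <- y / max(y)
    f <- fit_t1(tr_schedule(), y, normalize = FALSE)
    o <- oracle_fit_time(tr_schedule(), y, "T1")
    expect_lt(abs(f$time_ms - o) / o, 1e-3)
  }
  for (i in 1:12) {
    t2 <- runif(1, 30, 250)
    y <- signal_model(1, 1e7, t2, tr_ms = 1e7, te_ms = te_schedule())
    y <- rician(y, 0.005)  # mild noise: oracle finds the same LS optimum
    f <- fit_t2(te_schedule(), y, normalize = FALSE)
    o <- oracle_fit_time(te_schedule(), y, "T2")
    expect_lt(abs(f$time_ms - o) / o, 1e-3)
  }
})

test_that("inverse-consistency: fitted curve crosses its readout fraction at time_ms", {
  set.seed(21)
  for (i in 1:10) {
    t1 <- runif(1, 400, 2500)
    y <- rician(signal_model(1, t1, 150, tr_schedule(), te_ms = 0), 0.01)
    f <- fit_t1(tr_schedule(), y)
    if (!f$valid) next
    # at the readout time the curve sits at 63.21% of its fitted plateau
    val <- f$a - f$b * exp(-(f$c * f$time_ms) / 1000)
    expect_equal(val / f$a, 1 - exp(-1), tolerance = 1e-6)
  }
  y2 <- signal_model(1, 1e7, 80, 1e7, te_schedule())
  f2 <- fit_t2(te_schedule(), y2)
  val2 <- f2$a * exp(-(f2$c * f2$time_ms) / 1000)
  expect_equal(val2 / f2$a, exp(-1), tolerance = 1e-6)
})

test_that("bi-exponential fit nests the mono model and separates mixtures", {
  # single-exponential data: dominant component matches mono, 2nd amp ~ 0
  y <- signal_model(1, 10000, 120, 10000, te_schedule())
  mono <- fit_t2(te_schedule(), y)
  bi <- fit_biexponential(te_schedule(), y, mode = "T2")
  expect_true(bi$valid)
  if (bi$model == "bi-exponential") {
    expect_lt(abs(bi$time_ms - mono$time_ms) / mono$time_ms, 0.02)
    expect_lt(abs(bi$components$amplitude[2]), 0.05)
  } else {
    expect_lt(abs(bi$time_ms - mono$time_ms) / mono$time_ms, 0.02)
  }

  # 50/50 mixture of T2 = 30 and 300 ms, densely sampled
  te <- seq(5, 600, by = 12)
  ymix <- 0.5 * exp(-te / 30) + 0.5 * exp(-te / 300)
  bi2 <- fit_biexponential(te, ymix, mode = "T2", normalize = FALSE)
  expect_identical(bi2$model, "bi-exponential")
  times <- sort(bi2$components$time_ms)
  expect_lt(abs(times[1] - 30) / 30, 0.1)
  expect_lt(abs(times[2] - 300) / 300, 0.1)

  expect_error(fit_biexponential(c(1, 2, 3, 4), c(1, 0.8, 0.6, 0.5), "T2"),
               "insufficient")
})

test_that("smoothing kernels behave as convolution with reflected edges", {
  m <- matrix(runif(64), 8, 8)
  expect_identical(smooth_series(array(m, c(8, 8, 1)), "none")[, , 1], m)
  cm <- matrix(3.5, 8, 8)
  expect_equal(smooth_series(array(cm, c(8, 8, 1)), "mean3")[, , 1], cm)
  # single bright pixel spreads to 1/9 over the 3x3 neighborhood
  z <- matrix(0, 9, 9); z[5, 5] <- 1
  sm <- smooth_series(array(z, c(9, 9, 1)), "mean3")[, , 1]
  expect_equal(sm[4:6, 4:6], matrix(1 / 9, 3, 3))
  expect_equal(sum(sm), 1)
  # gaussian preserves constants too
  expect_equal(smooth_series(array(cm, c(8, 8, 1)), "gaussian:1.2")[, , 1], cm)
  expect_error(smooth_series(array(m, c(8, 8, 1)), "boxcar"), "kernel")
})
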