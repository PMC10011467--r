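test_that("waveform constructor enforces its invariants", {
  expect_error(waveform(c(0.5, 0.2), c(1, 2), 1, "flow"), "non-monotone")
  expect_error(waveform(c(0, 0.5), c(1, NA), 1, "flow"), "finite")
  expect_error(waveform(c(0, 0.5), c(1, -2), 1, "pressure"), "positive")
  expect_error(waveform(c(0, 1.5), c(1, 2), 1, "flow"), "within")
  expect_error(waveform(c(0, 0.5), c(1, 2), -1, "flow"), "period")
  # flow reversal is allowed
  w <- waveform(c(0, 0.5), c(-1, 2), 1, "flow")
  expect_s3_class(w, "wk_waveform")
  expect_equal(wf_period(w), 1)
})

test_that("waveform CSV round trip preserves values and metadata", {
  w <- sin_flow(mean = 5, amp = 1.5, period = 0.8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform(w, path)
  w2 <- read_waveform(path)
  expect_equal(wf_quantity(w2), "flow")
  expect_equal(wf_period(w2), 0.8, tolerance = 1e-9)
  expect_equal(w2$value, w$value, tolerance = 1e-5)  # 6 significant digits
  expect_equal(w2$time, w$time, tolerance = 1e-5)
})

test_that("read_waveform converts mL/min and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# quantity=flow period_s=1", "time_s,value", "0,5", "0.5,5"),
             path)
  w <- read_waveform(path)
  expect_equal(w$value, c(5, 5))
  w_min <- read_waveform(path, flow_units = "mL/min")
  expect_equal(w_min$value, c(5, 5) / 60, tolerance = 1e-12)

  writeLines(c("# quantity=flow period_s=1", "time_s,value", "0.5,1", "0.2,2"),
             path)
  expect_error(read_waveform(path), "non-monotone")

  writeLines(c("# quantity=flow", "time_s,value", "0,5", "0.5,5"), path)
  expect_error(read_waveform(path), "period")

  writeLines(c("# quantity=flow period_s=1", "time_s,value", "0,5", "0.5,NaN"),
             path)
  expect_error(read_waveform(path), "NaN")
})

test_that("waveform_mean matches constants, sinusoids and a fine-grid oracle", {
  expect_equal(waveform_mean(sin_flow(mean = 7.63, amp = 0)), 7.63,
               tolerance = 1e-12)
  # sinusoid averages out (uniform sampling is spectrally accurate)
  expect_equal(waveform_mean(sin_pressure(mean = 80, amp = 20)), 80,
               tolerance = 1e-6)
  # triangular pulse vs brute-force quadrature of the periodic polyline
  t <- c(0, 0.1, 0.25, 0.4, 0.7)
  v <- c(0.5, 4, 9, 1, 0.8)
  w <- waveform(t, v, period = 1, quantity = "flow")
  tt <- c(t, 1)
  vv <- c(v, v[1])
  fine <- seq(0, 1, length.out = 200001)
  oracle <- mean(approx(tt, vv, xout = fine)$y[-200001])
  expect_equal(waveform_mean(w), oracle, tolerance = 1e-6)
})

test_that("normalize_waveform hits unit mean, keeps shape, and is idempotent", {
  # constant pressure -> constant 1
  nw <- normalize_waveform(sin_pressure(mean = 85, amp = 0))
  expect_equal(nw$value, rep(1, 100), tolerance = 1e-12)
  expect_equal(nw$tau, seq(0, 0.99, by = 0.01))

  # sinusoid: mean 1, relative amplitude a/mean
  nw2 <- normalize_waveform(sin_pressure(mean = 80, amp = 20))
  expect_equal(mean(nw2$value), 1, tolerance = 1e-9)
  expect_equal((max(nw2$value) - min(nw2$value)) / 2, 0.25,
               tolerance = 1e-3)

  # idempotence
  nw3 <- normalize_waveform(nw2)
  expect_equal(nw3$value, nw2$value, tolerance = 1e-12)

  # zero-mean flow is undefined
  zero <- waveform(seq(0, 0.99, by = 0.01),
                   sin(2 * pi * seq(0, 0.99, by = 0.01)),
                   period = 1, quantity = "flow")
  expect_error(normalize_waveform(zero), "zero")
})

test_that("property: normalized mean is 1 for randomized waveforms", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(30:200, 1)
    t <- sort(runif(n, 0, 0.95))
    v <- 60 + 30 * runif(1) * sin(2 * pi * t) + rnorm(n, 0, 2)
    w <- waveform(t, abs(v), period = 1, quantity = "pressure")
    expect_equal(mean(normalize_waveform(w)$value), 1, tolerance = 1e-9)
  }
})

test_that("average_waveforms: degenerate, symmetric, and brute-force cases", {
  base <- normalize_waveform(sin_pressure(mean = 80, amp = 15))
  ens <- average_waveforms(list(base, base))
  expect_equal(ens$mean, base$value)
  expect_equal(ens$sd, rep(0, 100))

  up <- normalize_waveform(sin_pressure(mean = 100, amp = 10))
  dn <- normalize_waveform(sin_pressure(mean = 100, amp = 10))
  dn$value <- 2 - dn$value  # mirror around 1
  ens2 <- average_waveforms(list(up, dn))
  expect_equal(ens2$mean, rep(1, 100), tolerance = 1e-9)
  expect_equal(mean(ens2$mean), 1, tolerance = 1e-9)

  set.seed(1)
  members <- lapply(1:10, function(i) {
    normalize_waveform(sin_pressure(mean = runif(1, 70, 100),
                                    amp = runif(1, 5, 20)))
  })
  ens3 <- average_waveforms(members)
  mat <- vapply(members, function(m) m$value, numeric(100))
  expect_identical(ens3$mean, rowMeans(mat))

  expect_error(average_waveforms(list()), "non-empty")
  flow_norm <- normalize_waveform(sin_flow())
  expect_error(average_waveforms(list(base, flow_norm)), "mixed")
})

test_that("smooth_pressure_trace extracts the period and preserves the mean", {
  # noiseless periodic trace: reproduced up to resampling
  t <- seq(0, 2, by = 0.002)
  clean <- 85 + 12 * sin(2 * pi * t) + 4 * sin(4 * pi * t + 0.7)
  sm <- smooth_pressure_trace(data.frame(time = t, value = clean),
                              heart_rate = 60)
  expect_equal(wf_period(sm), 1)
  ref <- 85 + 12 * sin(2 * pi * sm$time) + 4 * sin(4 * pi * sm$time + 0.7)
  expect_equal(sm$value, ref, tolerance = 1e-3)

  # additive zero-mean noise: mean preserved within 0.5%
  set.seed(99)
  noisy <- clean + rnorm(length(t), 0, 3)
  sm2 <- smooth_pressure_trace(data.frame(time = t, value = noisy),
                               heart_rate = 60)
  expect_lt(abs(waveform_mean(sm2) - 85) / 85, 0.005)

  expect_error(
    smooth_pressure_trace(data.frame(time = c(0, 0.3), value = c(80, 82)),
                          heart_rate = 60),
    "shorter")
})

test_that("ensemble CSV export carries grid, mean and sd", {
  ens <- average_waveforms(list(normalize_waveform(sin_pressure()),
                                normalize_waveform(sin_pressure(amp = 5))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ensemble(ens, path)
  back <- read.csv(path)
  expect_named(back, c("grid", "mean", "sd"))
  expect_equal(back$mean, ens$mean, tolerance = 1e-5)
})
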