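test_that("l2_relative_error matches its closed forms", {
  w <- sin_pressure()
  expect_equal(l2_relative_error(w, w), 0)
  w2 <- w
  w2$value <- 2 * w$value
  expect_equal(l2_relative_error(w2, w), 100, tolerance = 1e-12)
  expect_equal(l2_relative_error(c(110, 90), c(100, 100)), 10,
               tolerance = 1e-12)
  expect_error(l2_relative_error(c(1, 2, 3), c(1, 2)), "grid mismatch")
  expect_error(l2_relative_error(c(1, 2), c(0, 0)), "zero norm")
})

test_that("fit_wk3 recovers generating parameters on noiseless data", {
  cases <- list(
    list(artery = "CCA", params = wk3_params(1.14, 10.35, 0.04), qbar = 7.63),
    list(artery = "SA", params = wk3_params(0.96, 33.10, 0.06), qbar = 3.08))
  for (cs in cases) {
    pair <- template_pair(cs$artery, params = cs$params, qbar = cs$qbar)
    fit <- fit_wk3(pair$flow, pair$pressure, artery = cs$artery)
    expect_true(fit$converged)
    expect_true(fit$identifiable)
    expect_equal(fit$params$r1, cs$params$r1, tolerance = 5e-3)
    expect_equal(fit$params$r2, cs$params$r2, tolerance = 5e-3)
    expect_equal(fit$params$c, cs$params$c, tolerance = 5e-3)
    expect_lt(fit$sse, 1e-4)
    # constraint holds exactly by construction
    expect_equal(fit$params$r1 + fit$params$r2, fit$rtot, tolerance = 1e-12)
    # cost history is non-increasing at accepted steps
    expect_true(all(diff(fit$cost_history) <= 1e-12))
  }
})

test_that("constant-flow input is flagged unidentifiable, not fatal", {
  q <- waveform(seq(0, 0.99, by = 0.01), rep(5, 100), 1, "flow")
  p <- waveform(seq(0, 0.99, by = 0.01), rep(55, 100), 1, "pressure")
  fit <- fit_wk3(q, p, settings = fit_settings(initial_guess = c(0.2, 0.7)))
  expect_false(fit$identifiable)
  expect_true(fit$converged)
  expect_equal(fit$nparams$r1norm, 0.2)
  expect_equal(fit$nparams$cnorm, 0.7)
  expect_lt(fit$sse, 1e-12)
})

test_that("fit rejects inconsistent inputs", {
  pair <- template_pair("CCA")
  short <- waveform(pair$pressure$time / 2, pair$pressure$value,
                    period = wf_period(pair$pressure) / 2,
                    quantity = "pressure")
  expect_error(fit_wk3(pair$flow, short), "periods disagree")
})

test_that("tidy/glance expose the fit in broom style", {
  pair <- template_pair("CCA")
  fit <- fit_wk3(pair$flow, pair$pressure)
  td <- tidy(fit)
  expect_true(all(c("r1", "r2", "c", "rtot", "r1norm", "cnorm") %in% td$term))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
})

test_that("fit_cohort summarizes with type-7 quantiles and flags failures", {
  # three patients with r1norm 0.1, 0.2, 0.3 at fixed cnorm
  T <- 0.9
  rows <- purrr::map(c(0.1, 0.2, 0.3), function(r1n) {
    fl <- template_flow("CCA", qbar = 6, period = T)
    params <- denormalize_params(wk3_nparams(r1n, 0.5), 12, T)
    pr <- simulate_pressure(fl, params)
    tibble::tibble(id = sprintf("p%.1f", r1n), artery = "CCA",
                   flow = list(fl), pressure = list(pr))
  })
  cohort <- dplyr::bind_rows(rows)
  cf <- fit_cohort(cohort)
  expect_true(all(cf$fits$ok))
  r1n <- cf$summary[cf$summary$parameter == "r1norm", ]
  expect_equal(r1n$median, 0.2, tolerance = 1e-3)
  expect_equal(r1n$q25, 0.15, tolerance = 1e-3)
  expect_equal(r1n$q75, 0.25, tolerance = 1e-3)

  # a corrupt patient propagates as a flagged row, not an abort
  bad <- cohort
  bad$pressure[[2]] <- waveform(c(0, 0.4), c(80, 85), period = 0.45,
                                quantity = "pressure")
  cf2 <- fit_cohort(bad)
  expect_equal(sum(cf2$fits$ok), 2)
  expect_false(cf2$fits$ok[2])
  expect_match(cf2$fits$error[2], "periods")
})

test_that("noise robustness: median recovery within 5% at sigma = 1 mmHg", {
  pair <- template_pair("CCA")
  true_np <- normalize_params(pair$params, wf_period(pair$flow))
  set.seed(77)
  fits <- purrr::map(1:20, function(i) {
    noisy <- waveform(pair$pressure$time,
                      pair$pressure$value + rnorm(100, 0, 1),
                      period = wf_period(pair$pressure),
                      quantity = "pressure")
    fit_wk3(pair$flow, noisy, artery = "CCA")
  })
  r1n <- median(purrr::map_dbl(fits, ~ .x$nparams$r1norm))
  cn <- median(purrr::map_dbl(fits, ~ .x$nparams$cnorm))
  expect_lt(abs(r1n / true_np$r1norm - 1), 0.05)
  expect_lt(abs(cn / true_np$cnorm - 1), 0.05)
})

test_that("scale and period invariance of the identified parameters", {
  pair <- template_pair("CCA")
  fit0 <- fit_wk3(pair$flow, pair$pressure)

  # pressure scaled by alpha: R1, R2 scale by alpha, C by 1/alpha
  alpha <- 1.3
  p_scaled <- waveform(pair$pressure$time, alpha * pair$pressure$value,
                       period = wf_period(pair$pressure),
                       quantity = "pressure")
  fit_a <- fit_wk3(pair$flow, p_scaled)
  expect_equal(fit_a$params$r1, alpha * fit0$params$r1, tolerance = 1e-3)
  expect_equal(fit_a$params$r2, alpha * fit0$params$r2, tolerance = 1e-3)
  expect_equal(fit_a$params$c, fit0$params$c / alpha, tolerance = 1e-3)
  expect_equal(fit_a$nparams$r1norm, fit0$nparams$r1norm, tolerance = 1e-3)
  expect_equal(fit_a$nparams$cnorm, fit0$nparams$cnorm, tolerance = 1e-3)

  # time stretched by beta: normalized parameters unchanged
  beta <- 1.25
  stretch <- function(w) {
    waveform(w$time * beta, w$value, period = wf_period(w) * beta,
             quantity = wf_quantity(w))
  }
  fit_b <- fit_wk3(stretch(pair$flow), stretch(pair$pressure))
  expect_equal(fit_b$nparams$r1norm, fit0$nparams$r1norm, tolerance = 1e-3)
  expect_equal(fit_b$nparams$cnorm, fit0$nparams$cnorm, tolerance = 1e-3)
})
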