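test_that("mean arterial pressure follows the one-third rule", {
  expect_equal(mean_arterial_pressure(120, 80), 93.3333, tolerance = 1e-4)
  expect_equal(mean_arterial_pressure(150, 90), 110)
  expect_equal(mean_arterial_pressure(100, 100 - 1e-9), 100,
               tolerance = 1e-6)
  expect_error(mean_arterial_pressure(80, 90), "SBP > DBP")
})

test_that("total resistance is mean pressure over mean flow", {
  expect_equal(total_resistance(93.33, 458 / 60), 12.227, tolerance = 1e-3)
  expect_equal(total_resistance(7, 7), 1)
  expect_error(total_resistance(-1, 5), "positive")
})

test_that("parameter normalization matches the cohort table and inverts", {
  # carotid and subclavian median rows
  np_cca <- normalize_params(wk3_params(1.14, 10.35, 0.04), period = 0.952)
  expect_equal(round(np_cca$r1norm, 2), 0.10)
  np_sa <- normalize_params(wk3_params(0.96, 33.10, 0.06), period = 0.952)
  expect_equal(round(np_sa$r1norm, 2), 0.03)
  # symmetry
  np_eq <- normalize_params(wk3_params(2, 2, 0.05), period = 1)
  expect_equal(np_eq$r1norm, 0.5)
  expect_equal(np_eq$r2norm, 0.5)

  # denormalize(normalize(p)) = p exactly
  set.seed(5)
  for (i in 1:10) {
    p <- random_params()
    T <- runif(1, 0.5, 1.5)
    back <- denormalize_params(normalize_params(p, T), rtot(p), T)
    expect_equal(back$r1, p$r1, tolerance = 1e-12)
    expect_equal(back$r2, p$r2, tolerance = 1e-12)
    expect_equal(back$c, p$c, tolerance = 1e-12)
  }

  # worked carotid example
  p <- denormalize_params(wk3_nparams(0.10, 0.46), rtot = 11.49,
                          period = 0.952)
  expect_equal(p$r1, 1.149, tolerance = 1e-3)
  expect_equal(p$r2, 10.341, tolerance = 1e-3)
  expect_equal(p$c, 0.0381, tolerance = 1e-2)
})

test_that("flow-diameter law scales as a power and warns out of range", {
  law <- flow_diameter_law(k = 0.12, b = 2)
  expect_equal(mean_flow_from_diameter(6, law), 4.32, tolerance = 1e-12)
  expect_equal(mean_flow_from_diameter(2, law) / mean_flow_from_diameter(1, law),
               4)
  expect_equal(mean_flow_from_diameter(1, flow_diameter_law(1, 1.6)), 1)
  expect_warning(flow_diameter_law(0.1, 3.0), "1.6-2.4")
  expect_error(mean_flow_from_diameter(-2, law), "positive")
})

test_that("non-invasive estimation chains MAP, Rtot and the table", {
  p <- estimate_wk3_noninvasive("CCA", sbp = 120, dbp = 80, heart_rate = 63,
                                mean_flow_ml_min = 458)
  expect_equal(attr(p, "map"), 93.333, tolerance = 1e-4)
  expect_equal(attr(p, "rtot"), 12.227, tolerance = 1e-3)
  expect_equal(attr(p, "period"), 0.952, tolerance = 1e-3)
  expect_equal(p$r1, 1.223, tolerance = 1e-3)
  expect_equal(p$r2, 11.00, tolerance = 1e-3)
  expect_equal(p$c, 0.0358, tolerance = 1e-2)

  # construction identity: r1norm of output equals the table median
  tbl <- default_parameter_table()
  for (a in c("CCA", "SA", "VA")) {
    pa <- estimate_wk3_noninvasive(a, 135, 85, 70, mean_flow_ml_min = 185)
    expect_equal(pa$r1 / (pa$r1 + pa$r2), tbl$r1norm[tbl$artery == a],
                 tolerance = 1e-12)
  }
  expect_equal(
    round(estimate_wk3_noninvasive("SA", 120, 80, 63,
                                   mean_flow_ml_min = 185)$r1 /
            attr(estimate_wk3_noninvasive("SA", 120, 80, 63,
                                          mean_flow_ml_min = 185), "rtot"),
          2), 0.03)

  # diameter route
  law <- flow_diameter_law(0.12, 2)
  pd <- estimate_wk3_noninvasive("CCA", 120, 80, 63, diameter = 6, law = law)
  expect_equal(attr(pd, "mean_flow"), 4.32, tolerance = 1e-12)

  expect_error(estimate_wk3_noninvasive("XX", 120, 80, 60,
                                        mean_flow_ml_min = 100),
               "not present")
  expect_error(estimate_wk3_noninvasive("CCA", 120, 80, 60), "supply")
})

test_that("evaluate_on_testset: self-test is exact, single pair matches Eq. 5", {
  # identical noiseless training and testing patients -> ~0 pressure error
  flow <- template_flow("CCA", qbar = 6, period = 0.9)
  params <- denormalize_params(wk3_nparams(0.12, 0.5), 13, 0.9)
  pressure <- simulate_pressure(flow, params)
  cohort <- tibble::tibble(id = c("a", "b"), artery = "CCA",
                           flow = list(flow, flow),
                           pressure = list(pressure, pressure))
  a <- evaluate_on_testset(cohort, cohort)
  pe <- a$summary$median[a$summary$direction == "pressure"]
  expect_lt(pe, 0.05)

  # one training / one differing testing patient: errors equal the direct
  # computation with the training medians
  flow2 <- template_flow("CCA", qbar = 4, period = 1.05)
  params2 <- denormalize_params(wk3_nparams(0.25, 0.9), 18, 1.05)
  pressure2 <- simulate_pressure(flow2, params2)
  testset <- tibble::tibble(id = "t", artery = "CCA",
                            flow = list(flow2), pressure = list(pressure2))
  a2 <- evaluate_on_testset(cohort[1, ], testset)

  train_fit <- fit_wk3(flow, pressure, artery = "CCA")
  est <- denormalize_params(train_fit$nparams,
                            waveform_mean(pressure2) / waveform_mean(flow2),
                            1.05)
  p_direct <- simulate_pressure(flow2, est)
  expect_equal(a2$patients$pressure_error_pct,
               l2_relative_error(p_direct$value, pressure2$value),
               tolerance = 1e-6)
  q_direct <- estimate_flow(pressure2, est)
  expect_equal(a2$patients$flow_error_pct,
               l2_relative_error(q_direct$value, flow2$value),
               tolerance = 1e-6)
})
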