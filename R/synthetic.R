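#' Artery-specific normalized flow templates
#'
#' Smooth periodic unit-mean flow shapes that emulate the qualitative
#' Doppler morphology of the arch branch arteries: mono-phasic waveforms
#' for the common carotid (CCA) and vertebral (VA) arteries, and the
#' subclavian (SA) pattern of a high systolic peak followed by
#' early-diastolic flow reversal. The template is a truncated Fourier
#' series shaped by the systolic peak-to-mean ratio, the reversal depth
#' (SA only), and the systolic fraction of the cycle.
#'
#' @param artery `"CCA"`, `"SA"` or `"VA"`.
#' @param peak_ratio Systolic peak over mean. Defaults: CCA 2.2, SA 4.5,
#'   VA 1.8.
#' @param reversal_depth Most negative value over mean (must be <= 0; only
#'   the SA template may request reversal). Defaults: CCA/VA 0, SA -0.6.
#' @param systolic_fraction Fraction of the period in systole
#'   (default 1/3).
#' @param harmonics Fourier harmonics retained (default 12).
#' @return A `wk3_flow_template_params` list.
#' @export
flow_template_params <- function(artery = c("CCA", "SA", "VA"),
                                 peak_ratio = NULL, reversal_depth = NULL,
                                 systolic_fraction = 1 / 3,
                                 harmonics = 12L) {
  artery <- match.arg(artery)
  defaults <- list(CCA = c(2.2, 0), SA = c(4.5, -0.6), VA = c(1.8, 0))
  peak_ratio <- peak_ratio %||% defaults[[artery]][1]
  reversal_depth <- reversal_depth %||% defaults[[artery]][2]
  if (peak_ratio <= 1) abort("`peak_ratio` must exceed 1")
  if (reversal_depth > 0) abort("`reversal_depth` must be <= 0")
  if (artery != "SA" && reversal_depth < 0) {
    abort(sprintf("flow reversal is not part of the %s morphology", artery))
  }
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    abort("`systolic_fraction` must lie in (0, 1)")
  }
  structure(list(artery = artery, peak_ratio = peak_ratio,
                 reversal_depth = reversal_depth,
                 systolic_fraction = systolic_fraction,
                 harmonics = as.integer(harmonics)),
            class = "wk3_flow_template_params")
}

#' Build a normalized flow template
#'
#' Constructs the unit-mean pulse: a sin^2 systolic lobe over the systolic
#' fraction, an optional negative early-diastolic lobe (reversal), linear
#' amplitudes solved so the peak and trough hit `peak_ratio` and
#' `reversal_depth`, then low-pass truncation to `harmonics` Fourier terms
#' (which preserves the mean exactly) on the 0.01 grid.
#'
#' @param params A [flow_template_params()].
#' @return A normalized flow `wk_nwaveform` with grid mean exactly 1.
#' @export
make_flow_template <- function(params) {
  if (!inherits(params, "wk3_flow_template_params")) {
    abort("expected `wk3_flow_template_params`")
  }
  tau <- norm_grid()
  s <- params$systolic_fraction
  d <- min(0.15, (1 - s) / 2)  # reversal window in early diastole
  pulse <- ifelse(tau < s, sin(pi * tau / s)^2, 0)
  lobe <- ifelse(tau >= s & tau < s + d, sin(pi * (tau - s) / d)^2, 0)
  p0 <- pulse - mean(pulse)
  l0 <- lobe - mean(lobe)
  # amplitudes from the values at the pulse peak and the lobe trough
  if (params$reversal_depth < 0) {
    A <- rbind(c(1 - mean(pulse), mean(lobe)),
               c(-mean(pulse), -(1 - mean(lobe))))
    ab <- solve(A, c(params$peak_ratio - 1, params$reversal_depth - 1))
  } else {
    ab <- c((params$peak_ratio - 1) / (1 - mean(pulse)), 0)
  }
  f <- 1 + ab[1] * p0 - ab[2] * l0
  # zero-phase low-pass: keep DC + `harmonics` harmonics
  co <- fft(f)
  n <- length(f)
  keep <- c(seq_len(params$harmonics + 1L),
            seq(n - params$harmonics + 1L, n))
  co[setdiff(seq_len(n), keep)] <- 0
  f <- Re(fft(co, inverse = TRUE)) / n
  if (params$reversal_depth == 0 && min(f) <= 0) {
    abort("peak_ratio too large: mono-phasic template would cross zero")
  }
  new_nwaveform(f / mean(f), "flow")
}

default_artery_config <- function() {
  # cohort statistics: flow mL/min (mean, sd), pressure mmHg (mean, sd),
  # heart rate bpm; normalized-parameter medians with log-sd matched to the
  # cohort IQRs (sdlog = log(q75/q25) / (2 * qnorm(0.75))).
  tbl <- default_parameter_table()
  iqr_sdlog <- function(q25, q75) log(q75 / q25) / (2 * stats::qnorm(0.75))
  tibble(
    artery = c("CCA", "SA", "VA"),
    flow_mean = c(458, 185, 90), flow_sd = c(139, 116, 59),
    pressure_mean = c(83, 85, 85), pressure_sd = c(11, 12, 12),
    hr_mean = 63, hr_sd = 10,
    r1norm_median = tbl$r1norm,
    r1norm_sdlog = iqr_sdlog(tbl$r1norm_q25, tbl$r1norm_q75),
    cnorm_median = tbl$cnorm,
    cnorm_sdlog = iqr_sdlog(tbl$cnorm_q25, tbl$cnorm_q75),
    peak_ratio = c(2.2, 4.5, 1.8),
    peak_sdlog = c(0.15, 0.3, 0.15),
    reversal_depth = c(0, -0.6, 0),
    reversal_sdlog = c(0, 0.4, 0)
  )
}

#' Synthetic cohort configuration
#'
#' Defines the generating distributions for artery-specific synthetic
#' patients. Defaults reproduce the cohort statistics the pipeline was
#' developed on: mean flows (mL/min) CCA 458 +/- 139, SA 185 +/- 116,
#' VA 90 +/- 59 (lognormal, moment-matched, to guarantee positivity);
#' mean pressures (mmHg, normal) CCA 83 +/- 11, SA 85 +/- 12 (VA reuses the
#' SA pressure distribution — vertebral pressure was never measured
#' directly); heart rate 63 +/- 10 bpm; normalized parameters lognormal
#' around the cohort medians with log-spread matched to the cohort IQRs.
#'
#' @param n_patients Patients per artery (default 10).
#' @param arteries Subset of `c("CCA", "SA", "VA")`.
#' @param noise_sd Additive Gaussian pressure noise, mmHg (default 1).
#' @param seed Integer seed used by [generate_cohort()].
#' @param artery_config Optional replacement for the per-artery
#'   distribution tibble (columns as in the default).
#' @param nparam_spread Multiplier on the normalized-parameter log-spread
#'   (1 = cohort IQRs; 0 = every patient at the medians).
#' @param shape_spread Multiplier on the per-patient waveform-morphology
#'   log-spread (peak ratio, reversal depth). 1 emulates the visible
#'   patient-to-patient variation of the normalized waveform profiles,
#'   strongest for the subclavian artery; 0 gives every patient the
#'   artery's canonical template.
#' @param solver A [solver_settings()] used for forward simulation.
#' @return A `wk3_cohort_config` list.
#' @export
cohort_config <- function(n_patients = 10L,
                          arteries = c("CCA", "SA", "VA"),
                          noise_sd = 1,
                          seed = 1L,
                          artery_config = NULL,
                          nparam_spread = 1,
                          shape_spread = 1,
                          solver = solver_settings()) {
  cfg <- artery_config %||% default_artery_config()
  arteries <- match.arg(arteries, several.ok = TRUE)
  cfg <- cfg[cfg$artery %in% arteries, ]
  if (n_patients < 1) abort("`n_patients` must be at least 1")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  if (any(cfg$flow_mean <= 0) || any(cfg$pressure_mean <= 0) ||
      any(cfg$hr_mean <= 0) || any(cfg$flow_sd < 0)) {
    abort("distribution parameters must be positive")
  }
  structure(list(n_patients = as.integer(n_patients),
                 arteries = arteries, noise_sd = noise_sd,
                 seed = as.integer(seed), artery_config = cfg,
                 nparam_spread = nparam_spread,
                 shape_spread = shape_spread, solver = solver),
            class = "wk3_cohort_config")
}

# moment-matched lognormal draw
rlnorm_mom <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one synthetic patient
#'
#' Draws the clinical scalars and normalized parameters from the cohort
#' configuration, builds the dimensional flow waveform (artery template
#' scaled by the drawn mean flow on the drawn cardiac period), pins
#' Rtot = drawn mean pressure / mean flow, denormalizes, forward-simulates
#' the pressure, reads SBP/DBP off the noiseless simulated extrema, and
#' finally adds Gaussian measurement noise to the pressure. Uses the
#' current RNG state (seed management belongs to [generate_cohort()]).
#'
#' @param artery `"CCA"`, `"SA"` or `"VA"`.
#' @param config A [cohort_config()].
#' @return A `wk3_synthetic_patient` list: `artery`, `true_params`,
#'   `true_nparams`, `rtot`, `flow`, `pressure`, `pressure_clean`,
#'   `clinical` (one-row tibble: sbp, dbp, heart_rate, mean_flow_ml_min,
#'   mean_pressure).
#' @export
generate_patient <- function(artery, config = cohort_config()) {
  cfg <- config$artery_config[config$artery_config$artery == artery, ]
  if (nrow(cfg) != 1) abort(sprintf("artery %s not in config", artery))
  draw <- function() {
    list(
      qbar_min = rlnorm_mom(1, cfg$flow_mean, cfg$flow_sd),
      pbar = rnorm(1, cfg$pressure_mean, cfg$pressure_sd),
      hr = rnorm(1, cfg$hr_mean, cfg$hr_sd),
      r1norm = rlnorm(1, log(cfg$r1norm_median),
                      cfg$r1norm_sdlog * config$nparam_spread),
      cnorm = rlnorm(1, log(cfg$cnorm_median),
                     cfg$cnorm_sdlog * config$nparam_spread),
      peak_ratio = cfg$peak_ratio *
        rlnorm(1, 0, cfg$peak_sdlog * config$shape_spread),
      reversal_depth = cfg$reversal_depth *
        rlnorm(1, 0, cfg$reversal_sdlog * config$shape_spread))
  }
  ok <- function(d) {
    d$pbar > 40 && d$hr > 35 && d$hr < 120 && d$qbar_min > 1 &&
      d$r1norm > 1e-3 && d$r1norm < 0.95 && d$cnorm > 0.01 && d$cnorm < 10 &&
      d$peak_ratio > 1.3 && d$peak_ratio < 8 && d$reversal_depth > -1.5
  }
  d <- draw()
  tries <- 1L
  while (!ok(d) && tries < 100L) {
    d <- draw()
    tries <- tries + 1L
  }
  if (!ok(d)) abort("could not draw physiologic patient values in 100 tries")

  T <- 60 / d$hr
  qbar <- d$qbar_min / 60  # mL/s
  template <- make_flow_template(flow_template_params(
    artery, peak_ratio = d$peak_ratio,
    reversal_depth = d$reversal_depth))
  flow <- waveform(template$tau * T, template$value * qbar,
                   period = T, quantity = "flow")
  rt <- d$pbar / qbar
  nparams <- wk3_nparams(d$r1norm, d$cnorm)
  params <- denormalize_params(nparams, rt, T)
  p_clean <- simulate_pressure(flow, params, config$solver)
  noise <- if (config$noise_sd > 0) {
    rnorm(nrow(p_clean), 0, config$noise_sd)
  } else {
    0
  }
  pressure <- waveform(p_clean$time, pmax(p_clean$value + noise, 1e-3),
                       period = T, quantity = "pressure")
  structure(list(
    artery = artery,
    true_params = params,
    true_nparams = nparams,
    rtot = rt,
    flow = flow,
    pressure = pressure,
    pressure_clean = p_clean,
    clinical = tibble(sbp = max(p_clean$value), dbp = min(p_clean$value),
                      heart_rate = d$hr, mean_flow_ml_min = d$qbar_min,
                      mean_pressure = d$pbar)
  ), class = "wk3_synthetic_patient")
}

#' Generate a synthetic cohort
#'
#' Seeds the RNG from the configuration (so identical configurations give
#' identical cohorts) and generates `n_patients` per configured artery.
#' Ground truth always travels with the data: the returned tibble carries
#' the generating parameters next to the waveforms, and [write_cohort()]
#' serializes both.
#'
#' @param config A [cohort_config()].
#' @return A `wk3_cohort` tibble: `id`, `artery`, clinical scalars, true
#'   parameters (`true_r1`, `true_r2`, `true_c`, `true_rtot`,
#'   `true_r1norm`, `true_cnorm`), and list-columns `flow`, `pressure`,
#'   `patient`. Attribute `config` holds the configuration.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "wk3_cohort_config")) {
    abort("expected a `wk3_cohort_config`")
  }
  set.seed(config$seed)
  rows <- purrr::map(config$arteries, function(a) {
    purrr::map(seq_len(config$n_patients), function(i) {
      p <- generate_patient(a, config)
      tibble(
        id = sprintf("%s%02d", tolower(a), i),
        artery = a,
        sbp = p$clinical$sbp, dbp = p$clinical$dbp,
        heart_rate = p$clinical$heart_rate,
        mean_flow_ml_min = p$clinical$mean_flow_ml_min,
        true_r1 = p$true_params$r1, true_r2 = p$true_params$r2,
        true_c = p$true_params$c, true_rtot = p$rtot,
        true_r1norm = p$true_nparams$r1norm,
        true_cnorm = p$true_nparams$cnorm,
        flow = list(p$flow), pressure = list(p$pressure),
        patient = list(p))
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  structure(out, config = config,
            class = c("wk3_cohort", class(out)))
}

#' Serialize a synthetic cohort to plain-text files
#'
#' Writes one flow and one pressure CSV per patient (waveform CSV format),
#' a `manifest.csv` (id, artery, file paths), `truth.json` with the
#' generating parameters, and `config.json` with the resolved
#' configuration and seed.
#'
#' @param cohort A `wk3_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "wk3_cohort")) abort("expected a `wk3_cohort`")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::pmap(
    list(cohort$id, cohort$artery, cohort$flow, cohort$pressure),
    function(id, artery, flow, pressure) {
      fp <- file.path(dir, paste0(id, "_flow.csv"))
      pp <- file.path(dir, paste0(id, "_pressure.csv"))
      write_waveform(flow, fp)
      write_waveform(pressure, pp)
      tibble(id = id, artery = artery, flow = basename(fp),
             pressure = basename(pp))
    }) |> dplyr::bind_rows()
  write.csv(manifest, file.path(dir, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  truth <- cohort |>
    dplyr::select("id", "artery", "sbp", "dbp", "heart_rate",
                  "mean_flow_ml_min", dplyr::starts_with("true_")) |>
    as.data.frame()
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  config <- attr(cohort, "config")
  jsonlite::write_json(
    list(n_patients = config$n_patients, arteries = config$arteries,
         noise_sd = config$noise_sd, seed = config$seed,
         nparam_spread = config$nparam_spread,
         shape_spread = config$shape_spread,
         solver = unclass(config$solver),
         artery_config = as.data.frame(config$artery_config)),
    file.path(dir, "config.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort back from a manifest
#'
#' Loads the waveforms listed in a `manifest.csv` written by
#' [write_cohort()] (or hand-built with columns id, artery, flow,
#' pressure file paths relative to the manifest).
#'
#' @param manifest Path to a manifest CSV.
#' @return A cohort tibble with columns `id`, `artery`, `flow`, `pressure`.
#' @export
read_cohort <- function(manifest) {
  dir <- dirname(manifest)
  m <- read.csv(manifest, stringsAsFactors = FALSE)
  needed <- c("id", "artery", "flow", "pressure")
  if (!all(needed %in% names(m))) {
    abort("manifest needs columns id, artery, flow, pressure")
  }
  tibble(
    id = m$id, artery = m$artery,
    flow = purrr::map(file.path(dir, m$flow), read_waveform,
                      quantity = "flow"),
    pressure = purrr::map(file.path(dir, m$pressure), read_waveform,
                          quantity = "pressure"))
}
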