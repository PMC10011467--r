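#' Estimate Windkessel parameters from non-invasive clinical data
#'
#' The non-invasive estimation path: brachial cuff pressures give the mean
#' arterial pressure via the one-third pulse-pressure rule; mean flow comes
#' from Doppler ultrasound (mL/min) or from a flow--diameter power law
#' applied to the CTA lumen diameter; their ratio gives Rtot and the heart
#' rate gives the cardiac period T = 60/HR. The artery's median normalized
#' parameters from `table` are then scaled to (Rtot, T).
#'
#' @param artery `"CCA"`, `"SA"` or `"VA"` (or any artery present in
#'   `table`).
#' @param sbp,dbp Brachial systolic/diastolic pressure, mmHg.
#' @param heart_rate Heart rate, bpm.
#' @param mean_flow_ml_min Mean flow in mL/min (clinical convention;
#'   converted to mL/s internally). Optional if `diameter` and `law` are
#'   given.
#' @param diameter Lumen diameter in mm (used with `law` when
#'   `mean_flow_ml_min` is absent).
#' @param law A [flow_diameter_law()].
#' @param table Normalized parameter table
#'   (default [default_parameter_table()]).
#' @return A `wk3_params` with attributes `rtot`, `period`, `map`,
#'   `mean_flow` (mL/s) and `artery`.
#' @examples
#' estimate_wk3_noninvasive("CCA", sbp = 120, dbp = 80, heart_rate = 63,
#'                          mean_flow_ml_min = 458)
#' @export
estimate_wk3_noninvasive <- function(artery, sbp, dbp, heart_rate,
                                     mean_flow_ml_min = NULL,
                                     diameter = NULL, law = NULL,
                                     table = default_parameter_table()) {
  check_parameter_table(table)
  if (!artery %in% table$artery) {
    abort(sprintf("artery %s is not present in the parameter table", artery))
  }
  if (heart_rate <= 0) abort("`heart_rate` must be positive")
  map <- mean_arterial_pressure(sbp, dbp)
  qbar <- if (!is.null(mean_flow_ml_min)) {
    if (mean_flow_ml_min <= 0) abort("`mean_flow_ml_min` must be positive")
    mean_flow_ml_min / 60
  } else if (!is.null(diameter) && !is.null(law)) {
    mean_flow_from_diameter(diameter, law)
  } else {
    abort("supply `mean_flow_ml_min`, or `diameter` together with `law`")
  }
  rt <- total_resistance(map, qbar)
  T <- 60 / heart_rate
  row <- table[table$artery == artery, ][1, ]
  params <- denormalize_params(wk3_nparams(row$r1norm, row$cnorm), rt, T)
  attr(params, "rtot") <- rt
  attr(params, "period") <- T
  attr(params, "map") <- map
  attr(params, "mean_flow") <- qbar
  attr(params, "artery") <- artery
  params
}

#' Assess normalized parameters on a held-out test cohort
#'
#' Mirrors the training/testing assessment of the pipeline: the training
#' cohort is fitted per patient and the per-artery medians of the
#' normalized parameters are taken; for each test patient, Rtot and T are
#' computed from its own measured waveforms, the medians are denormalized,
#' and the resulting parameters are exercised in both directions —
#' simulating pressure from the measured flow (pressure direction) and
#' estimating flow from the measured pressure (flow direction). Relative L2
#' errors against the measured counterparts are summarized per artery as
#' median (IQR).
#'
#' Per-patient failures (e.g. a non-converged inverse solve) are propagated
#' as flagged rows.
#'
#' @param training,testing Cohort tibbles with columns `id`, `artery`,
#'   `flow`, `pressure` (see [fit_cohort()]).
#' @param settings A [fit_settings()] for the training fits.
#' @param solver A [solver_settings()].
#' @return A `wk3_assessment` list: `$patients` (per test patient errors in
#'   both directions), `$summary` (artery x direction median/q25/q75), and
#'   `$table` (the training-derived parameter table).
#' @export
evaluate_on_testset <- function(training, testing,
                                settings = fit_settings(),
                                solver = solver_settings()) {
  train_fit <- fit_cohort(training, settings = settings, solver = solver)
  table <- as_parameter_table(train_fit)
  rows <- purrr::pmap(
    list(testing$id, testing$artery, testing$flow, testing$pressure),
    function(id, artery, flow, pressure) {
      res <- tryCatch({
        if (!artery %in% table$artery) {
          abort(sprintf("artery %s missing from training medians", artery))
        }
        row <- table[table$artery == artery, ][1, ]
        qbar <- waveform_mean(flow)
        pbar <- waveform_mean(pressure)
        rt <- total_resistance(pbar, qbar)
        T <- wf_period(flow)
        params <- denormalize_params(wk3_nparams(row$r1norm, row$cnorm),
                                     rt, T)
        p_sim <- simulate_pressure(flow, params, solver)
        ep <- l2_relative_error(p_sim, pressure_on_grid(pressure, flow))
        q_sim <- estimate_flow(pressure, params, solver)
        eq <- l2_relative_error(q_sim$value,
                                wf_splinefun(flow)(pressure$time))
        list(ok = TRUE, error = NA_character_,
             pressure_error_pct = ep, flow_error_pct = eq)
      }, error = function(e) {
        list(ok = FALSE, error = conditionMessage(e),
             pressure_error_pct = NA_real_, flow_error_pct = NA_real_)
      })
      tibble(id = id, artery = artery, ok = res$ok, error = res$error,
             pressure_error_pct = res$pressure_error_pct,
             flow_error_pct = res$flow_error_pct)
    })
  patients <- dplyr::bind_rows(rows)
  summary <- patients |>
    dplyr::filter(.data$ok) |>
    tidyr::pivot_longer(c("pressure_error_pct", "flow_error_pct"),
                        names_to = "direction", values_to = "error_pct") |>
    dplyr::mutate(direction = ifelse(
      .data$direction == "pressure_error_pct", "pressure", "flow")) |>
    dplyr::group_by(.data$artery, .data$direction) |>
    dplyr::summarise(
      median = median(.data$error_pct),
      q25 = quantile(.data$error_pct, 0.25, names = FALSE),
      q75 = quantile(.data$error_pct, 0.75, names = FALSE),
      n = dplyr::n(),
      .groups = "drop")
  structure(list(patients = patients, summary = summary, table = table),
            class = "wk3_assessment")
}

# measured pressure resampled onto the simulated-pressure time base
pressure_on_grid <- function(pressure, flow) {
  ps <- wf_splinefun(pressure)
  phase <- (flow$time - flow$time[1]) / wf_period(flow)
  waveform(flow$time, ps(pressure$time[1] + phase * wf_period(pressure)),
           period = wf_period(flow), quantity = "pressure")
}

#' @export
print.wk3_assessment <- function(x, ...) {
  cat(sprintf("<wk3_assessment> %d test patients (%d ok)\n",
              nrow(x$patients), sum(x$patients$ok)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.wk3_assessment <- function(x, ...) x$patients

#' @export
glance.wk3_assessment <- function(x, ...) {
  tidyr::pivot_wider(
    dplyr::select(x$summary, "artery", "direction", "median"),
    names_from = c("artery", "direction"), values_from = "median",
    names_glue = "{tolower(artery)}_{direction}_median_pct")
}
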