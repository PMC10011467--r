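#' Settings for the constrained Windkessel fit
#'
#' Because Rtot = R1 + R2 is pinned to mean pressure over mean flow, only
#' two independent parameters remain. The fit optimizes (R1norm, Cnorm) —
#' Cnorm on a log scale — by bounded nonlinear least squares on the pressure
#' residuals; the Rtot constraint then holds exactly by construction.
#'
#' @param parameter_tolerance Relative step tolerance (default 0.001).
#' @param function_tolerance Relative cost tolerance (default 0.001).
#' @param r1norm_bounds Bounds for R1norm inside (0, 1)
#'   (default `c(1e-3, 0.999)`).
#' @param cnorm_bounds Bounds for Cnorm (default `c(1e-3, 10)`).
#' @param initial_guess Optional `c(r1norm, cnorm)` start; defaults to the
#'   artery's table median when the artery is known, else `c(0.1, 0.5)`.
#' @param max_iterations Iteration cap (default 100).
#' @return A `wk3_fit_settings` list.
#' @export
fit_settings <- function(parameter_tolerance = 1e-3,
                         function_tolerance = 1e-3,
                         r1norm_bounds = c(1e-3, 0.999),
                         cnorm_bounds = c(1e-3, 10),
                         initial_guess = NULL,
                         max_iterations = 100L) {
  if (parameter_tolerance <= 0 || function_tolerance <= 0) {
    abort("tolerances must be positive")
  }
  stopifnot(length(r1norm_bounds) == 2, length(cnorm_bounds) == 2)
  if (r1norm_bounds[1] >= r1norm_bounds[2] ||
      cnorm_bounds[1] >= cnorm_bounds[2]) {
    abort("bounds must be ordered (lo < hi)")
  }
  if (r1norm_bounds[1] <= 0 || r1norm_bounds[2] >= 1 ||
      cnorm_bounds[1] <= 0) {
    abort("R1norm bounds must lie in (0,1) and Cnorm bounds must be positive")
  }
  if (!is.null(initial_guess)) {
    stopifnot(length(initial_guess) == 2)
    if (initial_guess[1] < r1norm_bounds[1] ||
        initial_guess[1] > r1norm_bounds[2] ||
        initial_guess[2] < cnorm_bounds[1] ||
        initial_guess[2] > cnorm_bounds[2]) {
      abort("initial guess must lie inside the bounds")
    }
  }
  structure(list(parameter_tolerance = parameter_tolerance,
                 function_tolerance = function_tolerance,
                 r1norm_bounds = r1norm_bounds,
                 cnorm_bounds = cnorm_bounds,
                 initial_guess = initial_guess,
                 max_iterations = as.integer(max_iterations)),
            class = "wk3_fit_settings")
}

#' Relative L2 waveform-matching error
#'
#' The percentage L2-norm of the residual between a simulated and an
#' expected waveform on a shared comparison grid of N points:
#' 100 · sqrt( sum (x_sim - x_exp)^2 / sum x_exp^2 ).
#'
#' @param simulated,expected Waveforms (`wk_waveform` or `wk_nwaveform` on
#'   identical grids) or plain numeric vectors of equal length.
#' @return Error in percent.
#' @examples
#' l2_relative_error(c(110, 90), c(100, 100))  # 10
#' @export
l2_relative_error <- function(simulated, expected) {
  s <- extract_values(simulated)
  e <- extract_values(expected)
  if (length(s$value) != length(e$value) ||
      (!is.null(s$grid) && !is.null(e$grid) &&
       max(abs(s$grid - e$grid)) > 1e-9)) {
    abort("grid mismatch: waveforms must share the comparison grid")
  }
  denom <- sum(e$value^2)
  if (denom == 0) abort("expected waveform has zero norm")
  100 * sqrt(sum((s$value - e$value)^2) / denom)
}

extract_values <- function(x) {
  if (is_waveform(x)) list(grid = x$time, value = x$value)
  else if (is_nwaveform(x)) list(grid = x$tau, value = x$value)
  else if (is.numeric(x)) list(grid = NULL, value = as.double(x))
  else abort("expected a waveform or a numeric vector")
}

#' Fit Windkessel parameters to paired flow and pressure waveforms
#'
#' Identifies the patient-specific WK3 parameters. Rtot is fixed at mean
#' pressure over mean flow; the two free parameters (R1norm, log Cnorm) are
#' optimized by bounded Levenberg--Marquardt (trust-region) nonlinear least
#' squares on the residuals between simulated and measured pressure sampled
#' on the dimensionless 0.01 grid in dimensional time (N = 100). The sum of
#' squared errors (SSE, mmHg^2) is the cost; the relative L2 error at the
#' optimum is also reported.
#'
#' A constant flow input makes the two free parameters unidentifiable (any
#' pair reproduces P = Rtot·Q); the fit then returns the initial guess
#' flagged `identifiable = FALSE` rather than failing.
#'
#' @param flow Flow `wk_waveform` (mL/s), positive mean.
#' @param pressure Pressure `wk_waveform` (mmHg) sharing the cardiac period
#'   (within 1%); it is resampled onto the comparison grid.
#' @param artery Optional `"CCA"`, `"SA"` or `"VA"`; selects the default
#'   initial guess from [default_parameter_table()].
#' @param settings A [fit_settings()].
#' @param solver A [solver_settings()].
#' @return A `wk3_fit` object: `params`, `nparams`, `rtot`, `period`,
#'   `sse`, `l2_error_percent`, `iterations`, `converged`, `identifiable`,
#'   `cost_history`, and the fitted/measured pressures on the comparison
#'   grid. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_wk3 <- function(flow, pressure, artery = NULL,
                    settings = fit_settings(),
                    solver = solver_settings()) {
  check_waveform(flow, "flow")
  check_waveform(pressure, "pressure")
  T <- wf_period(flow)
  Tp <- wf_period(pressure)
  if (abs(Tp - T) > 0.01 * T) {
    abort(sprintf("cardiac periods disagree: flow %.4g s vs pressure %.4g s",
                  T, Tp))
  }
  check_solver(solver, T)
  qbar <- waveform_mean(flow)
  pbar <- waveform_mean(pressure)
  if (qbar <= 0 || pbar <= 0) {
    abort("mean flow and mean pressure must be positive")
  }
  rt <- pbar / qbar

  # comparison grid in dimensional time (flow time base origin)
  tk <- flow$time[1] + norm_grid() * T
  qs <- wf_splinefun(flow)
  ps <- wf_splinefun(pressure)
  p_exp <- ps(pressure$time[1] + norm_grid() * Tp)
  q_grid <- qs(tk)

  g <- solver_grid(T, solver)
  qhalf <- qs(flow$time[1] + g$t_half)

  guess <- settings$initial_guess %||% default_guess(artery)
  guess[1] <- clamp(guess[1], settings$r1norm_bounds)
  guess[2] <- clamp(guess[2], settings$cnorm_bounds)

  simulate_grid <- function(r1norm, cnorm) {
    params <- denormalize_params(wk3_nparams(r1norm, cnorm), rt, T)
    res <- integrate_cycles(qhalf / params$c, params$r2 * params$c, g$h,
                            y0 = params$r2 * qbar, solver, "fit simulation")
    pc <- splinefun(g$t_full, res$y)
    pc(tk - flow$time[1]) + params$r1 * q_grid
  }

  make_result <- function(r1norm, cnorm, iterations, converged,
                          identifiable, cost_history) {
    params <- denormalize_params(wk3_nparams(r1norm, cnorm), rt, T)
    p_sim <- simulate_grid(r1norm, cnorm)
    structure(list(
      params = params,
      nparams = wk3_nparams(r1norm, cnorm),
      rtot = rt, period = T,
      sse = sum((p_sim - p_exp)^2),
      l2_error_percent = l2_relative_error(p_sim, p_exp),
      iterations = iterations,
      converged = converged,
      identifiable = identifiable,
      cost_history = cost_history,
      fitted = new_comparison_waveform(tk, p_sim, T),
      measured = new_comparison_waveform(tk, p_exp, T),
      artery = artery
    ), class = "wk3_fit")
  }

  # rank-deficient degenerate case: constant flow
  if ((max(flow$value) - min(flow$value)) < 1e-8 * abs(qbar)) {
    return(make_result(guess[1], guess[2], 0L, TRUE, FALSE, numeric(0)))
  }

  residual_fun <- function(par) {
    simulate_grid(par[1], exp(par[2])) - p_exp
  }
  lm <- minpack.lm::nls.lm(
    par = c(guess[1], log(guess[2])),
    lower = c(settings$r1norm_bounds[1], log(settings$cnorm_bounds[1])),
    upper = c(settings$r1norm_bounds[2], log(settings$cnorm_bounds[2])),
    fn = residual_fun,
    control = minpack.lm::nls.lm.control(
      ftol = settings$function_tolerance,
      ptol = settings$parameter_tolerance,
      maxiter = settings$max_iterations))
  make_result(lm$par[1], exp(lm$par[2]), lm$niter,
              converged = lm$info %in% 1:3, identifiable = TRUE,
              cost_history = as.numeric(lm$rsstrace))
}

new_comparison_waveform <- function(time, value, period) {
  waveform(time, value, period = period, quantity = "pressure")
}

default_guess <- function(artery) {
  tbl <- default_parameter_table()
  if (!is.null(artery) && artery %in% tbl$artery) {
    row <- tbl[tbl$artery == artery, ]
    c(row$r1norm, row$cnorm)
  } else {
    c(0.1, 0.5)
  }
}

clamp <- function(x, bounds) min(max(x, bounds[1]), bounds[2])

#' @export
print.wk3_fit <- function(x, ...) {
  cat("<wk3_fit>\n")
  print(x$params)
  print(x$nparams)
  cat(sprintf("  SSE %.4g mmHg^2, L2 error %.3g%%, %d iterations%s%s\n",
              x$sse, x$l2_error_percent, x$iterations,
              if (x$converged) ", converged" else ", NOT converged",
              if (x$identifiable) "" else " (unidentifiable input)"))
  invisible(x)
}

#' @export
tidy.wk3_fit <- function(x, ...) {
  dplyr::bind_rows(tidy(x$params), tidy(x$nparams))
}

#' @export
glance.wk3_fit <- function(x, ...) {
  tibble(sse = x$sse, l2_error_percent = x$l2_error_percent,
         iterations = x$iterations, converged = x$converged,
         identifiable = x$identifiable, rtot = x$rtot, period = x$period)
}

#' Fit a cohort of patients and summarize per artery
#'
#' Runs [fit_wk3()] for every row of a cohort table and summarizes the
#' identified parameters per artery as medians and interquartile ranges
#' (linear-interpolation, type-7 quantiles), in both non-normalized and
#' normalized form. Per-patient failures are propagated as flagged rows,
#' not a batch abort.
#'
#' @param cohort A tibble with columns `id`, `artery`, and list-columns
#'   `flow`, `pressure` of `wk_waveform` objects (e.g. from
#'   [generate_cohort()]).
#' @param settings A [fit_settings()].
#' @param solver A [solver_settings()].
#' @return A `wk3_cohort_fit` list: `$fits` (per-patient tibble with an
#'   `ok` flag and a `fit` list-column) and `$summary` (artery x parameter
#'   median/q25/q75).
#' @export
fit_cohort <- function(cohort, settings = fit_settings(),
                       solver = solver_settings()) {
  needed <- c("id", "artery", "flow", "pressure")
  if (!is.data.frame(cohort) || !all(needed %in% names(cohort))) {
    abort("`cohort` needs columns id, artery, flow, pressure")
  }
  fits <- purrr::pmap(
    list(cohort$id, cohort$artery, cohort$flow, cohort$pressure),
    function(id, artery, flow, pressure) {
      res <- tryCatch(
        list(ok = TRUE, error = NA_character_,
             fit = fit_wk3(flow, pressure, artery = artery,
                           settings = settings, solver = solver)),
        error = function(e) list(ok = FALSE, error = conditionMessage(e),
                                 fit = NULL))
      tibble(id = id, artery = artery, ok = res$ok, error = res$error,
             r1 = fit_field(res$fit, function(f) f$params$r1),
             r2 = fit_field(res$fit, function(f) f$params$r2),
             c = fit_field(res$fit, function(f) f$params$c),
             rtot = fit_field(res$fit, function(f) f$rtot),
             r1norm = fit_field(res$fit, function(f) f$nparams$r1norm),
             r2norm = fit_field(res$fit, function(f) f$nparams$r2norm),
             cnorm = fit_field(res$fit, function(f) f$nparams$cnorm),
             sse = fit_field(res$fit, function(f) f$sse),
             l2_error_percent = fit_field(res$fit,
                                          function(f) f$l2_error_percent),
             converged = if (res$ok) res$fit$converged else NA,
             identifiable = if (res$ok) res$fit$identifiable else NA,
             fit = list(res$fit))
    })
  fits <- dplyr::bind_rows(fits)
  summary <- fits |>
    dplyr::filter(.data$ok) |>
    tidyr::pivot_longer(c("r1", "r2", "c", "rtot",
                          "r1norm", "r2norm", "cnorm"),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$artery, .data$parameter) |>
    dplyr::summarise(
      median = median(.data$value),
      q25 = quantile(.data$value, 0.25, names = FALSE, type = 7),
      q75 = quantile(.data$value, 0.75, names = FALSE, type = 7),
      n = dplyr::n(),
      .groups = "drop")
  structure(list(fits = fits, summary = summary), class = "wk3_cohort_fit")
}

fit_field <- function(fit, getter) {
  if (is.null(fit)) NA_real_ else getter(fit)
}

#' @export
print.wk3_cohort_fit <- function(x, ...) {
  cat(sprintf("<wk3_cohort_fit> %d patients (%d ok)\n",
              nrow(x$fits), sum(x$fits$ok)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.wk3_cohort_fit <- function(x, ...) {
  dplyr::select(x$fits, -"fit")
}

#' @export
glance.wk3_cohort_fit <- function(x, ...) {
  tibble(n_patients = nrow(x$fits), n_ok = sum(x$fits$ok),
         n_converged = sum(x$fits$converged, na.rm = TRUE))
}

#' Turn cohort-fit medians into a normalized parameter table
#'
#' Extracts the per-artery medians and IQRs of the normalized parameters in
#' the column layout of [default_parameter_table()], so a fitted training
#' cohort can drive the non-invasive estimation path.
#'
#' @param cohort_fit A `wk3_cohort_fit`.
#' @return A parameter-table tibble.
#' @export
as_parameter_table <- function(cohort_fit) {
  if (!inherits(cohort_fit, "wk3_cohort_fit")) {
    abort("expected a `wk3_cohort_fit`")
  }
  s <- cohort_fit$summary
  wide <- function(par, col) {
    v <- s[s$parameter == par, ]
    stats::setNames(v[[col]], v$artery)
  }
  arteries <- unique(s$artery)
  tibble(
    artery = arteries,
    r1norm = wide("r1norm", "median")[arteries],
    r1norm_q25 = wide("r1norm", "q25")[arteries],
    r1norm_q75 = wide("r1norm", "q75")[arteries],
    cnorm = wide("cnorm", "median")[arteries],
    cnorm_q25 = wide("cnorm", "q25")[arteries],
    cnorm_q75 = wide("cnorm", "q75")[arteries],
    provenance = "cohort fit medians"
  )
}
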