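#' Solver settings for the fixed-step Runge--Kutta integration
#'
#' The Windkessel ODE is integrated by classical fourth-order Runge--Kutta
#' at a fixed step (default 1e-4 s), repeating cardiac cycles from the end
#' state of the previous cycle until the max-norm relative change of the
#' trace between consecutive cycles falls below `cycle_tolerance` (periodic
#' steady state).
#'
#' @param step Time step in seconds (default `1e-4`); must not exceed
#'   period/100.
#' @param max_cycles Maximum number of cardiac cycles (default 50).
#' @param cycle_tolerance Relative cycle-to-cycle change threshold
#'   (default `1e-6`).
#' @return A `wk3_solver_settings` list.
#' @export
solver_settings <- function(step = 1e-4, max_cycles = 50L,
                            cycle_tolerance = 1e-6) {
  if (!is.finite(step) || step <= 0) abort("`step` must be positive")
  if (max_cycles < 2) abort("`max_cycles` must be at least 2")
  if (cycle_tolerance <= 0) abort("`cycle_tolerance` must be positive")
  structure(list(step = step, max_cycles = as.integer(max_cycles),
                 cycle_tolerance = cycle_tolerance),
            class = "wk3_solver_settings")
}

check_solver <- function(settings, period) {
  if (!inherits(settings, "wk3_solver_settings")) {
    abort("`settings` must come from `solver_settings()`")
  }
  if (settings$step > period / 100) {
    abort(sprintf("step %.3g s exceeds period/100 = %.3g s",
                  settings$step, period / 100))
  }
  invisible(settings)
}

# Core multi-cycle integration of y' = f(t) - y/tau on n fixed steps.
# fhalf: f at half-step resolution (length 2n+1). Errors on non-convergence.
integrate_cycles <- function(fhalf, tau, h, y0, settings, what) {
  res <- .wk_integrate_cycles(fhalf, tau, h, y0,
                              settings$max_cycles, settings$cycle_tolerance)
  if (!res$converged) {
    abort(sprintf(
      "%s did not reach periodic steady state in %d cycles (last cycle-to-cycle residual %.3g)",
      what, settings$max_cycles, res$residual))
  }
  res
}

# Shared plumbing: choose the step count, build half-step times.
solver_grid <- function(period, settings) {
  n <- max(100L, as.integer(round(period / settings$step)))
  list(n = n, h = period / n,
       t_half = seq(0, period, length.out = 2L * n + 1L),
       t_full = seq(0, period, length.out = n + 1L))
}

#' Simulate the Windkessel pressure response to a flow waveform
#'
#' Forward direction of the WK3 model. With capacitor pressure Pc as the
#' state, dPc/dt = (Q(t) - Pc/R2)/C and the output pressure is
#' P(t) = Pc(t) + R1·Q(t). Q between samples is evaluated from the periodic
#' cubic spline of the flow waveform. Integration starts from
#' Pc(0) = R2·mean(Q) (the steady capacitor mean, which minimizes the
#' transient) and repeats cycles to periodic steady state.
#'
#' @param flow A flow `wk_waveform` (mL/s).
#' @param params A `wk3_params`.
#' @param settings A [solver_settings()].
#' @return The steady-state pressure as a `wk_waveform` sampled on the flow
#'   waveform's time base, with attributes `cycles` and `residual`.
#' @examples
#' t <- seq(0, 0.99, by = 0.01)
#' q <- waveform(t, 5 + 2 * sin(2 * pi * t), period = 1, quantity = "flow")
#' p <- simulate_pressure(q, wk3_params(1, 10, 0.04))
#' waveform_mean(p) / waveform_mean(q)  # ~ Rtot = 11
#' @export
simulate_pressure <- function(flow, params, settings = solver_settings()) {
  check_waveform(flow, "flow")
  if (!inherits(params, "wk3_params")) abort("expected `wk3_params`")
  T <- wf_period(flow)
  check_solver(settings, T)
  g <- solver_grid(T, settings)
  qs <- wf_splinefun(flow)
  qhalf <- qs(flow$time[1] + g$t_half)
  qbar <- waveform_mean(flow)
  res <- integrate_cycles(qhalf / params$c, params$r2 * params$c, g$h,
                          y0 = params$r2 * qbar, settings,
                          "pressure simulation")
  pc <- splinefun(g$t_full, res$y)
  p <- pc(flow$time - flow$time[1]) + params$r1 * flow$value
  out <- waveform(flow$time, p, period = T, quantity = "pressure")
  attr(out, "cycles") <- res$cycles
  attr(out, "residual") <- res$residual
  out
}

#' Estimate the flow waveform from a pressure waveform
#'
#' Inverse direction of the WK3 model: eliminating the capacitor node gives
#' R1·C·dQ/dt = C·dP/dt - Q·(1 + R1/R2) + P/R2, integrated by the same
#' fixed-step RK4 to periodic steady state. dP/dt comes from the analytic
#' derivative of the periodic spline of the pressure samples. The flow
#' relaxation time R1·R2·C/(R1+R2) must be well resolved by the step; for
#' vanishing R1 the ODE degenerates and the algebraic relation
#' Q = C·dP/dt + P/R2 applies instead.
#'
#' @param pressure A pressure `wk_waveform` (mmHg).
#' @param params A `wk3_params`.
#' @param settings A [solver_settings()].
#' @return The steady-state flow as a `wk_waveform` (mL/s) on the pressure
#'   waveform's time base.
#' @export
estimate_flow <- function(pressure, params, settings = solver_settings()) {
  check_waveform(pressure, "pressure")
  if (!inherits(params, "wk3_params")) abort("expected `wk3_params`")
  T <- wf_period(pressure)
  check_solver(settings, T)
  tau <- params$r1 * params$r2 * params$c / (params$r1 + params$r2)
  if (settings$step > 2 * tau) {
    abort(paste0(
      sprintf("R1·C relaxation time %.3g s is too stiff for step %.3g s; ",
              tau, settings$step),
      "for R1 ~ 0 use the algebraic relation Q = C*dP/dt + P/R2"))
  }
  g <- solver_grid(T, settings)
  ps <- wf_splinefun(pressure)
  dps <- wf_splinefun(pressure, deriv = 1L)
  th <- pressure$time[1] + g$t_half
  fhalf <- (params$c * dps(th) + ps(th) / params$r2) / (params$r1 * params$c)
  pbar <- waveform_mean(pressure)
  res <- integrate_cycles(fhalf, tau, g$h,
                          y0 = pbar / (params$r1 + params$r2), settings,
                          "flow estimation")
  qf <- splinefun(g$t_full, res$y)
  q <- qf(pressure$time - pressure$time[1])
  out <- waveform(pressure$time, q, period = T, quantity = "flow")
  attr(out, "cycles") <- res$cycles
  attr(out, "residual") <- res$residual
  out
}

# Dimensionless forward solve on the 0.01 grid from precomputed half-step
# flow samples. Used by simulate_pressure_normalized() and by the Monte
# Carlo loop, which re-uses qhalf/qgrid across draws.
forward_normalized_core <- function(qhalf, qgrid, nparams, settings) {
  n <- (length(qhalf) - 1L) %/% 2L
  h <- 1 / n
  res <- integrate_cycles(qhalf / nparams$cnorm,
                          nparams$r2norm * nparams$cnorm, h,
                          y0 = nparams$r2norm, settings,
                          "normalized pressure simulation")
  if (n %% 100L == 0L) {
    pc <- res$y[seq(1L, n, by = n %/% 100L)]
  } else {
    pc <- splinefun(seq(0, 1, length.out = n + 1L), res$y)(norm_grid())
  }
  pc + nparams$r1norm * qgrid
}

#' Simulate normalized pressure from a normalized flow waveform
#'
#' The governing WK3 equation keeps its form under normalization of flow and
#' pressure by their means and time by the period: with Rtot = 1 and T = 1
#' the state equation is dPc/dtau = (q(tau) - Pc/R2norm)/Cnorm and
#' p = Pc + R1norm·q. The output is re-pinned to grid mean 1 to guard
#' against discretization drift.
#'
#' @param flow_norm A normalized flow `wk_nwaveform`.
#' @param nparams A `wk3_nparams`.
#' @param settings A [solver_settings()] (the step applies to dimensionless
#'   time; the default 1e-4 gives 10,000 steps per cycle).
#' @return A normalized pressure `wk_nwaveform`.
#' @export
simulate_pressure_normalized <- function(flow_norm, nparams,
                                         settings = solver_settings()) {
  check_nwaveform(flow_norm, "flow")
  if (!inherits(nparams, "wk3_nparams")) abort("expected `wk3_nparams`")
  check_solver(settings, 1)
  g <- solver_grid(1, settings)
  qs <- nwf_splinefun(flow_norm)
  p <- forward_normalized_core(qs(g$t_half), flow_norm$value, nparams,
                               settings)
  new_nwaveform(p / mean(p), "pressure")
}
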