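#' Single-period arterial waveforms
#'
#' A waveform is one cardiac period of a sampled quantity — volumetric flow
#' rate (mL/s) or pressure (mmHg) — stored as a tibble with columns `time`
#' (seconds, strictly increasing, within `[0, period]`) and `value`, plus
#' attributes `period` (cardiac period T in seconds) and `quantity`
#' (`"flow"` or `"pressure"`). Waveforms are treated as periodic: the value
#' at `t = period` wraps to the value at the first sample, and interpolation
#' between samples uses a periodic cubic spline so that the time derivative
#' needed by the Windkessel ODE is smooth.
#'
#' Pressure values must be positive; flow may be negative (early-diastolic
#' reversal, typical of the subclavian artery). At least two samples are
#' required; 16 or more are recommended for spline fidelity.
#'
#' @param time Numeric vector of sample times in seconds.
#' @param value Numeric vector of sampled values (mL/s for flow, mmHg for
#'   pressure).
#' @param period Cardiac period T in seconds.
#' @param quantity `"flow"` or `"pressure"`.
#' @return A `wk_waveform` tibble.
#' @examples
#' t <- seq(0, 0.99, by = 0.01)
#' w <- waveform(t, 5 + 2 * sin(2 * pi * t), period = 1, quantity = "flow")
#' waveform_mean(w)
#' @export
waveform <- function(time, value, period, quantity = c("flow", "pressure")) {
  quantity <- match.arg(quantity)
  time <- as.double(time)
  value <- as.double(value)
  if (length(time) != length(value)) {
    abort("`time` and `value` must have equal length")
  }
  if (length(time) < 2) {
    abort("a waveform needs at least 2 samples")
  }
  if (!is.numeric(period) || length(period) != 1 || !is.finite(period) ||
      period <= 0) {
    abort("`period` must be a single positive number (seconds)")
  }
  if (anyNA(time) || anyNA(value) || !all(is.finite(value)) ||
      !all(is.finite(time))) {
    abort("waveform samples must be finite (no NaN/NA)")
  }
  if (any(diff(time) <= 0)) {
    abort("non-monotone time: sample times must be strictly increasing")
  }
  if (time[1] < 0 || time[length(time)] > period + 1e-12) {
    abort("sample times must lie within [0, period]")
  }
  if (quantity == "pressure" && any(value <= 0)) {
    abort("pressure values must be positive")
  }
  out <- tibble(time = time, value = value)
  structure(out,
            period = period,
            quantity = quantity,
            class = c("wk_waveform", class(out)))
}

#' @export
print.wk_waveform <- function(x, ...) {
  cat(sprintf("<wk_waveform> %s, period %.4g s, %d samples\n",
              wf_quantity(x), wf_period(x), nrow(x)))
  NextMethod()
}

#' Waveform accessors
#'
#' `wf_period()` returns the cardiac period in seconds; `wf_quantity()`
#' returns `"flow"` or `"pressure"`.
#'
#' @param w A `wk_waveform` or `wk_nwaveform`.
#' @return A scalar.
#' @export
wf_period <- function(w) attr(w, "period")

#' @rdname wf_period
#' @export
wf_quantity <- function(w) attr(w, "quantity")

is_waveform <- function(w) inherits(w, "wk_waveform")

check_waveform <- function(w, quantity = NULL) {
  if (!is_waveform(w)) abort("expected a `wk_waveform` (see `waveform()`)")
  if (!is.null(quantity) && wf_quantity(w) != quantity) {
    abort(sprintf("expected a %s waveform, got %s", quantity, wf_quantity(w)))
  }
  invisible(w)
}

# Periodic cubic spline through the samples, wrapping value(T) = value(t0).
# Returns a function of absolute time; evaluation outside [t0, t0 + T]
# wraps periodically. deriv = 1 gives the analytic spline derivative.
wf_splinefun <- function(w, deriv = 0L) {
  t <- w$time
  v <- w$value
  T <- wf_period(w)
  n <- length(t)
  # drop a duplicated closing sample before appending the wrap point
  if (abs((t[n] - t[1]) - T) < 1e-12) {
    t <- t[-n]
    v <- v[-n]
  }
  f <- splinefun(c(t, t[1] + T), c(v, v[1]), method = "periodic")
  if (deriv == 0L) f else function(x) f(x, deriv = deriv)
}

# Periodic spline of a normalized waveform over dimensionless time.
nwf_splinefun <- function(w, deriv = 0L) {
  f <- splinefun(c(w$tau, 1), c(w$value, w$value[1]), method = "periodic")
  if (deriv == 0L) f else function(x) f(x, deriv = deriv)
}

# Period-average by the periodic trapezoidal rule: the sample polyline is
# closed through the wrap segment and integrated over one full period.
trapz_periodic_mean <- function(time, value, period) {
  n <- length(time)
  if (abs((time[n] - time[1]) - period) >= 1e-12) {
    time <- c(time, time[1] + period)
    value <- c(value, value[1])
  }
  dt <- diff(time)
  sum(dt * (value[-length(value)] + value[-1]) / 2) / period
}

#' Period mean of a waveform
#'
#' The average of the sampled quantity over one cardiac period, computed by
#' periodic trapezoidal integration (the polyline is closed through the wrap
#' segment from the last sample back to the first) divided by the period.
#' Mean flow and mean pressure computed this way define the total resistance
#' Rtot = mean pressure / mean flow.
#'
#' @param w A `wk_waveform`.
#' @return Scalar mean in the waveform's units.
#' @export
waveform_mean <- function(w) {
  check_waveform(w)
  trapz_periodic_mean(w$time, w$value, wf_period(w))
}

#' The dimensionless comparison grid
#'
#' All normalized waveforms live on the half-open uniform grid
#' tau = 0, 0.01, ..., 0.99 (100 points) of time over period; the period
#' point is not duplicated.
#'
#' @return Numeric vector of length 100.
#' @export
norm_grid <- function() seq(0, 0.99, by = 0.01)

new_nwaveform <- function(value, quantity) {
  out <- tibble(tau = norm_grid(), value = as.double(value))
  structure(out, quantity = quantity,
            class = c("wk_nwaveform", class(out)))
}

#' @export
print.wk_nwaveform <- function(x, ...) {
  cat(sprintf("<wk_nwaveform> normalized %s on the 0.01 grid\n",
              wf_quantity(x)))
  NextMethod()
}

is_nwaveform <- function(w) inherits(w, "wk_nwaveform")

check_nwaveform <- function(w, quantity = NULL) {
  if (!is_nwaveform(w)) {
    abort("expected a `wk_nwaveform` (see `normalize_waveform()`)")
  }
  if (!is.null(quantity) && wf_quantity(w) != quantity) {
    abort(sprintf("expected a normalized %s waveform", quantity))
  }
  invisible(w)
}

#' Normalize a waveform to unit mean and unit period
#'
#' Divides the values by their period mean and rescales time by the cardiac
#' period, then resamples onto the dimensionless 0.01 grid (100 points on
#' [0, 1)) by periodic cubic-spline interpolation. The resampled trace is
#' re-centred so its grid mean is exactly 1, making normalization idempotent
#' to machine precision. Normalized waveforms are what the cohort averaging,
#' Monte Carlo sensitivity analysis, and the dimensionless Windkessel solver
#' operate on.
#'
#' @param w A `wk_waveform`, or an already-normalized `wk_nwaveform`
#'   (returned unchanged).
#' @return A `wk_nwaveform` tibble with columns `tau`, `value`.
#' @export
normalize_waveform <- function(w) {
  if (is_nwaveform(w)) {
    # idempotence: re-pin the grid mean and return
    return(new_nwaveform(w$value / mean(w$value), wf_quantity(w)))
  }
  check_waveform(w)
  m <- waveform_mean(w)
  if (abs(m) < 1e-12) {
    abort("waveform mean is zero: normalization undefined")
  }
  s <- wf_splinefun(w)
  T <- wf_period(w)
  v <- s(w$time[1] + norm_grid() * T) / m
  new_nwaveform(v / mean(v), wf_quantity(w))
}

#' Pointwise ensemble average of normalized waveforms
#'
#' Averages a set of normalized waveforms of the same quantity on the common
#' 0.01 grid, as used to build the artery-specific reference inputs for the
#' sensitivity analysis. Returns the pointwise mean and standard deviation.
#'
#' @param members A list of `wk_nwaveform` objects of identical quantity.
#' @return A `wk_ensemble` tibble with columns `tau`, `mean`, `sd`;
#'   attributes `quantity`, `n_members`, and `members`.
#' @export
average_waveforms <- function(members) {
  if (!is.list(members) || length(members) == 0) {
    abort("`members` must be a non-empty list of normalized waveforms")
  }
  purrr::walk(members, check_nwaveform)
  quantities <- purrr::map_chr(members, wf_quantity)
  if (length(unique(quantities)) != 1) {
    abort("mixed quantities: all ensemble members must share one quantity")
  }
  mat <- vapply(members, function(m) m$value, numeric(100))
  mat <- matrix(mat, nrow = 100)
  mu <- rowMeans(mat)
  sdv <- if (ncol(mat) > 1) apply(mat, 1, sd) else rep(0, 100)
  out <- tibble(tau = norm_grid(), mean = mu, sd = sdv)
  structure(out,
            quantity = quantities[1],
            n_members = length(members),
            members = members,
            class = c("wk_ensemble", class(out)))
}

#' Convert an ensemble mean back to a normalized waveform
#'
#' @param ens A `wk_ensemble`.
#' @return The pointwise mean as a `wk_nwaveform` (grid mean re-pinned to 1).
#' @export
ensemble_mean <- function(ens) {
  if (!inherits(ens, "wk_ensemble")) abort("expected a `wk_ensemble`")
  new_nwaveform(ens$mean / mean(ens$mean), attr(ens, "quantity"))
}

#' Extract and smooth one pressure period from a raw trace
#'
#' Intra-operative pressure recordings span several beats and carry
#' transducer noise. Given the heart rate (taken from the imaging exam, as
#' the patient is sedated during pressure measurement), this extracts the
#' representative period T = 60/heart_rate by folding all complete periods
#' onto a common phase grid and averaging, then low-pass filters by keeping
#' the first `harmonics` Fourier harmonics of the cardiac frequency
#' (zero-phase; the DC term is kept so the mean is preserved exactly).
#'
#' @param raw A data frame with columns `time` (s) and `value` (mmHg)
#'   covering at least one cardiac period, or a `wk_waveform`.
#' @param heart_rate Heart rate in beats per minute.
#' @param harmonics Number of harmonics retained (default 10).
#' @param n_out Number of output samples on `[0, T)` (default 128).
#' @return A pressure `wk_waveform` with period `60/heart_rate`.
#' @export
smooth_pressure_trace <- function(raw, heart_rate, harmonics = 10L,
                                  n_out = 128L) {
  if (!is.data.frame(raw) || !all(c("time", "value") %in% names(raw))) {
    abort("`raw` must have columns `time` and `value`")
  }
  if (heart_rate <= 0) abort("`heart_rate` must be positive (bpm)")
  T <- 60 / heart_rate
  t0 <- raw$time[1]
  duration <- raw$time[nrow(raw)] - t0
  m <- floor(duration / T + 1e-9)
  if (m < 1) {
    abort(sprintf(
      "raw trace (%.3g s) is shorter than one cardiac period (%.3g s)",
      duration, T))
  }
  nfft <- 1024L
  tau <- seq(0, T, length.out = nfft + 1L)[-(nfft + 1L)]
  folded <- vapply(seq_len(m), function(j) {
    approx(raw$time, raw$value, xout = t0 + (j - 1) * T + tau,
           rule = 2)$y
  }, numeric(nfft))
  v <- rowMeans(matrix(folded, nrow = nfft))
  # zero-phase low-pass: truncate the Fourier series after `harmonics`
  co <- fft(v)
  keep <- c(seq_len(harmonics + 1L), seq(nfft - harmonics + 1L, nfft))
  co[setdiff(seq_len(nfft), keep)] <- 0
  vs <- Re(fft(co, inverse = TRUE)) / nfft
  idx <- round(seq(1, nfft, length.out = n_out + 1L))[seq_len(n_out)]
  waveform(tau[idx], vs[idx], period = T, quantity = "pressure")
}

#' Read a single-period waveform from CSV
#'
#' The format is a comment header followed by `time_s,value` rows:
#' ```
#' # quantity=flow units=mL/s period_s=0.952381
#' time_s,value
#' 0,1.23
#' ...
#' ```
#' Flow in mL/min is converted to mL/s on read; all internal computation is
#' in mL/s (resistances are mmHg·s/mL) and pressure is in mmHg.
#'
#' @param path CSV file path.
#' @param quantity Optional `"flow"`/`"pressure"`; must agree with the
#'   header when both are present.
#' @param flow_units Optional `"mL/s"` or `"mL/min"`; overrides the header
#'   units for flow.
#' @return A `wk_waveform`.
#' @export
read_waveform <- function(path, quantity = NULL, flow_units = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#")) {
    abort(sprintf("%s: missing `# quantity=... period_s=...` header", path))
  }
  hdr <- parse_header(lines[1])
  if (is.null(hdr$period_s)) {
    abort(sprintf("%s: missing period (period_s=...) in header", path))
  }
  q <- quantity %||% hdr$quantity
  if (is.null(q)) abort(sprintf("%s: quantity not declared", path))
  if (!is.null(quantity) && !is.null(hdr$quantity) &&
      quantity != hdr$quantity) {
    abort(sprintf("%s: header says quantity=%s but quantity=%s requested",
                  path, hdr$quantity, quantity))
  }
  dat <- read.csv(text = lines[-1])
  if (ncol(dat) < 2) abort(sprintf("%s: expected time_s,value columns", path))
  if (anyNA(dat[[1]]) || anyNA(dat[[2]])) {
    abort(sprintf("%s: NaN/missing values in waveform", path))
  }
  value <- dat[[2]]
  if (q == "flow") {
    units <- flow_units %||% hdr$units %||% "mL/s"
    if (!units %in% c("mL/s", "mL/min")) {
      abort(sprintf("%s: unknown flow units %s", path, units))
    }
    if (units == "mL/min") value <- value / 60
  }
  waveform(dat[[1]], value, period = as.double(hdr$period_s), quantity = q)
}

parse_header <- function(line) {
  line <- sub("^#\\s*", "", line)
  parts <- strsplit(trimws(line), "\\s+")[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) == 2) out[[p[1]]] <- p[2]
  }
  out
}

#' Write a waveform to CSV
#'
#' Inverse of [read_waveform()]; values are written with 6 significant
#' digits. Flow is always written in mL/s.
#'
#' @param w A `wk_waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path) {
  check_waveform(w)
  units <- if (wf_quantity(w) == "flow") "mL/s" else "mmHg"
  hdr <- sprintf("# quantity=%s units=%s period_s=%s",
                 wf_quantity(w), units, format(wf_period(w), digits = 10))
  body <- sprintf("%s,%s",
                  format(signif(w$time, 6), trim = TRUE, scientific = FALSE),
                  format(signif(w$value, 6), trim = TRUE))
  writeLines(c(hdr, "time_s,value", body), path)
  invisible(path)
}

#' Write an ensemble (grid, mean, sd) to CSV
#'
#' @param ens A `wk_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  if (!inherits(ens, "wk_ensemble")) abort("expected a `wk_ensemble`")
  df <- data.frame(grid = ens$tau, mean = signif(ens$mean, 6),
                   sd = signif(ens$sd, 6))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
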