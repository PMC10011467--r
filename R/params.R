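#' Three-element Windkessel parameters
#'
#' The WK3 (RCR) lumped model of a distal vascular bed: a proximal resistor
#' R1 in series with the parallel combination of a distal resistor R2 and a
#' capacitor (compliance) C. Pressure plays the role of voltage and flow of
#' current. The total resistance Rtot = R1 + R2 equals mean pressure over
#' mean flow at periodic steady state.
#'
#' @param r1 Proximal resistance, mmHg·s/mL (> 0).
#' @param r2 Distal resistance, mmHg·s/mL (> 0).
#' @param c Compliance, mL/mmHg (> 0).
#' @return A `wk3_params` object.
#' @examples
#' p <- wk3_params(r1 = 1.14, r2 = 10.35, c = 0.04)
#' rtot(p)
#' @export
wk3_params <- function(r1, r2, c) {
  vals <- c(r1 = r1, r2 = r2, c = c)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("R1, R2 and C must all be positive and finite")
  }
  structure(list(r1 = as.double(r1), r2 = as.double(r2), c = as.double(c)),
            class = "wk3_params")
}

#' @rdname wk3_params
#' @param params A `wk3_params` object.
#' @export
rtot <- function(params) {
  if (!inherits(params, "wk3_params")) abort("expected `wk3_params`")
  params$r1 + params$r2
}

#' @export
print.wk3_params <- function(x, ...) {
  cat(sprintf(
    "<wk3_params> R1 = %.4g, R2 = %.4g mmHg·s/mL; C = %.4g mL/mmHg (Rtot = %.4g)\n",
    x$r1, x$r2, x$c, rtot(x)))
  invisible(x)
}

#' Normalized (dimensionless) Windkessel parameters
#'
#' Normalization removes the patient-to-patient variation in mean flow,
#' mean pressure, and heart rate: R1norm = R1/Rtot, R2norm = R2/Rtot =
#' 1 - R1norm, Cnorm = Rtot·C/T. Only two of the three are independent;
#' `r2norm` is derived so the identity r1norm + r2norm = 1 holds exactly.
#'
#' @param r1norm Dimensionless proximal resistance fraction, in (0, 1).
#' @param cnorm Dimensionless compliance, > 0.
#' @return A `wk3_nparams` object with fields `r1norm`, `r2norm`, `cnorm`.
#' @export
wk3_nparams <- function(r1norm, cnorm) {
  if (!is.finite(r1norm) || r1norm <= 0 || r1norm >= 1) {
    abort("`r1norm` must lie strictly between 0 and 1")
  }
  if (!is.finite(cnorm) || cnorm <= 0) abort("`cnorm` must be positive")
  structure(list(r1norm = as.double(r1norm),
                 r2norm = 1 - as.double(r1norm),
                 cnorm = as.double(cnorm)),
            class = "wk3_nparams")
}

#' @export
print.wk3_nparams <- function(x, ...) {
  cat(sprintf(
    "<wk3_nparams> R1norm = %.4g, R2norm = %.4g, Cnorm = %.4g\n",
    x$r1norm, x$r2norm, x$cnorm))
  invisible(x)
}

#' Normalize / denormalize Windkessel parameters
#'
#' `normalize_params()` maps dimensional parameters to the dimensionless
#' form (R1norm = R1/Rtot, Cnorm = Rtot·C/T); `denormalize_params()` is its
#' exact inverse, scaling population-level normalized parameters to a
#' patient's total resistance and cardiac period (R1 = R1norm·Rtot,
#' R2 = R2norm·Rtot, C = Cnorm·T/Rtot).
#'
#' @param params A `wk3_params`.
#' @param nparams A `wk3_nparams`.
#' @param period Cardiac period T in seconds.
#' @param rtot Total resistance in mmHg·s/mL.
#' @return `wk3_nparams` or `wk3_params` respectively.
#' @export
normalize_params <- function(params, period) {
  if (!inherits(params, "wk3_params")) abort("expected `wk3_params`")
  if (period <= 0) abort("`period` must be positive")
  rt <- rtot(params)
  wk3_nparams(r1norm = params$r1 / rt, cnorm = rt * params$c / period)
}

#' @rdname normalize_params
#' @export
denormalize_params <- function(nparams, rtot, period) {
  if (!inherits(nparams, "wk3_nparams")) abort("expected `wk3_nparams`")
  if (rtot <= 0 || period <= 0) abort("`rtot` and `period` must be positive")
  wk3_params(r1 = nparams$r1norm * rtot,
             r2 = nparams$r2norm * rtot,
             c = nparams$cnorm * period / rtot)
}

#' Mean arterial pressure from cuff systolic/diastolic pressure
#'
#' The standard one-third pulse-pressure estimate, assuming systole occupies
#' one-third of the cardiac cycle: MAP = (SBP - DBP)/3 + DBP.
#'
#' @param sbp Systolic brachial pressure, mmHg.
#' @param dbp Diastolic brachial pressure, mmHg.
#' @return Mean arterial pressure in mmHg (vectorized).
#' @examples
#' mean_arterial_pressure(120, 80)
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(dbp <= 0) || any(sbp <= dbp)) {
    abort("require SBP > DBP > 0")
  }
  (sbp - dbp) / 3 + dbp
}

#' Total resistance from mean pressure and mean flow
#'
#' Rtot = mean pressure / mean flow, the periodic-steady-state identity of
#' the Windkessel circuit (the capacitor passes zero net charge per cycle).
#'
#' @param mean_pressure Mean pressure, mmHg.
#' @param mean_flow Mean flow, mL/s.
#' @return Total resistance in mmHg·s/mL (vectorized).
#' @export
total_resistance <- function(mean_pressure, mean_flow) {
  if (any(mean_pressure <= 0) || any(mean_flow <= 0)) {
    abort("mean pressure and mean flow must be positive")
  }
  mean_pressure / mean_flow
}

#' Empirical flow--diameter power law
#'
#' Mean flow scales with lumen diameter as Q = k·D^b. Exponents fitted for
#' the arch branch arteries fall between 1.6 and 2.4; an exponent outside
#' that range triggers a warning (not an error). No default coefficient is
#' shipped: k depends on the population and must be supplied.
#'
#' @param k Coefficient, (mL/s)/mm^b, > 0.
#' @param b Dimensionless exponent.
#' @return A `wk3_flow_diameter_law` object.
#' @export
flow_diameter_law <- function(k, b) {
  if (!is.finite(k) || k <= 0) abort("`k` must be positive")
  if (!is.finite(b)) abort("`b` must be finite")
  if (b < 1.6 || b > 2.4) {
    warn(sprintf(
      "exponent b = %.3g is outside the range 1.6-2.4 reported for arch branch arteries",
      b))
  }
  structure(list(k = as.double(k), b = as.double(b)),
            class = "wk3_flow_diameter_law")
}

#' Mean flow from lumen diameter
#'
#' Applies a [flow_diameter_law()]: Q = k·D^b.
#'
#' @param diameter Lumen diameter in mm, > 0.
#' @param law A `wk3_flow_diameter_law`.
#' @return Mean flow in mL/s (vectorized over `diameter`).
#' @export
mean_flow_from_diameter <- function(diameter, law) {
  if (!inherits(law, "wk3_flow_diameter_law")) {
    abort("`law` must be a `wk3_flow_diameter_law`")
  }
  if (any(diameter <= 0)) abort("`diameter` must be positive")
  law$k * diameter^law$b
}

#' Artery-specific normalized parameter table
#'
#' The cohort-derived medians and interquartile ranges of the normalized
#' Windkessel parameters for common carotid (CCA), subclavian (SA), and
#' vertebral (VA) arteries, from a ten-patient cohort fitted against
#' invasively measured pre-deployment pressures. `r2norm` columns are
#' derived as 1 - r1norm. These are the shipped defaults for the
#' non-invasive estimation path; a user table with the same columns can be
#' substituted.
#'
#' Provenance: vertebral-artery fits used subclavian pressure waveforms
#' (vertebral pressure was not measured); right-side arteries reused
#' left-side pressures.
#'
#' @return A tibble with columns `artery`, `r1norm`, `r1norm_q25`,
#'   `r1norm_q75`, `cnorm`, `cnorm_q25`, `cnorm_q75`, `provenance`.
#' @export
default_parameter_table <- function() {
  tibble(
    artery = c("CCA", "SA", "VA"),
    r1norm = c(0.10, 0.03, 0.18),
    r1norm_q25 = c(0.07, 0.02, 0.08),
    r1norm_q75 = c(0.15, 0.04, 0.41),
    cnorm = c(0.46, 1.91, 0.47),
    cnorm_q25 = c(0.33, 1.63, 0.32),
    cnorm_q75 = c(0.58, 2.26, 0.85),
    provenance = c(
      "cohort median (n = 10), invasive pre-deployment left CCA pressure; right side reuses left pressures",
      "cohort median (n = 10), invasive pre-deployment left SA pressure; right side reuses left pressures",
      "cohort median (n = 10), fitted with SA pressure waveforms (VA pressure not measured)"
    )
  )
}

check_parameter_table <- function(table) {
  needed <- c("artery", "r1norm", "cnorm")
  if (!is.data.frame(table) || !all(needed %in% names(table))) {
    abort("parameter table needs columns artery, r1norm, cnorm")
  }
  invisible(table)
}

#' @export
tidy.wk3_params <- function(x, ...) {
  tibble(term = c("r1", "r2", "c", "rtot"),
         estimate = c(x$r1, x$r2, x$c, rtot(x)),
         unit = c("mmHg·s/mL", "mmHg·s/mL", "mL/mmHg", "mmHg·s/mL"))
}

#' @export
tidy.wk3_nparams <- function(x, ...) {
  tibble(term = c("r1norm", "r2norm", "cnorm"),
         estimate = c(x$r1norm, x$r2norm, x$cnorm),
         unit = "dimensionless")
}
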