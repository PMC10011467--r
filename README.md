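# windkessel

Identification and non-invasive estimation of three-element Windkessel
(WK3/RCR) outflow parameters for the aortic arch branch arteries — common
carotid (CCA), subclavian (SA) and vertebral (VA).

Image-based CFD of the aortic arch needs outflow boundary conditions, and
the WK3 model — a proximal resistor R1 in series with a distal resistor R2
parallel to a capacitor C — is the standard choice. Patient-specific flow
*and* pressure waveforms to calibrate it are rarely available. This package
implements the full pipeline for the case when they are, and the fallback
for when they are not:

- **Forward/inverse solver** — fixed-step (1e-4 s) classical Runge–Kutta
  integration of `dPc/dt = (Q − Pc/R2)/C`, `P = Pc + R1·Q` to periodic
  steady state (flow → pressure), and of the eliminated form
  `R1·C·dQ/dt = C·dP/dt − Q(1 + R1/R2) + P/R2` (pressure → flow), validated
  against the analytic impedance `Z(ω) = R1 + R2/(1 + iωR2C)`.
- **Constrained fitting** — `Rtot = R1 + R2` is pinned at mean pressure
  over mean flow, and the two free parameters `(R1norm, Cnorm)` are found
  by bounded trust-region nonlinear least squares on the pressure residual.
- **Normalization** — `R1norm = R1/Rtot`, `R2norm = 1 − R1norm`,
  `Cnorm = Rtot·C/T` make parameters transferable across patients; a
  cohort-derived table of per-artery medians/IQRs ships as the default.
- **Non-invasive estimation** — cuff SBP/DBP → mean pressure via the
  one-third rule, mean flow from Doppler or a flow–diameter power law
  `Q = k·D^b`, then denormalization of the table medians.
- **Monte Carlo sensitivity** — 1500 uniform draws over the
  `(R1norm, Cnorm)` plane mapping the pressure-match cost.
- **Synthetic cohort generator** — artery-specific waveform templates and
  cohort-matched distributions, with ground truth always serialized, so the
  whole pipeline is testable end to end without any patient data.

## Worked example

```r
library(windkessel)

# Non-invasive path: cuff 120/80 mmHg, HR 63 bpm, carotid flow 458 mL/min
est <- estimate_wk3_noninvasive("CCA", sbp = 120, dbp = 80,
                                heart_rate = 63, mean_flow_ml_min = 458)
est
#> <wk3_params> R1 = 1.223, R2 = 11 mmHg·s/mL; C = 0.03583 mL/mmHg (Rtot = 12.23)
```

The chain behind those numbers: mean pressure `(120 − 80)/3 + 80 = 93.33`
mmHg, mean flow `458/60 = 7.633` mL/s, so `Rtot = 93.33/7.633 = 12.23`
mmHg·s/mL and `T = 60/63 = 0.952` s; the carotid table medians
`(R1norm, Cnorm) = (0.10, 0.46)` then give `R1 = 0.10 × 12.23 = 1.223`,
`R2 = 0.90 × 12.23 = 11.00` and `C = 0.46 × 0.952/12.23 = 0.0358`.

With measured waveforms, fit instead of transfer:

```r
cohort <- generate_cohort(cohort_config(n_patients = 1, seed = 4,
                                        arteries = "CCA", noise_sd = 0))
fit <- fit_wk3(cohort$flow[[1]], cohort$pressure[[1]], artery = "CCA")
glance(fit)
#> # A tibble: 1 × 7
#>            sse l2_error_percent iterations converged identifiable  rtot period
#>          <dbl>            <dbl>      <int> <lgl>     <lgl>        <dbl>  <dbl>
#> 1 0.0000000146        0.0000156          4 TRUE      TRUE          9.89  0.834
tidy(fit)          # r1, r2, c, rtot and the normalized parameters
autoplot(fit)      # measured vs simulated pressure overlay
```

A command-line wrapper lives in `exec/wk3`
(`wk3 fit --flow f.csv --pressure p.csv --out fit.json`, plus `simulate`,
`estimate-flow`, `estimate`, `fit-cohort`, `sensitivity`, `synth`,
`evaluate`).

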