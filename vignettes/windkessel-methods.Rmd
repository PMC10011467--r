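---
title: "Methods: Windkessel identification, normalization, and non-invasive estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Windkessel identification, normalization, and non-invasive estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windkessel)
```

## The model

The three-element Windkessel (WK3, or RCR) model lumps the vascular bed
distal to an artery into a proximal resistor $R_1$ in series with the
parallel combination of a distal resistor $R_2$ and a capacitor
(compliance) $C$. With pressure as voltage and flow as current, the state
equation for the capacitor pressure $P_c$ and the output pressure $P$ are

$$\frac{dP_c}{dt} = \frac{1}{C}\Big(Q(t) - \frac{P_c}{R_2}\Big), \qquad
  P(t) = P_c(t) + R_1\,Q(t).$$

At periodic steady state the capacitor passes no net charge, so the period
means satisfy $\bar P = R_{tot}\,\bar Q$ with $R_{tot} = R_1 + R_2$. For
sinusoidal forcing the analytic input impedance
$Z(\omega) = R_1 + R_2/(1 + i\omega R_2 C)$ provides an independent oracle
against which the numerical solver is validated in the test suite.

Units are mmHg, seconds and mL/s throughout (resistances mmHg·s/mL,
compliance mL/mmHg). Flow reported clinically in mL/min is converted on
read.

## Normalization

Patient-to-patient differences in mean flow, mean pressure and heart rate
are removed by the dimensionless parameters

$$R_{1,norm} = \frac{R_1}{R_{tot}},\quad
  R_{2,norm} = \frac{R_2}{R_{tot}} = 1 - R_{1,norm},\quad
  C_{norm} = \frac{R_{tot}\,C}{T},$$

where $T$ is the cardiac period. Normalizing flow and pressure by their
means and time by $T$ leaves the governing equation unchanged with
$R_{tot} = 1$ and $T = 1$; the package carries both a dimensional and a
dimensionless solver and tests their agreement. `normalize_params()` and
`denormalize_params()` are exact mutual inverses by construction.

The shipped `default_parameter_table()` holds the cohort medians and IQRs
of $(R_{1,norm}, C_{norm})$ for the common carotid (CCA), subclavian (SA)
and vertebral (VA) arteries, derived from ten patients with paired
ultrasound flow and invasive pressure recordings. Two provenance caveats
travel with the table: vertebral fits reused subclavian pressure waveforms
(vertebral pressure cannot be measured safely intra-operatively), and
right-side arteries reused left-side pressures.

## Numerical solver

Both directions of the model reduce to the scalar linear ODE
$y' = f(t) - y/\tau$ (forward: $y = P_c$, $f = Q/C$, $\tau = R_2 C$;
inverse: $y = Q$, $f = (C\,dP/dt + P/R_2)/(R_1 C)$,
$\tau = R_1 R_2 C / R_{tot}$). It is integrated by classical fourth-order
Runge–Kutta at a fixed step of $10^{-4}$ s (configurable via
`solver_settings()`), with cycles repeated until the max-norm relative
change between consecutive cycle traces falls below $10^{-6}$, and at most
50 cycles. The contraction factor per cycle is $e^{-T/\tau}$, so slowly
relaxing beds (large $R_2 C$) use most of that budget while typical arch
parameters converge in well under 20 cycles. Numerical choices:

- **Initial condition** $P_c(0) = R_2 \bar Q$ (the steady capacitor mean):
  any start converges, this one minimizes the transient.
- **Interpolation**: waveforms are treated as periodic; $Q(t)$ and
  $dP/dt$ between samples come from a periodic cubic spline and its
  analytic derivative, never from finite differences of samples.
- **Stiffness guard**: the inverse direction errors out when the step
  exceeds twice the relaxation time $R_1 R_2 C / R_{tot}$ (explicit RK4
  would be unstable) and points to the algebraic limit
  $Q = C\,dP/dt + P/R_2$ that applies as $R_1 \to 0$.
- Halving the step changes the converged pressure by less than $10^{-6}$
  relative (verified in the tests), so the default step is far inside the
  asymptotic regime.

## Parameter identification

`fit_wk3()` pins $R_{tot} = \bar P / \bar Q$ from the measured waveforms —
the constraint then holds exactly, not approximately — and optimizes the
two free parameters $(R_{1,norm}, \log C_{norm})$ by bounded
Levenberg–Marquardt nonlinear least squares (`minpack.lm`), with both
parameter and function tolerances of $10^{-3}$. The residual is
$P_{sim}(t_k) - P_{exp}(t_k)$ on the dimensionless 0.01 grid mapped into
dimensional time ($N = 100$ points): the integration step controls solver
accuracy, while residual sampling at 100 points per cycle is ample for
waveforms whose energy sits in the first dozen harmonics. The optimizer
works in $\log C_{norm}$ because compliance is a scale parameter; bounds
default to $R_{1,norm} \in [10^{-3}, 0.999]$, $C_{norm} \in [10^{-3}, 10]$.
The default initial guess is the artery's table median when the artery is
stated, else $(0.1, 0.5)$.

Degenerate inputs are handled, not hidden: a constant flow makes the two
free parameters unidentifiable (any pair reproduces $P = R_{tot} Q$), so
the fit returns its initial guess flagged `identifiable = FALSE`.

Cohort summaries use type-7 (linear-interpolation) quantiles for the
medians and IQRs.

## Non-invasive estimation path

When no waveforms exist for a patient, `estimate_wk3_noninvasive()` chains

1. mean arterial pressure from cuff values, $\bar P = (SBP - DBP)/3 + DBP$
   (systole taken as one-third of the cycle);
2. mean flow from Doppler (mL/min) or from a flow–diameter power law
   $\bar Q = k D^b$ — the package ships no default coefficient because $k$
   is population-specific; exponents outside the reported 1.6–2.4 range
   warn rather than fail;
3. $R_{tot} = \bar P / \bar Q$ and $T = 60/\text{HR}$;
4. denormalization of the artery's median normalized parameters.

`evaluate_on_testset()` assesses such transferred parameters end to end:
it fits a training cohort, takes per-artery medians, scales them to each
test patient's own $R_{tot}$ and $T$, then measures the relative L2 error
$100\sqrt{\sum(x_{sim}-x_{exp})^2 / \sum x_{exp}^2}$ in both directions —
simulated pressure against measured pressure, and estimated flow against
measured flow.

## Monte Carlo sensitivity

`monte_carlo_sensitivity()` draws 1500 (configurable) parameter pairs
uniformly over $R_{1,norm} \in (0.001, 0.6]$, $C_{norm} \in (0.01, 3]$ —
ranges chosen to cover the plausible normalized plane and fully
configurable — and records, for each pair, the sum of squared differences
between the simulated and reference normalized pressures over the 0.01
grid. All draws are evaluated (no early stopping); the map is
deterministic given its seed, which is stored in the result. Because the
cost is a plain SSE on the dimensionless grid, its absolute magnitude is
comparable across arteries only qualitatively.

## The synthetic cohort generator

No patient recordings are distributable, so every end-to-end claim is
exercised on synthetic patients whose generating truth is known and always
serialized next to the data. The generator emulates:

- **Waveform morphology.** Truncated-Fourier templates (12 harmonics)
  shaped by peak-to-mean ratio, early-diastolic reversal depth, and a
  systolic fraction of 1/3: mono-phasic shapes for CCA (peak 2.2) and VA
  (peak 1.8), and the subclavian pattern of a high systolic peak (4.5)
  with flow reversal (−0.6). Published waveform figures are emulated
  qualitatively, never digitized.
- **Cohort statistics.** Mean flows (mL/min) CCA 458 ± 139, SA 185 ± 116,
  VA 90 ± 59 (lognormal, moment-matched, guaranteeing positivity); mean
  pressures (mmHg, normal) CCA 83 ± 11 and SA 85 ± 12, with VA reusing the
  SA distribution because vertebral pressure was never measured directly;
  heart rate 63 ± 10 bpm.
- **Parameter heterogeneity.** $(R_{1,norm}, C_{norm})$ lognormal around
  the table medians with log-spread matched to the table IQRs
  ($\sigma_{\log} = \log(q_{75}/q_{25}) / (2 \Phi^{-1}(0.75))$).
- **Morphology heterogeneity.** Per-patient lognormal jitter of the
  template shape (peak ratio $\sigma_{\log}$ 0.15 for CCA/VA and 0.30 for
  SA; reversal depth $\sigma_{\log}$ 0.40 for SA). The cohort the method
  was built on showed clearly varying normalized flow profiles, strongest
  for the subclavian artery, and the largest flow-direction errors arose
  in subclavian vessels with very high systolic peaks and deep reversal;
  a fixed-template cohort would miss that feature entirely.
- **Measurement noise.** Additive Gaussian pressure noise, default
  $\sigma = 1$ mmHg. Cuff SBP/DBP are read off the *noiseless* simulated
  extrema, so the one-third MAP rule disagrees slightly with the true
  waveform mean — a realistic, intentional discrepancy.

What the generator does **not** emulate: model mismatch (its pressures are
produced by the same WK3 family that is later fitted, so fit errors on
synthetic data are lower than the 3–4% seen on real recordings), beat-to-
beat variability, pathological shapes such as subclavian-steal negative
systolic peaks, and measurement systematics of Doppler tracing. Passing
tests therefore demonstrate the correctness and conditioning of the
algorithms, not clinical accuracy.

```{r example, eval = FALSE}
training <- generate_cohort(cohort_config(n_patients = 10, seed = 1))
testing <- generate_cohort(cohort_config(n_patients = 10, seed = 2))
assessment <- evaluate_on_testset(training, testing)
assessment$summary
```

With the default configuration (10 patients per artery, the study's size)
the flow-direction median errors exceed the pressure-direction errors for
every artery and are largest for the subclavian template — the same
asymmetry reported on the real cohort, where a WK3 driven by pressure
cannot reconstruct the high-frequency complexity of peaky, reversing flow
waveforms. The dimensionless problem sizes used throughout the tests
(100-point comparison grids, $10^{-4}$ step, 1500 Monte Carlo draws,
cohorts of 10 per artery, 20 noise replicates) match the scales the
method is used at on real data.

## Known limitations

- The identification assumes one representative cycle; beat selection from
  multi-beat recordings is limited to period folding and harmonic
  smoothing in `smooth_pressure_trace()`.
- The inverse (pressure-to-flow) direction is intrinsically
  ill-conditioned for small $R_{1,norm}$: high-frequency pressure content
  is amplified by $1/R_1$. That is a property of the model, reported
  honestly by the assessment, not a solver artifact.
- A four-element Windkessel (adding inertance) could capture sharper flow
  features but is deliberately out of scope: inertance is hard to estimate
  from the available data.
- Estimation is limited to arteries present in the parameter table
  (CCA, SA, VA); no stratification by sex or age is attempted.
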