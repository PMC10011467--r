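# Fixtures built in code: sinusoidal and template-based waveform pairs.

sin_flow <- function(mean = 7.63, amp = 2, period = 1, n = 100,
                     phase = 0) {
  t <- seq(0, period * (n - 1) / n, length.out = n)
  waveform(t, mean + amp * sin(2 * pi * t / period + phase),
           period = period, quantity = "flow")
}

sin_pressure <- function(mean = 85, amp = 10, period = 1, n = 100) {
  t <- seq(0, period * (n - 1) / n, length.out = n)
  waveform(t, mean + amp * sin(2 * pi * t / period),
           period = period, quantity = "pressure")
}

# dimensional flow from an artery template
template_flow <- function(artery = "CCA", qbar = 7.63, period = 0.952,
                          ...) {
  tmpl <- make_flow_template(flow_template_params(artery, ...))
  waveform(tmpl$tau * period, tmpl$value * qbar,
           period = period, quantity = "flow")
}

# paired (flow, noiseless pressure) generated by the forward model
template_pair <- function(artery = "CCA", params = wk3_params(1.14, 10.35, 0.04),
                          qbar = 7.63, period = 0.952) {
  flow <- template_flow(artery, qbar = qbar, period = period)
  list(flow = flow,
       pressure = simulate_pressure(flow, params),
       params = params)
}

# WK3 input impedance at angular frequency w (the analytic oracle)
wk3_impedance <- function(params, w) {
  params$r1 + params$r2 / (1 + 1i * w * params$r2 * params$c)
}

# amplitude and phase of the fundamental of a sampled waveform
fundamental <- function(w, omega) {
  X <- cbind(1, sin(omega * w$time), cos(omega * w$time))
  co <- qr.solve(X, w$value)
  list(mean = co[1], amp = sqrt(co[2]^2 + co[3]^2),
       phase = atan2(co[3], co[2]))
}

random_params <- function() {
  wk3_params(r1 = runif(1, 0.3, 3), r2 = runif(1, 5, 50),
             c = runif(1, 0.005, 0.1))
}
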