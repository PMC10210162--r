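# shared fixtures, built in code

# a physiological branch pressure cycle: truth-Windkessel response to a
# synthetic systolic flow pulse, taken at the periodic state
physio_pressure_cycle <- function(truth = wk_params(3.7e7, 8.5e8, 2e-9),
                                  dt = 0.001) {
  synth_wk_truth_pair(truth, dt = dt)$pressure
}

# analytic 3EWM pressure response to Q(t) = Q0 + Qa sin(om t):
# particular solution via the complex input impedance Z + R/(1 + i om R C),
# homogeneous decay exp(-t / RC) fixed by P(0) = p_init
analytic_wk_pressure <- function(params, t, Q0, Qa, om, p_init) {
  H <- params$Z + params$R / (1 + 1i * om * params$R * params$C)
  Pp <- (params$R + params$Z) * Q0 + Im(H * Qa * exp(1i * om * t))
  Pp0 <- (params$R + params$Z) * Q0 + Im(H * Qa + 0i)
  Pp + (p_init - Pp0) * exp(-t / (params$R * params$C))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
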