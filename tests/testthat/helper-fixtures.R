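# Shared fixtures and independent oracles for the test suite.

# Closed-form solution of the adaptive-threshold ODE for a constant input:
# with e = u - x and e(0) = e0 > 0,  de/dt = -e^b / tau  integrates to
# e(t) = (e0^(1-b) + (b-1) t / tau)^(-1/(b-1)).  Independent of the RK4
# integration path used by the package.
threshold_gap_closed_form <- function(t, e0, b, tau) {
  (e0^(1 - b) + (b - 1) * t / tau)^(-1 / (b - 1))
}

# 60 samples/s grid, the robot's serial rate.
grid60 <- function(t_end) seq(0, t_end, by = 1 / 60)

# Small, quiet sensor chain for pipeline tests where noise is not the point.
quiet_chain <- function() {
  sensor_chain_params(noise_sd = 0, drift_amp = 0)
}

# One short stepping run (shared across tests; computed lazily once).
.fixture_env <- new.env(parent = emptyenv())
baseline_3step <- function() {
  if (is.null(.fixture_env$rec3)) {
    .fixture_env$rec3 <- simulate_stepping(n_steps = 3, seed = 11)
  }
  .fixture_env$rec3
}
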