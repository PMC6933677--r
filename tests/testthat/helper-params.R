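# Canonical dimensionless parameter point used throughout the tests:
# mu = k = ln 2, s0 = 1 gives tau = 1, theta = k*s0/mu = 1, delta_bar = 1,
# so times are in doubling times and sizes are relative to s0.
params_unit <- function() model_params(mu = log(2), k = log(2), s0 = 1)

# Uniform grid on [0, n_tau] whose step divides tau exactly.
grid_tau <- function(n_tau, per_tau = 73L) {
  seq(0, n_tau, length.out = n_tau * per_tau + 1L)
}
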