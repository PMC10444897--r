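# Shared fixtures for the test-suite: small, fast parameter sets built in code.

# Representative 1D-model parameters (tube-experiment scale)
params_default <- function(k1 = 12.5, Delta = 1e-4, L = 5e-3) {
  lysis_params(F0 = 2.4, Fstar = 0.2, Fbar0 = 1e-5, k1 = k1,
               u_f = 5e-6, Delta = Delta, L = L)
}

# Random valid parameter draw for property-style tests
random_params <- function() {
  F0 <- stats::runif(1, 0.5, 6)
  lysis_params(F0 = F0,
               Fstar = F0 * stats::runif(1, 0.01, 0.6),
               Fbar0 = 10^stats::runif(1, -6, -4),
               k1 = 10^stats::runif(1, 0, 3),
               u_f = 10^stats::runif(1, -7, -5),
               Delta = 1e-4, L = 5e-3)
}

# Small unit system for solver tests (tau = 1 unless stated otherwise)
units_tau <- function(tau = 1, dx = 1e-4, nu = 1e-6) {
  nu_lu <- (tau - 0.5) / 3
  lb_units(dx = dx, dt = nu_lu * dx^2 / nu, nu = nu)
}
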