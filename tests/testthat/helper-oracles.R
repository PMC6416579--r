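# Independent oracles used across test files.

# Closed-form per-axis Debye loss power (independent of the package's
# complex-phasor implementation): P = (mu0/2) chi H^2 w^2 tau / (1 + (w tau)^2)
closed_form_power <- function(chi, H, omega, tau) {
  mu0 <- 4 * pi * 1e-7
  mu0 / 2 * chi * H^2 * omega^2 * tau / (1 + (omega * tau)^2)
}

# Reference suspension used by several tests: the twelve-group maghemite /
# mineral-oil system with the quoted anchor values.
reference_system <- function(viscosity = 0.075, T_C = 20, ...) {
  m <- material_spec(4e5, M_s_fluid = 42.3e3)
  g <- make_group_grid(3.5e-9, 14.5e-9, 1e-9)
  v <- surrogate_group_vector(g, 7.5e-9, 0.01611, m$phi)
  mfh_system(m, g, v, viscosity = viscosity, T_C = T_C, ...)
}
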