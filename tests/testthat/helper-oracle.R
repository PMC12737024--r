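# Independent oracles, kept deliberately separate from the package's own
# solver path.

# Direct transcription of the published numeric torque balance for the
# average subject (full activation, zero traction). Left side: GRF
# abduction torque; right side: adduction torque sum.
balance_lhs <- function(fy, alpha_deg) {
  fy * 0.59486 * sin(alpha_deg * pi / 180)
}

balance_rhs <- function(alpha_deg) {
  2300 * 0.02606 + 799 * 0.0688 + 8000 * 0.05846 / 2 + 1604 * 0.0688 +
    802 * (0.12378 + 0.4618 * sin(alpha_deg * pi / 180))
}

# Scalar root-find for the critical Fy on the net torque residual, used to
# cross-check the closed-form solver.
oracle_critical_grf <- function(alpha_deg, profile = average_profile(),
                                tissue = tissue_parameters(),
                                activation = activation_state(),
                                surface = surface_state()) {
  f <- function(fy) {
    s <- landing_scenario(alpha_deg, fy, profile, activation, surface)
    net_abduction_torque(s, tissue)
  }
  stats::uniroot(f, c(1, 1e7), tol = 1e-10)$root
}

ref_pop <- function() population_parameters()
ref_profile <- function() average_profile(ref_pop())
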