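# Shared fixtures and independent oracles, built in code at test time.

zetasizer_geometry <- function() dls_geometry(633, 173, 1.33)
water_25C <- function(nacl_M = 0) solvent_spec(298.15, nacl_M)

# Brute-force single-mode KWW search on a dense log grid over (tau, gamma),
# amplitude solved analytically. Independent of the package's fitting path.
brute_force_kww1 <- function(t, y, n_tau = 400L, gammas = seq(0.5, 1, by = 0.005)) {
  taus <- exp(seq(log(min(t)), log(max(t)), length.out = n_tau))
  best <- list(rss = Inf)
  for (tau in taus) {
    for (g in gammas) {
      m <- exp(-(t / tau)^g)
      a <- sum(m * y) / sum(m^2)
      rss <- sum((y - a * m)^2)
      if (rss < best$rss) best <- list(amplitude = a, tau = tau, gamma = g, rss = rss)
    }
  }
  best
}

# Closed-form buffering capacity of C mol/L of an ideal weak base with the
# given pKa, plus the water term: beta(pH) = ln10 ([H] + [OH] + C Ka [H] / (Ka + [H])^2)
# (the dose is measured per unit volume at constant concentration).
ideal_buffer_capacity <- function(ph, pka, conc) {
  h <- 10^(-ph)
  oh <- 1e-14 / h
  ka <- 10^(-pka)
  log(10) * (h + oh + conc * ka * h / (ka + h)^2)
}

# Electroneutrality residual of simulated samples, recomputed independently
# of the solver: A0*P(pH) + [H+] + [Na+] - [OH-] - [Cl-]
charge_residual <- function(samples, isotherm) {
  h <- 10^(-samples$ph)
  p <- ifelse(samples$is_control, 0, eval_isotherm(isotherm, samples$ph))
  samples$amine_total_M * p + h + samples$added_naoh_M -
    1e-14 * 10^(samples$ph) - samples$added_hcl_M
}
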