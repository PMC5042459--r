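test_that("charge balance gives the protonated fraction from pH and dose", {
  # neutral, no dose: [H+] = [OH-], nothing else -> P = 0
  expect_equal(protonated_fraction(7, 4.08e-3)$fraction, 0, tolerance = 1e-9)
  # strong-acid regime: all added H+ remains free
  expect_equal(protonated_fraction(3, 4.08e-3, added_hcl_M = 1e-3)$fraction, 0,
               tolerance = 1e-6)
  # buffered sample: [AH+] = 1e-8 + 2e-3 - 1e-6 ~ 1.999e-3
  res <- protonated_fraction(6, 4.08e-3, added_hcl_M = 2e-3)
  expect_equal(res$protonated_amine_M, 1e-8 + 2e-3 - 1e-6, tolerance = 1e-12)
  expect_equal(res$fraction, 0.490, tolerance = 1e-3)
  expect_false(res$out_of_range)
})

test_that("protonated fraction is affine in each dose at fixed pH and never clamped", {
  doses <- c(0, 1e-4, 5e-4, 2e-3)
  f_hcl <- protonated_fraction(5, 4.08e-3, added_hcl_M = doses)$fraction
  slopes <- diff(f_hcl) / diff(doses)
  expect_equal(max(slopes), min(slopes), tolerance = 1e-12)
  f_naoh <- protonated_fraction(9, 4.08e-3, added_naoh_M = doses)$fraction
  slopes_b <- diff(f_naoh) / diff(doses)
  expect_equal(max(slopes_b), min(slopes_b), tolerance = 1e-12)

  # basic region bookkeeping: P < 0 is reported, flagged, not clamped
  neg <- protonated_fraction(11, 4.08e-3, added_naoh_M = 2e-3)
  expect_lt(neg$fraction, 0)
  expect_true(neg$out_of_range)
  expect_error(protonated_fraction(7, 0), "division undefined")
})

test_that("control correction subtracts the spurious signal dose by dose", {
  iso <- protonation_isotherm()
  d <- titration_design(n_per_decade = 40)
  sim <- simulate_titration(iso, d, ph_noise_sd = 0)
  samples <- sim[!sim$is_control, ]
  controls <- sim[sim$is_control, ]

  # ideal controls carry no spurious signal: corrected = uncorrected
  curve <- analyze_titration(samples, controls)
  raw <- protonated_fraction(samples$ph, 4.08e-3, samples$added_hcl_M,
                             samples$added_naoh_M)$fraction
  expect_equal(sort(curve$points$fraction), sort(raw), tolerance = 1e-9)

  # controls all reporting the same spurious [AH+] c0 shift P down by c0/[A]0
  c0 <- 2e-4
  shifted <- controls
  # a control pH implying apparent [AH+] = c0: solve 1e-14/h + cl - h - na = c0
  cl <- shifted$added_hcl_M; na <- shifted$added_naoh_M
  disc <- (cl - na - c0)^2 + 4e-14
  h <- ((cl - na - c0) + sqrt(disc)) / 2
  shifted$ph <- -log10(h)
  curve2 <- analyze_titration(samples, shifted)
  expect_equal(curve2$points$fraction, curve$points$fraction - c0 / 4.08e-3,
               tolerance = 1e-6)

  # baseline offset enters as a constant
  curve3 <- analyze_titration(samples, controls, baseline_offset_M = 1e-4)
  expect_equal(curve3$points$fraction, curve$points$fraction + 1e-4 / 4.08e-3,
               tolerance = 1e-9)

  # a missing control leaves the point uncorrected, with a warning
  expect_warning(analyze_titration(samples, controls[-1, ]), "no dose-matched control")
})

test_that("titration analysis round-trips the generating isotherm", {
  iso <- protonation_isotherm()
  sim <- simulate_titration(iso, titration_design(n_per_decade = 60),
                            ph_noise_sd = 0)
  curve <- analyze_titration(sim)
  truth <- eval_isotherm(iso, curve$points$ph)
  expect_lt(max(abs(curve$points$fraction - truth)), 0.005)
})

test_that("numerical buffering capacity matches the ideal-buffer closed form", {
  # ideal weak base, pKa 7, 5 mM: a single-step Henderson-Hasselbalch isotherm
  iso <- protonation_isotherm(plateau_levels = c(0, 1),
                              transition_centers = 7, transition_widths = 1)
  # the finite-difference estimate needs the dose grid to resolve the steep
  # equivalence-point jump (pH ~4-5.5), hence the high per-decade density
  d <- titration_design(amine_total_M = 5e-3, n_per_decade = 1000,
                        acid_max_M = 3e-2, base_max_M = 3e-2)
  sim <- simulate_titration(iso, d, ph_noise_sd = 0)
  samples <- sim[!sim$is_control, ]
  beta <- buffering_capacity(data.frame(dose = samples$added_hcl_M - samples$added_naoh_M,
                                        ph = samples$ph))
  mid <- beta[beta$ph > 3.5 & beta$ph < 10.5, ]
  expected <- ideal_buffer_capacity(mid$ph, 7, 5e-3)
  expect_lt(max(abs(mid$beta - expected) / expected), 0.02)
  # maximum at the pKa with the textbook peak height ln10 * C / 4 + water term
  pk <- apparent_pkas(beta, n_peaks = 1)
  expect_equal(pk, 7.0, tolerance = 0.1)
  expect_equal(max(mid$beta), log(10) * 5e-3 / 4 + ideal_buffer_capacity(7, 20, 0),
               tolerance = 0.02)
})

test_that("a strong-acid-only series shows only water buffering, minimal near pH 7", {
  iso <- protonation_isotherm(plateau_levels = c(0, 1e-12),
                              transition_centers = 7, transition_widths = 1)
  # doses reach down to 10 nM so the water region around pH 7 is resolved
  d <- titration_design(amine_total_M = 0, n_per_decade = 100,
                        dose_min_M = 1e-8)
  sim <- simulate_titration(iso, d, ph_noise_sd = 0)
  ctrl <- sim[sim$is_control, ]
  beta <- buffering_capacity(data.frame(dose = ctrl$added_hcl_M - ctrl$added_naoh_M,
                                        ph = ctrl$ph))
  inner <- beta[beta$ph > 3.2 & beta$ph < 10.8, ]
  expected <- ideal_buffer_capacity(inner$ph, 7, 0)  # water term only
  expect_lt(max(abs(inner$beta - expected) / expected), 0.05)
  expect_lt(abs(inner$ph[which.min(inner$beta)] - 7), 0.3)
})

test_that("apparent pKa detection finds the buffering maxima", {
  iso <- protonation_isotherm()
  sim <- simulate_titration(iso, titration_design(), ph_noise_sd = 0)
  curve <- analyze_titration(sim)
  beta <- buffering_capacity(curve)
  pks <- apparent_pkas(beta, n_peaks = 2)
  expect_length(pks, 2)
  expect_equal(pks[1], 4.5, tolerance = 0.05)
  expect_equal(pks[2], 10, tolerance = 0.05)

  # constant buffering capacity: no maxima, warning
  flat <- data.frame(ph = seq(3, 11, by = 0.5), beta = 1e-3)
  expect_warning(pk0 <- apparent_pkas(flat), "no local maxima")
  expect_length(pk0, 0)
})

test_that("stall detection reports plateaus and ignores sloped regions", {
  # two exact plateaus at 0.2 and 0.8 joined by a ramp
  ph <- seq(2, 12, by = 0.1)
  p <- ifelse(ph < 5, 0.8, ifelse(ph > 7, 0.2, 0.8 - 0.3 * (ph - 5)))
  st <- detect_stalls(data.frame(ph = ph, fraction = p))
  expect_equal(nrow(st), 2)
  expect_equal(sort(st$fraction_level), c(0.2, 0.8), tolerance = 1e-9)

  # strictly linear P(pH) with slope above tolerance: no stalls
  lin <- data.frame(ph = seq(3, 11, by = 0.2),
                    fraction = 0.9 - 0.05 * seq(3, 11, by = 0.2))
  expect_equal(nrow(detect_stalls(lin)), 0)
})

test_that("ninhydrin signal tracks the unprotonated amines", {
  expect_equal(ninhydrin_signal(1, scale = 0.7), 0)
  expect_equal(ninhydrin_signal(0, scale = 0.7), 0.7)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(ninhydrin_signal(p)) <= 0))
  # along the PEI isotherm: flat near pH 7, falling through the weak-acidic
  # region, negligible below pH 3 where protonation is near complete
  iso <- protonation_isotherm()
  sig <- ninhydrin_signal(eval_isotherm(iso, c(7.5, 7, 5.5, 4.4, 2.5)))
  expect_equal(sig[1], sig[2], tolerance = 1e-3)
  expect_gt(sig[3] - sig[4], 0.1)
  expect_lt(sig[5], 0.06)
})
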