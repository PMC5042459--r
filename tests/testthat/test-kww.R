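test_that("kww_model reproduces stretched-exponential identities", {
  expect_equal(kww_model(1e-3, 1, 1e-3, 1), exp(-1))
  # t -> 0 limit: sum of amplitudes
  expect_equal(kww_model(1e-300, c(0.3, 0.6), c(1e-4, 1e-2), c(0.8, 0.7)), 0.9,
               tolerance = 1e-12)
  # two modes: value is the plain sum of the two stretched exponentials
  t0 <- 0.5e-3
  expect_equal(kww_model(t0, c(0.5, 0.5), c(1e-4, 1e-3), c(0.8, 0.8)),
               0.5 * exp(-(t0 / 1e-4)^0.8) + 0.5 * exp(-(t0 / 1e-3)^0.8))
  expect_error(kww_model(1e-3, numeric(0), numeric(0), numeric(0)), "invalid model")
  expect_error(kww_model(1e-3, 1, 1e-3, 1.2), "invalid mode parameters")
})

test_that("kww_model is strictly decreasing in lag time for positive amplitudes", {
  set.seed(42)
  t <- 10^seq(-6, 0, length.out = 100)
  for (i in 1:20) {
    n <- sample(1:2, 1)
    y <- kww_model(t, stats::runif(n, 0.1, 1), 10^stats::runif(n, -5, -2),
                   stats::runif(n, 0.55, 1))
    # strictly decreasing wherever the exponentials have not underflowed
    expect_true(all(diff(y) < 0 | y[-1] < 1e-300))
  }
})

test_that("correlation_curve validates its inputs", {
  g <- zetasizer_geometry(); s <- water_25C()
  expect_error(correlation_curve(1:10 * 1e-6, rep(1, 10), g, s), "at least 20")
  t <- 10^seq(-6, 0, length.out = 30)
  expect_error(correlation_curve(rev(t), rep(1, 30), g, s), "strictly increasing")
  expect_error(correlation_curve(t, c(rep(1, 29), NA), g, s), "finite")
})

test_that("noise-free single-mode curves are recovered to high accuracy", {
  g <- zetasizer_geometry(); s <- water_25C()
  t <- 10^seq(-7, 0, length.out = 150)
  y <- kww_model(t, 1, 0.8e-3, 0.8)
  fit <- fit_correlation(correlation_curve(t, y, g, s), 1)
  expect_true(fit$converged)
  expect_equal(fit$modes$amplitude, 1, tolerance = 1e-3)
  expect_equal(fit$modes$relaxation_time_s, 0.8e-3, tolerance = 1e-3)
  expect_equal(fit$modes$stretch, 0.8, tolerance = 1e-3)
})

test_that("well-separated two-mode curves are recovered within 1 percent", {
  g <- zetasizer_geometry(); s <- water_25C(0.15)
  # tau ratio ~28, the free-chain (5 nm) vs aggregate (140 nm) separation
  pop <- population_spec(5, 140, 0.5)
  cc <- simulate_correlation(pop, g, s, noise_sd = 0)
  fit <- fit_correlation(cc, 2)
  taus_true <- radius_to_relaxation(c(5, 140), g, s)
  expect_equal(fit$modes$relaxation_time_s, taus_true, tolerance = 0.01)
  expect_equal(fit$modes$amplitude, c(0.5, 0.5), tolerance = 0.01)
  expect_identical(fit$modes$population, c("free", "aggregate"))
  # modes are sorted by relaxation time
  expect_true(diff(fit$modes$relaxation_time_s) > 0)
})

test_that("the fitter agrees with a brute-force grid search on single-mode data", {
  g <- zetasizer_geometry(); s <- water_25C()
  t <- 10^seq(-6, -1, length.out = 120)
  y <- kww_model(t, 0.9, 2e-4, 0.75)
  fit <- fit_correlation(correlation_curve(t, y, g, s), 1)
  oracle <- brute_force_kww1(t, y)
  # grid resolution: ~2.9 percent in tau, 0.005 in gamma
  expect_equal(fit$modes$relaxation_time_s, oracle$tau, tolerance = 0.03)
  expect_equal(fit$modes$stretch, oracle$gamma, tolerance = 0.005)
  expect_lte(fit$rss, oracle$rss + 1e-12)
})

test_that("fitting two modes to single-mode data degenerates and is not selected", {
  g <- zetasizer_geometry(); s <- water_25C()
  pop <- population_spec(5)
  cc <- simulate_correlation(pop, g, s, noise_sd = 0)
  f1 <- fit_correlation(cc, 1)
  f2 <- suppressWarnings(fit_correlation(cc, 2))
  # overfit: no residual improvement beyond the single-mode fit
  expect_lte(f2$rss, f1$rss + 1e-10)
  amp <- f2$modes$amplitude
  coalesced <- abs(log(f2$modes$relaxation_time_s[2] /
                         f2$modes$relaxation_time_s[1])) < 0.1
  expect_true(min(amp) / sum(amp) < 0.02 || coalesced)
  expect_identical(select_mode_count(cc), 1L)
})

test_that("mode-count selection follows the information criterion and amplitude floor", {
  g <- zetasizer_geometry(); s <- water_25C(0.15)
  two <- simulate_correlation(population_spec(5, 140, 0.5), g, s,
                              noise_sd = 0.01, seed = 11)
  expect_identical(select_mode_count(two), 2L)
  # aggregate amplitude below the 2 percent floor -> treated as one mode
  faint <- simulate_correlation(population_spec(5, 140, 0.995), g, s,
                                noise_sd = 0.01, seed = 12)
  expect_identical(select_mode_count(faint), 1L)
})

test_that("degenerate constant curves are rejected", {
  g <- zetasizer_geometry(); s <- water_25C()
  t <- 10^seq(-6, 0, length.out = 30)
  expect_error(fit_correlation(correlation_curve(t, rep(0.5, 30), g, s), 1),
               "degenerate input")
})

test_that("intensity fractions are normalized and classify lone modes by size", {
  g <- zetasizer_geometry(); s <- water_25C(0.15)
  fit <- fit_correlation(simulate_correlation(population_spec(5, 140, 0.5),
                                              g, s, noise_sd = 0), 2)
  fr <- intensity_fractions(fit)
  expect_equal(unname(fr), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sum(fr), 1)

  # dominant free polymer: fractions within 0.02 of (0.95, 0.05)
  fit95 <- suppressWarnings(
    fit_correlation(simulate_correlation(population_spec(5, 140, 0.95),
                                         g, s, noise_sd = 0.01, seed = 5), 2))
  fr95 <- intensity_fractions(fit95)
  expect_equal(unname(fr95), c(0.95, 0.05), tolerance = 0.02)
  expect_equal(sum(fr95), 1)

  # lone fast mode sized below the cutoff is free; lone slow mode aggregate
  lone_free <- fit_correlation(simulate_correlation(population_spec(5), g, s,
                                                    noise_sd = 0), 1)
  expect_equal(intensity_fractions(lone_free), c(free = 1, aggregate = 0))
  lone_agg <- fit_correlation(simulate_correlation(population_spec(140), g, s,
                                                   noise_sd = 0), 1)
  expect_equal(intensity_fractions(lone_agg), c(free = 0, aggregate = 1))
})

test_that("diffusive modes show q-squared scaling across angles", {
  s <- water_25C()
  angles <- c(45, 70, 90, 120, 150)
  D <- 4.9e-11
  make_fit <- function(ang, tau) {
    g <- dls_geometry(633, ang, 1.33)
    t <- 10^seq(-7, 0, length.out = 60)
    fit_correlation(correlation_curve(t, kww_model(t, 1, tau, 0.8), g, s), 1)
  }
  taus <- vapply(angles, function(ang) {
    q <- scattering_vector(dls_geometry(633, ang, 1.33)); 1 / (D * q^2)
  }, numeric(1))
  fits <- mapply(make_fit, angles, taus, SIMPLIFY = FALSE)
  chk <- diffusive_scaling_check(fits)
  expect_equal(chk$slope, D, tolerance = 1e-3)
  expect_lt(abs(chk$intercept), 0.001 * max(1 / taus))
  expect_gt(chk$r_squared, 0.9999)
  expect_true(chk$diffusive)

  # 2 percent noise on the relaxation rates: slope still within 5 percent
  set.seed(8)
  df <- data.frame(angle_deg = angles, relaxation_time_s = taus * (1 + rnorm(5, 0, 0.02)))
  chk_n <- diffusive_scaling_check(df, geometry = dls_geometry(633, 90, 1.33))
  expect_equal(chk_n$slope, D, tolerance = 0.05)

  # tau independent of angle: no q^2 dependence, flagged non-diffusive
  flat <- data.frame(angle_deg = angles, relaxation_time_s = rep(1e-4, 5))
  chk_f <- diffusive_scaling_check(flat, geometry = dls_geometry(633, 90, 1.33))
  expect_lt(chk_f$r_squared, 0.1)
  expect_false(chk_f$diffusive)

  expect_error(diffusive_scaling_check(fits[1:2]), "insufficient data")
})
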