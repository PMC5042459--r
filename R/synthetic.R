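# Forward simulation of titration, DLS and osmometry measurements from an
# explicit ground truth, so each analysis stage is testable by recovery.

#' Ground-truth protonation isotherm
#'
#' Piecewise charge-fraction-vs-pH function built as a sum of base-10 logistic
#' steps between consecutive stalled charge levels:
#' P(pH) = sum_k dL_k / (1 + 10^((pH - c_k)/w_k)), dL_k the level increments.
#' P is monotone non-increasing in pH and confined to \[0, 1\].
#'
#' The defaults encode the protonation narrative of 2.5 kDa linear PEI:
#' stalled states at 0, 44, 70 and 95 percent charge; a basic transition
#' centered at pH 10 (aggregate protonation), a weak-acidic transition at the
#' apparent pKa 4.5 (free-polymer protonation), and a final rapid rise below
#' pH 3 that is essentially complete by pH ~2.5 (midpoint 2.75). Decade
#' widths of 0.4, 0.18 and 0.12 reproduce the reported plateau extents
#' (44 percent across roughly pH 7-9.5; a >= 1-pH-unit stall near 70 percent
#' between pH ~4.1 and ~3).
#'
#' @param plateau_levels Charge fractions of the stalled states, strictly
#'   increasing with decreasing pH, within \[0, 1\].
#' @param transition_centers pH midpoints of the steps between consecutive
#'   levels (length = number of levels - 1), decreasing.
#' @param transition_widths Decade widths of each step (same length).
#' @return An object of class `"protonation_isotherm"`; evaluate it with
#'   [eval_isotherm()] or `predict()`.
#' @examples
#' iso <- protonation_isotherm()
#' eval_isotherm(iso, c(7.5, 3.5, 2.5))  # ~0.44, ~0.70, ~0.95
#' @export
protonation_isotherm <- function(plateau_levels = c(0, 0.44, 0.70, 0.95),
                                 transition_centers = c(10, 4.5, 2.75),
                                 transition_widths = c(0.4, 0.18, 0.12)) {
  k <- length(plateau_levels) - 1L
  if (k < 1L) stop("need at least two plateau levels", call. = FALSE)
  if (any(plateau_levels < 0) || any(plateau_levels > 1) ||
      any(diff(plateau_levels) <= 0)) {
    stop("plateau levels must be strictly increasing within [0, 1]", call. = FALSE)
  }
  if (length(transition_centers) != k || length(transition_widths) != k) {
    stop("need one transition center and width per consecutive level pair",
         call. = FALSE)
  }
  if (any(diff(transition_centers) >= 0)) {
    stop("transition centers must decrease (levels increase as pH falls)",
         call. = FALSE)
  }
  if (any(transition_widths <= 0)) stop("widths must be positive", call. = FALSE)
  structure(list(plateau_levels = plateau_levels,
                 transition_centers = transition_centers,
                 transition_widths = transition_widths),
            class = "protonation_isotherm")
}

#' Evaluate a protonation isotherm
#'
#' @param isotherm A [protonation_isotherm()].
#' @param ph Numeric vector of pH values.
#' @return Protonated fraction at each pH.
#' @export
eval_isotherm <- function(isotherm, ph) {
  stopifnot(inherits(isotherm, "protonation_isotherm"))
  dl <- diff(isotherm$plateau_levels)
  p <- rep(isotherm$plateau_levels[1], length(ph))
  for (k in seq_along(dl)) {
    x <- (ph - isotherm$transition_centers[k]) / isotherm$transition_widths[k]
    p <- p + dl[k] / (1 + 10^x)
  }
  p
}

#' @export
predict.protonation_isotherm <- function(object, ph, ...) eval_isotherm(object, ph)

#' @export
print.protonation_isotherm <- function(x, ...) {
  cat("Protonation isotherm:\n  levels :",
      paste(x$plateau_levels, collapse = ", "),
      "\n  centers:", paste(x$transition_centers, collapse = ", "),
      "\n  widths :", paste(x$transition_widths, collapse = ", "), "\n")
  invisible(x)
}

#' Constant-concentration titration design
#'
#' Signed doses (HCl positive, NaOH negative) of logarithmically increasing
#' molarity applied to separate samples, so polymer and salt concentrations
#' stay constant. The default grid is dense (800 doses per decade per side)
#' because the neutral-plateau branch of the titration is extremely steep in
#' dose: the whole pH 7-9 window spans about 2 percent in added acid.
#'
#' @param amine_total_M Total amine concentration, mol/L. Default 4.08e-3.
#' @param nacl_M NaCl molarity. Default 0.15.
#' @param acid_max_M,base_max_M Largest HCl / NaOH dose, mol/L.
#' @param dose_min_M Smallest non-zero dose, mol/L. Default 1e-6.
#' @param n_per_decade Doses per decade on each side. Default 800.
#' @param include_controls Emit matched polymer-free controls. Default TRUE.
#' @return An object of class `"titration_design"` with the signed `doses_M`
#'   (sorted, including 0) and the series constants.
#' @export
titration_design <- function(amine_total_M = 4.08e-3, nacl_M = 0.15,
                             acid_max_M = 4e-3, base_max_M = 4e-3,
                             dose_min_M = 1e-6, n_per_decade = 800,
                             include_controls = TRUE) {
  if (amine_total_M < 0) stop("`amine_total_M` must be >= 0", call. = FALSE)
  stopifnot(acid_max_M > dose_min_M, base_max_M > dose_min_M, dose_min_M > 0)
  logspace <- function(lo, hi) {
    n <- max(2L, ceiling(log10(hi / lo) * n_per_decade))
    10^seq(log10(lo), log10(hi), length.out = n)
  }
  doses <- sort(c(-logspace(dose_min_M, base_max_M), 0,
                  logspace(dose_min_M, acid_max_M)))
  structure(list(doses_M = doses, amine_total_M = amine_total_M,
                 nacl_M = nacl_M, include_controls = isTRUE(include_controls)),
            class = "titration_design")
}

# Solve the electroneutrality condition for pH, vectorized over doses:
#   A0 * P(pH) + [H+] + [Na+]_added = kw * 10^pH + [Cl-]_added
# f(pH) = A0 P + 10^-pH + na - kw 10^pH - cl is strictly decreasing in pH,
# so bisection on (0.5, 13.5) always converges; a Newton polish drives the
# charge residual to machine precision (well under 1e-12 mol/L).
.solve_ph <- function(isotherm, amine_total_M, added_hcl_M, added_naoh_M,
                      lo = 0.5, hi = 13.5) {
  f <- function(ph) {
    p <- if (amine_total_M > 0) eval_isotherm(isotherm, ph) else 0
    amine_total_M * p + 10^(-ph) + added_naoh_M - 1e-14 * 10^ph - added_hcl_M
  }
  flo <- f(lo); fhi <- f(hi)
  bad <- sign(flo) == sign(fhi)
  if (any(bad)) {
    stop("unsolvable design: no electroneutral pH in (0.5, 13.5) for dose(s) ",
         paste(signif((added_hcl_M - added_naoh_M)[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  a <- rep_len(lo, length(flo)); b <- rep_len(hi, length(flo))
  for (i in 1:60) {
    m <- (a + b) / 2
    fm <- f(m)
    takes_lower <- sign(fm) == sign(flo)
    a <- ifelse(takes_lower, m, a)
    b <- ifelse(takes_lower, b, m)
  }
  ph <- (a + b) / 2
  # Newton polish on the analytic derivative
  dl <- diff(isotherm$plateau_levels)
  for (i in 1:4) {
    h <- 10^(-ph); oh <- 1e-14 * 10^ph
    dp <- 0
    if (amine_total_M > 0) {
      for (k in seq_along(dl)) {
        x <- (ph - isotherm$transition_centers[k]) / isotherm$transition_widths[k]
        s <- 1 / (1 + 10^x)
        dp <- dp - dl[k] * log(10) / isotherm$transition_widths[k] * s * (1 - s)
      }
    }
    deriv <- amine_total_M * dp - log(10) * (h + oh)
    ph <- ph - f(ph) / deriv
  }
  ph
}

#' Forward-simulate a constant-concentration pH titration
#'
#' For every dose in the design, solves the electroneutrality condition for
#' the equilibrium pH of a solution of a weak-base polymer whose charge
#' follows the given isotherm, and (optionally) of the matched polymer-free
#' control. The charge residual of every sample is below 1e-12 mol/L.
#' Optional Gaussian read noise can be added to the reported pH.
#'
#' @param isotherm A [protonation_isotherm()].
#' @param design A [titration_design()].
#' @param ph_noise_sd Standard deviation of additive pH read noise. Default
#'   0.02 pH units; set 0 for exact forward values.
#' @param seed Optional integer seed for the noise (ignored when
#'   `ph_noise_sd = 0`).
#' @return Data frame of samples with columns `sample_id`, `added_hcl_M`,
#'   `added_naoh_M`, `ph`, `amine_total_M`, `nacl_M`, `is_control`. Controls
#'   (when requested) carry the same doses with `amine_total_M = 0`.
#' @examples
#' d <- titration_design(n_per_decade = 40)
#' sim <- simulate_titration(protonation_isotherm(), d, ph_noise_sd = 0)
#' curve <- analyze_titration(sim)
#' @export
simulate_titration <- function(isotherm, design, ph_noise_sd = 0.02,
                               seed = NULL) {
  stopifnot(inherits(isotherm, "protonation_isotherm"),
            inherits(design, "titration_design"))
  if (ph_noise_sd < 0) stop("`ph_noise_sd` must be >= 0", call. = FALSE)
  doses <- design$doses_M
  hcl <- pmax(doses, 0)
  naoh <- pmax(-doses, 0)
  ph <- .solve_ph(isotherm, design$amine_total_M, hcl, naoh)
  samples <- data.frame(
    sample_id = sprintf("s%04d", seq_along(doses)),
    added_hcl_M = hcl, added_naoh_M = naoh, ph = ph,
    amine_total_M = design$amine_total_M, nacl_M = design$nacl_M,
    is_control = FALSE)
  if (design$include_controls) {
    phc <- .solve_ph(isotherm, 0, hcl, naoh)
    controls <- data.frame(
      sample_id = sprintf("c%04d", seq_along(doses)),
      added_hcl_M = hcl, added_naoh_M = naoh, ph = phc,
      amine_total_M = 0, nacl_M = design$nacl_M, is_control = TRUE)
    samples <- rbind(samples, controls)
  }
  if (ph_noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    samples$ph <- samples$ph + stats::rnorm(nrow(samples), 0, ph_noise_sd)
    samples$ph <- pmin(pmax(samples$ph, 0.01), 13.99)
  }
  samples
}

#' Free/aggregate population specification for DLS simulation
#'
#' @param free_radius_nm Hydrodynamic radius of the free chains, nm.
#' @param aggregate_radius_nm Radius of the aggregates, nm, or NA for a
#'   single-population solution.
#' @param free_intensity_fraction Share of correlation amplitude carried by
#'   the free chains, in \[0, 1\]. Default 1.
#' @param stretch_free,stretch_aggregate Stretch exponents in (0.5, 1\].
#'   Defaults 0.8 (mild polydispersity).
#' @return Object of class `"population_spec"`.
#' @export
population_spec <- function(free_radius_nm = 5, aggregate_radius_nm = NA,
                            free_intensity_fraction = 1,
                            stretch_free = 0.8, stretch_aggregate = 0.8) {
  if (free_radius_nm <= 0) stop("radii must be positive", call. = FALSE)
  if (!is.na(aggregate_radius_nm) && aggregate_radius_nm <= 0) {
    stop("radii must be positive", call. = FALSE)
  }
  if (free_intensity_fraction < 0 || free_intensity_fraction > 1) {
    stop("`free_intensity_fraction` must lie in [0, 1]", call. = FALSE)
  }
  for (s in c(stretch_free, stretch_aggregate)) {
    if (s <= 0.5 || s > 1) stop("stretches must lie in (0.5, 1]", call. = FALSE)
  }
  structure(list(free_radius_nm = free_radius_nm,
                 aggregate_radius_nm = aggregate_radius_nm,
                 free_intensity_fraction = free_intensity_fraction,
                 stretch_free = stretch_free,
                 stretch_aggregate = stretch_aggregate),
            class = "population_spec")
}

#' Forward-simulate a DLS correlation curve
#'
#' Converts the population radii to relaxation times through the diffusive
#' q^2 relation and the Stokes-Einstein equation, evaluates the one- or
#' two-mode KWW model, and applies multiplicative Gaussian noise.
#'
#' @param population A [population_spec()].
#' @param geometry A [dls_geometry()].
#' @param solvent A [solvent_spec()].
#' @param lag_times_s Lag-time grid, seconds. Default: 200 log-spaced points
#'   over 1e-7..1 s. A warning is issued if the grid does not cover every
#'   relaxation time by a factor of 10 on both sides.
#' @param noise_sd Relative (multiplicative) Gaussian noise level. Default
#'   0.01; 0 gives exact model values.
#' @param seed Optional integer seed for reproducible noise.
#' @param label Curve label.
#' @return A [correlation_curve()].
#' @export
simulate_correlation <- function(population, geometry, solvent,
                                 lag_times_s = 10^seq(-7, 0, length.out = 200),
                                 noise_sd = 0.01, seed = NULL, label = "") {
  stopifnot(inherits(population, "population_spec"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  two <- !is.na(population$aggregate_radius_nm) &&
    population$free_intensity_fraction < 1
  radii <- if (two) {
    c(population$free_radius_nm, population$aggregate_radius_nm)
  } else population$free_radius_nm
  taus <- radius_to_relaxation(radii, geometry, solvent)
  if (min(lag_times_s) > min(taus) * 0.1 || max(lag_times_s) < max(taus) * 10) {
    warning("lag grid does not cover every relaxation time by a factor of 10",
            call. = FALSE)
  }
  amps <- if (two) {
    c(population$free_intensity_fraction, 1 - population$free_intensity_fraction)
  } else 1
  stretches <- if (two) {
    c(population$stretch_free, population$stretch_aggregate)
  } else population$stretch_free
  g <- kww_model(lag_times_s, amps, taus, stretches)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    g <- g * (1 + stats::rnorm(length(g), 0, noise_sd))
  }
  correlation_curve(lag_times_s, g, geometry, solvent, label = label)
}

#' Forward-simulate a vapor-pressure osmometry series
#'
#' Below the association onset the reduced signal follows the virial
#' expansion; above it the signal saturates smoothly to its onset value
#' through a logistic blend (associating solutions show a plateau).
#'
#' @param molar_mass_g_mol Polymer molar mass, g/mol.
#' @param b2 Second virial coefficient (mass-concentration units). Default 0.
#' @param association_onset_M Amine molarity at which association saturates
#'   the signal; `Inf` for an ideal (non-associating) series.
#' @param conc_amine_M Concentration grid, mol/L amine. Default 12 points,
#'   0.5-8 mM.
#' @param nacl_M NaCl molarity recorded with the series. Default 0.15.
#' @param noise_sd Relative Gaussian noise on the signal. Default 0; set > 0
#'   with a `seed` for reproducible noise.
#' @param seed Optional integer seed.
#' @param blend_width_frac Width of the logistic blend, as a fraction of the
#'   onset concentration. Default 0.1.
#' @return An [osmotic_series()] (calibrated).
#' @export
simulate_osmometry <- function(molar_mass_g_mol, b2 = 0,
                               association_onset_M = Inf,
                               conc_amine_M = seq(5e-4, 8e-3, length.out = 12),
                               nacl_M = 0.15, noise_sd = 0, seed = NULL,
                               blend_width_frac = 0.1) {
  stopifnot(molar_mass_g_mol > 0, all(diff(conc_amine_M) > 0))
  cm <- conc_amine_M * .pei_monomer_g_mol
  ideal <- cm / molar_mass_g_mol + b2 * cm^2
  if (is.finite(association_onset_M)) {
    c0m <- association_onset_M * .pei_monomer_g_mol
    plateau <- c0m / molar_mass_g_mol + b2 * c0m^2
    w <- 1 / (1 + exp((cm - c0m) / (blend_width_frac * c0m)))
    y <- w * ideal + (1 - w) * plateau
  } else {
    y <- ideal
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y * (1 + stats::rnorm(length(y), 0, noise_sd))
  }
  osmotic_series(conc_amine_M, y, nacl_M = nacl_M, calibrated = TRUE)
}
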