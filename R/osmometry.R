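# Osmotic virial analysis and association (plateau/maximum) detection.
#
# In dilute, molecularly dispersed solutions the osmotic pressure follows
#   Pi = (RT / V1) (c/M + B2 c^2 + B3 c^3 + ...)
# Association (aggregation) makes the signal plateau or pass through a
# maximum as concentration grows, where the expansion no longer applies.

# PEI repeat unit (-CH2-CH2-NH-) molar mass, g/mol; converts amine molarity
# to mass concentration so the fitted M comes out in g/mol.
.pei_monomer_g_mol <- 43.07

#' Osmometry concentration series
#'
#' @param conc_amine_M Amine concentrations in mol/L; strictly increasing,
#'   at least 4 points.
#' @param signal Osmotic signal: the reduced osmotic pressure Pi V1 / (R T)
#'   (mol/L) when calibrated, or a proportional instrument readout otherwise.
#' @param nacl_M NaCl molarity of the series. Default 0.
#' @param calibrated Logical: is `signal` in absolute reduced-pressure units?
#'   Default TRUE. Uncalibrated series yield apparent (scaled) virial
#'   parameters, flagged in the fit.
#' @return An object of class `"osmotic_series"`.
#' @export
osmotic_series <- function(conc_amine_M, signal, nacl_M = 0, calibrated = TRUE) {
  if (length(conc_amine_M) < 4L) stop("need at least 4 points", call. = FALSE)
  if (length(signal) != length(conc_amine_M)) {
    stop("`conc_amine_M` and `signal` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(conc_amine_M)) || any(conc_amine_M <= 0) ||
      any(diff(conc_amine_M) <= 0)) {
    stop("concentrations must be positive and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(signal))) stop("signals must be finite", call. = FALSE)
  structure(list(conc_amine_M = as.numeric(conc_amine_M),
                 signal = as.numeric(signal), nacl_M = nacl_M,
                 calibrated = isTRUE(calibrated)),
            class = "osmotic_series")
}

#' @export
print.osmotic_series <- function(x, ...) {
  cat(sprintf("Osmotic series: %d points, c in [%.3g, %.3g] M amine, NaCl %g M%s\n",
              length(x$conc_amine_M), min(x$conc_amine_M), max(x$conc_amine_M),
              x$nacl_M, if (x$calibrated) "" else " (uncalibrated)"))
  invisible(x)
}

#' @export
plot.osmotic_series <- function(x, ...) {
  graphics::plot(x$conc_amine_M * 1e3, x$signal, xlab = "c (mM amine)",
                 ylab = "osmotic signal", ...)
  invisible(x)
}

#' Fit the osmotic virial expansion
#'
#' Zero-intercept polynomial least squares of the reduced osmotic signal
#' against mass concentration up to the requested degree. The linear
#' coefficient gives 1/M; the quadratic and cubic coefficients are the second
#' and third virial coefficients. The expansion only holds for molecularly
#' dispersed solutions, so by default the fit range is truncated below any
#' detected association plateau; fitting an explicitly requested range that
#' contains a plateau is an error.
#'
#' @param series An [osmotic_series()].
#' @param degree Polynomial degree, 1, 2 or 3. Default 2.
#' @param fit_range Optional integer index range (e.g. `1:5`) of points to
#'   fit. Default: all points below the detected plateau onset (all points if
#'   no association is detected).
#' @param slope_tol Passed to [association_profile()] when choosing the
#'   default fit range.
#' @return Object of class `"virial_fit"`: list with `molar_mass_g_mol`, `b2`,
#'   `b3` (NA unless degree 3), `degree`, `fit_range`, `apparent` (TRUE for
#'   uncalibrated series), `residual_norm`, and the input series.
#' @examples
#' s <- simulate_osmometry(2500, b2 = 0, association_onset_M = Inf,
#'                         noise_sd = 0)
#' coef(virial_fit(s, degree = 1))
#' @export
virial_fit <- function(series, degree = 2L, fit_range = NULL, slope_tol = 0.1) {
  stopifnot(inherits(series, "osmotic_series"))
  degree <- as.integer(degree)
  if (!degree %in% 1:3) stop("`degree` must be 1, 2 or 3", call. = FALSE)

  prof <- if (length(series$conc_amine_M) >= 5L) {
    association_profile(series, slope_tol = slope_tol)
  } else {
    list(is_associating = FALSE, plateau_onset_M = NA_real_,
         peak_location_M = NA_real_)
  }
  if (is.null(fit_range)) {
    fit_range <- seq_along(series$conc_amine_M)
    if (prof$is_associating && !is.na(prof$plateau_onset_M)) {
      fit_range <- which(series$conc_amine_M < prof$plateau_onset_M)
    }
  } else {
    fit_range <- as.integer(fit_range)
    if (any(fit_range < 1L) || any(fit_range > length(series$conc_amine_M))) {
      stop("`fit_range` out of bounds", call. = FALSE)
    }
    if (prof$is_associating && !is.na(prof$plateau_onset_M) &&
        max(series$conc_amine_M[fit_range]) >= prof$plateau_onset_M) {
      stop("association-dominated: the requested fit range extends into the ",
           "plateau where the virial expansion breaks down", call. = FALSE)
    }
  }
  if (length(fit_range) < degree + 1L) {
    stop(sprintf("fit range has %d points; degree %d needs at least %d",
                 length(fit_range), degree, degree + 1L), call. = FALSE)
  }

  c_mass <- series$conc_amine_M[fit_range] * .pei_monomer_g_mol  # g/L
  y <- series$signal[fit_range]
  X <- vapply(seq_len(degree), function(d) c_mass^d, numeric(length(c_mass)))
  X <- matrix(X, ncol = degree)
  ls <- stats::lsfit(X, y, intercept = FALSE)
  b <- ls$coefficients
  if (!is.finite(b[1]) || b[1] <= 0) {
    stop("association-dominated: non-positive linear virial coefficient",
         call. = FALSE)
  }
  structure(list(
    molar_mass_g_mol = 1 / b[[1]],
    b2 = if (degree >= 2) b[[2]] else 0,
    b3 = if (degree >= 3) b[[3]] else NA_real_,
    degree = degree, fit_range = fit_range,
    apparent = !series$calibrated,
    residual_norm = sqrt(sum(ls$residuals^2)),
    series = series), class = "virial_fit")
}

#' @export
print.virial_fit <- function(x, ...) {
  cat(sprintf("Virial fit (degree %d, %d points%s):\n", x$degree,
              length(x$fit_range),
              if (x$apparent) ", APPARENT - uncalibrated signal" else ""))
  cat(sprintf("  M  = %.6g g/mol\n  B2 = %.6g\n", x$molar_mass_g_mol, x$b2))
  if (!is.na(x$b3)) cat(sprintf("  B3 = %.6g\n", x$b3))
  invisible(x)
}

#' @export
coef.virial_fit <- function(object, ...) {
  c(molar_mass_g_mol = object$molar_mass_g_mol, b2 = object$b2, b3 = object$b3)
}

#' @export
predict.virial_fit <- function(object, conc_amine_M = NULL, ...) {
  if (is.null(conc_amine_M)) conc_amine_M <- object$series$conc_amine_M
  cm <- conc_amine_M * .pei_monomer_g_mol
  y <- cm / object$molar_mass_g_mol + object$b2 * cm^2
  if (!is.na(object$b3)) y <- y + object$b3 * cm^3
  y
}

#' @export
residuals.virial_fit <- function(object, ...) {
  i <- object$fit_range
  object$series$signal[i] - predict(object)[i]
}

#' @export
plot.virial_fit <- function(x, ...) {
  plot(x$series, ...)
  cg <- seq(min(x$series$conc_amine_M), max(x$series$conc_amine_M),
            length.out = 200)
  graphics::lines(cg * 1e3, predict(x, cg), col = "red3", lwd = 2)
  invisible(x)
}

#' Detect association signatures in an osmotic series
#'
#' Scans finite-difference slopes, normalized to the initial slope. A plateau
#' is declared at the first concentration where the normalized slope stays
#' below `slope_tol` for `persistence` consecutive intervals; a maximum is
#' declared where the signal decreases after its peak. Either signature marks
#' an associating solution. The result is invariant under monotone
#' re-gridding of the concentrations.
#'
#' @param series An [osmotic_series()] (at least 5 points).
#' @param slope_tol Normalized-slope threshold. Default 0.1.
#' @param persistence Consecutive sub-threshold intervals required. Default 2.
#' @return List with `is_associating`, `plateau_onset_M` (NA if none) and
#'   `peak_location_M` (NA if none).
#' @export
association_profile <- function(series, slope_tol = 0.1, persistence = 2L) {
  stopifnot(inherits(series, "osmotic_series"))
  cc <- series$conc_amine_M
  y <- series$signal
  if (length(cc) < 5L) stop("need at least 5 points", call. = FALSE)
  slopes <- diff(y) / diff(cc)
  s0 <- slopes[1]
  if (!is.finite(s0) || s0 <= 0) s0 <- max(abs(slopes))
  ns <- slopes / s0

  plateau_onset <- NA_real_
  low <- ns < slope_tol & ns > -slope_tol
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit)) plateau_onset <- cc[starts[hit[1]]]

  peak_location <- NA_real_
  imax <- which.max(y)
  if (imax < length(y) && any(ns[imax:length(ns)] < -slope_tol)) {
    peak_location <- cc[imax]
  }

  list(is_associating = !is.na(plateau_onset) || !is.na(peak_location),
       plateau_onset_M = plateau_onset,
       peak_location_M = peak_location)
}
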