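# Scattering geometry, solvent properties and Stokes-Einstein conversions.

#' Scattering geometry of a DLS experiment
#'
#' Bundles the instrument parameters that determine the scattering vector:
#' laser wavelength (in vacuo), detection angle, and solvent refractive index.
#'
#' @param wavelength_nm Laser wavelength in nm (in vacuo). Must be positive.
#' @param angle_deg Scattering angle in degrees, strictly between 0 and 180.
#' @param refractive_index Solvent refractive index (>= 1). Default 1.33 (water).
#' @return An object of class `"dls_geometry"`.
#' @examples
#' g <- dls_geometry(633, 173)
#' scattering_vector(g)
#' @export
dls_geometry <- function(wavelength_nm, angle_deg, refractive_index = 1.33) {
  if (!is.numeric(wavelength_nm) || length(wavelength_nm) != 1L ||
      !is.finite(wavelength_nm) || wavelength_nm <= 0) {
    stop("invalid geometry: `wavelength_nm` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(angle_deg) || length(angle_deg) != 1L ||
      !is.finite(angle_deg) || angle_deg <= 0 || angle_deg >= 180) {
    stop("invalid geometry: `angle_deg` must lie strictly between 0 and 180", call. = FALSE)
  }
  if (!is.numeric(refractive_index) || length(refractive_index) != 1L ||
      !is.finite(refractive_index) || refractive_index < 1) {
    stop("invalid geometry: `refractive_index` must be >= 1", call. = FALSE)
  }
  structure(
    list(wavelength_nm = wavelength_nm, angle_deg = angle_deg,
         refractive_index = refractive_index),
    class = "dls_geometry"
  )
}

#' @export
print.dls_geometry <- function(x, ...) {
  cat(sprintf("DLS geometry: lambda = %g nm, theta = %g deg, n = %g (q = %.4g 1/m)\n",
              x$wavelength_nm, x$angle_deg, x$refractive_index, scattering_vector(x)))
  invisible(x)
}

#' Scattering vector magnitude
#'
#' q = (4 pi n / lambda) sin(theta / 2), with the wavelength taken in vacuo.
#'
#' @param geometry A [dls_geometry()] object.
#' @return Scattering vector magnitude in 1/m.
#' @examples
#' scattering_vector(dls_geometry(633, 173, 1.33)) # ~2.64e7 1/m
#' @export
scattering_vector <- function(geometry) {
  stopifnot(inherits(geometry, "dls_geometry"))
  lambda_m <- geometry$wavelength_nm * 1e-9
  (4 * pi * geometry$refractive_index / lambda_m) *
    sin(geometry$angle_deg * pi / 360)
}

#' Viscosity of pure water
#'
#' Vogel-type empirical correlation eta(T) = 2.414e-5 * 10^(247.8/(T - 140))
#' Pa s, accurate to well under 1% across 0-100 degrees C.
#'
#' @param temperature_K Absolute temperature in K (must lie in (273, 373)).
#' @return Dynamic viscosity in Pa s.
#' @export
water_viscosity <- function(temperature_K) {
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 273) || any(temperature_K >= 373)) {
    stop("temperature out of supported liquid-water range (273, 373) K", call. = FALSE)
  }
  2.414e-5 * 10^(247.8 / (temperature_K - 140))
}

# Jones-Dole coefficients for NaCl at 25 C (L/mol units); the B coefficient is
# the sum of the Na+ and Cl- ionic contributions. The correction is monotone
# increasing in molarity over the range of interest (< 1 M).
.nacl_jones_dole <- c(A = 0.0062, B = 0.0793)

#' Solvent specification for Stokes-Einstein sizing
#'
#' Temperature, NaCl content and viscosity of the aqueous solvent. When
#' `viscosity` is not supplied it is computed from the pure-water correlation
#' at `temperature_K` with a Jones-Dole correction for the added NaCl,
#' eta = eta_w(T) * (1 + A sqrt(c) + B c).
#'
#' @param temperature_K Absolute temperature in K. Default 298.15 (25 C).
#' @param nacl_M NaCl molarity in mol/L (>= 0). Default 0.
#' @param viscosity Optional solvent viscosity in Pa s; overrides the
#'   correlation when given.
#' @return An object of class `"solvent_spec"` with fields `temperature_K`,
#'   `nacl_M`, `viscosity` (Pa s) and `kB` (Boltzmann constant, J/K).
#' @examples
#' solvent_spec()                 # water at 25 C, ~8.9e-4 Pa s
#' solvent_spec(nacl_M = 0.15)    # slightly more viscous
#' @export
solvent_spec <- function(temperature_K = 298.15, nacl_M = 0, viscosity = NULL) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L || temperature_K <= 0) {
    stop("`temperature_K` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(nacl_M) || length(nacl_M) != 1L || !is.finite(nacl_M) || nacl_M < 0) {
    stop("`nacl_M` must be a single non-negative number", call. = FALSE)
  }
  if (is.null(viscosity)) {
    eta_w <- water_viscosity(temperature_K)
    jd <- .nacl_jones_dole
    viscosity <- eta_w * (1 + jd[["A"]] * sqrt(nacl_M) + jd[["B"]] * nacl_M)
  }
  if (!is.numeric(viscosity) || length(viscosity) != 1L || viscosity <= 0) {
    stop("`viscosity` must be a single positive number (Pa s)", call. = FALSE)
  }
  structure(
    list(temperature_K = temperature_K, nacl_M = nacl_M,
         viscosity = viscosity, kB = 1.380649e-23),
    class = "solvent_spec"
  )
}

#' @rdname solvent_spec
#' @param temperature Alias of `temperature_K` for `solvent_properties()`.
#' @param nacl_molarity Alias of `nacl_M`.
#' @export
solvent_properties <- function(temperature = 298.15, nacl_molarity = 0) {
  solvent_spec(temperature_K = temperature, nacl_M = nacl_molarity)
}

#' @export
print.solvent_spec <- function(x, ...) {
  cat(sprintf("Solvent: T = %.2f K, NaCl = %g M, eta = %.4g Pa s\n",
              x$temperature_K, x$nacl_M, x$viscosity))
  invisible(x)
}

#' Convert a relaxation mode to a diffusion coefficient and hydrodynamic radius
#'
#' Diffusive modes satisfy 1/tau = D q^2; the hydrodynamic radius follows from
#' the Stokes-Einstein relation R_h = kB T / (6 pi eta D).
#'
#' @param relaxation_time_s Relaxation time tau in seconds (> 0). Vectorized.
#' @param geometry A [dls_geometry()].
#' @param solvent A [solvent_spec()].
#' @return A data frame with columns `relaxation_time_s`,
#'   `diffusion_coefficient_m2s` and `hydrodynamic_radius_nm`.
#' @seealso [radius_to_relaxation()] for the inverse map.
#' @examples
#' g <- dls_geometry(633, 173); s <- solvent_spec()
#' tau <- radius_to_relaxation(5, g, s)
#' mode_to_radius(tau, g, s)$hydrodynamic_radius_nm  # 5, round trip
#' @export
mode_to_radius <- function(relaxation_time_s, geometry, solvent) {
  if (any(!is.finite(relaxation_time_s)) || any(relaxation_time_s <= 0)) {
    stop("invalid mode: relaxation time must be positive", call. = FALSE)
  }
  q <- scattering_vector(geometry)
  D <- 1 / (relaxation_time_s * q^2)
  Rh_m <- solvent$kB * solvent$temperature_K / (6 * pi * solvent$viscosity * D)
  data.frame(
    relaxation_time_s = relaxation_time_s,
    diffusion_coefficient_m2s = D,
    hydrodynamic_radius_nm = Rh_m * 1e9
  )
}

#' Relaxation time of a sphere of given hydrodynamic radius
#'
#' Inverse of [mode_to_radius()]: tau = 1 / (D q^2) with
#' D = kB T / (6 pi eta R_h).
#'
#' @param radius_nm Hydrodynamic radius in nm (> 0). Vectorized.
#' @inheritParams mode_to_radius
#' @return Relaxation time(s) in seconds.
#' @export
radius_to_relaxation <- function(radius_nm, geometry, solvent) {
  if (any(!is.finite(radius_nm)) || any(radius_nm <= 0)) {
    stop("radius must be positive", call. = FALSE)
  }
  q <- scattering_vector(geometry)
  D <- solvent$kB * solvent$temperature_K / (6 * pi * solvent$viscosity * radius_nm * 1e-9)
  1 / (D * q^2)
}
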