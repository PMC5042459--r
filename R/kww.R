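# Stretched-exponential (KWW) decomposition of DLS autocorrelation curves.
#
# G(t) - 1 = sum_i A_i exp(-(t / tau_i)^gamma_i)
#
# The observed stretch exponents for linear PEI fall between 0.7 and 0.85;
# fitted values outside that band are allowed but flagged.

.stretch_band <- c(0.7, 0.85)

#' DLS intensity-autocorrelation curve
#'
#' Container for a measured (or simulated) correlation curve G(t) - 1 together
#' with the scattering geometry and solvent conditions needed for sizing.
#'
#' @param lag_times_s Lag times in seconds; strictly increasing, positive,
#'   at least 20 points.
#' @param g_minus_1 Correlation values G(t) - 1, same length, finite.
#' @param geometry A [dls_geometry()].
#' @param solvent A [solvent_spec()].
#' @param label Optional text label.
#' @return An object of class `"correlation_curve"`.
#' @export
correlation_curve <- function(lag_times_s, g_minus_1, geometry, solvent,
                              label = "") {
  if (length(lag_times_s) < 20L) {
    stop("a correlation curve needs at least 20 points", call. = FALSE)
  }
  if (length(g_minus_1) != length(lag_times_s)) {
    stop("`lag_times_s` and `g_minus_1` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(lag_times_s)) || any(lag_times_s <= 0) ||
      any(diff(lag_times_s) <= 0)) {
    stop("lag times must be positive, finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(g_minus_1))) {
    stop("`g_minus_1` must be finite", call. = FALSE)
  }
  stopifnot(inherits(geometry, "dls_geometry"), inherits(solvent, "solvent_spec"))
  structure(
    list(lag_times_s = as.numeric(lag_times_s),
         g_minus_1 = as.numeric(g_minus_1),
         geometry = geometry, solvent = solvent, label = label),
    class = "correlation_curve"
  )
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("Correlation curve%s: %d points, t in [%.3g, %.3g] s, theta = %g deg\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$lag_times_s), min(x$lag_times_s), max(x$lag_times_s),
              x$geometry$angle_deg))
  invisible(x)
}

#' @export
plot.correlation_curve <- function(x, ...) {
  graphics::plot(x$lag_times_s, x$g_minus_1, log = "x",
                 xlab = "lag time (s)", ylab = "G(t) - 1",
                 main = x$label, ...)
  invisible(x)
}

#' Multi-mode stretched-exponential model
#'
#' Evaluates G(t) - 1 = sum_i A_i exp(-(t / tau_i)^gamma_i).
#'
#' @param lag_times_s Positive lag times in seconds.
#' @param amplitude,relaxation_time_s,stretch Parallel vectors of mode
#'   parameters A_i (>= 0), tau_i (> 0, seconds) and gamma_i (0 < gamma <= 1).
#' @return Model values at each lag time.
#' @examples
#' kww_model(1e-3, 1, 1e-3, 1)  # exp(-1)
#' @export
kww_model <- function(lag_times_s, amplitude, relaxation_time_s, stretch) {
  n <- length(amplitude)
  if (n == 0L) stop("invalid model: at least one mode is required", call. = FALSE)
  if (length(relaxation_time_s) != n || length(stretch) != n) {
    stop("mode parameter vectors must have equal length", call. = FALSE)
  }
  if (any(amplitude < 0) || any(relaxation_time_s <= 0) ||
      any(stretch <= 0) || any(stretch > 1)) {
    stop("invalid mode parameters: need A >= 0, tau > 0, 0 < gamma <= 1", call. = FALSE)
  }
  if (any(lag_times_s < 0)) stop("lag times must be non-negative", call. = FALSE)
  out <- numeric(length(lag_times_s))
  for (i in seq_len(n)) {
    out <- out + amplitude[i] *
      exp(-(lag_times_s / relaxation_time_s[i])^stretch[i])
  }
  out
}

# Coarse grid search over (tau, gamma) combinations, with amplitudes solved
# by (non-negative) linear least squares, to seed the bounded
# Levenberg-Marquardt refinement. KWW sums are ill-conditioned and
# multi-modal, so several good seeds matter more than optimizer
# sophistication. Returns the `k_best` seeds ranked by residual sum of
# squares; all pairwise products are taken from one precomputed Gram matrix.
.kww_grid_seeds <- function(t, y, n_modes, k_best = 4L, n_tau = 32L,
                            gammas = c(0.6, 0.7, 0.8, 0.9, 1.0)) {
  taus <- exp(seq(log(min(t) * 0.2), log(max(t) * 5), length.out = n_tau))
  grid <- expand.grid(tau = taus, gamma = gammas)
  X <- exp(-outer(t, seq_len(nrow(grid)),
                  function(ti, j) (ti / grid$tau[j])^grid$gamma[j]))
  G <- crossprod(X)
  v <- drop(crossprod(X, y))
  yy <- sum(y^2)

  seeds <- list()
  if (n_modes == 1L) {
    a <- pmax(v / diag(G), 0)
    rss <- yy - 2 * a * v + a^2 * diag(G)
    ord <- order(rss)
    # keep seeds with distinct tau so the restarts genuinely differ
    seen <- numeric(0)
    for (j in ord) {
      if (any(abs(log(grid$tau[j] / seen)) < 0.3)) next
      seeds[[length(seeds) + 1L]] <- list(
        amplitude = max(a[j], 1e-8), relaxation_time_s = grid$tau[j],
        stretch = grid$gamma[j], rss = rss[j])
      seen <- c(seen, grid$tau[j])
      if (length(seeds) >= k_best) break
    }
    return(seeds)
  }

  m <- nrow(grid)
  cand <- list()
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (grid$tau[j] <= grid$tau[i]) next
      det <- G[i, i] * G[j, j] - G[i, j]^2
      if (det <= 0) next
      a1 <- (v[i] * G[j, j] - v[j] * G[i, j]) / det
      a2 <- (v[j] * G[i, i] - v[i] * G[i, j]) / det
      if (a1 < 0 || a2 < 0) next
      rss <- yy - 2 * (a1 * v[i] + a2 * v[j]) +
        a1^2 * G[i, i] + 2 * a1 * a2 * G[i, j] + a2^2 * G[j, j]
      cand[[length(cand) + 1L]] <- c(i, j, a1, a2, rss)
    }
  }
  if (!length(cand)) {
    # fall back to duplicating the best single mode at separated taus
    s1 <- .kww_grid_seeds(t, y, 1L, k_best = 1L)[[1]]
    return(list(list(amplitude = rep(s1$amplitude / 2, 2),
                     relaxation_time_s = s1$relaxation_time_s * c(0.3, 3),
                     stretch = rep(s1$stretch, 2), rss = Inf)))
  }
  cm <- do.call(rbind, cand)
  ord <- order(cm[, 5])
  seen <- matrix(numeric(0), ncol = 2)
  for (r in ord) {
    i <- cm[r, 1]; j <- cm[r, 2]
    key <- log(c(grid$tau[i], grid$tau[j]))
    if (nrow(seen) &&
        any(abs(seen[, 1] - key[1]) < 0.3 & abs(seen[, 2] - key[2]) < 0.3)) next
    seeds[[length(seeds) + 1L]] <- list(
      amplitude = pmax(c(cm[r, 3], cm[r, 4]), 1e-8),
      relaxation_time_s = c(grid$tau[i], grid$tau[j]),
      stretch = c(grid$gamma[i], grid$gamma[j]), rss = cm[r, 5])
    seen <- rbind(seen, key)
    if (length(seeds) >= k_best) break
  }
  seeds
}

#' Fit one or two stretched-exponential relaxation modes to a correlation curve
#'
#' Least-squares decomposition of G(t) - 1 into `n_modes` KWW modes. A coarse
#' log-spaced grid over (tau, gamma), with amplitudes solved linearly, seeds a
#' bounded Levenberg-Marquardt refinement. Bounds: A >= 0, gamma in (0.5, 1],
#' tau within the observed lag window times [0.01, 100]. Modes are reported in
#' order of increasing relaxation time; for a two-mode fit the first (fast)
#' mode is the free-polymer mode and the second (slow) the aggregate mode.
#' Fitted stretch exponents outside the 0.7-0.85 band observed for PEI are
#' kept but signalled with a warning.
#'
#' @param curve A [correlation_curve()].
#' @param n_modes Number of modes, 1 or 2, or `"auto"` to choose by the
#'   corrected Akaike criterion (see [select_mode_count()]).
#' @param init Optional starting values: a list with elements `amplitude`,
#'   `relaxation_time_s`, `stretch` (vectors of length `n_modes`).
#' @param max_restarts Bounded random restarts attempted if the refinement
#'   fails to converge.
#' @return An object of class `"kww_fit"` with components `modes` (data frame
#'   with columns `amplitude`, `relaxation_time_s`, `stretch`, and for
#'   two-mode fits a `population` label), `n_modes`, `residual_norm` (sqrt of
#'   the residual sum of squares), `converged`, `stretch_in_band`, plus the
#'   input curve for downstream sizing.
#' @seealso [select_mode_count()], [intensity_fractions()], [size_modes()]
#' @examples
#' g <- dls_geometry(633, 173); s <- solvent_spec()
#' cc <- simulate_correlation(population_spec(free_radius_nm = 5),
#'                            g, s, noise_sd = 0)
#' coef(fit_correlation(cc, 1))
#' @export
fit_correlation <- function(curve, n_modes = "auto", init = NULL,
                            max_restarts = 5L) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (identical(n_modes, "auto")) n_modes <- select_mode_count(curve)
  n_modes <- as.integer(n_modes)
  if (!n_modes %in% c(1L, 2L)) stop("`n_modes` must be 1 or 2", call. = FALSE)
  t <- curve$lag_times_s
  y <- curve$g_minus_1
  if (stats::sd(y) < 1e-12 * max(abs(y), 1e-300)) {
    stop("degenerate input: correlation signal is constant", call. = FALSE)
  }
  if (length(t) <= 3L * n_modes) {
    stop("curve has fewer points than free parameters", call. = FALSE)
  }

  lower <- c(rep(0, n_modes), rep(min(t) * 0.01, n_modes), rep(0.5 + 1e-6, n_modes))
  upper <- c(rep(Inf, n_modes), rep(max(t) * 100, n_modes), rep(1, n_modes))

  resid_fun <- function(p) {
    kww_model(t, p[seq_len(n_modes)],
              p[n_modes + seq_len(n_modes)],
              p[2L * n_modes + seq_len(n_modes)]) - y
  }

  seeds <- if (!is.null(init)) {
    list(list(amplitude = init$amplitude,
              relaxation_time_s = init$relaxation_time_s,
              stretch = init$stretch))
  } else {
    .kww_grid_seeds(t, y, n_modes)
  }
  starts <- lapply(seeds, function(sd) {
    pmin(pmax(c(sd$amplitude, sd$relaxation_time_s, sd$stretch),
              lower + 1e-12), upper)
  })
  # bounded random restarts around the best seed if nothing converges
  for (attempt in seq_len(max_restarts)) {
    jitter <- stats::runif(length(starts[[1]]), 0.5, 2)
    starts[[length(starts) + 1L]] <-
      pmin(pmax(starts[[1]] * jitter, lower + 1e-12), upper)
  }

  best <- NULL
  converged <- FALSE
  n_seeds <- length(seeds)
  for (attempt in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[attempt]], lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
      converged <- fit$info %in% 1:4
    }
    # stop after the grid seeds once something has converged; the random
    # restarts are only a rescue path
    if (attempt >= n_seeds && converged) break
  }
  if (is.null(best)) {
    stop("fit failure: no Levenberg-Marquardt attempt produced a candidate",
         call. = FALSE)
  }
  p <- best$fit$par
  A <- p[seq_len(n_modes)]
  tau <- p[n_modes + seq_len(n_modes)]
  gam <- p[2L * n_modes + seq_len(n_modes)]
  ord <- order(tau)          # re-sort if modes crossed during optimization
  A <- A[ord]; tau <- tau[ord]; gam <- gam[ord]

  modes <- data.frame(amplitude = A, relaxation_time_s = tau, stretch = gam)
  if (n_modes == 2L) modes$population <- c("free", "aggregate")

  in_band <- gam >= .stretch_band[1] & gam <= .stretch_band[2]
  active <- A > 1e-6 * sum(A)
  if (any(!in_band[active])) {
    warning(sprintf(
      "fitted stretch exponent(s) %s outside the plausibility band [%g, %g]",
      paste(sprintf("%.3f", gam[active][!in_band[active]]), collapse = ", "),
      .stretch_band[1], .stretch_band[2]), call. = FALSE)
  }

  out <- structure(
    list(modes = modes, n_modes = n_modes,
         residual_norm = sqrt(best$rss), rss = best$rss,
         converged = converged, stretch_in_band = in_band,
         curve = curve),
    class = "kww_fit"
  )
  if (!converged) {
    cond <- structure(
      class = c("polyion_fit_failure", "error", "condition"),
      list(message = "fit failure: refinement did not converge within bounded restarts",
           call = sys.call(-1), best_candidate = out))
    stop(cond)
  }
  out
}

# Corrected Akaike information criterion for a least-squares fit.
.aicc <- function(rss, n, k) {
  k <- k + 1  # variance parameter
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Choose between a one- and two-mode decomposition
#'
#' Fits both models and accepts the two-mode decomposition only if it improves
#' the corrected Akaike criterion by at least `delta_aicc` and both amplitudes
#' exceed `amplitude_floor` of the total amplitude. This makes the usually
#' visual one-vs-two-relaxation judgement reproducible.
#'
#' @param curve A [correlation_curve()].
#' @param delta_aicc Required AICc improvement to accept two modes. Default 10.
#' @param amplitude_floor Minimum fractional amplitude of each mode. Default 0.02.
#' @return 1 or 2.
#' @export
select_mode_count <- function(curve, delta_aicc = 10, amplitude_floor = 0.02) {
  # exploratory fits: out-of-band stretch warnings are not meaningful here
  quiet_fit <- function(n) withCallingHandlers(
    tryCatch(fit_correlation(curve, n), error = function(e) e),
    warning = function(w) invokeRestart("muffleWarning"))
  f1 <- quiet_fit(1L)
  f2 <- quiet_fit(2L)
  if (inherits(f1, "error") && inherits(f2, "error")) {
    stop("fit failure: neither the 1- nor the 2-mode model could be fitted",
         call. = FALSE)
  }
  if (inherits(f2, "error")) return(1L)
  if (inherits(f1, "error")) return(2L)
  n <- length(curve$lag_times_s)
  a1 <- .aicc(max(f1$rss, 1e-300), n, 3)
  a2 <- .aicc(max(f2$rss, 1e-300), n, 6)
  amp <- f2$modes$amplitude
  if ((a1 - a2) >= delta_aicc && all(amp / sum(amp) >= amplitude_floor)) 2L else 1L
}

#' @export
print.kww_fit <- function(x, ...) {
  cat(sprintf("KWW fit: %d mode(s), residual norm %.3g%s\n",
              x$n_modes, x$residual_norm,
              if (x$converged) "" else " (NOT converged)"))
  print(cbind(x$modes,
              size_modes(x)[, c("diffusion_coefficient_m2s",
                                "hydrodynamic_radius_nm")]), ...)
  invisible(x)
}

#' @export
coef.kww_fit <- function(object, ...) {
  m <- object$modes
  stats::setNames(
    c(m$amplitude, m$relaxation_time_s, m$stretch),
    c(paste0("A", seq_len(nrow(m))), paste0("tau", seq_len(nrow(m))),
      paste0("gamma", seq_len(nrow(m)))))
}

#' @export
predict.kww_fit <- function(object, lag_times_s = NULL, ...) {
  if (is.null(lag_times_s)) lag_times_s <- object$curve$lag_times_s
  m <- object$modes
  kww_model(lag_times_s, m$amplitude, m$relaxation_time_s, m$stretch)
}

#' @export
fitted.kww_fit <- function(object, ...) predict(object)

#' @export
residuals.kww_fit <- function(object, ...) {
  object$curve$g_minus_1 - predict(object)
}

#' @export
summary.kww_fit <- function(object, ...) {
  sized <- size_modes(object)
  fr <- intensity_fractions(object)
  structure(list(fit = object, sized = sized, fractions = fr),
            class = "summary.kww_fit")
}

#' @export
print.summary.kww_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Intensity fractions: free %.3f, aggregate %.3f\n",
              x$fractions[["free"]], x$fractions[["aggregate"]]))
  invisible(x)
}

#' @export
plot.kww_fit <- function(x, ...) {
  cc <- x$curve
  graphics::plot(cc$lag_times_s, cc$g_minus_1, log = "x",
                 xlab = "lag time (s)", ylab = "G(t) - 1", main = cc$label, ...)
  graphics::lines(cc$lag_times_s, predict(x), col = "red3", lwd = 2)
  invisible(x)
}

#' Size the fitted relaxation modes
#'
#' Applies [mode_to_radius()] to every mode of a fit, using the geometry and
#' solvent stored with the fitted curve.
#'
#' @param fit A `"kww_fit"` object.
#' @return Data frame with one row per mode: amplitude, relaxation time,
#'   stretch, diffusion coefficient (m^2/s) and hydrodynamic radius (nm).
#' @export
size_modes <- function(fit) {
  stopifnot(inherits(fit, "kww_fit"))
  sized <- mode_to_radius(fit$modes$relaxation_time_s,
                          fit$curve$geometry, fit$curve$solvent)
  cbind(fit$modes["amplitude"], sized)
}

#' Free and aggregate intensity fractions
#'
#' The share of correlation amplitude carried by each population,
#' f_i = A_i / sum(A). For a two-mode fit the fast mode is free polymer and
#' the slow mode aggregate. A lone mode is classified by its hydrodynamic
#' radius: below `free_cutoff_nm` it is free polymer (a 2.5 kDa chain of
#' contour length ~19 nm cannot exceed ~20 nm), otherwise aggregate.
#'
#' @param fit A converged `"kww_fit"`.
#' @param free_cutoff_nm Radius classifying a lone mode. Default 20.
#' @return Named numeric vector `c(free = , aggregate = )`, summing to 1.
#' @export
intensity_fractions <- function(fit, free_cutoff_nm = 20) {
  stopifnot(inherits(fit, "kww_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  A <- fit$modes$amplitude
  if (sum(A) <= 0) stop("degenerate fit: all amplitudes are zero", call. = FALSE)
  if (fit$n_modes == 2L) {
    f <- A / sum(A)
    return(c(free = f[1], aggregate = f[2]))
  }
  rh <- size_modes(fit)$hydrodynamic_radius_nm[1]
  if (rh < free_cutoff_nm) c(free = 1, aggregate = 0) else c(free = 0, aggregate = 1)
}

#' Check diffusive (q-squared) scaling across scattering angles
#'
#' For a diffusive mode 1/tau = D q^2: an ordinary least-squares regression of
#' the relaxation rates against q^2 across angles should be linear through the
#' origin with slope D.
#'
#' @param fits A list of `"kww_fit"` objects measured at three or more
#'   distinct angles (each fit carries its own geometry), or a data frame with
#'   columns `angle_deg` and `relaxation_time_s` plus a `geometry` argument.
#' @param mode Which mode of each fit to use (by increasing relaxation time).
#'   Default 1 (the fast, free-polymer mode).
#' @param geometry Base geometry supplying wavelength and refractive index when
#'   `fits` is a data frame.
#' @param r2_threshold Coefficient of determination below which the mode is
#'   flagged non-diffusive. Default 0.95.
#' @return List with `slope` (the diffusion coefficient, m^2/s), `intercept`
#'   (1/s), `r_squared`, and logical `diffusive`.
#' @export
diffusive_scaling_check <- function(fits, mode = 1L, geometry = NULL,
                                    r2_threshold = 0.95) {
  if (is.data.frame(fits)) {
    if (is.null(geometry)) {
      stop("supply `geometry` (wavelength, refractive index) with a data frame",
           call. = FALSE)
    }
    angles <- fits$angle_deg
    taus <- fits$relaxation_time_s
    qs <- vapply(angles, function(a)
      scattering_vector(dls_geometry(geometry$wavelength_nm, a,
                                     geometry$refractive_index)),
      numeric(1))
  } else {
    angles <- vapply(fits, function(f) f$curve$geometry$angle_deg, numeric(1))
    taus <- vapply(fits, function(f) f$modes$relaxation_time_s[mode], numeric(1))
    qs <- vapply(fits, function(f) scattering_vector(f$curve$geometry), numeric(1))
  }
  if (length(unique(angles)) < 3L) {
    stop("insufficient data: at least 3 distinct angles are required", call. = FALSE)
  }
  rate <- 1 / taus
  fit <- stats::lm(rate ~ I(qs^2))
  tss <- sum((rate - mean(rate))^2)
  # constant rates: q^2 explains none of the (zero) variance
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 0
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       diffusive = is.finite(r2) && r2 >= r2_threshold)
}
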