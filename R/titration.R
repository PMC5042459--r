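# Charge-balance analysis of constant-concentration pH titrations.
#
# Electroneutrality of a PEI + NaCl + HCl/NaOH solution, with the NaCl
# contributions cancelling, gives the protonated amine concentration
#
#   [AH+] = [OH-]_free + [Cl-]_HCl - [H+]_free - [Na+]_NaOH
#
# with [H+] = 10^(-pH) and [OH-] = kw / [H+]. pH is treated as -log10 of
# concentration (ideal solution) and kw is fixed at 1e-14 (25 C).

.kw <- 1e-14

#' Protonated amine concentration and fraction from charge balance
#'
#' Infers the protonated-amine concentration of a weak-base polyelectrolyte
#' sample from its measured pH and the known strong acid/base dose, via
#' electroneutrality. The fraction P = \[AH+\]/\[A\]_0 is deliberately not
#' clamped to \[0, 1\]; values outside that range (which arise in the basic
#' region as a bookkeeping consequence of uncorrected hydroxide accounting)
#' are returned as-is with `out_of_range = TRUE`.
#'
#' @param ph Measured pH (0 < pH < 14). Vectorized.
#' @param amine_total_M Total amine concentration \[A\]_0 in mol/L (> 0).
#' @param added_hcl_M Added HCl in mol/L (>= 0). Default 0.
#' @param added_naoh_M Added NaOH in mol/L (>= 0). Default 0.
#' @return A data frame with columns `protonated_amine_M`, `fraction` and
#'   `out_of_range`.
#' @examples
#' protonated_fraction(6, 4.08e-3, added_hcl_M = 2e-3)$fraction  # ~0.490
#' @export
protonated_fraction <- function(ph, amine_total_M, added_hcl_M = 0,
                                added_naoh_M = 0) {
  n <- max(length(ph), length(added_hcl_M), length(added_naoh_M))
  ph <- rep_len(ph, n)
  added_hcl_M <- rep_len(added_hcl_M, n)
  added_naoh_M <- rep_len(added_naoh_M, n)
  if (any(!is.finite(ph)) || any(ph <= 0) || any(ph >= 14)) {
    stop("pH must lie in (0, 14)", call. = FALSE)
  }
  if (any(added_hcl_M < 0) || any(added_naoh_M < 0)) {
    stop("acid/base doses must be non-negative", call. = FALSE)
  }
  if (!is.numeric(amine_total_M) || length(amine_total_M) != 1L ||
      amine_total_M <= 0) {
    stop("division undefined: `amine_total_M` must be positive ",
         "(use the control pathway for polymer-free samples)", call. = FALSE)
  }
  h <- 10^(-ph)
  oh <- .kw / h
  ah <- oh + added_hcl_M - h - added_naoh_M
  frac <- ah / amine_total_M
  data.frame(protonated_amine_M = ah, fraction = frac,
             out_of_range = frac < 0 | frac > 1)
}

# Apparent [AH+] of a polymer-free control: same arithmetic, tracks spurious
# H+ uptake (e.g. dissolved CO2) in the absence of polymer buffering.
.control_apparent_ah <- function(ph, added_hcl_M, added_naoh_M) {
  h <- 10^(-ph)
  .kw / h + added_hcl_M - h - added_naoh_M
}

#' Analyze a constant-concentration titration series
#'
#' Applies [protonated_fraction()] to every polymer sample, subtracts the
#' spurious protonation signal inferred from the matched polymer-free control
#' (matched exactly on the signed dose), optionally adds a constant baseline
#' for acid supplied at stock dissolution, and returns the protonation curve
#' sorted by pH.
#'
#' @param samples Data frame of polymer samples with columns `added_hcl_M`,
#'   `added_naoh_M`, `ph`, `amine_total_M` (constant across the series), e.g.
#'   from [simulate_titration()] or [read_titration_csv()]. An `is_control`
#'   column, if present, is used to split off controls when `controls` is NULL.
#' @param controls Optional data frame of polymer-free controls with the same
#'   dose columns and `ph`.
#' @param baseline_offset_M Constant protonated-amine offset in mol/L for the
#'   H+ added at stock dissolution (excluded from the dose axis). Default 0.
#' @return An object of class `"protonation_curve"`: a list with `points`
#'   (data frame sorted by pH with `ph`, `dose_M` = signed added acid,
#'   `fraction`, `corrected`, `out_of_range`), `amine_total_M` and
#'   `baseline_offset_M`.
#' @seealso [buffering_capacity()], [apparent_pkas()], [detect_stalls()]
#' @export
analyze_titration <- function(samples, controls = NULL, baseline_offset_M = 0) {
  if (is.null(controls) && "is_control" %in% names(samples)) {
    controls <- samples[samples$is_control, , drop = FALSE]
    samples <- samples[!samples$is_control, , drop = FALSE]
  }
  req <- c("added_hcl_M", "added_naoh_M", "ph", "amine_total_M")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(samples) == 0L) stop("empty titration series", call. = FALSE)
  a0 <- unique(samples$amine_total_M)
  if (length(a0) != 1L) {
    stop("constant-concentration series expected: `amine_total_M` varies",
         call. = FALSE)
  }

  pf <- protonated_fraction(samples$ph, a0,
                            samples$added_hcl_M, samples$added_naoh_M)
  dose <- samples$added_hcl_M - samples$added_naoh_M

  correction <- rep(0, nrow(samples))
  corrected <- rep(TRUE, nrow(samples))
  if (!is.null(controls) && nrow(controls) > 0L) {
    cdose <- controls$added_hcl_M - controls$added_naoh_M
    idx <- match(dose, cdose)
    unmatched <- is.na(idx)
    if (any(unmatched)) {
      warning(sprintf("%d sample(s) have no dose-matched control; left uncorrected",
                      sum(unmatched)), call. = FALSE)
      corrected[unmatched] <- FALSE
    }
    ok <- !unmatched
    correction[ok] <- .control_apparent_ah(controls$ph[idx[ok]],
                                           controls$added_hcl_M[idx[ok]],
                                           controls$added_naoh_M[idx[ok]])
  } else {
    corrected[] <- FALSE
  }

  ah <- pf$protonated_amine_M - correction + baseline_offset_M
  frac <- ah / a0

  pts <- data.frame(ph = samples$ph, dose_M = dose, fraction = frac,
                    corrected = corrected,
                    out_of_range = frac < 0 | frac > 1)

  # average duplicated pH readings, flagging them
  if (anyDuplicated(pts$ph)) {
    warning("duplicate pH values averaged", call. = FALSE)
    agg <- stats::aggregate(cbind(dose_M, fraction) ~ ph, data = pts, FUN = mean)
    agg$corrected <- vapply(agg$ph, function(p) all(pts$corrected[pts$ph == p]),
                            logical(1))
    agg$out_of_range <- agg$fraction < 0 | agg$fraction > 1
    pts <- agg
  }
  pts <- pts[order(pts$ph), , drop = FALSE]
  rownames(pts) <- NULL

  structure(list(points = pts, amine_total_M = a0,
                 baseline_offset_M = baseline_offset_M),
            class = "protonation_curve")
}

#' @export
print.protonation_curve <- function(x, ...) {
  cat(sprintf(
    "Protonation curve: %d samples, pH %.2f-%.2f, [A]0 = %g M, P range %.3f-%.3f\n",
    nrow(x$points), min(x$points$ph), max(x$points$ph), x$amine_total_M,
    min(x$points$fraction), max(x$points$fraction)))
  if (any(x$points$out_of_range)) {
    cat(sprintf("  %d point(s) with P outside [0, 1] (reported unclamped)\n",
                sum(x$points$out_of_range)))
  }
  invisible(x)
}

#' @export
plot.protonation_curve <- function(x, ...) {
  graphics::plot(x$points$ph, x$points$fraction, xlab = "pH",
                 ylab = "protonated fraction P", ...)
  invisible(x)
}

#' @export
summary.protonation_curve <- function(object, n_peaks = 2L, ...) {
  beta <- buffering_capacity(object$points[, c("dose_M", "ph")])
  pk <- tryCatch(apparent_pkas(beta, n_peaks), warning = function(w) {
    suppressWarnings(apparent_pkas(beta, n_peaks))
  })
  st <- detect_stalls(object)
  structure(list(curve = object, beta = beta, pkas = pk, stalls = st),
            class = "summary.protonation_curve")
}

#' @export
print.summary.protonation_curve <- function(x, ...) {
  print(x$curve)
  cat("Apparent pKa:", paste(sprintf("%.2f", x$pkas), collapse = ", "), "\n")
  if (nrow(x$stalls)) {
    cat("Stalled charge states:\n")
    print(x$stalls)
  } else cat("No stalled charge states detected\n")
  invisible(x)
}

# centered moving average, window must be odd; ends use shrinking windows
.moving_average <- function(x, window = 5L) {
  n <- length(x)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Buffering capacity from dose-pH data
#'
#' beta(pH) = |d(added acid - base) / d pH| estimated by centered finite
#' differences on dose-sorted points. High beta means a large acid dose is
#' needed to move the pH: the maxima of beta locate apparent pKa values.
#'
#' @param dose_ph A data frame (or 2-column matrix) whose first column is the
#'   signed dose in mol/L (HCl positive, NaOH negative) and second column the
#'   measured pH; or a `"protonation_curve"`.
#' @return Data frame with columns `ph` and `beta` (mol/L per pH unit),
#'   sorted by pH.
#' @export
buffering_capacity <- function(dose_ph) {
  if (inherits(dose_ph, "protonation_curve")) {
    dose_ph <- dose_ph$points[, c("dose_M", "ph")]
  }
  dose <- dose_ph[[1]]
  ph <- dose_ph[[2]]
  if (length(dose) < 4L) {
    stop("need at least 4 points spanning a pH interval", call. = FALSE)
  }
  ord <- order(dose)
  dose <- dose[ord]; ph <- ph[ord]
  # pH should fall monotonically as acid dose grows
  backsteps <- diff(ph) > 0
  if (mean(backsteps) > 0.05) {
    warning("data inconsistency: pH is not monotone in dose beyond tolerance",
            call. = FALSE)
  }
  n <- length(dose)
  idx <- 2:(n - 1)
  dph <- ph[idx + 1L] - ph[idx - 1L]
  dph[dph == 0] <- NA_real_
  beta <- abs((dose[idx + 1L] - dose[idx - 1L]) / dph)
  out <- data.frame(ph = ph[idx], beta = beta)
  out <- out[is.finite(out$beta), , drop = FALSE]
  out <- out[order(out$ph), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate apparent pKa values as buffering-capacity maxima
#'
#' Smooths beta with a centered moving window (on dose order, equivalently
#' monotone pH order) and returns the pH of the `n_peaks` largest local
#' maxima, sorted by pH. Ties between equal peaks are broken in favour of the
#' lower pH.
#'
#' @param beta_curve Data frame with columns `ph` and `beta`, e.g. from
#'   [buffering_capacity()].
#' @param n_peaks Number of maxima requested. Default 2.
#' @param window Smoothing window (points). Default 5.
#' @return Numeric vector of pH values (ascending); fewer than `n_peaks` with
#'   a warning if the curve has fewer local maxima.
#' @export
apparent_pkas <- function(beta_curve, n_peaks = 2L, window = 5L) {
  if (!nrow(beta_curve)) stop("empty buffering-capacity curve", call. = FALSE)
  ph <- beta_curve$ph
  b <- .moving_average(beta_curve$beta, window)
  n <- length(b)
  if (n < 3L) {
    warning("too few points for peak detection", call. = FALSE)
    return(numeric(0))
  }
  i <- 2:(n - 1L)
  is_max <- b[i] > b[i - 1L] & b[i] >= b[i + 1L]
  peaks <- i[is_max]
  if (!length(peaks)) {
    warning("no local maxima found in buffering capacity", call. = FALSE)
    return(numeric(0))
  }
  # largest first; ties -> lower pH
  ord <- order(-b[peaks], ph[peaks])
  peaks <- peaks[ord]
  if (length(peaks) < n_peaks) {
    warning(sprintf("only %d local maxima found (%d requested)",
                    length(peaks), n_peaks), call. = FALSE)
  }
  sort(ph[utils::head(peaks, n_peaks)])
}

#' Detect stalled charge states (protonation plateaus)
#'
#' Finds contiguous pH windows of span at least `min_span` over which the
#' protonation fraction is locally flat (|dP/dpH| below `slope_tol`), and
#' reports the mean fraction of each window. These are the stalled charge
#' states between which buffering occurs.
#'
#' @param curve A `"protonation_curve"`, or a data frame with columns `ph`
#'   and `fraction`.
#' @param slope_tol Maximum |dP/dpH| within a stall. Default 0.02 per pH unit.
#' @param min_span Minimum pH span of a stall. Default 1 pH unit.
#' @return Data frame with columns `fraction_level`, `ph_min`, `ph_max`
#'   (possibly zero rows).
#' @export
detect_stalls <- function(curve, slope_tol = 0.02, min_span = 1) {
  pts <- if (inherits(curve, "protonation_curve")) curve$points else curve
  pts <- pts[order(pts$ph), , drop = FALSE]
  ph <- pts$ph; p <- pts$fraction
  n <- length(ph)
  if (n < 5L) stop("need at least 5 points", call. = FALSE)
  slope <- abs(diff(p) / diff(ph))   # slope of each interval
  flat <- slope < slope_tol
  out <- data.frame(fraction_level = numeric(0), ph_min = numeric(0),
                    ph_max = numeric(0))
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k] + 1L   # interval run -> point range
    if (ph[i1] - ph[i0] >= min_span) {
      out <- rbind(out, data.frame(fraction_level = mean(p[i0:i1]),
                                   ph_min = ph[i0], ph_max = ph[i1]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Predicted ninhydrin signal
#'
#' The ninhydrin reaction requires a transferable lone pair, so the developed
#' absorbance tracks the unprotonated secondary amines: signal =
#' scale * (1 - P), floored at zero.
#'
#' @param fraction Protonated fraction(s) P.
#' @param scale Positive calibration constant mapping the unprotonated
#'   fraction to an absorbance proxy. Default 1.
#' @return Predicted signal, same length as `fraction`.
#' @export
ninhydrin_signal <- function(fraction, scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("`scale` must be a single positive number", call. = FALSE)
  }
  pmax(scale * (1 - fraction), 0)
}
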