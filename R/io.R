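# CSV readers/writers for the three measurement schemas, and the synthetic
# reproduction pipeline. All unit conversions happen here, at the boundary;
# internal computation is SI + mol/L.

.read_metadata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    ln <- sub("^\\s*#\\s*", "", ln)
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    meta[[key]] <- val
  }
  meta
}

.check_columns <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("schema error in '%s': missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in required) {
    if (col %in% c("sample_id", "is_control")) next
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(sprintf("parse error in '%s': non-numeric value in column '%s' (row %d)",
                   path, col, if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a DLS correlation curve from CSV
#'
#' Expects columns `lag_time_s, g_minus_1` and metadata header lines
#' `# wavelength_nm=`, `# angle_deg=`, `# refractive_index=`,
#' `# temperature_K=`, `# nacl_mM=`.
#'
#' @param path Path to the CSV file.
#' @return A [correlation_curve()].
#' @export
read_correlation_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- .read_metadata(path)
  need <- c("wavelength_nm", "angle_deg", "refractive_index",
            "temperature_K", "nacl_mM")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("schema error: missing metadata header(s) ",
         paste(paste0("# ", miss, "="), collapse = ", "), call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#")
  .check_columns(df, c("lag_time_s", "g_minus_1"), path)
  geom <- dls_geometry(as.numeric(meta$wavelength_nm),
                       as.numeric(meta$angle_deg),
                       as.numeric(meta$refractive_index))
  solv <- solvent_spec(as.numeric(meta$temperature_K),
                       as.numeric(meta$nacl_mM) * 1e-3)
  correlation_curve(df$lag_time_s, df$g_minus_1, geom, solv,
                    label = if (!is.null(meta$label)) meta$label else basename(path))
}

#' Write a DLS correlation curve to CSV
#'
#' @param curve A [correlation_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  g <- curve$geometry; s <- curve$solvent
  hdr <- c(sprintf("# wavelength_nm=%.10g", g$wavelength_nm),
           sprintf("# angle_deg=%.10g", g$angle_deg),
           sprintf("# refractive_index=%.10g", g$refractive_index),
           sprintf("# temperature_K=%.10g", s$temperature_K),
           sprintf("# nacl_mM=%.10g", s$nacl_M * 1e3))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(lag_time_s = curve$lag_times_s,
                              g_minus_1 = curve$g_minus_1),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a titration table from CSV
#'
#' Expects columns `sample_id, added_hcl_M, added_naoh_M, ph, amine_total_M,
#' nacl_M, is_control`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of titration samples suitable for [analyze_titration()].
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  .check_columns(df, c("sample_id", "added_hcl_M", "added_naoh_M", "ph",
                       "amine_total_M", "nacl_M", "is_control"), path)
  df$is_control <- as.logical(df$is_control)
  bad <- df$added_hcl_M > 0 & df$added_naoh_M > 0
  if (any(bad)) {
    stop(sprintf("schema error in '%s': %d sample(s) have both HCl and NaOH doses",
                 path, sum(bad)), call. = FALSE)
  }
  df
}

#' Write a titration table to CSV
#'
#' @param samples Data frame as returned by [simulate_titration()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' Read an osmometry table from CSV
#'
#' Expects columns `conc_mM, signal, nacl_mM`; an optional metadata line
#' `# calibrated=` (true/false, default true) marks whether the signal is in
#' absolute reduced-pressure units.
#'
#' @param path Path to the CSV file.
#' @return An [osmotic_series()].
#' @export
read_osmometry_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- .read_metadata(path)
  df <- utils::read.csv(path, comment.char = "#")
  .check_columns(df, c("conc_mM", "signal", "nacl_mM"), path)
  calibrated <- if (!is.null(meta$calibrated)) {
    tolower(meta$calibrated) %in% c("true", "1", "yes")
  } else TRUE
  osmotic_series(df$conc_mM * 1e-3, df$signal,
                 nacl_M = df$nacl_mM[1] * 1e-3, calibrated = calibrated)
}

#' Write an osmometry table to CSV
#'
#' @param series An [osmotic_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_osmometry_csv <- function(series, path) {
  stopifnot(inherits(series, "osmotic_series"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# calibrated=%s", tolower(series$calibrated)), con)
  utils::write.csv(data.frame(conc_mM = series$conc_amine_M * 1e3,
                              signal = series$signal,
                              nacl_mM = series$nacl_M * 1e3),
                   con, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic reproduction pipeline
#'
#' Forward-simulates all three measurement types from ground truth and runs
#' the corresponding analyses, reporting recovered against true parameters:
#'
#' * DLS: a two-population solution (free chains 5 nm, aggregates 140 nm,
#'   equal intensity) at 633 nm / 173 degrees / 25 C, noise-free and at 1
#'   percent multiplicative noise; fitted radii and intensity fractions.
#' * Titration: the 4.08 mM amine / 150 mM NaCl constant-concentration
#'   titration of the default isotherm, analyzed by charge balance; mean
#'   protonation across pH 7-9, the acidic stall level, the protonation of
#'   the sample nearest pH 2.5 (from a grid extended below pH 3), and the
#'   buffering-capacity maxima below pH 7 and above pH 8.
#' * Osmometry: virial recovery on an ideal series and plateau-onset
#'   detection on an associating series (onset 3 mM).
#'
#' Stages run independently: a failing stage is recorded in the report and
#' the remaining stages still run.
#'
#' @param seed Integer seed used for every stochastic element.
#' @param quiet Suppress per-stage progress messages. Default TRUE.
#' @return A nested list (one element per stage) with inputs, recovered
#'   quantities and any warnings, plus `seed` and package version.
#' @export
reproduce_analysis <- function(seed = 1L, quiet = TRUE) {
  seed <- as.integer(seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  report <- list(seed = seed,
                 package_version = as.character(utils::packageVersion("polyion")))
  run_stage <- function(expr) {
    warns <- character(0)
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) list(failed = TRUE,
                                              error = conditionMessage(e))),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (is.null(res$failed)) res$failed <- FALSE
    res$warnings <- warns
    res
  }

  say("stage: dls")
  report$dls <- run_stage({
    geom <- dls_geometry(633, 173, 1.33)
    solv <- solvent_spec(298.15, 0.15)
    truth <- c(free = 5, aggregate = 140)
    pop <- population_spec(free_radius_nm = truth[["free"]],
                           aggregate_radius_nm = truth[["aggregate"]],
                           free_intensity_fraction = 0.5)
    one <- function(noise, sd_seed) {
      cc <- simulate_correlation(pop, geom, solv, noise_sd = noise,
                                 seed = sd_seed)
      fit <- fit_correlation(cc, 2L)
      sized <- size_modes(fit)
      list(noise_sd = noise,
           radii_nm = stats::setNames(sized$hydrodynamic_radius_nm,
                                      c("free", "aggregate")),
           relative_error = stats::setNames(
             abs(sized$hydrodynamic_radius_nm - truth) / truth,
             c("free", "aggregate")),
           fractions = intensity_fractions(fit))
    }
    list(truth_radii_nm = truth,
         noise_free = one(0, NULL),
         one_percent_noise = one(0.01, seed))
  })

  say("stage: titration")
  report$titration <- run_stage({
    iso <- protonation_isotherm()
    base_design <- titration_design()
    sim <- simulate_titration(iso, base_design, ph_noise_sd = 0)
    curve <- analyze_titration(sim)
    pts <- curve$points
    neutral <- pts$fraction[pts$ph > 7 & pts$ph < 9]
    stalls <- detect_stalls(curve)
    acid_stall <- stalls[stalls$ph_min >= 3 & stalls$ph_max <= 4.5, ]
    beta <- buffering_capacity(curve)
    peaks <- apparent_pkas(beta, n_peaks = 2L)
    ext_design <- titration_design(acid_max_M = 8e-3)
    ext <- simulate_titration(iso, ext_design, ph_noise_sd = 0)
    ext_curve <- analyze_titration(ext)
    low <- ext_curve$points[which.min(abs(ext_curve$points$ph - 2.5)), ]
    list(n_samples = nrow(pts),
         neutral_mean_fraction = mean(neutral),
         n_neutral_samples = length(neutral),
         acid_stall_fraction = if (nrow(acid_stall)) acid_stall$fraction_level[1] else NA_real_,
         acid_stall_window = if (nrow(acid_stall)) c(acid_stall$ph_min[1], acid_stall$ph_max[1]) else NULL,
         low_ph = low$ph, low_ph_fraction = low$fraction,
         pka_acidic = min(peaks), pka_basic = max(peaks),
         isotherm_truth = list(levels = iso$plateau_levels,
                               centers = iso$transition_centers))
  })

  say("stage: osmometry")
  report$osmometry <- run_stage({
    ideal <- simulate_osmometry(2500, b2 = 1e-6, association_onset_M = Inf,
                                noise_sd = 0)
    vf <- virial_fit(ideal, degree = 2)
    assoc <- simulate_osmometry(2500, b2 = 0, association_onset_M = 3e-3,
                                conc_amine_M = seq(5e-4, 8e-3, by = 5e-4),
                                noise_sd = 0)
    prof <- association_profile(assoc)
    list(molar_mass_truth = 2500, molar_mass_fit = vf$molar_mass_g_mol,
         b2_truth = 1e-6, b2_fit = vf$b2,
         plateau_onset_truth_M = 3e-3,
         plateau_onset_fit_M = prof$plateau_onset_M,
         is_associating = prof$is_associating)
  })

  report
}
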