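#' Degrees-to-microns conversion on the emmetropic retina
#'
#' Standard approximation used to place OCT scan geometry (given in microns)
#' into visual-field degree space.
#' @format Numeric scalar, microns per degree.
#' @export
UM_PER_DEG <- 288

#' Instrument dynamic range of the microperimeter (dB)
#' @format Numeric vector `c(min, max)`.
#' @export
DB_RANGE <- c(0, 36)

#' Cohort generator configuration
#'
#' Builds the configuration object that parameterizes the synthetic MEWDS
#' cohort generator. The defaults define the study conditions emulated by the
#' package: 13 patients (one bilateral case expected, so ~14 eyes), half the
#' eyes with foveal granularity, visits at presentation and 2 weeks / 6 weeks
#' / 3 months, a centrifugal recovery gradient (central lesions recover
#' fastest, peripapillary slowest), and a forward structure-function model
#' `PRR = sf_intercept + sf_slope * 10^(S/10)` with hierarchical noise.
#'
#' @param n_patients Number of patients.
#' @param p_bilateral Probability a patient contributes both eyes.
#' @param p_granularity Probability an eye shows foveal granularity.
#' @param visit_days Day offsets of the study visits (day 0 = baseline);
#'   must be nonnegative and strictly increasing.
#' @param visit_jitter_days Half-width (days) of the uniform jitter applied to
#'   follow-up visit days (baseline is never jittered).
#' @param healthy_fovea_db Healthy foveal sensitivity (dB).
#' @param healthy_slope_db_per_deg Linear decline of healthy sensitivity per
#'   degree of eccentricity (dB/deg).
#' @param lesion_count_range Integer range (min, max) of focal lesions per eye
#'   (foveal granularity lesion and peripapillary cluster not included).
#' @param lesion_depth_db_range Range of raw focal lesion depths (dB), before
#'   attenuation by time already elapsed since symptom onset.
#' @param lesion_sigma_deg_range Range of focal lesion Gaussian widths (deg).
#' @param recovery_tau_days Named list of recovery time constants (days) with
#'   entries `central`, `extramacular`, `peripapillary`.
#' @param sf_intercept,sf_slope Forward structure-function model coefficients
#'   (PRR units; PRR per unit linear sensitivity).
#' @param sf_eye_sd Between-eye random-intercept SD of PRR (PRR units).
#' @param sf_resid_sd Location-level residual SD of PRR (PRR units).
#' @param fixation_sigma0_deg Fixation dispersion (deg) of a healthy eye.
#' @param fixation_sensitivity_gain Additional dispersion (deg) per dB of
#'   foveal sensitivity deficit.
#' @param fixation_log_jitter_sd SD of lognormal per-eye jitter applied to the
#'   fixation dispersion (captures eye-level fixation variability that is not
#'   explained by sensitivity).
#' @param granularity_fixation_multiplier Multiplier on fixation dispersion in
#'   eyes with foveal granularity.
#' @param granularity_depth_db_range Range of raw foveal-lesion depths (dB)
#'   for granularity eyes.
#' @param granularity_sigma_deg_range Range of foveal-lesion widths (deg).
#' @param diffuse_depth_db_range Range of raw depths of the broad diffuse
#'   sensitivity loss accompanying the focal spots.
#' @param bcva_per_db LogMAR increase per dB of foveal deficit (acuity
#'   coupling).
#' @param bcva_noise_sd SD of LogMAR measurement noise.
#' @param onset_days_range Range (days) of time from symptom onset to
#'   presentation; the study inclusion window.
#' @param staircase_start_db Starting attenuation of the 4-2 staircase (dB).
#' @param psycho_slope_db Slope of the psychometric function (dB).
#' @param fp_rate,fn_rate False-positive / false-negative response rates.
#' @param seed Default seed recorded in the config (operations take an
#'   explicit seed argument which wins).
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @export
#' @examples
#' cfg <- cohort_config()
#' cfg$recovery_tau_days$central
cohort_config <- function(n_patients = 13,
                          p_bilateral = 1 / 13,
                          p_granularity = 0.5,
                          visit_days = c(0, 14, 42, 90),
                          visit_jitter_days = 7,
                          healthy_fovea_db = 27,
                          healthy_slope_db_per_deg = 0.3,
                          lesion_count_range = c(4, 9),
                          lesion_depth_db_range = c(6, 20),
                          lesion_sigma_deg_range = c(0.6, 1.4),
                          recovery_tau_days = list(central = 15,
                                                   extramacular = 35,
                                                   peripapillary = 70),
                          sf_intercept = 5.36,
                          sf_slope = 0.66e-2,
                          sf_eye_sd = 0.5,
                          sf_resid_sd = 0.4,
                          fixation_sigma0_deg = 0.18,
                          fixation_sensitivity_gain = 0.017,
                          fixation_log_jitter_sd = 0.30,
                          granularity_fixation_multiplier = 1.05,
                          granularity_depth_db_range = c(9, 23),
                          granularity_sigma_deg_range = c(0.6, 1.1),
                          diffuse_depth_db_range = c(1, 8),
                          bcva_per_db = 0.03,
                          bcva_noise_sd = 0.04,
                          onset_days_range = c(1, 30),
                          staircase_start_db = 25,
                          psycho_slope_db = 1.5,
                          fp_rate = 0.02,
                          fn_rate = 0.02,
                          seed = 1L) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  validate_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks field types, probability bounds, visit ordering and the region keys
#' of the recovery time-constant map. Called by [cohort_config()]; exported so
#' configs read from YAML can be revalidated.
#'
#' @param cfg A `cohort_config` object or compatible named list.
#' @return `cfg`, invisibly, if valid; otherwise an error naming the field.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid config field '%s': %s", field, why), call. = FALSE)
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      fail(field, "must be a probability in [0, 1]")
  }
  chk_pos <- function(field, strict = FALSE) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || (strict && v <= 0))
      fail(field, "must be a nonnegative number")
  }
  chk_range <- function(field, lo = -Inf) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 2 || any(is.na(v)) || v[1] > v[2] || v[1] < lo)
      fail(field, "must be an ordered (min, max) pair")
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != round(cfg$n_patients))
    fail("n_patients", "must be a nonnegative integer")
  for (f in c("p_bilateral", "p_granularity", "fp_rate", "fn_rate")) chk_prob(f)
  v <- cfg$visit_days
  if (!is.numeric(v) || length(v) < 1 || any(is.na(v)) || any(v < 0) ||
      any(diff(v) <= 0))
    fail("visit_days", "must be nonnegative and strictly increasing")
  tau <- cfg$recovery_tau_days
  if (!is.list(tau) ||
      !setequal(names(tau), c("central", "extramacular", "peripapillary")) ||
      !all(vapply(tau, function(x) is.numeric(x) && x > 0, logical(1))))
    fail("recovery_tau_days",
         "must be a list with positive entries central, extramacular, peripapillary")
  if (!is.numeric(cfg$sf_slope) || cfg$sf_slope <= 0)
    fail("sf_slope", "must be > 0")
  for (f in c("sf_eye_sd", "sf_resid_sd", "bcva_noise_sd",
              "fixation_log_jitter_sd", "fixation_sigma0_deg",
              "fixation_sensitivity_gain", "visit_jitter_days")) chk_pos(f)
  for (f in c("lesion_depth_db_range", "lesion_sigma_deg_range",
              "granularity_depth_db_range", "granularity_sigma_deg_range",
              "diffuse_depth_db_range", "onset_days_range")) chk_range(f, lo = 0)
  chk_range("lesion_count_range", lo = 0)
  if (cfg$staircase_start_db < DB_RANGE[1] || cfg$staircase_start_db > DB_RANGE[2])
    fail("staircase_start_db", "must lie in the instrument dynamic range")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d patients, p(bilateral) = %.3f, p(granularity) = %.2f\n",
              x$n_patients, x$p_bilateral, x$p_granularity))
  cat(sprintf("  visits at days %s (jitter +/- %g d)\n",
              paste(x$visit_days, collapse = "/"), x$visit_jitter_days))
  cat(sprintf("  recovery tau (d): central %g < extramacular %g < peripapillary %g\n",
              x$recovery_tau_days$central, x$recovery_tau_days$extramacular,
              x$recovery_tau_days$peripapillary))
  cat(sprintf("  forward SF model: PRR = %.3g + %.3g * 10^(S/10)\n",
              x$sf_intercept, x$sf_slope))
  invisible(x)
}

#' Read / write a cohort configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns a validated `cohort_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(cohort_config, raw)
  cfg
}

#' @rdname read_config
#' @param cfg A `cohort_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Anatomical region of a retinal location
#'
#' Assigns the region labels used by the recovery-gradient analysis. The disc
#' is placed 15 degrees nasal to (and 1.5 degrees above) the fovea; locations
#' within 4.25 degrees of the disc center are peripapillary, locations within
#' 2.5 degrees of fixation are central, and everything else is extramacular.
#'
#' @param x_deg,y_deg Retinal coordinates in degrees (x positive temporal,
#'   origin at the fovea); vectorized.
#' @return Character vector with levels central / extramacular / peripapillary.
#' @export
region_of <- function(x_deg, y_deg) {
  disc <- c(-15, 1.5)
  d_disc <- sqrt((x_deg - disc[1])^2 + (y_deg - disc[2])^2)
  ecc <- sqrt(x_deg^2 + y_deg^2)
  out <- rep("extramacular", length(ecc))
  out[ecc <= 2.5] <- "central"
  out[d_disc <= 4.25] <- "peripapillary"
  out
}

# clamp to the instrument dynamic range
clamp_db <- function(x) pmin(pmax(x, DB_RANGE[1]), DB_RANGE[2])

# derive a reproducible 32-bit substream seed from (seed, stage offset)
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}
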