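#' Generate a synthetic MEWDS cohort
#'
#' Draws a cohort of eyes whose ground-truth sensitivity fields, covariates
#' and acuity carry the statistical structure of an acute MEWDS cohort:
#' multifocal Gaussian lesions plus a broad diffuse sensitivity loss, a
#' peripapillary lesion cluster, optional foveal granularity (a deep foveal
#' lesion whose depth and size shrink with time from symptom onset), and
#' best-corrected visual acuity coupled to the true foveal sensitivity.
#' Lesion depths are attenuated by `exp(-onset/tau)` for the time already
#' elapsed between symptom onset and the baseline visit, so eyes presenting
#' later present shallower deficits.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; identical `(config, seed)` give identical output.
#' @return A list with elements
#'   \describe{
#'     \item{eyes}{data.frame of eye-level records (one row per eye): ids,
#'       laterality, primary/secondary type, granularity flag and size,
#'       onset days, BCVA (LogMAR), refraction, choroidal thickness, the
#'       per-eye PRR random intercept, and the true baseline foveal
#'       sensitivity used to couple acuity and fixation.}
#'     \item{fields}{named list of [sensitivity_field()] objects keyed by
#'       `eye_id`.}
#'   }
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_config(config)
  if (config$n_patients == 0)
    stop("empty cohort: n_patients is 0", call. = FALSE)
  withr::with_seed(substream_seed(seed, 1L), {
    rows <- list()
    fields <- list()
    for (p in seq_len(config$n_patients)) {
      n_eyes <- 1L + stats::rbinom(1, 1, config$p_bilateral)
      sides <- if (n_eyes == 2) c("OD", "OS") else sample(c("OD", "OS"), 1)
      for (side in sides) {
        eye <- .draw_eye(config, patient_id = sprintf("P%02d", p), side = side)
        rows[[length(rows) + 1L]] <- eye$record
        fields[[eye$record$eye_id]] <- eye$field
      }
    }
    eyes <- do.call(rbind, rows)
    rownames(eyes) <- NULL
    list(eyes = eyes, fields = fields)
  })
}

# draw one eye: covariates, lesion set, acuity
.draw_eye <- function(config, patient_id, side) {
  tau <- config$recovery_tau_days
  onset <- round(stats::rlnorm(1, meanlog = log(7), sdlog = 0.8))
  onset <- min(max(onset, config$onset_days_range[1]), config$onset_days_range[2])
  granularity <- stats::runif(1) < config$p_granularity
  mewds_type <- if (stats::runif(1) < 0.79) "primary" else "secondary"
  # secondary cases are older and more myopic
  age <- if (mewds_type == "primary") stats::rnorm(1, 28, 7.1)
         else stats::rnorm(1, 49, 16.5)
  age <- min(max(round(age), 18), 75)
  female <- stats::runif(1) < 0.77
  refraction <- stats::rnorm(1, if (mewds_type == "primary") -0.72 else -3.95,
                             2.0)
  choroid <- stats::rnorm(1, 350, 93)

  lesions <- list()

  # broad diffuse loss centered under the macula; being central it recovers
  # on the fast central time scale, giving the early-concentrated gains
  d_depth <- stats::runif(1, config$diffuse_depth_db_range[1],
                          config$diffuse_depth_db_range[2])
  d_ecc <- stats::runif(1, 0, 2)
  d_ang <- stats::runif(1, 0, 2 * pi)
  d_ctr <- d_ecc * c(cos(d_ang), sin(d_ang))
  lesions[[1]] <- lesion(center_deg = d_ctr,
                         sigma_deg = stats::runif(1, 6, 10),
                         depth_db = d_depth * exp(-onset / tau$central))

  # focal white spots across the central field
  n_focal <- sample(seq(config$lesion_count_range[1],
                        config$lesion_count_range[2]), 1)
  for (k in seq_len(n_focal)) {
    ecc <- sqrt(stats::runif(1, 2.0^2, 5.2^2))
    ang <- stats::runif(1, 0, 2 * pi)
    ctr <- ecc * c(cos(ang), sin(ang))
    reg <- region_of(ctr[1], ctr[2])
    raw <- stats::runif(1, config$lesion_depth_db_range[1],
                        config$lesion_depth_db_range[2])
    lesions[[length(lesions) + 1L]] <-
      lesion(ctr,
             sigma_deg = stats::runif(1, config$lesion_sigma_deg_range[1],
                                      config$lesion_sigma_deg_range[2]),
             depth_db = raw * exp(-onset / tau[[reg]]),
             region = reg)
  }

  # peripapillary cluster around the disc (slowest to recover)
  for (k in seq_len(sample(2:4, 1))) {
    ctr <- c(-15, 1.5) + stats::rnorm(2, 0, 1.8)
    raw <- stats::runif(1, 8, 20)
    lesions[[length(lesions) + 1L]] <-
      lesion(ctr, sigma_deg = stats::runif(1, 1, 2.5),
             depth_db = raw * exp(-onset / tau$peripapillary),
             region = "peripapillary")
  }

  # foveal granularity: one deep foveal lesion, size and depth shrinking with
  # time from onset
  size_um <- NA_real_
  if (granularity) {
    size_um <- 1500 * exp(-onset / 25) * exp(stats::rnorm(1, 0, 0.25))
    size_um <- min(max(size_um, 250), 1600)
    sig <- size_um / UM_PER_DEG / 2.355  # FWHM -> sigma
    sig <- min(max(sig, config$granularity_sigma_deg_range[1]),
               config$granularity_sigma_deg_range[2])
    raw <- stats::runif(1, config$granularity_depth_db_range[1],
                        config$granularity_depth_db_range[2])
    lesions[[length(lesions) + 1L]] <-
      lesion(stats::rnorm(2, 0, 0.15), sigma_deg = sig,
             depth_db = raw * exp(-onset / tau$central),
             region = "central")
  }

  eye_id <- paste(patient_id, side, sep = "_")
  field <- sensitivity_field(eye_id, lesions,
                             healthy_fovea_db = config$healthy_fovea_db,
                             healthy_slope_db_per_deg = config$healthy_slope_db_per_deg,
                             recovery_tau_days = tau)

  # acuity coupled to true foveal sensitivity at presentation
  fov_pts <- expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5))
  fov_true <- mean(true_sensitivity(field, fov_pts$x, fov_pts$y, 0))
  healthy_fov <- config$healthy_fovea_db -
    config$healthy_slope_db_per_deg * sqrt(0.5)
  bcva <- config$bcva_per_db * (healthy_fov - fov_true) +
    stats::rnorm(1, 0, config$bcva_noise_sd)
  bcva <- min(max(bcva, 0), 1)

  record <- data.frame(
    patient_id = patient_id,
    eye = side,
    eye_id = eye_id,
    mewds_type = mewds_type,
    age_years = age,
    female = female,
    granularity = granularity,
    granularity_size_um = size_um,
    onset_days = onset,
    bcva_logmar = bcva,
    refraction_d = refraction,
    choroid_um = choroid,
    sf_eye_effect = stats::rnorm(1, 0, config$sf_eye_sd),
    foveal_true_db = fov_true,
    stringsAsFactors = FALSE
  )
  list(record = record, field = field)
}

#' Simulate a fixation point cloud
#'
#' Fixation samples are drawn from an isotropic bivariate normal centered
#' near fixation. Dispersion grows with the foveal sensitivity deficit
#' (`sigma = sigma0 + gain * deficit`), is inflated by the granularity
#' multiplier in eyes with foveal granularity, and carries a lognormal
#' per-eye jitter representing fixation variability unrelated to sensitivity.
#'
#' @param eye One row of the `eyes` data.frame from [generate_cohort()] (or
#'   any list with a logical `granularity` element).
#' @param foveal_true_db True foveal sensitivity of the eye (dB).
#' @param n_samples Number of fixation samples (>= 10).
#' @param seed Integer seed.
#' @param config A [cohort_config()] supplying the dispersion parameters.
#' @return A `fixation_cloud`: data.frame with columns `t`, `x_deg`, `y_deg`.
#' @export
generate_fixation_cloud <- function(eye, foveal_true_db, n_samples = 600,
                                    seed = 1L, config = cohort_config()) {
  if (n_samples < 10)
    stop("insufficient samples: n_samples must be >= 10", call. = FALSE)
  withr::with_seed(substream_seed(seed, 2L), {
    deficit <- max(0, config$healthy_fovea_db - foveal_true_db)
    sigma <- config$fixation_sigma0_deg +
      config$fixation_sensitivity_gain * deficit
    if (isTRUE(eye$granularity))
      sigma <- sigma * config$granularity_fixation_multiplier
    sigma <- sigma * exp(stats::rnorm(1, 0, config$fixation_log_jitter_sd))
    ctr <- stats::rnorm(2, 0, 0.05)
    cloud <- data.frame(
      t = seq_len(n_samples),
      x_deg = stats::rnorm(n_samples, ctr[1], sigma),
      y_deg = stats::rnorm(n_samples, ctr[2], sigma)
    )
    class(cloud) <- c("fixation_cloud", "data.frame")
    cloud
  })
}
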