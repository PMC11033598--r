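#' Construct a focal retinal lesion
#'
#' A lesion is a Gaussian sensitivity deficit: at baseline it subtracts
#' `depth_db * exp(-r^2 / (2 sigma^2))` dB at distance `r` from its center,
#' and the deficit decays exponentially over follow-up with the recovery time
#' constant of its region (central lesions recover fastest, peripapillary
#' slowest — the centrifugal pattern).
#'
#' @param center_deg Length-2 numeric, lesion center (x, y) in degrees.
#' @param sigma_deg Gaussian width (deg), > 0.
#' @param depth_db Maximal sensitivity loss at baseline (dB), >= 0.
#' @param region One of `"central"`, `"extramacular"`, `"peripapillary"`;
#'   defaults to [region_of()] at the center.
#' @return A `lesion` object.
#' @export
lesion <- function(center_deg, sigma_deg, depth_db,
                   region = region_of(center_deg[1], center_deg[2])) {
  stopifnot(length(center_deg) == 2, is.finite(center_deg))
  if (!is.numeric(sigma_deg) || sigma_deg <= 0)
    stop("sigma_deg must be > 0", call. = FALSE)
  if (!is.numeric(depth_db) || depth_db < 0)
    stop("depth_db must be >= 0", call. = FALSE)
  region <- match.arg(region, c("central", "extramacular", "peripapillary"))
  structure(list(center_deg = as.numeric(center_deg),
                 sigma_deg = sigma_deg,
                 depth_db = depth_db,
                 region = region),
            class = "lesion")
}

#' Construct a ground-truth sensitivity field
#'
#' The field is the healthy hill of vision (linear decline from the foveal
#' peak) minus the sum of its lesions' time-decaying deficits, clamped to the
#' instrument dynamic range.
#'
#' @param eye_ref Identifier of the eye the field belongs to.
#' @param lesions List of [lesion()] objects.
#' @param healthy_fovea_db Healthy foveal sensitivity (dB).
#' @param healthy_slope_db_per_deg Decline per degree of eccentricity (dB/deg).
#' @param recovery_tau_days Named list of recovery time constants (days), keys
#'   central / extramacular / peripapillary.
#' @return A `sensitivity_field` object.
#' @export
sensitivity_field <- function(eye_ref, lesions = list(),
                              healthy_fovea_db = 26,
                              healthy_slope_db_per_deg = 0.3,
                              recovery_tau_days = list(central = 15,
                                                       extramacular = 35,
                                                       peripapillary = 70)) {
  stopifnot(all(vapply(lesions, inherits, logical(1), "lesion")))
  structure(list(eye_ref = eye_ref,
                 lesions = lesions,
                 healthy_fovea_db = healthy_fovea_db,
                 healthy_slope_db_per_deg = healthy_slope_db_per_deg,
                 recovery_tau_days = recovery_tau_days),
            class = "sensitivity_field")
}

#' @export
print.sensitivity_field <- function(x, ...) {
  cat(sprintf("<sensitivity_field> eye %s: %d lesion(s), healthy %g dB - %g dB/deg\n",
              x$eye_ref, length(x$lesions), x$healthy_fovea_db,
              x$healthy_slope_db_per_deg))
  invisible(x)
}

#' Evaluate the true retinal sensitivity
#'
#' Returns the ground-truth threshold sensitivity (dB) at retinal locations
#' `(x_deg, y_deg)` and follow-up time `t_days` (days since baseline):
#' `clamp( healthy(x, y) - sum_j depth_j exp(-r_j^2 / 2 sigma_j^2) exp(-t / tau_region(j)) )`.
#' Monotone nondecreasing in `t` everywhere.
#'
#' @param field A [sensitivity_field()].
#' @param x_deg,y_deg Coordinates in degrees (vectorized, recycled).
#' @param t_days Days since baseline, >= 0 (scalar).
#' @return Numeric vector of sensitivities in `[0, 36]` dB.
#' @export
#' @examples
#' f <- sensitivity_field("eye1", list(lesion(c(1, 0), 1, 10)))
#' true_sensitivity(f, 1, 0, 0)    # healthy - 10 at the center
#' true_sensitivity(f, 1, 0, 300)  # recovered to ~healthy
true_sensitivity <- function(field, x_deg, y_deg, t_days) {
  stopifnot(inherits(field, "sensitivity_field"))
  if (!is.numeric(t_days) || length(t_days) != 1 || is.na(t_days) || t_days < 0)
    stop("t_days must be a nonnegative scalar", call. = FALSE)
  n <- max(length(x_deg), length(y_deg))
  x <- rep_len(x_deg, n)
  y <- rep_len(y_deg, n)
  s <- field$healthy_fovea_db - field$healthy_slope_db_per_deg * sqrt(x^2 + y^2)
  for (L in field$lesions) {
    tau <- field$recovery_tau_days[[L$region]]
    r2 <- (x - L$center_deg[1])^2 + (y - L$center_deg[2])^2
    s <- s - L$depth_db * exp(-r2 / (2 * L$sigma_deg^2)) * exp(-t_days / tau)
  }
  clamp_db(s)
}
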