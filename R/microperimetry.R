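#' Build the 68-point microperimetry stimulus grid
#'
#' Rectilinear 1-degree-spaced lattice offset 0.5 degrees from both axes,
#' restricted to `x^2 + y^2 <= 20.5`, which keeps exactly 68 of the 100 raw
#' lattice points and covers the central 10 degrees. The innermost four
#' locations at `(+/-0.5, +/-0.5)` define the foveal sensitivity average.
#'
#' @return data.frame with columns `location_id`, `x_deg`, `y_deg`,
#'   `eccentricity_deg`, `region`.
#' @export
build_grid <- function() {
  v <- c(-4.5, -3.5, -2.5, -1.5, -0.5, 0.5, 1.5, 2.5, 3.5, 4.5)
  g <- expand.grid(x_deg = v, y_deg = v)
  g <- g[g$x_deg^2 + g$y_deg^2 <= 20.5, ]
  g <- g[order(-g$y_deg, g$x_deg), ]
  data.frame(location_id = seq_len(nrow(g)),
             x_deg = g$x_deg, y_deg = g$y_deg,
             eccentricity_deg = sqrt(g$x_deg^2 + g$y_deg^2),
             region = region_of(g$x_deg, g$y_deg),
             row.names = NULL)
}

#' Extended sampling grid including a peripapillary ring
#'
#' The central 68-point grid plus a ring of locations around the optic disc
#' (15 degrees nasal), used by the recovery-gradient analysis: the centrifugal
#' pattern ends at the disc, which the central grid cannot see.
#'
#' @param n_ring Number of ring locations around the disc.
#' @param ring_radius_deg Radius of the ring (deg) about the disc center.
#' @return data.frame with the same columns as [build_grid()].
#' @export
build_extended_grid <- function(n_ring = 16, ring_radius_deg = 2.5) {
  g <- build_grid()
  ang <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
  ring <- data.frame(x_deg = -15 + ring_radius_deg * cos(ang),
                     y_deg = 1.5 + ring_radius_deg * sin(ang))
  ext <- data.frame(location_id = max(g$location_id) + seq_len(n_ring),
                    x_deg = ring$x_deg, y_deg = ring$y_deg,
                    eccentricity_deg = sqrt(ring$x_deg^2 + ring$y_deg^2),
                    region = region_of(ring$x_deg, ring$y_deg))
  rbind(g, ext)
}

#' Run a 4-2 staircase threshold estimate
#'
#' Adaptive threshold strategy: the stimulus level moves in 4 dB steps until
#' the first response reversal, then in 2 dB steps until the second reversal;
#' the threshold is the last-seen level. Higher dB means stronger attenuation
#' (dimmer stimulus); a stimulus is seen with probability
#' `fp + (1 - fp - fn) * pnorm((true_db - level) / psycho_slope_db)`.
#' If the brightest stimulus (0 dB) is never seen the location is an absolute
#' scotoma: flagged, threshold 0.
#'
#' @param true_db True threshold (dB).
#' @param psycho_slope_db Psychometric slope (dB); 0 gives a deterministic
#'   observer that sees iff `level <= true_db`.
#' @param fp_rate,fn_rate False-positive / false-negative rates.
#' @param start_db Starting level (dB), within the dynamic range.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return list with `threshold_db` and logical `absolute`.
#' @export
run_staircase <- function(true_db, psycho_slope_db = 1.5,
                          fp_rate = 0.02, fn_rate = 0.02,
                          start_db = 25, seed = NULL) {
  if (fp_rate < 0 || fp_rate > 1 || fn_rate < 0 || fn_rate > 1)
    stop("invalid response rates: fp_rate/fn_rate must be in [0, 1]",
         call. = FALSE)
  if (start_db < DB_RANGE[1] || start_db > DB_RANGE[2])
    stop("start_db outside the dynamic range", call. = FALSE)
  run <- function() .staircase_core(true_db, psycho_slope_db, fp_rate,
                                    fn_rate, start_db)
  if (is.null(seed)) run() else withr::with_seed(substream_seed(seed, 3L), run())
}

.staircase_core <- function(true_db, slope, fp, fn, start_db) {
  sees <- function(level) {
    p <- if (slope <= 0) as.numeric(true_db >= level)
         else stats::pnorm((true_db - level) / slope)
    stats::runif(1) < fp + (1 - fp - fn) * p
  }
  level <- start_db
  last_seen <- NA_real_
  step <- 4
  reversals <- 0L
  prev_resp <- NA
  for (trial in 1:60) {
    resp <- sees(level)
    if (resp) last_seen <- level
    if (!is.na(prev_resp) && resp != prev_resp) {
      reversals <- reversals + 1L
      if (reversals == 1L) step <- 2
      if (reversals == 2L) break
    }
    prev_resp <- resp
    # seen -> dimmer (higher dB); not seen -> brighter (lower dB)
    level <- level + if (resp) step else -step
    if (level > DB_RANGE[2]) level <- DB_RANGE[2]
    if (level < DB_RANGE[1]) level <- DB_RANGE[1]
  }
  if (is.na(last_seen))
    return(list(threshold_db = 0, absolute = TRUE))
  list(threshold_db = last_seen, absolute = FALSE)
}

#' Examine one eye with microperimetry
#'
#' Runs one 4-2 staircase per grid location against the ground-truth
#' sensitivity of the eye at the given visit day.
#'
#' @param field A [sensitivity_field()].
#' @param grid Stimulus grid from [build_grid()] (or [build_extended_grid()]).
#' @param visit_day Days since baseline.
#' @param config A [cohort_config()] supplying the observer parameters.
#' @param seed Integer seed.
#' @return A `threshold_exam`: list with `eye_ref`, `visit_day` and a
#'   `thresholds` data.frame (grid columns plus `true_db`, `threshold_db`,
#'   `absolute`).
#' @export
examine_eye <- function(field, grid = build_grid(), visit_day = 0,
                        config = cohort_config(), seed = 1L) {
  stopifnot(inherits(field, "sensitivity_field"))
  true_db <- true_sensitivity(field, grid$x_deg, grid$y_deg, visit_day)
  withr::with_seed(substream_seed(seed, 4L), {
    res <- lapply(true_db, function(s)
      .staircase_core(s, config$psycho_slope_db, config$fp_rate,
                      config$fn_rate, config$staircase_start_db))
    thresholds <- cbind(grid,
                        true_db = true_db,
                        threshold_db = vapply(res, `[[`, numeric(1), "threshold_db"),
                        absolute = vapply(res, `[[`, logical(1), "absolute"))
    structure(list(eye_ref = field$eye_ref, visit_day = visit_day,
                   thresholds = thresholds),
              class = "threshold_exam")
  })
}

#' @export
print.threshold_exam <- function(x, ...) {
  cat(sprintf("<threshold_exam> eye %s, day %g: %d locations, mean RTS %.1f dB, %d absolute\n",
              x$eye_ref, x$visit_day, nrow(x$thresholds),
              mean(x$thresholds$threshold_db), sum(x$thresholds$absolute)))
  invisible(x)
}

#' Average retinal threshold sensitivity of an exam
#'
#' Arithmetic mean over all tested locations; absolute scotomata enter as
#' 0 dB.
#'
#' @param exam A `threshold_exam` from [examine_eye()].
#' @return Mean sensitivity (dB).
#' @export
average_rts <- function(exam) {
  stopifnot(inherits(exam, "threshold_exam"))
  if (nrow(exam$thresholds) == 0) stop("empty exam", call. = FALSE)
  mean(exam$thresholds$threshold_db)
}

#' Foveal retinal threshold sensitivity
#'
#' Mean of the thresholds at the four innermost grid locations
#' `(+/-0.5, +/-0.5)`.
#'
#' @param exam A `threshold_exam`.
#' @return Foveal sensitivity (dB).
#' @export
foveal_rts <- function(exam) {
  stopifnot(inherits(exam, "threshold_exam"))
  th <- exam$thresholds
  ctr <- th[abs(th$x_deg) == 0.5 & abs(th$y_deg) == 0.5, ]
  if (nrow(ctr) != 4)
    stop("the four central (+/-0.5, +/-0.5) locations are not all present",
         call. = FALSE)
  mean(ctr$threshold_db)
}

#' Bivariate contour ellipse area of a fixation cloud
#'
#' `BCEA_P = -2 ln(1 - P) * pi * sd_x * sd_y * sqrt(1 - rho^2)` with sample
#' standard deviations and correlation of the fixation points — the area of
#' the ellipse expected to contain a fraction `P` of fixation samples under a
#' bivariate normal model.
#'
#' @param cloud A `fixation_cloud` (data.frame with `x_deg`, `y_deg`), or any
#'   two-column matrix/data.frame of points.
#' @param coverage Fraction `P` in (0, 1); conventionally 0.63 or 0.95.
#' @return Area in deg^2 (0 for a degenerate cloud).
#' @export
bcea <- function(cloud, coverage = 0.63) {
  pts <- .cloud_points(cloud)
  if (nrow(pts) < 10) stop("fixation cloud must have >= 10 points", call. = FALSE)
  if (coverage <= 0 || coverage >= 1)
    stop("coverage must be in (0, 1)", call. = FALSE)
  sx <- stats::sd(pts[, 1])
  sy <- stats::sd(pts[, 2])
  if (sx == 0 || sy == 0) return(0)
  rho <- stats::cor(pts[, 1], pts[, 2])
  -2 * log(1 - coverage) * pi * sx * sy * sqrt(1 - rho^2)
}

.cloud_points <- function(cloud) {
  if (is.data.frame(cloud) && all(c("x_deg", "y_deg") %in% names(cloud)))
    return(cbind(cloud$x_deg, cloud$y_deg))
  m <- as.matrix(cloud)
  stopifnot(ncol(m) == 2)
  m
}

#' Fixation stability metrics and classification
#'
#' Computes the fractions of fixation points within 2-degree- and
#' 4-degree-diameter circles about the cloud barycenter (P1, P2) and both
#' BCEAs, and classifies fixation: stable if P1 > 0.75, relatively unstable
#' if P1 <= 0.75 but P2 > 0.75, unstable otherwise.
#'
#' @param cloud A `fixation_cloud`.
#' @return list with `bcea63`, `bcea95`, `p1`, `p2`, `category`.
#' @export
classify_fixation <- function(cloud) {
  pts <- .cloud_points(cloud)
  if (nrow(pts) < 10) stop("fixation cloud must have >= 10 points", call. = FALSE)
  ctr <- colMeans(pts)
  r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  p1 <- mean(r <= 1)  # 2 deg diameter
  p2 <- mean(r <= 2)  # 4 deg diameter
  category <- if (p1 > 0.75) "stable"
              else if (p2 > 0.75) "relatively unstable"
              else "unstable"
  list(bcea63 = bcea(cloud, 0.63), bcea95 = bcea(cloud, 0.95),
       p1 = p1, p2 = p2, category = category)
}

#' Write / read a threshold exam as CSV
#'
#' @param exam A `threshold_exam`.
#' @param path CSV path.
#' @return `write_exam()` the path, invisibly; `read_exam()` the exam.
#' @export
write_exam <- function(exam, path) {
  df <- cbind(eye_ref = exam$eye_ref, visit_day = exam$visit_day,
              exam$thresholds)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exam
#' @export
read_exam <- function(path) {
  df <- utils::read.csv(path)
  structure(list(eye_ref = df$eye_ref[1], visit_day = df$visit_day[1],
                 thresholds = df[, setdiff(names(df), c("eye_ref", "visit_day"))]),
            class = "threshold_exam")
}
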