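#' Fit a 2-D affine transform from point correspondences
#'
#' Least-squares affine `y = L x + t` minimizing the mean squared residual
#' over corresponding point pairs; exact (to numerical precision) when the
#' pairs are exactly affine-related. Stands in for intensity-based
#' registration of the microperimetry fundus frame onto the OCT en-face
#' frame, using known landmark correspondences.
#'
#' @param src Two-column matrix/data.frame of source points (deg).
#' @param dst Matching destination points.
#' @return An `affine2d`: list with 2x2 `linear` and length-2 `translation`.
#' @export
fit_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst)) stop("src and dst lengths differ", call. = FALSE)
  if (nrow(src) < 3)
    stop("degenerate configuration: need >= 3 correspondence pairs",
         call. = FALSE)
  X <- cbind(src, 1)
  if (qr(X)$rank < 3)
    stop("degenerate configuration: correspondence points are collinear",
         call. = FALSE)
  beta <- qr.solve(X, dst)  # 3 x 2: rows (a, b, t)
  L <- t(beta[1:2, , drop = FALSE])
  tr <- as.numeric(beta[3, ])
  if (abs(det(L)) <= 1e-8)
    stop("degenerate configuration: singular linear part", call. = FALSE)
  structure(list(linear = L, translation = tr), class = "affine2d")
}

#' Apply (or invert) a 2-D affine transform
#'
#' @param transform An `affine2d`.
#' @param points Two-column matrix/data.frame of points.
#' @return Matrix of transformed points.
#' @export
apply_affine <- function(transform, points) {
  stopifnot(inherits(transform, "affine2d"))
  p <- as.matrix(points)
  out <- p %*% t(transform$linear)
  out[, 1] <- out[, 1] + transform$translation[1]
  out[, 2] <- out[, 2] + transform$translation[2]
  out
}

#' @rdname apply_affine
#' @export
invert_affine <- function(transform) {
  Li <- solve(transform$linear)
  structure(list(linear = Li,
                 translation = as.numeric(-Li %*% transform$translation)),
            class = "affine2d")
}

#' Identity affine transform
#' @return An `affine2d`.
#' @export
identity_affine <- function() {
  structure(list(linear = diag(2), translation = c(0, 0)), class = "affine2d")
}

#' Join microperimetry exams with PRR maps into a structure-function table
#'
#' Transforms each stimulus location into the OCT en-face frame through the
#' fitted affine, samples the PRR map there, and emits one row per (eye,
#' visit, location) with the threshold, its linear-scale sensitivity
#' `10^(dB/10)`, eccentricity and the sampled PRR. Stimuli falling outside
#' the scanned footprint (or on missing map cells) are dropped and counted.
#'
#' @param exams List of `threshold_exam` objects.
#' @param maps List of `prr_map` objects, parallel to `exams` (or a named
#'   list keyed `"<eye_ref>@<visit_day>"`).
#' @param transform An `affine2d` mapping MP coordinates into the OCT frame.
#' @param patient_ids Optional character vector of patient ids parallel to
#'   `exams`; defaults to the eye refs.
#' @return data.frame with columns `patient_id`, `eye_id`, `visit_day`,
#'   `location_id`, `x_deg`, `y_deg`, `eccentricity_deg`, `region`, `rts_db`,
#'   `sens_linear`, `prr`; attribute `dropped` holds the per-exam dropped
#'   counts.
#' @export
build_structure_function_table <- function(exams, maps,
                                           transform = identity_affine(),
                                           patient_ids = NULL) {
  stopifnot(length(exams) > 0)
  keyed <- !is.null(names(maps)) && all(nzchar(names(maps)))
  rows <- vector("list", length(exams))
  dropped <- integer(length(exams))
  for (i in seq_along(exams)) {
    ex <- exams[[i]]
    key <- sprintf("%s@%g", ex$eye_ref, ex$visit_day)
    map <- if (keyed) {
      if (!key %in% names(maps))
        stop(sprintf("join error: no PRR map for key '%s'", key), call. = FALSE)
      maps[[key]]
    } else {
      if (i > length(maps))
        stop(sprintf("join error: no PRR map for exam %d (%s)", i, key),
             call. = FALSE)
      maps[[i]]
    }
    th <- ex$thresholds
    oct_xy <- apply_affine(transform, cbind(th$x_deg, th$y_deg))
    prr <- sample_prr(map, oct_xy[, 1], oct_xy[, 2])
    keep <- !is.na(prr)
    dropped[i] <- sum(!keep)
    pid <- if (is.null(patient_ids)) ex$eye_ref else patient_ids[i]
    rows[[i]] <- data.frame(
      patient_id = pid,
      eye_id = ex$eye_ref,
      visit_day = ex$visit_day,
      location_id = th$location_id[keep],
      x_deg = th$x_deg[keep],
      y_deg = th$y_deg[keep],
      eccentricity_deg = th$eccentricity_deg[keep],
      region = th$region[keep],
      rts_db = th$threshold_db[keep],
      sens_linear = db_to_linear(th$threshold_db[keep]),
      prr = prr[keep],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
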