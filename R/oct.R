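#' OCT cube scan geometry
#'
#' Geometry of the raster volume: 19 B-scans spaced 258 microns apart by
#' default, with the en-face frame centered on the fovea. The conversion
#' between microns and degrees uses [UM_PER_DEG].
#'
#' @param n_bscans Number of B-scans (slow axis, vertical).
#' @param bscan_spacing_um B-scan spacing (microns).
#' @param n_ascans A-scans per B-scan (fast axis, horizontal).
#' @param ascan_pitch_um A-scan pitch (microns).
#' @param depth_px Axial image depth (pixels), >= 64.
#' @param axial_pitch_um Axial pixel pitch (microns).
#' @param rpe_depth_px Nominal axial position (1-based pixel row) of the RPE.
#' @param rpe_tilt_px_per_ascan Linear tilt of the RPE plane along the A-scan
#'   axis (pixels per A-scan), for phantoms with a non-flat RPE.
#' @return A `scan_geometry` list with derived `x_deg` / `y_deg` axis
#'   coordinates.
#' @export
scan_geometry <- function(n_bscans = 19, bscan_spacing_um = 258,
                          n_ascans = 128, ascan_pitch_um = 30,
                          depth_px = 160, axial_pitch_um = 3.9,
                          rpe_depth_px = 120, rpe_tilt_px_per_ascan = 0) {
  if (depth_px < 64) stop("depth_px must be >= 64", call. = FALSE)
  if (rpe_depth_px + 20 > depth_px)
    stop("geometry error: RPE depth + 20 exceeds image depth", call. = FALSE)
  y <- (seq_len(n_bscans) - (n_bscans + 1) / 2) * bscan_spacing_um / UM_PER_DEG
  x <- (seq_len(n_ascans) - (n_ascans + 1) / 2) * ascan_pitch_um / UM_PER_DEG
  structure(list(n_bscans = n_bscans, bscan_spacing_um = bscan_spacing_um,
                 n_ascans = n_ascans, ascan_pitch_um = ascan_pitch_um,
                 depth_px = depth_px, axial_pitch_um = axial_pitch_um,
                 rpe_depth_px = rpe_depth_px,
                 rpe_tilt_px_per_ascan = rpe_tilt_px_per_ascan,
                 x_deg = x, y_deg = y),
            class = "scan_geometry")
}

#' Construct an OCT volume container
#'
#' @param intensity 3-D array `[bscan, ascan, depth]` of nonnegative
#'   intensities.
#' @param geometry A [scan_geometry()] matching the array dimensions.
#' @return An `oct_volume` object.
#' @export
oct_volume <- function(intensity, geometry) {
  stopifnot(length(dim(intensity)) == 3)
  d <- dim(intensity)
  if (d[1] != geometry$n_bscans || d[2] != geometry$n_ascans ||
      d[3] != geometry$depth_px)
    stop("intensity dimensions do not match geometry", call. = FALSE)
  if (d[3] < 64) stop("axial depth must be >= 64 pixels", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  structure(list(intensity = intensity, geometry = geometry),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<oct_volume> %d B-scans x %d A-scans x %d depth px (B-scan spacing %g um)\n",
              d[1], d[2], d[3], x$geometry$bscan_spacing_um))
  invisible(x)
}

# intensity levels of the layered phantom, in units of the vitreous
# (reference) level; the RPE is a peaked 5-row profile so its smoothed
# maximum is unique and centered
.PHANTOM <- list(reference = 100, inner_retina = 1.5, gap = 3, below_rpe = 3,
                 rpe_profile = c(40, 90, 150, 90, 40))

#' Render a layered OCT phantom volume from a sensitivity field
#'
#' Builds a raster volume with a bright RPE band at the geometry's RPE depth,
#' a vitreous reference band, and a photoreceptor outer-segment band spanning
#' 20 to 6 pixels above the RPE whose mean intensity encodes the forward
#' structure-function model:
#' `reference * (sf_intercept + sf_slope * 10^(S/10) + eye_effect + eps)`,
#' where `S` is the true sensitivity at the A-scan's retinal position and
#' `eps ~ N(0, sf_resid_sd)` is local noise. Recomputing the PRR from the
#' rendered volume therefore inverts the forward model.
#'
#' @param field A [sensitivity_field()].
#' @param t_days Days since baseline.
#' @param geometry A [scan_geometry()].
#' @param config A [cohort_config()] supplying the forward-model parameters.
#' @param seed Integer seed.
#' @param eye_effect Per-eye PRR random intercept (PRR units) added to the
#'   band level; draw it once per eye for visit-to-visit consistency.
#' @param resid_sd Local band noise SD; defaults to `config$sf_resid_sd`.
#' @param speckle_cv Coefficient of variation of multiplicative speckle
#'   applied to every voxel (0 disables speckle).
#' @return An [oct_volume()].
#' @export
render_oct_volume <- function(field, t_days = 0, geometry = scan_geometry(),
                              config = cohort_config(), seed = 1L,
                              eye_effect = 0, resid_sd = config$sf_resid_sd,
                              speckle_cv = 0) {
  stopifnot(inherits(field, "sensitivity_field"),
            inherits(geometry, "scan_geometry"))
  nb <- geometry$n_bscans; na <- geometry$n_ascans; nd <- geometry$depth_px
  withr::with_seed(substream_seed(seed, 5L), {
    vol <- array(.PHANTOM$reference * 0.0, dim = c(nb, na, nd))
    ref <- .PHANTOM$reference
    for (b in seq_len(nb)) {
      S <- true_sensitivity(field, geometry$x_deg,
                            rep(geometry$y_deg[b], na), t_days)
      band_level <- ref * (config$sf_intercept +
                             config$sf_slope * 10^(S / 10) +
                             eye_effect +
                             stats::rnorm(na, 0, resid_sd))
      band_level <- pmax(band_level, 0)
      for (a in seq_len(na)) {
        rpe <- round(geometry$rpe_depth_px + geometry$rpe_tilt_px_per_ascan * (a - 1))
        rpe <- min(max(rpe, 41L), nd - 3L)
        prof <- rep(ref, nd)                        # vitreous / background
        prof[(rpe - 40):(rpe - 21)] <- ref * .PHANTOM$inner_retina
        prof[(rpe - 20):(rpe - 7)] <- band_level[a] # outer-segment band
        prof[(rpe - 6):(rpe - 3)] <- ref * .PHANTOM$gap
        prof[(rpe - 2):(rpe + 2)] <- ref * .PHANTOM$rpe_profile
        if (rpe + 3 <= nd) prof[(rpe + 3):nd] <- ref * .PHANTOM$below_rpe
        vol[b, a, ] <- prof
      }
    }
    if (speckle_cv > 0) {
      sl <- sqrt(log(1 + speckle_cv^2))
      vol <- vol * exp(stats::rnorm(length(vol), -sl^2 / 2, sl))
    }
    oct_volume(vol, geometry)
  })
}

#' Write / read an OCT volume as multipage TIFF
#'
#' One 16-bit page per B-scan (rows = depth, columns = A-scans); the
#' intensity scale is stored in a YAML sidecar together with the geometry so
#' the volume round-trips exactly up to 16-bit quantization.
#'
#' @param volume An [oct_volume()].
#' @param path TIFF path; the sidecar is written to `<path>.yaml`.
#' @return `write_oct_tiff()` the path, invisibly; `read_oct_tiff()` an
#'   [oct_volume()].
#' @export
write_oct_tiff <- function(volume, path) {
  scale <- max(volume$intensity, 1e-12)
  pages <- lapply(seq_len(volume$geometry$n_bscans), function(b)
    t(volume$intensity[b, , ]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  geo <- volume$geometry
  yaml::write_yaml(c(geo[setdiff(names(geo), c("x_deg", "y_deg"))],
                     list(intensity_scale = scale)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_oct_tiff
#' @export
read_oct_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  scale <- side$intensity_scale
  geo <- do.call(scan_geometry, side[setdiff(names(side), "intensity_scale")])
  vol <- array(0, dim = c(geo$n_bscans, geo$n_ascans, geo$depth_px))
  for (b in seq_along(pages)) vol[b, , ] <- t(pages[[b]]) * scale
  oct_volume(vol, geo)
}
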