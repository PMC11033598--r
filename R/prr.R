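#' Detect the RPE surface in an OCT volume
#'
#' Per A-scan, the RPE depth is taken as the maximum of the axially smoothed
#' intensity profile (the RPE is the brightest band of the layered retina),
#' then regularized by a transverse running-median filter across A-scans.
#' A-scans whose peak does not stand out from the rest of the profile
#' (prominence below `min_prominence`) or whose peak sits too close to the
#' image top for the reflectivity band are flagged invalid.
#'
#' @param volume An [oct_volume()].
#' @param min_prominence Minimal relative prominence
#'   `(peak - median) / peak` of the smoothed peak for a valid A-scan.
#' @param median_window Transverse running-median window (A-scans, odd).
#' @return An `rpe_surface`: list with integer matrix `depth_index`
#'   `[bscan, ascan]` (1-based axial pixel) and logical matrix `valid`.
#' @export
detect_rpe <- function(volume, min_prominence = 0.5, median_window = 15) {
  stopifnot(inherits(volume, "oct_volume"))
  if (all(volume$intensity == 0))
    stop("no signal: volume is identically zero", call. = FALSE)
  nb <- volume$geometry$n_bscans
  na <- volume$geometry$n_ascans
  depth <- matrix(NA_integer_, nb, na)
  valid <- matrix(TRUE, nb, na)
  kern <- rep(1 / 5, 5)
  for (b in seq_len(nb)) {
    for (a in seq_len(na)) {
      prof <- volume$intensity[b, a, ]
      sm <- stats::filter(prof, kern, sides = 2)
      sm[is.na(sm)] <- 0
      pk <- which.max(sm)
      prom <- (sm[pk] - stats::median(sm)) / max(sm[pk], 1e-12)
      depth[b, a] <- pk
      if (prom < min_prominence) valid[b, a] <- FALSE
    }
    med <- as.integer(round(stats::runmed(depth[b, ], k = min(median_window,
                                                              .odd_below(na)))))
    depth[b, ] <- med
  }
  valid[depth <= 20] <- FALSE
  structure(list(depth_index = depth, valid = valid), class = "rpe_surface")
}

.odd_below <- function(n) if (n %% 2 == 1) n else n - 1L

#' Photoreceptor reflectivity ratio of one A-scan
#'
#' Mean back-reflected intensity of the outer-segment band spanning 20 to 6
#' pixels above the RPE (half-open: 14 pixels at offsets -20..-7 from the RPE
#' row), divided by the mean intensity of a reference band. The default
#' reference is a 30-pixel vitreous band ending 60 pixels above the RPE
#' (clamped to the image top), which normalizes away media opacities and
#' other global intensity factors.
#'
#' @param ascan_profile Numeric axial intensity vector.
#' @param rpe_index 1-based axial index of the RPE row.
#' @param band Length-2 `(upper_px, lower_px)` offsets above the RPE.
#' @param reference List with `offset` (pixels above the RPE at which the
#'   reference band ends) and `width` (band height in pixels).
#' @return Positive PRR value.
#' @export
prr_ascan <- function(ascan_profile, rpe_index, band = c(20, 6),
                      reference = list(offset = 60, width = 30)) {
  if (rpe_index <= band[1])
    stop("band out of range: rpe_index must exceed the upper band offset",
         call. = FALSE)
  rows_band <- (rpe_index - band[1]):(rpe_index - band[2] - 1)
  top <- max(1, rpe_index - reference$offset - reference$width + 1)
  rows_ref <- top:(top + reference$width - 1)
  rows_ref <- rows_ref[rows_ref >= 1 & rows_ref <= length(ascan_profile)]
  ref_mean <- mean(ascan_profile[rows_ref])
  if (!is.finite(ref_mean) || ref_mean == 0)
    stop("zero reference: reference band mean is 0", call. = FALSE)
  mean(ascan_profile[rows_band]) / ref_mean
}

#' Build an en-face PRR map from a volume
#'
#' Applies [prr_ascan()] at every valid A-scan of the detected RPE surface;
#' invalid A-scans become missing map cells.
#'
#' @param volume An [oct_volume()].
#' @param rpe An `rpe_surface` from [detect_rpe()].
#' @param band,reference Passed to [prr_ascan()].
#' @return A `prr_map`: list with matrix `prr` `[bscan, ascan]` (NA where
#'   missing) and the en-face axis coordinates `x_deg`, `y_deg`.
#' @export
build_prr_map <- function(volume, rpe, band = c(20, 6),
                          reference = list(offset = 60, width = 30)) {
  stopifnot(inherits(volume, "oct_volume"), inherits(rpe, "rpe_surface"))
  nb <- volume$geometry$n_bscans
  na <- volume$geometry$n_ascans
  if (!all(dim(rpe$depth_index) == c(nb, na)))
    stop("shape mismatch between volume and RPE surface", call. = FALSE)
  prr <- matrix(NA_real_, nb, na)
  for (b in seq_len(nb)) for (a in seq_len(na)) {
    if (!rpe$valid[b, a]) next
    prr[b, a] <- prr_ascan(volume$intensity[b, a, ], rpe$depth_index[b, a],
                           band = band, reference = reference)
  }
  structure(list(prr = prr, x_deg = volume$geometry$x_deg,
                 y_deg = volume$geometry$y_deg),
            class = "prr_map")
}

#' @export
print.prr_map <- function(x, ...) {
  cat(sprintf("<prr_map> %d x %d cells, %d missing, mean PRR %.2f\n",
              nrow(x$prr), ncol(x$prr), sum(is.na(x$prr)),
              mean(x$prr, na.rm = TRUE)))
  invisible(x)
}

#' Sample a PRR map at retinal coordinates
#'
#' Bilinear interpolation in the en-face plane across the (coarse) B-scan
#' axis and the A-scan axis. Queries outside the scanned footprint return
#' `NA`; a query whose four surrounding grid cells are all missing returns
#' `NA`; partially missing neighborhoods use the weight-renormalized mean of
#' the available cells.
#'
#' @param map A `prr_map`.
#' @param x_deg,y_deg Query coordinates (vectorized, recycled).
#' @return Numeric vector of interpolated PRR values (NA where missing).
#' @export
sample_prr <- function(map, x_deg, y_deg) {
  stopifnot(inherits(map, "prr_map"))
  n <- max(length(x_deg), length(y_deg))
  x <- rep_len(x_deg, n); y <- rep_len(y_deg, n)
  xs <- map$x_deg; ys <- map$y_deg
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i]) || is.na(y[i])) next
    if (x[i] < xs[1] || x[i] > xs[length(xs)] ||
        y[i] < ys[1] || y[i] > ys[length(ys)]) next
    ix <- findInterval(x[i], xs, rightmost.closed = TRUE)
    iy <- findInterval(y[i], ys, rightmost.closed = TRUE)
    ix <- min(ix, length(xs) - 1); iy <- min(iy, length(ys) - 1)
    fx <- (x[i] - xs[ix]) / (xs[ix + 1] - xs[ix])
    fy <- (y[i] - ys[iy]) / (ys[iy + 1] - ys[iy])
    vals <- c(map$prr[iy, ix], map$prr[iy, ix + 1],
              map$prr[iy + 1, ix], map$prr[iy + 1, ix + 1])
    w <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
    keep <- !is.na(vals)
    if (!any(keep) || sum(w[keep]) == 0) next
    out[i] <- sum(vals[keep] * w[keep]) / sum(w[keep])
  }
  out
}

#' Render a PRR map as an image
#'
#' Blue-to-yellow colormap: darker blue marks lower PRR (disrupted outer
#' segments), bright yellow marks higher PRR.
#'
#' @param map A `prr_map`.
#' @param ... Passed to [graphics::image()].
#' @return The map, invisibly.
#' @export
plot_prr_map <- function(map, ...) {
  pal <- grDevices::colorRampPalette(
    c("#08306B", "#2171B5", "#6BAED6", "#C6DBEF", "#FFF7BC", "#FEC44F"))(64)
  graphics::image(map$x_deg, map$y_deg, t(map$prr), col = pal,
                  xlab = "x (deg)", ylab = "y (deg)", useRaster = TRUE, ...)
  invisible(map)
}

#' Write a PRR map as CSV
#'
#' Long format: one row per (bscan, ascan) cell with en-face coordinates.
#'
#' @param map A `prr_map`.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_prr_map <- function(map, path) {
  df <- expand.grid(bscan = seq_along(map$y_deg), ascan = seq_along(map$x_deg))
  df$x_deg <- map$x_deg[df$ascan]
  df$y_deg <- map$y_deg[df$bscan]
  df$prr <- map$prr[cbind(df$bscan, df$ascan)]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
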