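test_that("RPE detection finds a constant plane exactly and flags no-signal", {
  ph <- make_phantom(rpe_at = 300)
  rpe <- detect_rpe(ph)
  expect_true(all(rpe$depth_index == 300))
  expect_true(all(rpe$valid))
  geo <- scan_geometry(n_bscans = 2, n_ascans = 5, depth_px = 80,
                       rpe_depth_px = 50)
  expect_error(detect_rpe(oct_volume(array(0, c(2, 5, 80)), geo)),
               "no signal")
})

test_that("a tilted RPE plane is recovered within one pixel", {
  ph <- make_phantom(n_ascans = 60, rpe_at = 290, tilt = 0.02)
  rpe <- detect_rpe(ph)
  truth <- outer(rep(1, 3), 290 + 0.02 * (seq_len(60) - 1))
  expect_lte(max(abs(rpe$depth_index - truth)), 1)
})

test_that("PRR of an A-scan follows the band/reference ratio contract", {
  # uniform profile: ratio identity
  expect_equal(prr_ascan(rep(7, 400), 300), 1.0)
  # band set to 6.58 x the reference level
  prof <- rep(100, 400)
  prof[280:293] <- 658
  expect_equal(prr_ascan(prof, 300), 6.58)
  # linearity in the numerator
  prof2 <- prof
  prof2[280:293] <- 329
  expect_equal(prr_ascan(prof2, 300), 3.29)
  expect_error(prr_ascan(rep(1, 400), 15), "band out of range")
  expect_error(prr_ascan(rep(0, 400), 300), "zero reference")
})

test_that("the map equals the programmed ratio field on a noiseless phantom", {
  cfg <- cohort_config()
  f <- cached_cohort(11)$fields[[1]]
  geo <- scan_geometry()
  vol <- render_oct_volume(f, 0, geo, cfg, seed = 2, eye_effect = 0,
                          resid_sd = 0)
  map <- build_prr_map(vol, detect_rpe(vol))
  truth <- outer(geo$y_deg, geo$x_deg, function(y, x) {
    s <- true_sensitivity(f, as.vector(x), as.vector(y), 0)
    cfg$sf_intercept + cfg$sf_slope * 10^(s / 10)
  })
  expect_lt(max(abs(map$prr - truth) / truth), 1e-6)
})

test_that("PRR is invariant to global intensity rescaling", {
  cfg <- cohort_config()
  f <- cached_cohort(11)$fields[[2]]
  vol <- render_oct_volume(f, 0, scan_geometry(), cfg, seed = 3,
                          resid_sd = 0.2, speckle_cv = 0.1)
  m1 <- build_prr_map(vol, detect_rpe(vol))
  vol2 <- oct_volume(vol$intensity * 3.7, vol$geometry)
  m2 <- build_prr_map(vol2, detect_rpe(vol2))
  expect_equal(m1$prr, m2$prr, tolerance = 1e-12)
})

test_that("speckle of 20% CV perturbs the uniform map mean by under 2%", {
  cfg <- cohort_config()
  f <- sensitivity_field("e", healthy_fovea_db = 20,
                         healthy_slope_db_per_deg = 0)
  vol <- render_oct_volume(f, 0, scan_geometry(), cfg, seed = 4,
                          resid_sd = 0, speckle_cv = 0.2)
  map <- build_prr_map(vol, detect_rpe(vol))
  truth <- cfg$sf_intercept + cfg$sf_slope * 10^2
  expect_equal(mean(map$prr, na.rm = TRUE), truth, tolerance = 0.02)
})

test_that("invalid A-scans propagate to missing map cells only", {
  ph <- make_phantom(n_bscans = 4, n_ascans = 30, band_mult = 5)
  rpe <- detect_rpe(ph)
  drop <- matrix(FALSE, 4, 30)
  drop[cbind(c(1, 2, 3, 4), c(3, 7, 20, 30))] <- TRUE
  rpe$valid[drop] <- FALSE
  map <- build_prr_map(ph, rpe)
  expect_identical(is.na(map$prr), drop)
  expect_equal(unique(stats::na.omit(as.vector(map$prr))),
               5 / 1, tolerance = 1e-12)
})

test_that("map sampling interpolates, respects the footprint, and keeps constants", {
  ph <- make_phantom(n_bscans = 5, n_ascans = 40, band_mult = 4)
  map <- build_prr_map(ph, detect_rpe(ph))
  # node identity
  expect_equal(sample_prr(map, map$x_deg[10], map$y_deg[2]), 4)
  # constant map: any interior query returns the constant
  expect_equal(sample_prr(map, 0.123, 0.2), 4)
  # outside the footprint
  expect_true(is.na(sample_prr(map, 99, 0)))
  expect_true(is.na(sample_prr(map, 0, 99)))
  # all-missing neighborhood
  map$prr[, ] <- NA
  expect_true(is.na(sample_prr(map, 0.1, 0.1)))
})

test_that("volumes round-trip through multipage TIFF", {
  cfg <- cohort_config()
  f <- cached_cohort(11)$fields[[1]]
  geo <- scan_geometry(n_bscans = 3, n_ascans = 16, depth_px = 160)
  vol <- render_oct_volume(f, 0, geo, cfg, seed = 5, resid_sd = 0)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_oct_tiff(vol, path)
  vol2 <- read_oct_tiff(path)
  expect_equal(dim(vol2$intensity), dim(vol$intensity))
  expect_lt(max(abs(vol2$intensity - vol$intensity)),
            2 / 65535 * max(vol$intensity))
  expect_equal(vol2$geometry$bscan_spacing_um, geo$bscan_spacing_um)
})

test_that("scan geometry rejects impossible band placement", {
  expect_error(scan_geometry(depth_px = 100, rpe_depth_px = 90), "geometry")
  expect_error(scan_geometry(depth_px = 40), "depth_px")
})
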