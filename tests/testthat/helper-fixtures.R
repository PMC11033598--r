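# Shared fixtures: noiseless configs, tiny phantoms, and a memoised store of
# simulated cohorts reused across acceptance checks.

noiseless_config <- function(...) {
  cohort_config(sf_eye_sd = 0, sf_resid_sd = 0, psycho_slope_db = 0,
                fp_rate = 0, fn_rate = 0, bcva_noise_sd = 0,
                fixation_log_jitter_sd = 0, ...)
}

# minimal layered phantom built by hand (not via render_oct_volume): peaked
# RPE profile at a chosen depth, optional outer-segment band as a multiple of
# the background level
make_phantom <- function(n_bscans = 3, n_ascans = 20, depth = 400,
                         rpe_at = 300, band_mult = NULL, background = 100,
                         tilt = 0) {
  geo <- scan_geometry(n_bscans = n_bscans, n_ascans = n_ascans,
                       depth_px = depth, rpe_depth_px = rpe_at,
                       rpe_tilt_px_per_ascan = tilt)
  vol <- array(background, dim = c(n_bscans, n_ascans, depth))
  for (b in seq_len(n_bscans)) for (a in seq_len(n_ascans)) {
    rpe <- round(rpe_at + tilt * (a - 1))
    vol[b, a, (rpe - 2):(rpe + 2)] <-
      background * c(10, 25, 60, 25, 10)
    if (!is.null(band_mult))
      vol[b, a, (rpe - 20):(rpe - 7)] <- background * band_mult
  }
  oct_volume(vol, geo)
}

# cohort store: generate once per (seed), reuse across tests in the session
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(seed, config = cohort_config()) {
  key <- as.character(seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(config, seed)
  .cohort_cache[[key]]
}
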