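#' Examine a whole cohort over its visit schedule
#'
#' Runs one microperimetry exam per eye and visit against the eye's
#' ground-truth field and summarizes it (average and foveal RTS). Follow-up
#' visit days receive uniform jitter of +/- `config$visit_jitter_days` days
#' (baseline is never jittered); the jittered day is used both to evaluate
#' the field and as the model time covariate, mirroring a real visit window.
#'
#' @param cohort Output of [generate_cohort()].
#' @param config The [cohort_config()] used to generate it.
#' @param seed Integer seed.
#' @param grid Stimulus grid (default the 68-point grid).
#' @param visits Nominal visit days (default `config$visit_days`).
#' @param jitter Apply the visit-window jitter to follow-ups.
#' @param keep_exams Also return the exam objects.
#' @return data.frame with one row per (eye, visit): `patient_id`, `eye_id`,
#'   `granularity`, `bcva_logmar`, `onset_days`, `nominal_day`, `day`,
#'   `avg_rts`, `foveal_rts`, `n_absolute`. With `keep_exams = TRUE`, a list
#'   `list(summaries, exams)` where `exams` is keyed `"<eye_id>@<day>"`.
#' @export
examine_cohort <- function(cohort, config = cohort_config(), seed = 1L,
                           grid = build_grid(),
                           visits = config$visit_days, jitter = TRUE,
                           keep_exams = FALSE) {
  eyes <- cohort$eyes
  has_fovea <- sum(abs(grid$x_deg) == 0.5 & abs(grid$y_deg) == 0.5) == 4
  jit <- withr::with_seed(substream_seed(seed, 6L), {
    matrix(stats::runif(nrow(eyes) * length(visits),
                        -config$visit_jitter_days, config$visit_jitter_days),
           nrow(eyes))
  })
  rows <- list(); exams <- list()
  for (i in seq_len(nrow(eyes))) {
    eye <- eyes[i, ]
    fld <- cohort$fields[[eye$eye_id]]
    for (v in seq_along(visits)) {
      day <- visits[v]
      if (jitter && day > 0) day <- max(1, round(day + jit[i, v]))
      ex <- examine_eye(fld, grid, day, config,
                        seed = substream_seed(seed, 7L + i * 101L + v))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = eye$patient_id, eye_id = eye$eye_id,
        granularity = eye$granularity, bcva_logmar = eye$bcva_logmar,
        onset_days = eye$onset_days, nominal_day = visits[v], day = day,
        avg_rts = average_rts(ex),
        foveal_rts = if (has_fovea) foveal_rts(ex) else NA_real_,
        n_absolute = sum(ex$thresholds$absolute),
        stringsAsFactors = FALSE)
      if (keep_exams) exams[[sprintf("%s@%g", eye$eye_id, day)]] <- ex
    }
  }
  summaries <- do.call(rbind, rows)
  rownames(summaries) <- NULL
  if (keep_exams) list(summaries = summaries, exams = exams) else summaries
}

#' Baseline microperimetry and fixation summary of a cohort
#'
#' Convenience wrapper for the cross-sectional (baseline, day 0) analyses:
#' per-eye average and foveal RTS from a baseline exam, plus a fixation
#' cloud drawn at the true baseline foveal sensitivity and its BCEAs.
#'
#' @inheritParams examine_cohort
#' @param n_fixation_samples Fixation samples per eye.
#' @return data.frame with one row per eye: cohort covariates plus
#'   `avg_rts`, `foveal_rts`, `bcea63`, `bcea95`, `fixation_category`.
#' @export
baseline_summary <- function(cohort, config = cohort_config(), seed = 1L,
                             n_fixation_samples = 600) {
  eyes <- cohort$eyes
  grid <- build_grid()
  rows <- lapply(seq_len(nrow(eyes)), function(i) {
    eye <- eyes[i, ]
    ex <- examine_eye(cohort$fields[[eye$eye_id]], grid, 0, config,
                      seed = substream_seed(seed, 8L + i * 97L))
    cloud <- generate_fixation_cloud(eye, eye$foveal_true_db,
                                     n_samples = n_fixation_samples,
                                     seed = substream_seed(seed, 9L + i * 89L),
                                     config = config)
    fx <- classify_fixation(cloud)
    cbind(eye,
          data.frame(avg_rts = average_rts(ex), foveal_rts = foveal_rts(ex),
                     bcea63 = fx$bcea63, bcea95 = fx$bcea95,
                     fixation_category = fx$category,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Composes generate -> examine -> render/PRR-map -> register -> model into
#' one reproducible run: writes the cohort table, per-visit exams, PRR maps,
#' the joined structure-function table, fitted models and cohort summary
#' tables under `out_dir`, and returns (and writes) a run manifest.
#' Deterministic for fixed `(config, seed)`.
#'
#' @param config A [cohort_config()] or path to a YAML config file.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if absent).
#' @param write_tiff Also write the rendered OCT volumes as multipage TIFFs.
#' @param write_png Also render PRR map PNGs.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L,
                         out_dir = "results/run", write_tiff = FALSE,
                         write_png = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- read_config(config)
  }
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("exams", "fixation", "maps", "truth", "tables"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  warnings_log <- character()

  cohort <- stage("generate", generate_cohort(config, seed))
  utils::write.csv(cohort$eyes, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)

  grid <- build_grid()
  mp <- stage("examine", examine_cohort(cohort, config, seed,
                                        keep_exams = TRUE))
  for (key in names(mp$exams))
    write_exam(mp$exams[[key]],
               file.path(out_dir, "exams", paste0(gsub("@", "_d", key), ".csv")))
  utils::write.csv(mp$summaries, file.path(out_dir, "mp_summaries.csv"),
                   row.names = FALSE)

  base <- stage("baseline_summary", baseline_summary(cohort, config, seed))
  utils::write.csv(base, file.path(out_dir, "baseline_summary.csv"),
                   row.names = FALSE)
  for (i in seq_len(nrow(cohort$eyes))) {
    eye <- cohort$eyes[i, ]
    cloud <- generate_fixation_cloud(eye, eye$foveal_true_db, 600,
                                     seed = substream_seed(seed, 9L + i * 89L),
                                     config = config)
    utils::write.csv(cloud, file.path(out_dir, "fixation",
                                      paste0(eye$eye_id, ".csv")),
                     row.names = FALSE)
  }

  # OCT rendering + PRR maps at every visit, on the cropped footprint
  geometry <- stage("geometry", cropped_geometry())
  maps <- list()
  stage("prr_maps", {
    for (i in seq_len(nrow(cohort$eyes))) {
      eye <- cohort$eyes[i, ]
      fld <- cohort$fields[[eye$eye_id]]
      days <- unique(mp$summaries$day[mp$summaries$eye_id == eye$eye_id])
      for (day in days) {
        vol <- render_oct_volume(fld, day, geometry, config,
                                 seed = substream_seed(seed, 10L + i * 83L + day),
                                 eye_effect = eye$sf_eye_effect)
        rpe <- detect_rpe(vol)
        key <- sprintf("%s@%g", eye$eye_id, day)
        maps[[key]] <- build_prr_map(vol, rpe)
        write_prr_map(maps[[key]],
                      file.path(out_dir, "maps", paste0(gsub("@", "_d", key), ".csv")))
        if (write_tiff)
          write_oct_tiff(vol, file.path(out_dir, "maps",
                                        paste0(gsub("@", "_d", key), ".tiff")))
        if (write_png) {
          grDevices::png(file.path(out_dir, "maps",
                                   paste0(gsub("@", "_d", key), ".png")),
                         480, 480)
          plot_prr_map(maps[[key]], main = key)
          grDevices::dev.off()
        }
      }
    }
  })

  # ground truth at grid points for recovery checks
  for (i in seq_len(nrow(cohort$eyes))) {
    eye <- cohort$eyes[i, ]
    fld <- cohort$fields[[eye$eye_id]]
    tr <- do.call(rbind, lapply(config$visit_days, function(d)
      data.frame(eye_id = eye$eye_id, day = d, grid,
                 true_db = true_sensitivity(fld, grid$x_deg, grid$y_deg, d))))
    utils::write.csv(tr, file.path(out_dir, "truth",
                                   paste0(eye$eye_id, ".csv")),
                     row.names = FALSE)
  }

  # registration: affine fitted from landmark correspondences (identical
  # frames in the synthetic setting)
  landmarks <- cbind(c(-4, 4, 4, -4), c(-4, -4, 4, 4))
  transform <- stage("register", fit_affine(landmarks, landmarks))
  sf_tab <- stage("sf_table", {
    pids <- cohort$eyes$patient_id[match(
      vapply(mp$exams, `[[`, character(1), "eye_ref"), cohort$eyes$eye_id)]
    build_structure_function_table(mp$exams, maps, transform,
                                   patient_ids = pids)
  })
  utils::write.csv(sf_tab, file.path(out_dir, "sf.csv"), row.names = FALSE)
  dropped <- attr(sf_tab, "dropped")
  warnings_log <- c(warnings_log,
                    sprintf("stimuli outside the OCT footprint per exam: %s",
                            paste(unique(dropped), collapse = "/")))

  fits <- stage("models", {
    long <- mp$summaries
    names(long)[names(long) == "avg_rts"] <- "rts_db"
    names(long)[names(long) == "bcva_logmar"] <- "baseline_bcva"
    ext <- examine_cohort(cohort, config, seed = substream_seed(seed, 13L),
                          grid = build_extended_grid(), keep_exams = TRUE)
    loc_long <- do.call(rbind, lapply(ext$exams, function(ex)
      data.frame(eye_id = ex$eye_ref, day = ex$visit_day,
                 region = ex$thresholds$region,
                 rts_db = ex$thresholds$threshold_db)))
    rownames(loc_long) <- NULL
    utils::write.csv(loc_long, file.path(out_dir, "location_rts.csv"),
                     row.names = FALSE)
    cmp <- function(metric) {
      # a tiny cohort can lack one granularity group; skip with a note
      tryCatch(compare_groups(base, metric, "granularity"),
               error = function(e) {
                 warnings_log <<- c(warnings_log,
                                    sprintf("group comparison for %s skipped: %s",
                                            metric, conditionMessage(e)))
                 NULL
               })
    }
    list(
      hood_kardon = fit_hood_kardon(sf_tab, nesting = "patient"),
      eccentricity = test_eccentricity_interaction(sf_tab),
      trajectory = fit_rts_trajectory(long),
      foveal_by_granularity = cmp("foveal_rts"),
      bcea_by_granularity = cmp("bcea63"),
      gradient = recovery_gradient(loc_long, window_days = 30),
      cor_foveal_bcea = pearson_test(base$foveal_rts, base$bcea63),
      cor_rts_bcva = pearson_test(base$avg_rts, base$bcva_logmar)
    )
  })
  .write_models_json(fits, file.path(out_dir, "models.json"))
  .write_summary_tables(cohort$eyes, base, out_dir)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mewdssf")),
    seed = seed,
    config = unclass(config),
    n_eyes = nrow(cohort$eyes),
    n_sf_rows = nrow(sf_tab),
    dropped_per_exam = dropped,
    file_hashes = as.list(tools::md5sum(
      list.files(out_dir, pattern = "\\.csv$", full.names = TRUE))),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' OCT geometry producing the cropped 64-stimulus footprint
#'
#' A cube whose B-scans span slightly less than +/-4.5 degrees vertically, so
#' the four most eccentric grid stimuli at `(+/-0.5, +/-4.5)` fall outside
#' the scanned footprint and 64 of the 68 stimuli survive the
#' structure-function join.
#'
#' @return A [scan_geometry()] with 11 B-scans at the standard 258-micron
#'   spacing.
#' @export
cropped_geometry <- function() {
  scan_geometry(n_bscans = 11, bscan_spacing_um = 258,
                n_ascans = 96, ascan_pitch_um = 30)
}

.fit_to_list <- function(f) {
  if (inherits(f, "model_fit"))
    return(list(coefficients = as.list(f$coefficients),
                std_errors = as.list(f$std_errors),
                p_values = as.list(f$p_values),
                varcomp = as.list(f$varcomp),
                n_obs = f$n_obs, converged = f$converged, loglik = f$loglik,
                group_means = if (!is.null(f$group_means)) as.list(f$group_means),
                difference = f$difference))
  if (is.list(f) && !is.null(f$slopes))
    return(list(slopes = as.list(f$slopes), slope_ses = as.list(f$slope_ses),
                ordering = f$ordering, notice = f$notice))
  f
}

.write_models_json <- function(fits, path) {
  jsonlite::write_json(lapply(fits, .fit_to_list), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
}

.write_summary_tables <- function(eyes, base, out_dir) {
  msd <- function(x) sprintf("%.3g (%.3g)", mean(x, na.rm = TRUE),
                             stats::sd(x, na.rm = TRUE))
  t1 <- data.frame(
    characteristic = c("Eyes", "Age (y)", "Female (n)",
                       "Onset to presentation (d)", "Primary MEWDS (n)",
                       "BCVA (LogMAR)", "Refraction (D)",
                       "Foveal granularity (n)", "Granularity size (um)",
                       "Choroidal thickness (um)"),
    value = c(nrow(eyes), msd(eyes$age_years), sum(eyes$female),
              msd(eyes$onset_days), sum(eyes$mewds_type == "primary"),
              msd(eyes$bcva_logmar), msd(eyes$refraction_d),
              sum(eyes$granularity), msd(eyes$granularity_size_um),
              msd(eyes$choroid_um)))
  utils::write.csv(t1, file.path(out_dir, "tables", "cohort_summary.csv"),
                   row.names = FALSE)
  g <- base$granularity
  t2 <- data.frame(
    metric = c("avg_rts", "foveal_rts", "bcea63", "bcea95"),
    no_granularity = c(msd(base$avg_rts[!g]), msd(base$foveal_rts[!g]),
                       msd(base$bcea63[!g]), msd(base$bcea95[!g])),
    granularity = c(msd(base$avg_rts[g]), msd(base$foveal_rts[g]),
                    msd(base$bcea63[g]), msd(base$bcea95[g])))
  utils::write.csv(t2, file.path(out_dir, "tables",
                                 "baseline_by_granularity.csv"),
                   row.names = FALSE)
}
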