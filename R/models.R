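#' Convert perimetric dB to linear sensitivity
#'
#' The Hood-Kardon scaling convention: `linear sensitivity = 10^(dB/10)`.
#' Structure-function regressions in this package are linear in this scale,
#' which makes the relationship asymptotic (toward the model intercept) for
#' deep sensitivity losses when viewed on the dB scale.
#'
#' @param s_db Sensitivity in dB (vectorized).
#' @return Linear-scale sensitivity (unitless).
#' @export
db_to_linear <- function(s_db) 10^(s_db / 10)

# --- model_fit container ----------------------------------------------------

.new_model_fit <- function(coefficients, std_errors, p_values, varcomp,
                           n_obs, converged, loglik, extra = list()) {
  stopifnot(length(coefficients) == length(std_errors),
            length(coefficients) == length(p_values))
  structure(c(list(coefficients = coefficients, std_errors = std_errors,
                   p_values = p_values, varcomp = varcomp, n_obs = n_obs,
                   converged = converged, loglik = loglik), extra),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit>", if (!x$converged) "(NOT converged)", "\n")
  tab <- data.frame(estimate = x$coefficients, se = x$std_errors,
                    p = signif(x$p_values, 3))
  print(signif(as.matrix(tab), 6))
  if (length(x$varcomp))
    cat("variance components:",
        paste(sprintf("%s = %.4g", names(x$varcomp), x$varcomp),
              collapse = ", "), "\n")
  cat(sprintf("n = %d, logLik = %.2f\n", x$n_obs, x$loglik))
  invisible(x)
}

# fit a mixed (or plain) linear model and normalize the output; random
# effects are dropped when random = NULL
.mixed_fit <- function(fixed, random, data) {
  if (is.null(random)) {
    fit <- stats::lm(fixed, data = data)
    sm <- summary(fit)$coefficients
    return(.new_model_fit(
      coefficients = sm[, 1], std_errors = sm[, 2], p_values = sm[, 4],
      varcomp = c(residual = summary(fit)$sigma^2),
      n_obs = stats::nobs(fit), converged = TRUE,
      loglik = as.numeric(stats::logLik(fit)),
      extra = list(fitted_model = fit)))
  }
  fml <- stats::as.formula(paste(deparse(fixed), "+", random))
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(
      lmerTest::lmer(fml, data = data, REML = TRUE,
                     control = lme4::lmerControl(
                       check.conv.singular = lme4::.makeCC(action = "ignore",
                                                           tol = 1e-4))),
      error = function(e) e),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    # degenerate variance structure (e.g. a noiseless table): the OLS
    # solution is the maximum-likelihood solution
    out <- .mixed_fit(fixed, NULL, data)
    out$varcomp <- c(out$varcomp, group = 0)
    return(out)
  }
  sm <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vnames <- ifelse(is.na(vc$var1), vc$grp, paste(vc$grp, vc$var1, sep = "."))
  varcomp <- stats::setNames(vc$vcov, vnames)
  .new_model_fit(
    coefficients = sm[, "Estimate"], std_errors = sm[, "Std. Error"],
    p_values = sm[, "Pr(>|t|)"], varcomp = varcomp,
    n_obs = stats::nobs(fit), converged = converged,
    loglik = as.numeric(stats::logLik(fit)),
    extra = list(fitted_model = fit))
}

.random_term <- function(nesting, has_patient = TRUE) {
  switch(nesting,
         patient = "(1 | patient_id)",
         eye = "(1 | eye_id)",
         patient_eye = "(1 | patient_id) + (1 | eye_id)",
         none = NULL,
         stop("unknown nesting: ", nesting, call. = FALSE))
}

# --- structure-function models ---------------------------------------------

.check_sf_table <- function(table) {
  need <- c("eye_id", "sens_linear", "prr")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("structure-function table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(unique(table$eye_id)) < 2)
    stop("need >= 2 eyes", call. = FALSE)
  if (length(unique(table$sens_linear)) < 2)
    stop("unidentifiable slope: sensitivity is constant", call. = FALSE)
  invisible(table)
}

#' Fit the hierarchical Hood-Kardon structure-function model
#'
#' Linear mixed regression of PRR on linear-scale sensitivity,
#' `PRR ~ 1 + sens_linear`, with a random intercept for the chosen nesting
#' (default: per patient, so eyes of a bilateral case share their effect)
#' and residual variation at the location level. REML fit; fixed-effect
#' p-values by Satterthwaite t-tests.
#'
#' @param table Structure-function table from
#'   [build_structure_function_table()] (or any data.frame with `patient_id`,
#'   `eye_id`, `sens_linear`, `prr`).
#' @param nesting Random-intercept grouping: `"patient"` (default), `"eye"`,
#'   `"patient_eye"` (both), or `"none"` (ordinary least squares).
#' @return A `model_fit` with coefficients `(Intercept)` and `sens_linear`.
#' @export
fit_hood_kardon <- function(table,
                            nesting = c("patient", "eye", "patient_eye",
                                        "none")) {
  nesting <- match.arg(nesting)
  .check_sf_table(table)
  if (nesting %in% c("patient", "patient_eye") &&
      !"patient_id" %in% names(table))
    stop("patient nesting requires a patient_id column", call. = FALSE)
  .mixed_fit(prr ~ sens_linear, .random_term(nesting), table)
}

#' Predict PRR from sensitivity through a fitted structure-function model
#'
#' `intercept + slope * 10^(s_db/10)`: strictly increasing in dB sensitivity
#' with lower asymptote equal to the intercept for deep losses.
#'
#' @param fit A `model_fit` from [fit_hood_kardon()].
#' @param s_db Sensitivity in dB (vectorized).
#' @return Predicted PRR.
#' @export
predict_prr <- function(fit, s_db) {
  stopifnot(inherits(fit, "model_fit"))
  unname(fit$coefficients["(Intercept)"] +
           fit$coefficients["sens_linear"] * db_to_linear(s_db))
}

#' Test eccentricity dependence of the structure-function slope
#'
#' Extends the hierarchical model with an eccentricity main effect and a
#' `sens_linear x eccentricity` interaction; the interaction p-value tests
#' whether the structure-function slope varies across the posterior pole.
#'
#' @inheritParams fit_hood_kardon
#' @return A `model_fit`; the interaction term is
#'   `sens_linear:eccentricity_deg`.
#' @export
test_eccentricity_interaction <- function(table,
                                          nesting = c("patient", "eye",
                                                      "patient_eye", "none")) {
  nesting <- match.arg(nesting)
  .check_sf_table(table)
  if (!"eccentricity_deg" %in% names(table))
    stop("table lacks an eccentricity_deg column", call. = FALSE)
  .mixed_fit(prr ~ sens_linear * eccentricity_deg, .random_term(nesting),
             table)
}

# --- longitudinal models ----------------------------------------------------

#' Fit the longitudinal RTS trajectory model
#'
#' Linear mixed model of per-visit average sensitivity:
#' `RTS ~ day * baseline_BCVA` with a random intercept per eye (optionally
#' plus patient). Baseline BCVA is centered at its per-eye sample mean before
#' fitting, so the `day` coefficient is the average recovery slope (dB/day)
#' and the interaction measures how the slope changes per LogMAR of worse
#' presenting acuity.
#'
#' @param long_table data.frame with columns `eye_id`, `day`, `rts_db`,
#'   `baseline_bcva` (and `patient_id` for patient nesting).
#' @param nesting `"eye"` (default), `"patient_eye"`, or `"none"`.
#' @return A `model_fit` with coefficients `(Intercept)`, `day`, `bcva_c`,
#'   `day:bcva_c`.
#' @export
fit_rts_trajectory <- function(long_table,
                               nesting = c("eye", "patient_eye", "none")) {
  nesting <- match.arg(nesting)
  need <- c("eye_id", "day", "rts_db", "baseline_bcva")
  miss <- setdiff(need, names(long_table))
  if (length(miss))
    stop("longitudinal table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  nv <- tapply(long_table$day, long_table$eye_id,
               function(d) length(unique(d)))
  if (max(nv) < 2)
    stop("insufficient longitudinal data: need >= 2 visits per eye",
         call. = FALSE)
  per_eye <- tapply(long_table$baseline_bcva, long_table$eye_id, mean)
  long_table$bcva_c <- long_table$baseline_bcva - mean(per_eye)
  .mixed_fit(rts_db ~ day * bcva_c, .random_term(nesting), long_table)
}

#' Compare an eye-level metric between two groups
#'
#' Linear mixed model `metric ~ group` with a random intercept per patient,
#' which keeps the two eyes of a bilateral case from counting as independent.
#'
#' @param summaries data.frame with one row per eye: `patient_id`, the metric
#'   column, and a logical/two-level group column.
#' @param metric Name of the metric column.
#' @param group Name of the grouping column.
#' @return A `model_fit` with extra elements `group_means` (named length-2)
#'   and `difference`; the group p-value is that of the group coefficient.
#' @export
compare_groups <- function(summaries, metric, group) {
  stopifnot(all(c("patient_id", metric, group) %in% names(summaries)))
  g <- factor(summaries[[group]])
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("both groups must be nonempty", call. = FALSE)
  d <- data.frame(patient_id = summaries$patient_id,
                  y = summaries[[metric]], g = g)
  fit <- .mixed_fit(y ~ g, "(1 | patient_id)", d)
  means <- c(tapply(d$y, d$g, mean))
  fit$group_means <- means
  fit$difference <- unname(diff(means))
  fit
}

#' Region-specific recovery slopes and the centrifugal-ordering test
#'
#' Location-level mixed model `RTS ~ day * region` with a random intercept
#' per eye, fitted over an early observation window where the recovery is
#' approximately linear. Returns the per-region slopes (dB/day) and one-sided
#' tests of the centrifugal ordering central > extramacular > peripapillary.
#'
#' @param location_long_table data.frame with columns `eye_id`, `day`,
#'   `region`, `rts_db`.
#' @param window_days Upper limit of days included (NULL keeps all).
#' @return list with `slopes` (named numeric), `slope_ses`, `ordering`
#'   (data.frame of one-sided contrast tests, or NULL with a `notice` when a
#'   single region is present), and the underlying `fit`.
#' @export
recovery_gradient <- function(location_long_table, window_days = NULL) {
  need <- c("eye_id", "day", "region", "rts_db")
  miss <- setdiff(need, names(location_long_table))
  if (length(miss))
    stop("table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- location_long_table
  if (!is.null(window_days)) d <- d[d$day <= window_days, ]
  if (any(is.na(d$region))) stop("missing region labels", call. = FALSE)
  d$region <- factor(d$region,
                     levels = intersect(c("central", "extramacular",
                                          "peripapillary"),
                                        unique(d$region)))
  if (length(unique(d$day)) < 2)
    stop("insufficient longitudinal data: need >= 2 visits", call. = FALSE)
  if (nlevels(d$region) == 1) {
    fit <- .mixed_fit(rts_db ~ day, "(1 | eye_id)", d)
    return(list(slopes = stats::setNames(fit$coefficients["day"],
                                         levels(d$region)),
                slope_ses = stats::setNames(fit$std_errors["day"],
                                            levels(d$region)),
                ordering = NULL,
                notice = "single region present; ordering test skipped",
                fit = fit))
  }
  fit <- .mixed_fit(rts_db ~ day * region, "(1 | eye_id)", d)
  V <- as.matrix(stats::vcov(fit$fitted_model))
  cf <- fit$coefficients
  regs <- levels(d$region)
  # slope of region r = day + day:region_r
  slope_vec <- function(r) {
    v <- stats::setNames(rep(0, length(cf)), names(cf))
    v["day"] <- 1
    nm <- paste0("day:region", r)
    if (nm %in% names(v)) v[nm] <- 1
    v
  }
  slopes <- ses <- stats::setNames(numeric(length(regs)), regs)
  for (r in regs) {
    v <- slope_vec(r)
    slopes[r] <- sum(v * cf)
    ses[r] <- sqrt(drop(t(v) %*% V %*% v))
  }
  pairs <- utils::combn(seq_along(regs), 2, simplify = FALSE)
  ordering <- do.call(rbind, lapply(pairs, function(ix) {
    v <- slope_vec(regs[ix[1]]) - slope_vec(regs[ix[2]])
    est <- sum(v * cf)
    se <- sqrt(drop(t(v) %*% V %*% v))
    data.frame(contrast = paste(regs[ix[1]], ">", regs[ix[2]]),
               estimate = est, se = se, z = est / se,
               p_one_sided = stats::pnorm(est / se, lower.tail = FALSE))
  }))
  list(slopes = slopes, slope_ses = ses, ordering = ordering, fit = fit)
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# --- forward-model simulation for estimator-recovery studies ----------------

#' Simulate a structure-function table directly from the forward model
#'
#' Draws a cohort of sensitivity fields, evaluates the true sensitivity at
#' the 64 grid locations covered by the cropped OCT footprint over the study
#' visits, and generates `PRR = sf_intercept + sf_slope * 10^(S/10) +
#' eye_effect + resid` with the configured hierarchical noise. Used for
#' estimator-recovery studies of [fit_hood_kardon()] without rendering OCT
#' volumes.
#'
#' @param config A [cohort_config()].
#' @param n_eyes Number of eyes (one per patient).
#' @param n_visits Number of study visits used (from `config$visit_days`).
#' @param seed Integer seed.
#' @param ecc_interaction Optional programmed interaction: adds
#'   `ecc_interaction * sens_linear * eccentricity` to the PRR.
#' @return A structure-function data.frame as in
#'   [build_structure_function_table()].
#' @export
simulate_sf_table <- function(config = cohort_config(), n_eyes = 12,
                              n_visits = 4, seed = 1L, ecc_interaction = 0) {
  cfg <- config
  cfg$n_patients <- n_eyes
  cfg$p_bilateral <- 0
  coh <- generate_cohort(cfg, seed = substream_seed(seed, 11L))
  grid <- build_grid()
  grid <- grid[abs(grid$y_deg) < 4.5, ]  # the 64-stimulus cropped footprint
  days <- cfg$visit_days[seq_len(min(n_visits, length(cfg$visit_days)))]
  withr::with_seed(substream_seed(seed, 12L), {
    rows <- lapply(seq_len(nrow(coh$eyes)), function(i) {
      eye <- coh$eyes[i, ]
      fld <- coh$fields[[eye$eye_id]]
      per_visit <- lapply(days, function(d) {
        s <- true_sensitivity(fld, grid$x_deg, grid$y_deg, d)
        lin <- db_to_linear(s)
        prr <- cfg$sf_intercept + cfg$sf_slope * lin + eye$sf_eye_effect +
          stats::rnorm(nrow(grid), 0, cfg$sf_resid_sd) +
          ecc_interaction * lin * grid$eccentricity_deg
        data.frame(patient_id = eye$patient_id, eye_id = eye$eye_id,
                   visit_day = d, location_id = grid$location_id,
                   x_deg = grid$x_deg, y_deg = grid$y_deg,
                   eccentricity_deg = grid$eccentricity_deg,
                   region = grid$region, rts_db = s, sens_linear = lin,
                   prr = prr, stringsAsFactors = FALSE)
      })
      do.call(rbind, per_visit)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
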