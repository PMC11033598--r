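test_that("dB to linear-sensitivity conversion is the 10^(dB/10) map", {
  expect_equal(db_to_linear(c(0, 10, 20)), c(1, 10, 100))
  expect_equal(db_to_linear(36), 10^3.6)
})

# noiseless structure-function table generated straight from the forward model
noiseless_sf <- function() {
  s <- rep(seq(0, 26, by = 2), times = 2)
  data.frame(patient_id = rep(c("P1", "P2"), each = 14),
             eye_id = rep(c("P1_OD", "P2_OS"), each = 14),
             eccentricity_deg = rep(seq(0.5, 4, length.out = 14), 2),
             rts_db = s, sens_linear = db_to_linear(s),
             prr = 5.36 + 0.66e-2 * db_to_linear(s))
}

test_that("the hierarchical fit recovers noiseless coefficients to 6+ digits", {
  fit <- fit_hood_kardon(noiseless_sf())
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - 5.36) / 5.36, 1e-6)
  expect_lt(abs(fit$coefficients[["sens_linear"]] - 0.0066) / 0.0066, 1e-6)
  expect_true(fit$converged)
})

test_that("degenerate structure-function tables are rejected", {
  tab <- noiseless_sf()
  tab$sens_linear <- 1
  expect_error(fit_hood_kardon(tab), "unidentifiable")
  one_eye <- noiseless_sf()
  one_eye$eye_id <- "E1"
  expect_error(fit_hood_kardon(one_eye), "2 eyes")
  expect_error(fit_hood_kardon(noiseless_sf()[, c("eye_id", "prr")]),
               "sens_linear")
})

test_that("PRR predictions are monotone with the intercept as asymptote", {
  fit <- fit_hood_kardon(noiseless_sf())
  expect_equal(predict_prr(fit, 0), 5.3666, tolerance = 1e-6)
  expect_equal(predict_prr(fit, -1e6), 5.36, tolerance = 1e-6)
  expect_true(predict_prr(fit, 25) > predict_prr(fit, 20))
  expect_true(predict_prr(fit, 20) > predict_prr(fit, 0))
})

test_that("with random effects off the fit equals the normal-equations oracle", {
  tab <- simulate_sf_table(cohort_config(), n_eyes = 8, n_visits = 2, seed = 3)
  fit <- fit_hood_kardon(tab, nesting = "none")
  X <- cbind(1, tab$sens_linear)
  beta <- solve(crossprod(X), crossprod(X, tab$prr))
  expect_lt(max(abs(fit$coefficients - as.vector(beta)) / abs(beta)), 1e-6)
  # same for the trajectory model against lm on the identical design
  long <- data.frame(patient_id = rep(sprintf("P%d", 1:6), each = 4),
                     eye_id = rep(sprintf("E%d", 1:6), each = 4),
                     day = rep(c(0, 14, 42, 90), 6),
                     baseline_bcva = rep(seq(0, 1, length.out = 6), each = 4))
  set.seed(4)
  long$rts_db <- 18 + 0.06 * long$day - 3 * long$baseline_bcva + rnorm(24, 0, 1)
  ft <- fit_rts_trajectory(long, nesting = "none")
  long$bcva_c <- long$baseline_bcva - mean(tapply(long$baseline_bcva,
                                                  long$eye_id, mean))
  ref <- stats::lm(rts_db ~ day * bcva_c, long)
  expect_equal(unname(ft$coefficients), unname(coef(ref)), tolerance = 1e-8)
})

test_that("noiseless linear trajectories return the programmed slope exactly", {
  long <- expand.grid(eye_id = sprintf("E%d", 1:6), day = c(0, 14, 42, 90))
  bcva <- stats::setNames(seq(0, 1, length.out = 6), sprintf("E%d", 1:6))
  long$baseline_bcva <- bcva[long$eye_id]
  long$patient_id <- long$eye_id
  # eye intercepts linear in BCVA keep the design exactly linear
  long$rts_db <- 20 - 5 * long$baseline_bcva + 0.066 * long$day
  fit <- fit_rts_trajectory(long)
  expect_equal(unname(fit$coefficients["day"]), 0.066, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["day:bcva_c"]), 0, tolerance = 1e-9)
})

test_that("the trajectory interaction recovers its programmed sign", {
  hits <- vapply(1:100, function(i) {
    set.seed(3000 + i)
    long <- expand.grid(eye_id = sprintf("E%d", 1:12), day = c(0, 14, 42, 90))
    bcva <- stats::setNames(runif(12, 0, 1), sprintf("E%d", 1:12))
    long$baseline_bcva <- bcva[long$eye_id]
    long$patient_id <- long$eye_id
    long$rts_db <- 20 - 4 * long$baseline_bcva +
      (0.03 + 0.08 * long$baseline_bcva) * long$day + rnorm(nrow(long), 0, 0.8)
    fit <- fit_rts_trajectory(long)
    fit$coefficients[["day:bcva_c"]] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("single-visit data trigger the longitudinal-data guard", {
  long <- data.frame(eye_id = c("A", "B"), day = 0, rts_db = c(10, 12),
                     baseline_bcva = c(0.1, 0.4), patient_id = c("A", "B"))
  expect_error(fit_rts_trajectory(long), "insufficient longitudinal")
})

test_that("group comparisons handle identical groups and guard empties", {
  d <- data.frame(patient_id = sprintf("P%d", 1:20),
                  foveal = rep(seq(10, 24, length.out = 10), 2),
                  flag = rep(c(FALSE, TRUE), each = 10))
  fit <- compare_groups(d, "foveal", "flag")
  expect_equal(fit$difference, 0, tolerance = 1e-9)
  expect_gt(fit$p_values[["gTRUE"]], 0.9)
  expect_equal(unname(fit$group_means), rep(mean(d$foveal), 2))
  d$flag <- FALSE
  expect_error(compare_groups(d, "foveal", "flag"), "nonempty")
})

test_that("region recovery slopes and their centrifugal ordering are detected", {
  mk_long <- function(slopes, noise_sd, seed) {
    set.seed(seed)
    grid <- expand.grid(eye_id = sprintf("E%d", 1:10), loc = 1:12,
                        day = c(0, 14, 42))
    grid$region <- rep(c("central", "extramacular", "peripapillary"),
                       length.out = nrow(grid))
    a <- stats::setNames(rnorm(10, 15, 2), sprintf("E%d", 1:10))
    grid$rts_db <- a[grid$eye_id] + slopes[grid$region] * grid$day +
      rnorm(nrow(grid), 0, noise_sd)
    grid
  }
  prog <- c(central = 0.20, extramacular = 0.10, peripapillary = 0.02)
  rg <- recovery_gradient(mk_long(prog, 1, 31))
  expect_equal(rg$slopes[names(prog)], prog, tolerance = 0.15)
  expect_true(all(diff(rg$slopes[c("central", "extramacular",
                                   "peripapillary")]) < 0))
  ord <- rg$ordering
  expect_lt(ord$p_one_sided[ord$contrast == "central > extramacular"], 0.01)
  expect_lt(ord$p_one_sided[ord$contrast == "extramacular > peripapillary"],
            0.01)
  # equal programmed slopes: the ordering contrasts stay non-significant
  flat <- c(central = 0.08, extramacular = 0.08, peripapillary = 0.08)
  rg0 <- recovery_gradient(mk_long(flat, 1, 32))
  expect_true(all(rg0$ordering$p_one_sided > 0.05))
  # single-region input returns the slope with a notice
  single <- mk_long(prog, 1, 33)
  single <- single[single$region == "central", ]
  rs <- recovery_gradient(single)
  expect_null(rs$ordering)
  expect_match(rs$notice, "single region")
  expect_equal(unname(rs$slopes["central"]), 0.20, tolerance = 0.05)
  expect_error(recovery_gradient(single[, c("eye_id", "day", "rts_db")]),
               "region")
})

test_that("Pearson helper matches analytic cases and guards degeneracy", {
  x <- 1:20
  expect_equal(pearson_test(x, x)$r, 1)
  expect_equal(pearson_test(x, -2 * x + 7)$r, -1)
  set.seed(41)
  null <- pearson_test(rnorm(1000), rnorm(1000))
  expect_lt(abs(null$r), 0.1)
  expect_error(pearson_test(rep(1, 10), 1:10), "zero variance")
  expect_error(pearson_test(1:2, 1:2), "n >= 3")
  expect_error(test_eccentricity_interaction(
    noiseless_sf()[, c("patient_id", "eye_id", "sens_linear", "prr")]),
    "eccentricity")
})
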