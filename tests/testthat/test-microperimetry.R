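test_that("the stimulus grid is the 68-point lattice the device uses", {
  g <- build_grid()
  expect_equal(nrow(g), 68)
  inner <- g[abs(g$x_deg) == 0.5 & abs(g$y_deg) == 0.5, ]
  expect_equal(nrow(inner), 4)
  expect_true(all(g$eccentricity_deg <= 4.6))
  # brute-force oracle: enumerate the full 10 x 10 lattice and count what the
  # radius cut excludes
  v <- seq(-4.5, 4.5, by = 1)
  raw <- expand.grid(x = v, y = v)
  expect_equal(nrow(raw), 100)
  expect_equal(sum(raw$x^2 + raw$y^2 > 20.5), 32)
  expect_setequal(paste(g$x_deg, g$y_deg),
                  with(raw[raw$x^2 + raw$y^2 <= 20.5, ], paste(x, y)))
})

test_that("the extended grid adds a peripapillary ring", {
  ge <- build_extended_grid()
  expect_equal(nrow(ge), 68 + 16)
  expect_equal(sum(ge$region == "peripapillary"), 16)
})

test_that("4-2 staircase follows the hand-enumerated reversal sequence", {
  # deterministic observer, true 10, start 10:
  # 10 seen -> 14 not seen (rev 1, step 2) -> 12 not seen -> 10 seen (rev 2)
  st <- run_staircase(10, psycho_slope_db = 0, fp_rate = 0, fn_rate = 0,
                      start_db = 10, seed = 1)
  expect_equal(st$threshold_db, 10)
  expect_false(st$absolute)
  # approached from above, the last-seen rule lands at true - 1 here:
  # 25 NS, 21 NS, 17 NS, 13 NS, 9 S (rev 1), 11 NS (rev 2) -> 9
  st2 <- run_staircase(10, 0, 0, 0, start_db = 25, seed = 1)
  expect_equal(st2$threshold_db, 9)
})

test_that("an observer who never sees yields an absolute scotoma at 0 dB", {
  st <- run_staircase(-100, psycho_slope_db = 0, fp_rate = 0, fn_rate = 0,
                      start_db = 25, seed = 1)
  expect_true(st$absolute)
  expect_equal(st$threshold_db, 0)
  expect_error(run_staircase(10, fp_rate = 2), "rates")
  expect_error(run_staircase(10, start_db = 40), "start_db")
})

.staircase_wrap <- function(true)
  run_staircase(true, psycho_slope_db = 2, fp_rate = 0, fn_rate = 0,
                start_db = 25)$threshold_db

test_that("staircase estimates track truth with low error", {
  set.seed(99)
  # mean absolute error against known truth (Monte-Carlo oracle)
  for (true in c(5, 15, 25)) {
    est <- replicate(200, .staircase_wrap(true))
    expect_lte(mean(abs(est - true)), 2)
  }
  # near-unbiased below the start level where the approach is symmetric
  for (true in c(4, 12, 20)) {
    est <- replicate(400, .staircase_wrap(true))
    expect_lte(abs(mean(est) - true), 1)
  }
})

test_that("examine_eye is deterministic and respects monotone recovery", {
  cfg <- cohort_config()
  coh <- cached_cohort(11)
  f <- coh$fields[[1]]
  e1 <- examine_eye(f, build_grid(), 0, cfg, seed = 5)
  e2 <- examine_eye(f, build_grid(), 0, cfg, seed = 5)
  expect_identical(e1$thresholds, e2$thresholds)
  e90 <- examine_eye(f, build_grid(), 90, cfg, seed = 6)
  expect_gt(average_rts(e90), average_rts(e1))
})

test_that("noiseless observer reproduces a true field on the staircase grid", {
  # the 4-2 staircase quantizes thresholds to the 2 dB grid anchored at the
  # start level, so exactness holds when truth sits on that grid
  cfg <- noiseless_config()
  f <- sensitivity_field("e", healthy_fovea_db = 25,
                         healthy_slope_db_per_deg = 0)
  ex <- examine_eye(f, build_grid(), 0, cfg, seed = 1)
  expect_true(all(ex$thresholds$threshold_db == 25))
})

test_that("RTS summaries follow their arithmetic contracts", {
  cfg <- noiseless_config()
  f <- sensitivity_field("e", healthy_fovea_db = 25,
                         healthy_slope_db_per_deg = 0)
  ex <- examine_eye(f, build_grid(), 0, cfg, seed = 1)
  ex$thresholds$threshold_db <- rep(20, 68)
  expect_equal(average_rts(ex), 20)
  expect_equal(foveal_rts(ex), 20)
  # one absolute scotoma among 67 intact locations
  ex$thresholds$threshold_db[10] <- 0
  expect_equal(round(average_rts(ex), 3), 19.706)
  expect_true(min(ex$thresholds$threshold_db) <= average_rts(ex))
  expect_true(average_rts(ex) <= max(ex$thresholds$threshold_db))
  # foveal mean of distinct values
  ctr <- abs(ex$thresholds$x_deg) == 0.5 & abs(ex$thresholds$y_deg) == 0.5
  ex$thresholds$threshold_db[ctr] <- c(10, 12, 14, 16)
  expect_equal(foveal_rts(ex), 13)
  ex$thresholds$threshold_db[ctr] <- 0
  expect_equal(foveal_rts(ex), 0)
  ex$thresholds <- ex$thresholds[!ctr, ]
  expect_error(foveal_rts(ex), "central")
})

test_that("exam files round-trip through CSV", {
  cfg <- cohort_config()
  ex <- examine_eye(cached_cohort(11)$fields[[2]], build_grid(), 14, cfg, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_exam(ex, path)
  ex2 <- read_exam(path)
  expect_equal(ex2$eye_ref, ex$eye_ref)
  expect_equal(ex2$thresholds$threshold_db, ex$thresholds$threshold_db)
})
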