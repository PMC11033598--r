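test_that("BCEA of a degenerate cloud is zero and errors are guarded", {
  pts <- data.frame(x_deg = rep(1, 20), y_deg = rep(-2, 20))
  expect_equal(bcea(pts, 0.63), 0)
  expect_error(bcea(pts[1:5, ], 0.63), ">= 10")
  expect_error(bcea(pts, 1.5), "coverage")
})

test_that("BCEA matches the chi-square area on a unit normal cloud and covers as stated", {
  set.seed(7)
  cloud <- data.frame(x_deg = rnorm(20000), y_deg = rnorm(20000))
  a63 <- bcea(cloud, 0.63)
  # analytic area for sigma = 1, rho = 0: -2 ln(0.37) * pi = 6.248
  expect_lt(abs(a63 - -2 * log(1 - 0.63) * pi), 0.1)
  # Monte-Carlo coverage oracle: fraction of points inside the 63% ellipse
  r2 <- (cloud$x_deg - mean(cloud$x_deg))^2 / stats::var(cloud$x_deg) +
    (cloud$y_deg - mean(cloud$y_deg))^2 / stats::var(cloud$y_deg)
  expect_lt(abs(mean(r2 <= -2 * log(1 - 0.63)) - 0.63), 0.03)
})

test_that("BCEA95/BCEA63 equals the analytic log ratio for any cloud", {
  set.seed(8)
  for (i in 1:20) {
    sx <- runif(1, 0.1, 3); sy <- runif(1, 0.1, 3); rho <- runif(1, -0.8, 0.8)
    z <- MASS::mvrnorm(50, c(0, 0),
                       matrix(c(sx^2, rho * sx * sy, rho * sx * sy, sy^2), 2))
    cloud <- data.frame(x_deg = z[, 1], y_deg = z[, 2])
    expect_equal(bcea(cloud, 0.95) / bcea(cloud, 0.63),
                 log(0.05) / log(0.37), tolerance = 1e-12)
  }
})

test_that("ellipse coverage holds across bivariate normal shapes", {
  set.seed(9)
  for (p in c(0.63, 0.95)) {
    sx <- runif(1, 0.2, 2); sy <- runif(1, 0.2, 2); rho <- runif(1, -0.7, 0.7)
    S <- matrix(c(sx^2, rho * sx * sy, rho * sx * sy, sy^2), 2)
    z <- MASS::mvrnorm(10000, c(0, 0), S)
    ctr <- colMeans(z)
    d2 <- stats::mahalanobis(z, ctr, stats::cov(z))
    expect_lt(abs(mean(d2 <= -2 * log(1 - p)) - p), 0.03)
  }
})

test_that("fixation classification follows the P1/P2 rules exhaustively", {
  tight <- data.frame(x_deg = rep(0, 20), y_deg = rep(0, 20))
  fx <- classify_fixation(tight)
  expect_equal(fx$category, "stable")
  expect_equal(fx$p1, 1)
  expect_equal(fx$p2, 1)
  # p1 = 0.5, p2 = 0.9: points at radius 0 (half), 1.5 (0.4), 5 (0.1)
  mk <- function(r, n) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-1]
    data.frame(x_deg = r * cos(th), y_deg = r * sin(th))
  }
  mixed <- rbind(mk(0.01, 50), mk(1.5, 40), mk(30, 10))
  fx2 <- classify_fixation(mixed)
  expect_equal(fx2$p1, 0.5, tolerance = 0.05)
  expect_equal(fx2$category, "relatively unstable")
  spread <- rbind(mk(0.01, 40), mk(30, 60))
  expect_equal(classify_fixation(spread)$category, "unstable")
})

test_that("fixation dispersion responds to deficit, granularity, and switches off", {
  cfg0 <- cohort_config(fixation_sensitivity_gain = 0,
                        granularity_fixation_multiplier = 1,
                        fixation_log_jitter_sd = 0)
  eye_g <- list(granularity = TRUE)
  eye_n <- list(granularity = FALSE)
  sd_of <- function(cloud) stats::sd(c(cloud$x_deg, cloud$y_deg))
  # switch-off: same sigma whatever the sensitivity or granularity
  c1 <- generate_fixation_cloud(eye_g, 5, 2000, seed = 1, config = cfg0)
  c2 <- generate_fixation_cloud(eye_n, 25, 2000, seed = 2, config = cfg0)
  expect_equal(sd_of(c1), sd_of(c2), tolerance = 0.05)
  # deficit raises dispersion when the gain is on
  cfg <- cohort_config(fixation_log_jitter_sd = 0)
  c3 <- generate_fixation_cloud(eye_n, 25, 2000, seed = 3, config = cfg)
  c4 <- generate_fixation_cloud(eye_n, 8, 2000, seed = 3, config = cfg)
  expect_gt(sd_of(c4), sd_of(c3))
  # determinism and the sample-size guard
  expect_identical(generate_fixation_cloud(eye_g, 15, 100, seed = 9),
                   generate_fixation_cloud(eye_g, 15, 100, seed = 9))
  expect_error(generate_fixation_cloud(eye_g, 15, 5, seed = 1),
               "insufficient")
})
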