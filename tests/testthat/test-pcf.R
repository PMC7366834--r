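test_that("edge weights hit the exact interior, edge and corner values", {
  w <- c(width = 1, height = 1)
  expect_equal(ripley_weight(0.5, 0.5, 0.1, w), 1)
  expect_equal(ripley_weight(0, 0.5, 0.05, w), 2)
  expect_equal(ripley_weight(0.5, 0, 0.05, w), 2)
  expect_equal(ripley_weight(0, 0, 0.05, w), 4)
  expect_equal(ripley_weight(1, 1, 0.05, w), 4)
  expect_error(ripley_weight(1.5, 0.5, 0.1, w), class = "grass_argument_error")
  expect_error(ripley_weight(0.5, 0.5, 0, w), class = "grass_argument_error")
})

test_that("closed-form edge weights agree with numeric arc integration", {
  w <- c(width = 1.1, height = 0.9)
  # lattice of positions (incl. edges, corners, near-corner) x radii
  xs <- c(0, 0.001, 0.01, 0.05, 0.2, 0.55, 1.05, 1.1)
  ys <- c(0, 0.002, 0.03, 0.45, 0.88, 0.9)
  rs <- c(0.01, 0.06, 0.2)
  cases <- expand.grid(x = xs, y = ys, r = rs)
  closed <- 1 / ripley_weight(cases$x, cases$y, cases$r, w)
  numeric_frac <- mapply(function(px, py, r) {
    covered_fraction_numeric(px, py, r, w, n_samples = 2e5)
  }, cases$x, cases$y, cases$r)
  expect_equal(nrow(cases), 144)
  expect_lt(max(abs(closed - numeric_frac)), 1e-4)

  # a denser check at full precision on the hardest (near-corner) cases
  hard <- cases[cases$x <= 0.05 & cases$y <= 0.03, ]
  hard_closed <- 1 / ripley_weight(hard$x, hard$y, hard$r, w)
  hard_numeric <- mapply(function(px, py, r) {
    covered_fraction_numeric(px, py, r, w, n_samples = 1e6)
  }, hard$x, hard$y, hard$r)
  expect_lt(max(abs(hard_closed - hard_numeric)), 1e-5)

  expect_true(all(ripley_weight(cases$x, cases$y, cases$r, w) >= 1))
})

test_that("the pcf estimator is calibrated under CSR", {
  withr::local_seed(14)
  w <- c(width = 1.1, height = 0.9)
  grid <- seq(0.02, 0.2, length.out = 19)
  gmat <- replicate(30, {
    pts <- csr_points(300, w)
    pcf_estimate(pts, w, r_grid = grid)$g
  })
  gbar <- rowMeans(gmat)
  expect_true(all(gbar > 0.92 & gbar < 1.08))

  # uncorrected estimation is biased low near the border scale
  g_none <- rowMeans(replicate(30, {
    pts <- csr_points(300, w)
    pcf_estimate(pts, w, r_grid = grid, correction = "none")$g
  }))
  expect_lt(mean(g_none), mean(gbar))

  # translation correction is an independent route to the same quantity
  g_trans <- rowMeans(replicate(30, {
    pts <- csr_points(300, w)
    pcf_estimate(pts, w, r_grid = grid, correction = "translation")$g
  }))
  expect_lt(max(abs(g_trans - 1)), 0.1)

  expect_error(pcf_estimate(csr_points(1, w), w),
               class = "grass_estimation_error")
  expect_error(pcf_estimate(csr_points(10, w), w, r_grid = c(-0.1, 0.1)),
               class = "grass_argument_error")
})

test_that("the estimator is species-blind", {
  withr::local_seed(15)
  w <- c(width = 1.1, height = 0.9)
  pts <- csr_points(200, w)
  a <- pcf_estimate(pts, w)
  pts$species_id <- sample(c("A", "B"), 200, TRUE)
  b <- pcf_estimate(pts, w)
  expect_identical(a$g, b$g)
})

test_that("a hard-core pattern shows near-zero pcf below its spacing", {
  withr::local_seed(16)
  w <- c(width = 1.1, height = 0.9)
  # sequential inhibition with minimum spacing 0.05 m
  n_target <- 250
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n_target) {
    cx <- runif(1, 0, 1.1); cy <- runif(1, 0, 0.9)
    if (length(xs) == 0 || min((xs - cx)^2 + (ys - cy)^2) >= 0.05^2) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  }
  est <- pcf_estimate(tibble::tibble(x = xs, y = ys), w,
                      r_grid = seq(0.015, 0.2, by = 0.005))
  expect_true(all(est$g[est$r < 0.04] < 0.05))
  expect_gt(mean(est$g[est$r > 0.1]), 0.8)
})

test_that("delta-pcf is exactly zero for identical censuses", {
  withr::local_seed(17)
  w <- c(width = 1.1, height = 0.9)
  pts <- csr_points(100, w)
  dp <- delta_pcf(pts, pts, w)
  expect_equal(dp$delta, rep(0, nrow(dp)))
})

test_that("independent thinning leaves the pcf unchanged in expectation", {
  withr::local_seed(18)
  w <- c(width = 1.1, height = 0.9)
  deltas <- replicate(25, {
    pts <- csr_points(400, w)
    keep <- runif(400) < 0.5
    dp <- delta_pcf(pts, pts[keep, ], w, r_grid = seq(0.02, 0.2, by = 0.01),
                    bandwidth = 0.01)
    mean(dp$delta)
  })
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se + 0.02)
})

test_that("replicate bands follow the t-interval closed form", {
  grid <- c(0.05, 0.1)
  curves <- tibble::tibble(
    plot_id = rep(c("a", "b", "c"), each = 2),
    r = rep(grid, 3),
    delta = c(0.1, -0.2, 0.3, 0.0, 0.2, -0.1)
  )
  band <- replicate_band(curves)
  d1 <- c(0.1, 0.3, 0.2)
  m <- mean(d1); half <- qt(0.975, 2) * sd(d1) / sqrt(3)
  expect_equal(band$mean_delta[band$r == 0.05], m, tolerance = 1e-12)
  expect_equal(band$ci_low[band$r == 0.05], m - half, tolerance = 1e-12)
  expect_equal(band$ci_high[band$r == 0.05], m + half, tolerance = 1e-12)

  sdband <- replicate_band(curves, band_type = "mean_pm_1sd")
  expect_equal(sdband$ci_high[sdband$r == 0.05], m + sd(d1),
               tolerance = 1e-12)

  # two identical curves give a zero-width band at the curve
  two <- curves[curves$plot_id %in% c("a", "b"), ]
  two$delta <- rep(c(0.1, -0.2), 2)
  bz <- replicate_band(two)
  expect_equal(bz$ci_low, bz$ci_high)
  expect_equal(bz$mean_delta, c(0.1, -0.2))

  bad <- curves
  bad$r[1] <- 0.07
  expect_error(replicate_band(bad), class = "grass_argument_error")
  expect_error(replicate_band(curves[curves$plot_id == "a", ]),
               class = "grass_argument_error")
})

test_that("interaction calls follow the strict sign rule and are monotone", {
  band <- tibble::tibble(
    r = c(0.02, 0.05, 0.1),
    mean_delta = c(-0.5, 0.2, 0.0),
    ci_low = c(-0.8, 0.1, -0.1),
    ci_high = c(-0.2, 0.3, 0.1),
    n_replicates = 12, band_type = "t_ci_95"
  )
  calls <- classify_interactions(band)
  expect_equal(calls$classification, c("negative", "positive", "none"))

  # widening the band can only move labels toward "none"
  wide <- band
  wide$ci_low <- band$ci_low - 0.5
  wide$ci_high <- band$ci_high + 0.5
  wide_calls <- classify_interactions(wide)
  moved <- calls$classification != wide_calls$classification
  expect_true(all(wide_calls$classification[moved] == "none"))
})

test_that("per-plot curves share one grid and skip unusable plots", {
  cfg <- sim_config(n_blocks = 2, light_map = c(no = 40, strong = 10),
                    lambda0 = 250, seed = 19)
  e <- generate_experiment(cfg)
  curves <- delta_pcf_by_plot(e)
  expect_setequal(unique(curves$plot_id), unique(e$plot_id))
  grids <- split(curves$r, curves$plot_id)
  expect_true(all(vapply(grids, identical, logical(1), y = grids[[1]])))

  smry <- delta_pcf_summary(e)
  expect_setequal(unique(smry$treatment), c("no", "strong"))
  expect_true(all(smry$ci_low <= smry$mean_delta &
                    smry$mean_delta <= smry$ci_high))
  expect_true(all(smry$classification %in% c("negative", "positive", "none")))
})
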