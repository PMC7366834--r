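test_that("bray_curtis matches its formula and its invariants", {
  expect_equal(bray_curtis(c(A = 3, B = 1), c(A = 3, B = 1)), 0)
  expect_equal(bray_curtis(c(A = 5), c(B = 2, C = 1)), 1)
  expect_equal(bray_curtis(c(A = 6, B = 2), c(A = 2, B = 2, C = 4)), 0.5)
  expect_error(bray_curtis(c(A = 1), numeric(0)),
               class = "grass_argument_error")

  withr::local_seed(8)
  for (i in 1:25) {
    x <- setNames(rpois(6, 5) + 1, letters[1:6])
    y <- setNames(rpois(6, 5) + 1, letters[1:6])
    b <- bray_curtis(x, y)
    expect_gte(b, 0); expect_lte(b, 1)
    expect_equal(b, bray_curtis(y, x))
    # invariant to species absent from both communities
    expect_equal(b, bray_curtis(c(x, zz = 0), c(y, zz = 0)))
    # agrees with the vegan implementation
    expect_equal(b, as.numeric(vegan::vegdist(rbind(x, y), "bray")),
                 tolerance = 1e-12)
  }
})

test_that("pair records obey the layout combinatorics", {
  cfg <- sim_config(lambda0 = 30, seed = 101)  # sparse: fast, full layout
  e <- generate_experiment(cfg)
  rec <- delta_dissimilarity(e, level = "plots")
  expect_equal(nrow(rec) + attr(rec, "n_dropped"), choose(48, 2))
  tt <- table(rec$group)
  if (attr(rec, "n_dropped") == 0) {
    expect_equal(unname(tt[["same_treatment"]]), 4 * choose(12, 2))
    expect_equal(unname(tt[["different_treatment"]]),
                 choose(48, 2) - 4 * choose(12, 2))
  }
  expect_true(all(rec$light_diff[rec$group == "same_treatment"] == 0))
  expect_true(all(rec$light_diff[rec$group == "different_treatment"] > 0))
  expect_true(all(rec$B_t1 >= 0 & rec$B_t1 <= 1))
  expect_true(all(abs(rec$delta_B) <= 1))

  # random layouts: same-treatment count is T * C(nb, 2)
  withr::local_seed(9)
  for (i in 1:3) {
    nb <- sample(2:5, 1)
    tn <- sample(2:4, 1)
    lm_ <- setNames(10 * seq_len(tn), paste0("tr", seq_len(tn)))
    cfg2 <- sim_config(n_blocks = nb, light_map = lm_, lambda0 = 60,
                       seed = 200 + i)
    rec2 <- delta_dissimilarity(generate_experiment(cfg2))
    expect_equal(nrow(rec2) + attr(rec2, "n_dropped"), choose(nb * tn, 2))
    expect_equal(sum(rec2$group == "same_treatment") == tn * choose(nb, 2),
                 attr(rec2, "n_dropped") == 0)
  }
})

test_that("subplot-level records pair subplots only within a plot", {
  cfg <- sim_config(n_blocks = 1, light_map = c(no = 40, strong = 10),
                    lambda0 = 400, seed = 111)
  e <- generate_experiment(cfg)
  rec <- delta_dissimilarity(e, level = "subplots")
  expect_true(all(rec$group == "within_plot_subplots"))
  expect_true(all(rec$light_diff == 0))
  # 2 plots x C(6,2) pairs when nothing is dropped
  expect_equal(nrow(rec) + attr(rec, "n_dropped"), 2 * choose(6, 2))
  # both subplots of a pair belong to the same plot
  plot_of <- function(u) sub(":s[0-9]+$", "", u)
  expect_true(all(plot_of(rec$unit_a) == plot_of(rec$unit_b)))
})

test_that("identical compositions at both censuses give delta_B = 0", {
  ind <- tibble::tibble(
    plot_id = rep(c("p1", "p2"), each = 4),
    block_id = "b1",
    treatment = rep(c("no", "strong"), each = 4),
    census = rep(c("t1", "t1", "t2", "t2"), 2),
    species_id = rep(c("A", "B"), 4),
    x = rep(c(0.1, 0.6), 4), y = rep(c(0.1, 0.6), 4)
  )
  e <- grass_experiment(ind)
  rec <- delta_dissimilarity(e)
  expect_equal(rec$delta_B, 0)
})

test_that("t statistics match closed-form oracles", {
  tt <- one_sample_ttest(c(0.1, 0.2, 0.3))
  expect_equal(tt$statistic, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(tt$df, 2)
  expect_equal(tt$p_value, 2 * pt(-abs(tt$statistic), 2), tolerance = 1e-12)

  expect_equal(one_sample_ttest(c(-0.4, 0.4))$statistic, 0)
  expect_error(one_sample_ttest(c(0.1)), class = "grass_argument_error")
  expect_error(one_sample_ttest(rep(0.2, 5)),
               class = "grass_degenerate_error")

  a <- c(0.11, 0.35, 0.27, 0.18, 0.4)
  b <- c(0.02, -0.05, 0.13, 0.08, -0.01)
  tt2 <- two_sample_ttest(a, b)
  expect_equal(tt2$statistic, pooled_t_oracle(a, b), tolerance = 1e-10)
  expect_equal(tt2$df, 8)
  expect_equal(tidy(tt2)$mean_a, mean(a))

  expect_equal(two_sample_ttest(a, a)$statistic, 0)
  jit <- c(rep(0, 5), 1e-9)
  expect_gt(abs(two_sample_ttest(jit + 1, jit)$statistic), 1e6)
  expect_error(two_sample_ttest(rep(1, 3), rep(0, 3)),
               class = "grass_degenerate_error")

  # Welch variant differs when variances do
  tw <- two_sample_ttest(a, b * 10, var_equal = FALSE)
  expect_false(isTRUE(all.equal(tw$df, 8)))
})

test_that("the illumination regression matches the OLS oracle", {
  rec <- tibble::tibble(
    group = "different_treatment",
    treatment_a = "x", treatment_b = rep(c("y", "z", "w"), each = 2),
    light_diff = c(10, 10, 20, 20, 30, 30),
    delta_B = c(0.12, 0.18, 0.25, 0.21, 0.34, 0.30)
  )
  reg <- regress_delta_on_light(rec)
  o <- ols_oracle(rec$light_diff, rec$delta_B)
  expect_equal(reg$slope, o$slope, tolerance = 1e-10)
  expect_equal(reg$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(reg$r_squared, o$r_squared, tolerance = 1e-10)

  # perfectly linear data: R^2 = 1 and the exact slope
  lin <- tibble::tibble(group = "different_treatment",
                        treatment_a = "x", treatment_b = "y",
                        light_diff = c(10, 20, 30),
                        delta_B = 0.01 * c(10, 20, 30) + 0.05)
  rl <- suppressWarnings(regress_delta_on_light(lin))  # perfect-fit lm note
  expect_equal(rl$slope, 0.01, tolerance = 1e-12)
  expect_equal(rl$r_squared, 1, tolerance = 1e-12)

  same_ld <- tibble::tibble(group = "different_treatment",
                            treatment_a = "x", treatment_b = "y",
                            light_diff = rep(10, 5),
                            delta_B = runif(5))
  expect_error(regress_delta_on_light(same_ld), class = "grass_rank_error")

  band <- confidence_band(reg)
  expect_true(all(band$lwr <= band$fit & band$fit <= band$upr))

  # treatment-pair aggregation averages delta_B within treatment pairs
  ragg <- regress_delta_on_light(rec, aggregate = "treatment_pairs")
  expect_equal(ragg$n, 3)
})

test_that("slope CI covers zero at about the nominal rate under the null", {
  withr::local_seed(12)
  n_rep <- 400
  covered <- logical(n_rep)
  light <- rep(c(10, 20, 30), each = 10)
  for (i in seq_len(n_rep)) {
    rec <- tibble::tibble(group = "different_treatment",
                          treatment_a = "x", treatment_b = "y",
                          light_diff = light,
                          delta_B = rnorm(30, 0, 0.1))
    reg <- regress_delta_on_light(rec)
    ci <- confint(reg$model)["light_diff", ]
    covered[i] <- ci[1] <= 0 && 0 <= ci[2]
  }
  expect_gt(mean(covered), 0.91)
  expect_lt(mean(covered), 0.99)
})

test_that("block permutation detects a treatment signal and spares a null", {
  cfg <- sim_config(n_blocks = 6, lambda0 = 150, filtering_strength = 2,
                    competition_strength = 0, seed = 131)
  rec <- delta_dissimilarity(generate_experiment(cfg))
  perm <- delta_b_permutation(rec, n_perm = 199, seed = 1)
  expect_lt(perm$p_value, 0.05)
  expect_equal(perm$observed_t,
               two_sample_ttest(rec$delta_B[rec$group == "different_treatment"],
                                rec$delta_B[rec$group == "same_treatment"]
               )$statistic)
})
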