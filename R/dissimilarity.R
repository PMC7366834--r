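#' Bray–Curtis dissimilarity between two communities
#'
#' `B = Σ|xᵢ − yᵢ| / Σ(xᵢ + yᵢ)` over the union of species: 0 for identical
#' abundance vectors, 1 for disjoint species sets. Symmetric and invariant
#' to species absent from both communities.
#'
#' @param x,y Named abundance vectors (as from [abundance_vector()]), each
#'   with positive total. Dissimilarity to an empty community is undefined
#'   and raises an error.
#' @return A value in `[0, 1]`.
#' @examples
#' bray_curtis(c(A = 6, B = 2), c(A = 2, B = 2, C = 4)) # 0.5
#' @export
bray_curtis <- function(x, y) {
  if (length(x) == 0 || sum(x) <= 0 || length(y) == 0 || sum(y) <= 0) {
    abort("Bray-Curtis is undefined for an empty community",
          class = "grass_argument_error")
  }
  species <- union(names(x), names(y))
  xi <- setNames(rep(0, length(species)), species)
  yi <- xi
  xi[names(x)] <- x
  yi[names(y)] <- y
  sum(abs(xi - yi)) / sum(xi + yi)
}

# Bray-Curtis matrix for a unit-by-species table (vegan does the heavy work)
bray_matrix <- function(ab_table, unit) {
  mat <- as.matrix(ab_table[setdiff(names(ab_table), unit)])
  rownames(mat) <- ab_table[[unit]]
  as.matrix(vegan::vegdist(mat, method = "bray"))
}

#' Change in pairwise Bray–Curtis dissimilarity between censuses
#'
#' For every community pair, the Bray–Curtis dissimilarity at each census
#' and its change `delta_B = B_t2 − B_t1`. At `level = "plots"` all
#' unordered plot pairs are formed (48 plots → 1128 pairs under the default
#' layout) and grouped by treatment equality; at `level = "subplots"` each
#' plot is split with [split_subplots()] and only pairs of subplots within
#' the same plot are formed (6 subplots → 15 pairs per plot). Pairs in
#' which any community is empty at either census are dropped; the dropped
#' count is attached as attribute `n_dropped` and messaged.
#'
#' @param experiment A two-census [grass_experiment()].
#' @param level `"plots"` or `"subplots"`.
#' @param ncols,nrows Subplot grid (used for `level = "subplots"`).
#' @return Tibble with one row per retained pair: `unit_a`, `unit_b`,
#'   `block_a`, `block_b`, `treatment_a`, `treatment_b`, `group`
#'   (`same_treatment` / `different_treatment` / `within_plot_subplots`),
#'   `B_t1`, `B_t2`, `delta_B`, `light_diff` (mol·m⁻²·d⁻¹, 0 within a
#'   treatment).
#' @export
delta_dissimilarity <- function(experiment, level = c("plots", "subplots"),
                                ncols = 3, nrows = 2) {
  level <- match.arg(level)
  light_map <- exp_light_map(experiment)
  if (level == "plots") {
    df <- as_tibble(experiment)
    unit <- "plot_id"
  } else {
    df <- as_tibble(split_subplots(experiment, ncols = ncols, nrows = nrows))
    unit <- "subplot_id"
  }
  meta <- distinct(df, unit_id = .data[[unit]], .data$plot_id,
                   .data$block_id, .data$treatment)

  ab1 <- abundance_table(df, "t1", unit = unit)
  ab2 <- abundance_table(df, "t2", unit = unit)
  units_ok <- intersect(ab1[[unit]], ab2[[unit]])

  all_units <- meta$unit_id
  d1 <- bray_matrix(ab1[ab1[[unit]] %in% units_ok, , drop = FALSE], unit)
  d2 <- bray_matrix(ab2[ab2[[unit]] %in% units_ok, , drop = FALSE], unit)

  pair_of <- function(units) {
    if (length(units) < 2) {
      return(tibble(unit_a = character(0), unit_b = character(0)))
    }
    cmb <- utils::combn(sort(units), 2)
    tibble(unit_a = cmb[1, ], unit_b = cmb[2, ])
  }
  if (level == "plots") {
    pairs <- pair_of(all_units)
  } else {
    pairs <- bind_rows(lapply(split(meta$unit_id, meta$plot_id), pair_of))
  }
  n_total <- nrow(pairs)
  keep <- pairs$unit_a %in% units_ok & pairs$unit_b %in% units_ok
  n_dropped <- n_total - sum(keep)
  if (n_dropped > 0) {
    message(n_dropped, " pair(s) dropped: a community was empty at a census")
  }
  pairs <- pairs[keep, , drop = FALSE]

  key <- function(field) setNames(meta[[field]], meta$unit_id)
  out <- mutate(pairs,
    block_a = unname(key("block_id")[.data$unit_a]),
    block_b = unname(key("block_id")[.data$unit_b]),
    treatment_a = unname(key("treatment")[.data$unit_a]),
    treatment_b = unname(key("treatment")[.data$unit_b]),
    group = if (level == "subplots") "within_plot_subplots" else
      ifelse(.data$treatment_a == .data$treatment_b,
             "same_treatment", "different_treatment"),
    B_t1 = d1[cbind(.data$unit_a, .data$unit_b)],
    B_t2 = d2[cbind(.data$unit_a, .data$unit_b)],
    delta_B = .data$B_t2 - .data$B_t1,
    light_diff = unname(abs(light_map[.data$treatment_a] -
                              light_map[.data$treatment_b]))
  )
  structure(as_tibble(out), n_dropped = n_dropped)
}

new_grass_ttest <- function(type, statistic, df, p_value, estimate, se, n,
                            group_means = NULL) {
  structure(list(type = type, statistic = statistic, df = df,
                 p_value = p_value, estimate = estimate, se = se, n = n,
                 group_means = group_means),
            class = "grass_ttest")
}

#' @export
print.grass_ttest <- function(x, ...) {
  cat(sprintf("<grass_ttest: %s> t = %.4f, df = %g, p = %.4g\n",
              x$type, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' One-sample Student's t test of delta-B against zero
#'
#' Tests whether the mean change in dissimilarity differs from zero.
#'
#' @param deltas Numeric vector of `delta_B` values (n ≥ 2, positive
#'   variance).
#' @param mu Null mean, default 0.
#' @return A `grass_ttest` object (see [tidy.grass_ttest()]).
#' @export
one_sample_ttest <- function(deltas, mu = 0) {
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) < 2) {
    abort("need at least 2 values", class = "grass_argument_error")
  }
  if (var(deltas) == 0) {
    abort("sample variance is zero; t statistic undefined",
          class = "grass_degenerate_error")
  }
  ht <- t.test(deltas, mu = mu)
  new_grass_ttest("one_sample",
                  statistic = unname(ht$statistic), df = unname(ht$parameter),
                  p_value = ht$p.value, estimate = mean(deltas),
                  se = unname(ht$stderr), n = length(deltas))
}

#' Two-sample t test between delta-B groups
#'
#' Student's pooled-variance two-sample t test by default (`var_equal =
#' FALSE` gives Welch). Used to compare different-treatment against
#' same-treatment changes in dissimilarity.
#'
#' @param deltas_a,deltas_b Numeric vectors, each n ≥ 2.
#' @param var_equal Pool the variances (classical Student form)? Default
#'   `TRUE`.
#' @return A `grass_ttest` object; `estimate` is mean(a) − mean(b) and
#'   `group_means` the two means.
#' @export
two_sample_ttest <- function(deltas_a, deltas_b, var_equal = TRUE) {
  deltas_a <- deltas_a[!is.na(deltas_a)]
  deltas_b <- deltas_b[!is.na(deltas_b)]
  if (length(deltas_a) < 2 || length(deltas_b) < 2) {
    abort("need at least 2 values per group", class = "grass_argument_error")
  }
  if (var(deltas_a) == 0 && var(deltas_b) == 0) {
    abort("both group variances are zero; t statistic undefined",
          class = "grass_degenerate_error")
  }
  ht <- t.test(deltas_a, deltas_b, var.equal = var_equal)
  new_grass_ttest(if (var_equal) "two_sample_pooled" else "two_sample_welch",
                  statistic = unname(ht$statistic), df = unname(ht$parameter),
                  p_value = ht$p.value,
                  estimate = mean(deltas_a) - mean(deltas_b),
                  se = unname(ht$stderr),
                  n = length(deltas_a) + length(deltas_b),
                  group_means = c(a = mean(deltas_a), b = mean(deltas_b)))
}

#' All delta-B group tests at once
#'
#' One-sample t tests of delta-B against zero per group, plus the
#' two-sample comparison of different-treatment vs same-treatment changes
#' when both groups are present.
#'
#' @param records Pair records from [delta_dissimilarity()].
#' @param var_equal Passed to [two_sample_ttest()].
#' @return Tidy tibble: `test`, `group`, `n`, `mean_delta_B`, `statistic`,
#'   `df`, `p_value`.
#' @export
delta_b_tests <- function(records, var_equal = TRUE) {
  rows <- lapply(unique(records$group), function(g) {
    d <- records$delta_B[records$group == g]
    tt <- tryCatch(one_sample_ttest(d), error = function(e) NULL)
    if (is.null(tt)) {  # degenerate group (n < 2 or zero variance)
      return(tibble(test = "one_sample_vs_zero", group = g, n = length(d),
                    mean_delta_B = mean(d), statistic = NA_real_,
                    df = NA_real_, p_value = NA_real_))
    }
    tibble(test = "one_sample_vs_zero", group = g, n = tt$n,
           mean_delta_B = tt$estimate, statistic = tt$statistic,
           df = tt$df, p_value = tt$p_value)
  })
  out <- bind_rows(rows)
  groups <- unique(records$group)
  if (all(c("different_treatment", "same_treatment") %in% groups)) {
    tt <- two_sample_ttest(
      records$delta_B[records$group == "different_treatment"],
      records$delta_B[records$group == "same_treatment"],
      var_equal = var_equal
    )
    out <- bind_rows(out, tibble(
      test = if (var_equal) "two_sample_pooled" else "two_sample_welch",
      group = "different_vs_same", n = tt$n, mean_delta_B = tt$estimate,
      statistic = tt$statistic, df = tt$df, p_value = tt$p_value
    ))
  }
  out
}

#' Regression of delta-B on illumination difference
#'
#' Ordinary least squares of the change in dissimilarity on the absolute
#' illumination difference between the two plots of each pair, the test of
#' whether compositional divergence grows with light contrast. By default
#' every different-treatment pair is a point; `aggregate =
#' "treatment_pairs"` first averages delta-B within each unordered treatment
#' pair.
#'
#' @param records Pair records from [delta_dissimilarity()];
#'   different-treatment records are selected automatically.
#' @param aggregate `"pairs"` (default) or `"treatment_pairs"`.
#' @return A `grass_lightreg` object: the `lm` fit plus `slope`,
#'   `intercept`, `r_squared`, `p_value` (slope), `n`. See
#'   [confidence_band()], [tidy.grass_lightreg()].
#' @export
regress_delta_on_light <- function(records,
                                   aggregate = c("pairs", "treatment_pairs")) {
  aggregate <- match.arg(aggregate)
  dat <- records[records$group == "different_treatment", , drop = FALSE]
  if (aggregate == "treatment_pairs") {
    dat <- mutate(dat, tp = paste(pmin(.data$treatment_a, .data$treatment_b),
                                  pmax(.data$treatment_a, .data$treatment_b)))
    dat <- summarise(group_by(dat, .data$tp),
                     delta_B = mean(.data$delta_B),
                     light_diff = .data$light_diff[1], .groups = "drop")
  }
  if (nrow(dat) < 3) {
    abort("need at least 3 records", class = "grass_argument_error")
  }
  if (length(unique(dat$light_diff)) < 2) {
    abort("all light_diff values are equal; slope is not identifiable",
          class = "grass_rank_error")
  }
  fit <- lm(delta_B ~ light_diff, data = dat)
  sm <- summary(fit)
  structure(list(
    model = fit,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients["light_diff", "Pr(>|t|)"],
    n = nrow(dat),
    aggregate = aggregate
  ), class = "grass_lightreg")
}

#' @export
print.grass_lightreg <- function(x, ...) {
  cat(sprintf(
    "<grass_lightreg> slope = %.5g per mol m^-2 d^-1, R^2 = %.3f, p = %.3g, n = %d\n",
    x$slope, x$r_squared, x$p_value, x$n
  ))
  invisible(x)
}

#' Pointwise 95% confidence band of the fitted regression mean
#'
#' @param reg A `grass_lightreg` from [regress_delta_on_light()].
#' @param light_diff Illumination differences at which to evaluate; defaults
#'   to 50 points over the observed range.
#' @param level Confidence level, default 0.95.
#' @return Tibble: `light_diff`, `fit`, `lwr`, `upr`.
#' @export
confidence_band <- function(reg, light_diff = NULL, level = 0.95) {
  obs <- reg$model$model$light_diff
  if (is.null(light_diff)) {
    light_diff <- seq(min(obs), max(obs), length.out = 50)
  }
  pr <- predict(reg$model, newdata = data.frame(light_diff = light_diff),
                interval = "confidence", level = level)
  tibble(light_diff = light_diff, fit = pr[, "fit"],
         lwr = pr[, "lwr"], upr = pr[, "upr"])
}

#' Block-restricted permutation test for the treatment-group contrast
#'
#' The pairwise delta-B values are not independent (each plot enters many
#' pairs), so alongside the plain two-sample t test this permutation test
#' shuffles treatment labels among the plots of each block, reassigns pair
#' groups, and recomputes the two-sample t statistic, giving a
#' design-respecting p-value for the different- vs same-treatment contrast.
#'
#' @param records Plot-level pair records from [delta_dissimilarity()].
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed for the permutation stream.
#' @return List: `observed_t`, `p_value`, `n_perm`.
#' @export
delta_b_permutation <- function(records, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  plots <- distinct(tibble(plot = c(records$unit_a, records$unit_b),
                           block = c(records$block_a, records$block_b),
                           treatment = c(records$treatment_a,
                                         records$treatment_b)))
  t_for <- function(treat_of) {
    same <- treat_of[records$unit_a] == treat_of[records$unit_b]
    two_sample_ttest(records$delta_B[!same], records$delta_B[same])$statistic
  }
  obs <- t_for(setNames(plots$treatment, plots$plot))
  perm_stats <- purrr::map_dbl(seq_len(n_perm), function(i) {
    shuffled <- unlist(lapply(split(plots$treatment, plots$block), sample),
                       use.names = FALSE)
    ord <- order(plots$block)
    treat_of <- setNames(character(nrow(plots)), plots$plot)
    treat_of[plots$plot[ord]] <- shuffled
    t_for(treat_of)
  })
  list(observed_t = obs,
       p_value = (1 + sum(abs(perm_stats) >= abs(obs))) / (n_perm + 1),
       n_perm = n_perm)
}
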