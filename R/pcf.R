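#' Ripley's isotropic edge-correction weight on a rectangle
#'
#' For a point inside a rectangular window and a radius `r`, the weight is
#' the reciprocal of the fraction of the circumference of the circle of
#' radius `r` centred at the point that lies inside the window. Computed by
#' the closed-form rectangle solution: each edge closer than `r` removes an
#' arc `2·acos(d/r)`, and arcs meeting at a corner inside the circle
#' (`d₁² + d₂² < r²`) overlap by `acos(d₁/r) + acos(d₂/r) − π/2`. The weight
#' is 1 exactly when the circle is fully interior and reaches 4 at a corner;
#' it is capped at 4 (the rectangle-corner maximum for small `r`).
#'
#' @param x,y Point coordinates (metres), inside the window; vectorised.
#' @param r Circle radius (metres), > 0; recycled against `x`/`y`.
#' @param window Named `c(width =, height =)` vector.
#' @return Numeric vector of weights ≥ 1.
#' @examples
#' w <- c(width = 1, height = 1)
#' ripley_weight(0.5, 0.5, 0.1, w)  # 1: interior circle
#' ripley_weight(0, 0.5, 0.05, w)   # 2: half circle inside
#' ripley_weight(0, 0, 0.05, w)     # 4: quarter circle inside
#' @export
ripley_weight <- function(x, y, r, window) {
  w <- window[["width"]]
  h <- window[["height"]]
  m <- max(length(x), length(y), length(r))
  x <- rep_len(x, m); y <- rep_len(y, m); r <- rep_len(r, m)
  if (any(x < 0 | x > w | y < 0 | y > h)) {
    abort("point outside window", class = "grass_argument_error")
  }
  if (any(r <= 0)) abort("r must be > 0", class = "grass_argument_error")
  dl <- x; dr <- w - x; dd <- y; du <- h - y
  arc <- function(d) 2 * acos(pmin(d / r, 1))
  ov <- function(d1, d2) {
    pmax(0, acos(pmin(d1 / r, 1)) + acos(pmin(d2 / r, 1)) - pi / 2)
  }
  exterior <- arc(dl) + arc(dr) + arc(dd) + arc(du) -
    ov(dl, dd) - ov(dl, du) - ov(dr, dd) - ov(dr, du)
  frac <- 1 - exterior / (2 * pi)
  pmin(1 / pmax(frac, 1e-12), 4)
}

#' Stoyan's rule-of-thumb bandwidth
#'
#' `h = 0.15 / sqrt(lambda)`, the standard default for kernel pcf
#' estimation, with the intensity estimated as points per window area.
#'
#' @param n Number of points (or a precomputed intensity via `lambda`).
#' @param window Named `c(width =, height =)` vector.
#' @param lambda Optional intensity (points·m⁻²) overriding `n`.
#' @return Bandwidth in metres.
#' @export
stoyan_bandwidth <- function(n, window, lambda = NULL) {
  lam <- lambda %||% (n / (window[["width"]] * window[["height"]]))
  0.15 / sqrt(lam)
}

#' Default distance grid for pcf estimation
#'
#' 101 points from the bandwidth to `min(width, height) / 4` (0.225 m for
#' the default 1.1 × 0.9 m plot). The estimator is not evaluated below the
#' bandwidth, where the `1/r` factor makes it unstable.
#'
#' @param bandwidth Kernel bandwidth in metres.
#' @param window Named `c(width =, height =)` vector.
#' @param length_out Grid length, default 101.
#' @return Strictly increasing numeric vector of distances (metres).
#' @export
default_r_grid <- function(bandwidth, window, length_out = 101) {
  r_max <- min(window[["width"]], window[["height"]]) / 4
  seq(bandwidth, r_max, length.out = length_out)
}

# Epanechnikov kernel with bandwidth h
epanechnikov <- function(t, h) {
  u <- t / h
  ifelse(abs(u) < 1, 0.75 * (1 - u^2) / h, 0)
}

# all unordered point pairs with distance in (0, dmax]
pairs_within <- function(x, y, dmax) {
  n <- length(x)
  jj <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  ii <- sequence(rev(seq_len(n - 1L)), from = seq_len(n - 1L) + 1L)
  d <- sqrt((x[ii] - x[jj])^2 + (y[ii] - y[jj])^2)
  keep <- d <= dmax
  list(i = ii[keep], j = jj[keep], d = d[keep])
}

#' Kernel estimate of the pair correlation function
#'
#' Estimates `g(r)`, the density of further individuals at distance `r`
#' from a typical individual standardised by the squared mean point
#' density, via the kernel sum
#' `ĝ(r) = Σ_{i≠j} e_i(d_ij) κ_h(r − d_ij) / (2πr · λ̂² · |W|)`
#' with the Epanechnikov kernel `κ_h` and, by default, Ripley's isotropic
#' edge weights `e_i` evaluated at point i and radius `d_ij`. Under complete
#' spatial randomness `g ≡ 1`; values < 1 indicate inhibition
#' (regularity), > 1 clustering. Species labels are ignored: the estimate
#' describes the whole community's spatial structure.
#'
#' @param community Data frame with `x`, `y` columns (one plot at one
#'   census), at least 2 points.
#' @param window Named `c(width =, height =)` vector (metres).
#' @param r_grid Distances at which to evaluate; default [default_r_grid()].
#' @param bandwidth Kernel bandwidth; default [stoyan_bandwidth()].
#' @param correction `"isotropic"` (default), `"translation"`, or `"none"`.
#' @param lambda2 Squared-intensity estimator: `"unbiased"` (default,
#'   `n(n−1)/|W|²`) or `"naive"` (`n²/|W|²`).
#' @return Tibble `r`, `g` with attributes `n_points`, `bandwidth`,
#'   `correction`, `window`.
#' @export
pcf_estimate <- function(community, window,
                         r_grid = NULL, bandwidth = NULL,
                         correction = c("isotropic", "translation", "none"),
                         lambda2 = c("unbiased", "naive")) {
  correction <- match.arg(correction)
  lambda2 <- match.arg(lambda2)
  x <- community$x
  y <- community$y
  n <- length(x)
  if (n < 2) {
    abort("pcf estimation needs at least 2 points",
          class = "grass_estimation_error")
  }
  area <- window[["width"]] * window[["height"]]
  h <- bandwidth %||% stoyan_bandwidth(n, window)
  if (is.null(r_grid)) r_grid <- default_r_grid(h, window)
  if (any(r_grid <= 0)) {
    abort("r_grid must be positive", class = "grass_argument_error")
  }
  half_diag <- sqrt(window[["width"]]^2 + window[["height"]]^2) / 2
  dmax <- min(max(r_grid) + h, half_diag)

  pp <- pairs_within(x, y, dmax)
  pw <- switch(correction,
    isotropic = ripley_weight(x[pp$i], y[pp$i], pp$d, window) +
      ripley_weight(x[pp$j], y[pp$j], pp$d, window),
    translation = 2 * area /
      ((window[["width"]] - abs(x[pp$i] - x[pp$j])) *
         (window[["height"]] - abs(y[pp$i] - y[pp$j]))),
    none = rep(2, length(pp$d))
  )
  lam2 <- switch(lambda2,
    unbiased = n * (n - 1) / area^2,
    naive = n^2 / area^2
  )
  g <- vapply(r_grid, function(r) {
    sum(pw * epanechnikov(r - pp$d, h)) / (2 * pi * r * lam2 * area)
  }, numeric(1))
  structure(tibble(r = r_grid, g = g),
            n_points = n, bandwidth = h, correction = correction,
            window = window)
}

#' Between-census change in the pair correlation function of one plot
#'
#' `Δpcf(r) = pcf_t2(r) − pcf_t1(r)` computed on a shared distance grid
#' with one shared bandwidth (from the pooled density of both censuses, so
#' the difference is not confounded by bandwidth changes). Negative values
#' at small `r` indicate a loss of close neighbours (competition), positive
#' values a gain (facilitation).
#'
#' @param community_t1,community_t2 Data frames with `x`, `y` (the same
#'   plot at the two censuses), each with ≥ 2 points.
#' @inheritParams pcf_estimate
#' @return Tibble `r`, `delta` with attributes `bandwidth`, `n_t1`, `n_t2`.
#' @export
delta_pcf <- function(community_t1, community_t2, window,
                      r_grid = NULL, bandwidth = NULL,
                      correction = "isotropic") {
  n1 <- nrow(community_t1)
  n2 <- nrow(community_t2)
  if (n1 < 2 || n2 < 2) {
    abort("each census needs at least 2 points",
          class = "grass_estimation_error")
  }
  area <- window[["width"]] * window[["height"]]
  h <- bandwidth %||% stoyan_bandwidth(NA, window,
                                       lambda = (n1 + n2) / (2 * area))
  if (is.null(r_grid)) r_grid <- default_r_grid(h, window)
  g1 <- pcf_estimate(community_t1, window, r_grid, h, correction)
  g2 <- pcf_estimate(community_t2, window, r_grid, h, correction)
  structure(tibble(r = r_grid, delta = g2$g - g1$g),
            bandwidth = h, n_t1 = n1, n_t2 = n2)
}

#' Per-plot delta-pcf curves for a whole experiment
#'
#' Computes [delta_pcf()] for every plot on one shared grid and bandwidth
#' (from the experiment-wide pooled density of both censuses) so replicate
#' curves are directly comparable. Plots with fewer than 2 individuals at
#' either census are excluded with a message.
#'
#' @param experiment A two-census [grass_experiment()].
#' @inheritParams pcf_estimate
#' @return Tibble `plot_id`, `block_id`, `treatment`, `r`, `delta`;
#'   attributes `bandwidth`, `r_grid`, `excluded` (plot ids).
#' @export
delta_pcf_by_plot <- function(experiment, r_grid = NULL, bandwidth = NULL,
                              correction = "isotropic") {
  df <- as_tibble(experiment)
  window <- exp_window(experiment)
  area <- window[["width"]] * window[["height"]]
  counts <- count(df, .data$plot_id, .data$census)
  wide <- tidyr::pivot_wider(counts, names_from = "census",
                             values_from = "n", values_fill = 0L)
  if (!all(c("t1", "t2") %in% names(wide))) {
    abort("experiment must contain both censuses", class = "grass_argument_error")
  }
  ok <- wide$plot_id[wide$t1 >= 2 & wide$t2 >= 2]
  excluded <- setdiff(unique(df$plot_id), ok)
  if (length(excluded) > 0) {
    message(length(excluded), " plot(s) excluded from delta-pcf (< 2 points ",
            "at a census): ", paste(excluded, collapse = ", "))
  }
  mean_n <- mean(c(wide$t1[wide$plot_id %in% ok], wide$t2[wide$plot_id %in% ok]))
  h <- bandwidth %||% stoyan_bandwidth(NA, window, lambda = mean_n / area)
  if (is.null(r_grid)) r_grid <- default_r_grid(h, window)

  curves <- purrr::map_dfr(ok, function(pid) {
    sub <- df[df$plot_id == pid, , drop = FALSE]
    dp <- delta_pcf(sub[sub$census == "t1", ], sub[sub$census == "t2", ],
                    window, r_grid = r_grid, bandwidth = h,
                    correction = correction)
    tibble(plot_id = pid, block_id = sub$block_id[1],
           treatment = sub$treatment[1], r = dp$r, delta = dp$delta)
  })
  structure(curves, bandwidth = h, r_grid = r_grid, excluded = excluded)
}

#' Replicate mean and confidence band of delta-pcf curves
#'
#' Pointwise mean across replicate plots with either the 95% t-interval
#' (`mean ± t_{0.975, n−1}·SE`, default) or a mean ± 1 SD band.
#'
#' @param curves Tibble of per-replicate curves with columns `r`, `delta`
#'   and a replicate identifier column (`plot_id` by default).
#' @param band_type `"t_ci_95"` or `"mean_pm_1sd"`.
#' @param replicate_col Column identifying replicates.
#' @return Tibble `r`, `mean_delta`, `ci_low`, `ci_high`, `n_replicates`,
#'   `band_type`.
#' @export
replicate_band <- function(curves, band_type = c("t_ci_95", "mean_pm_1sd"),
                           replicate_col = "plot_id") {
  band_type <- match.arg(band_type)
  grids <- split(curves$r, curves[[replicate_col]])
  if (length(grids) < 2) {
    abort("need at least 2 replicate curves", class = "grass_argument_error")
  }
  first <- grids[[1]]
  if (!all(vapply(grids, function(g) length(g) == length(first) &&
                    all(g == first), logical(1)))) {
    abort("replicate curves must share the same r grid",
          class = "grass_argument_error")
  }
  out <- summarise(group_by(curves, .data$r),
                   mean_delta = mean(.data$delta),
                   sd_delta = sd(.data$delta),
                   n_replicates = dplyr::n(),
                   .groups = "drop")
  half <- if (band_type == "t_ci_95") {
    qt(0.975, out$n_replicates - 1) * out$sd_delta / sqrt(out$n_replicates)
  } else {
    out$sd_delta
  }
  mutate(select(out, -"sd_delta"),
         ci_low = .data$mean_delta - half,
         ci_high = .data$mean_delta + half,
         band_type = band_type)
}

#' Classify biotic interactions from a delta-pcf band
#'
#' Applies the sign rule: where the whole band lies below zero the change
#' in relative neighbourhood density is read as a negative interaction
#' (competition), where it lies wholly above zero as positive
#' (facilitation), otherwise no call.
#'
#' @param band Output of [replicate_band()] (optionally grouped by extra
#'   columns such as `treatment`).
#' @return `band` with a `classification` column in
#'   `{"negative", "positive", "none"}`.
#' @export
classify_interactions <- function(band) {
  mutate(band, classification = dplyr::case_when(
    .data$ci_high < 0 ~ "negative",
    .data$ci_low > 0 ~ "positive",
    TRUE ~ "none"
  ))
}

#' Per-treatment delta-pcf summary with interaction calls
#'
#' Composes [delta_pcf_by_plot()], [replicate_band()] (one band per
#' treatment across its replicate plots) and [classify_interactions()].
#'
#' @param experiment A two-census [grass_experiment()].
#' @inheritParams delta_pcf_by_plot
#' @inheritParams replicate_band
#' @return Tibble `treatment`, `r`, `mean_delta`, `ci_low`, `ci_high`,
#'   `n_replicates`, `band_type`, `classification`; attribute `bandwidth`.
#' @export
delta_pcf_summary <- function(experiment, r_grid = NULL, bandwidth = NULL,
                              correction = "isotropic",
                              band_type = c("t_ci_95", "mean_pm_1sd")) {
  band_type <- match.arg(band_type)
  curves <- delta_pcf_by_plot(experiment, r_grid = r_grid,
                              bandwidth = bandwidth, correction = correction)
  out <- purrr::map_dfr(split(curves, curves$treatment), function(tc) {
    if (length(unique(tc$plot_id)) < 2) {
      message("treatment '", tc$treatment[1],
              "' skipped: fewer than 2 replicate curves")
      return(NULL)
    }
    band <- replicate_band(tc, band_type = band_type)
    tibble(treatment = tc$treatment[1], band)
  })
  if (nrow(out) == 0) {
    out <- tibble(treatment = character(0), r = numeric(0),
                  mean_delta = numeric(0), n_replicates = integer(0),
                  ci_low = numeric(0), ci_high = numeric(0),
                  band_type = character(0))
  }
  structure(classify_interactions(out),
            bandwidth = attr(curves, "bandwidth", exact = TRUE))
}
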