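# Fixture builders shared across test files. Everything is generated in code.

# a tiny valid two-census experiment (one plot, deterministic coordinates)
tiny_experiment <- function() {
  ind <- tibble::tibble(
    plot_id = "p1", block_id = "b1", treatment = "strong",
    census = rep(c("t1", "t2"), each = 2),
    species_id = c("A", "B", "A", "B"),
    x = c(0.2, 0.8, 0.2, 0.8),
    y = c(0.1, 0.5, 0.1, 0.5)
  )
  grass_experiment(ind, light_map = c(strong = 10))
}

# a random plot as a plain individuals tibble (window defaults to 1.1 x 0.9)
random_plot <- function(n, width = 1.1, height = 0.9, plot_id = "p1",
                        census = "t1", n_species = 5) {
  tibble::tibble(
    plot_id = plot_id, block_id = "b1", treatment = "no", census = census,
    species_id = sample(sprintf("sp%d", seq_len(n_species)), n, replace = TRUE),
    x = runif(n, 0, width), y = runif(n, 0, height)
  )
}

# uniform CSR point set in a window (coordinates only)
csr_points <- function(n, window = c(width = 1.1, height = 0.9)) {
  tibble::tibble(x = runif(n, 0, window[["width"]]),
                 y = runif(n, 0, window[["height"]]))
}

# numeric oracle for the edge-correction weight: midpoint-rule integration of
# the inside-window indicator over the circle of radius r
covered_fraction_numeric <- function(px, py, r, window, n_samples = 1e6) {
  theta <- (seq_len(n_samples) - 0.5) / n_samples * 2 * pi
  qx <- px + r * cos(theta)
  qy <- py + r * sin(theta)
  mean(qx >= 0 & qx <= window[["width"]] & qy >= 0 & qy <= window[["height"]])
}

# textbook pooled two-sample t statistic
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# textbook OLS slope/intercept/R^2
ols_oracle <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}
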