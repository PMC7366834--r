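#' Configuration for the synthetic shading experiment
#'
#' Bundles every knob of the generator. The defaults reproduce the design of
#' a blocked understory shading experiment: 12 blocks × 4 shading
#' treatments = 48 plots of 1.1 × 0.9 m regenerating from one shared seed
#' bank, an initial census of about 986 individuals per plot (≈ 47,300 over
#' the field) from a 39-species pool, and a second census after
#' light-dependent and crowding-dependent mortality calibrated to an
#' overall decline to ≈ 59% of the initial count.
#'
#' @param n_blocks Number of blocks; each block holds one plot per treatment.
#' @param light_map Named treatment → illumination map (mol·m⁻²·d⁻¹).
#' @param window Plot window `c(width =, height =)` in metres.
#' @param n_species Species-pool size S.
#' @param abundance_model `"lognormal"` (rank-abundance realism) or
#'   `"uniform"` seed-bank proportions.
#' @param sigma_logn Log-scale SD of the lognormal abundance model.
#' @param lambda0 Initial density, individuals·m⁻².
#' @param spatial_model `"csr"` (homogeneous Poisson positions) or
#'   `"thomas"` (Poisson cluster process: Gaussian-dispersed offspring
#'   around uniform parents, modelling clumped germination).
#' @param thomas_kappa Parent intensity (parents·m⁻²) of the Thomas model.
#' @param thomas_sd Cluster dispersal SD ω in metres.
#' @param filtering_strength Light-filtering exponent φ ≥ 0; 0 disables
#'   filtering.
#' @param competition_strength Crowding coefficient c in the survival factor
#'   `exp(-c * n_r)`; positive = competition, negative = facilitation,
#'   0 disables interactions.
#' @param competition_radius Neighbourhood radius r_c in metres.
#' @param baseline_survival Baseline survival probability p₀ ∈ (0, 1].
#' @param tolerance_range Range of the uniform draw for species light
#'   tolerances σ_s (mol·m⁻²·d⁻¹).
#' @param recruitment_rate Expected recruits between censuses as a fraction
#'   of `lambda0` (0 = off). Recruits are drawn from the seed-bank
#'   proportions with uniform positions, so a rate of `1 - p` exactly
#'   restores the expected t1 density after survival `p`.
#' @param seed Integer root seed; every stage derives its own stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_blocks = 12,
                       light_map = default_light_map(),
                       window = c(width = 1.1, height = 0.9),
                       n_species = 39,
                       abundance_model = c("lognormal", "uniform"),
                       sigma_logn = 1,
                       lambda0 = 47322 / 48 / (1.1 * 0.9),
                       spatial_model = c("csr", "thomas"),
                       thomas_kappa = 60,
                       thomas_sd = 0.03,
                       filtering_strength = 1,
                       competition_strength = 0.015,
                       competition_radius = 0.05,
                       baseline_survival = 0.90,
                       tolerance_range = c(12, 24),
                       recruitment_rate = 0,
                       seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  spatial_model <- match.arg(spatial_model)
  if (n_species < 1) abort("n_species must be >= 1", class = "grass_argument_error")
  if (lambda0 <= 0) abort("lambda0 must be > 0", class = "grass_argument_error")
  if (competition_radius <= 0) {
    abort("competition_radius must be > 0", class = "grass_argument_error")
  }
  if (baseline_survival <= 0 || baseline_survival > 1) {
    abort("baseline_survival must be in (0, 1]", class = "grass_argument_error")
  }
  if (filtering_strength < 0) {
    abort("filtering_strength must be >= 0", class = "grass_argument_error")
  }
  if (length(light_map) < 1 || is.null(names(light_map))) {
    abort("light_map must be a named numeric vector", class = "grass_argument_error")
  }
  structure(list(
    n_blocks = n_blocks, light_map = light_map, window = window,
    n_species = n_species, abundance_model = abundance_model,
    sigma_logn = sigma_logn, lambda0 = lambda0,
    spatial_model = spatial_model, thomas_kappa = thomas_kappa,
    thomas_sd = thomas_sd,
    filtering_strength = filtering_strength,
    competition_strength = competition_strength,
    competition_radius = competition_radius,
    baseline_survival = baseline_survival,
    tolerance_range = tolerance_range,
    recruitment_rate = recruitment_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# deterministic per-stage seed derived from the root seed, kept in 32-bit range
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage * 1000003) %% 2147483587
}

#' Build a species pool
#'
#' Draws seed-bank proportions from the configured abundance model
#' (normalised to sum to 1), a light optimum μ_s uniform over the range of
#' the configured illuminations, and a light tolerance σ_s uniform over
#' `tolerance_range`. Fully determined by the config seed.
#'
#' @param config A [sim_config()].
#' @param seed Override the stage seed (defaults to a stream derived from
#'   `config$seed`).
#' @return Tibble: `species_id`, `proportion`, `light_optimum`,
#'   `light_tolerance`.
#' @export
build_species_pool <- function(config, seed = stage_seed(config$seed, 1)) {
  s <- config$n_species
  set.seed(seed)
  raw <- switch(config$abundance_model,
    lognormal = rlnorm(s, meanlog = 0, sdlog = config$sigma_logn),
    uniform = rep(1, s)
  )
  lrange <- range(config$light_map)
  tibble(
    species_id = sprintf("sp%02d", seq_len(s)),
    proportion = raw / sum(raw),
    light_optimum = runif(s, lrange[1], lrange[2]),
    light_tolerance = runif(s, config$tolerance_range[1],
                            config$tolerance_range[2])
  )
}

# N point positions in the window under the configured spatial model
draw_positions <- function(n, config) {
  w <- config$window[["width"]]
  h <- config$window[["height"]]
  if (n == 0) return(tibble(x = numeric(0), y = numeric(0)))
  if (config$spatial_model == "csr") {
    return(tibble(x = runif(n, 0, w), y = runif(n, 0, h)))
  }
  # Thomas: uniform parents inside the window, Gaussian offsets, offspring
  # falling outside the window rejected and redrawn until n are accepted
  n_par <- max(1L, rpois(1, config$thomas_kappa * w * h))
  px <- runif(n_par, 0, w)
  py <- runif(n_par, 0, h)
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- 2L * (n - length(xs)) + 10L
    par <- sample.int(n_par, m, replace = TRUE)
    cx <- px[par] + rnorm(m, 0, config$thomas_sd)
    cy <- py[par] + rnorm(m, 0, config$thomas_sd)
    keep <- cx >= 0 & cx <= w & cy >= 0 & cy <= h
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  tibble(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Simulate the initial census
#'
#' One plot per block × treatment. Each plot's individual count is
#' Poisson(λ₀·|W|); species labels are i.i.d. draws from the shared
#' seed-bank proportions (every plot has the same expected composition);
#' positions follow the configured spatial model.
#'
#' @inheritParams build_species_pool
#' @param pool Species pool from [build_species_pool()].
#' @return A t1-only [grass_experiment()].
#' @export
simulate_initial_census <- function(pool, config,
                                    seed = stage_seed(config$seed, 2)) {
  set.seed(seed)
  area <- config$window[["width"]] * config$window[["height"]]
  treatments <- names(config$light_map)
  layout <- tidyr::expand_grid(block = seq_len(config$n_blocks),
                               treatment = treatments)
  rows <- purrr::pmap_dfr(layout, function(block, treatment) {
    n <- rpois(1, config$lambda0 * area)
    pos <- draw_positions(n, config)
    tibble(
      plot_id = sprintf("b%02d_%s", block, treatment),
      block_id = sprintf("b%02d", block),
      treatment = treatment,
      census = "t1",
      species_id = sample(pool$species_id, n, replace = TRUE,
                          prob = pool$proportion),
      x = pos$x, y = pos$y
    )
  })
  grass_experiment(rows, window = config$window,
                   light_map = config$light_map, require_paired = FALSE)
}

# neighbours within radius r_c (self excluded)
neighbour_counts <- function(x, y, r_c) {
  n <- length(x)
  if (n <= 1) return(rep(0L, n))
  pp <- pairs_within(x, y, r_c)
  tabulate(c(pp$i, pp$j), nbins = n)
}

#' Simulate between-census survival (and optional recruitment)
#'
#' Each t1 individual survives independently with probability
#' `p = min(1, p0 * F^phi * exp(-c * n_r))`, where
#' `F = exp(-(L - mu_s)^2 / (2 sigma_s^2))` is the light-match factor for the
#' plot's treatment illumination `L`, and `n_r` is the number of t1
#' neighbours within `competition_radius` (crowding is evaluated on the t1
#' configuration so survival events are independent given t1). Survivors
#' retain their coordinates. With `recruitment_rate > 0`, Poisson recruits
#' drawn from the seed-bank proportions with uniform positions are added at
#' t2.
#'
#' @param experiment_t1 A t1-only [grass_experiment()] (t2 rows, if present,
#'   are ignored and regenerated).
#' @inheritParams simulate_initial_census
#' @return A [grass_experiment()] holding both censuses.
#' @export
simulate_dynamics <- function(experiment_t1, pool, config,
                              seed = stage_seed(config$seed, 3)) {
  set.seed(seed)
  df <- as_tibble(experiment_t1)
  df <- df[df$census == "t1", , drop = FALSE]
  if (nrow(df) == 0) abort("no t1 individuals", class = "grass_argument_error")
  area <- config$window[["width"]] * config$window[["height"]]
  phi <- config$filtering_strength
  cc <- config$competition_strength
  p0 <- config$baseline_survival

  mu <- setNames(pool$light_optimum, pool$species_id)
  sig <- setNames(pool$light_tolerance, pool$species_id)

  survivors <- vector("list", 0)
  emptied <- character(0)
  for (pid in unique(df$plot_id)) {
    sub <- df[df$plot_id == pid, , drop = FALSE]
    l_treat <- config$light_map[[sub$treatment[1]]]
    f_light <- exp(-(l_treat - mu[sub$species_id])^2 /
                     (2 * sig[sub$species_id]^2))
    n_r <- if (cc != 0) {
      neighbour_counts(sub$x, sub$y, config$competition_radius)
    } else 0L
    p_surv <- pmin(1, p0 * f_light^phi * exp(-cc * n_r))
    alive <- rbinom(nrow(sub), 1, p_surv) == 1
    t2 <- sub[alive, , drop = FALSE]

    n_rec <- if (config$recruitment_rate > 0) {
      rpois(1, config$recruitment_rate * config$lambda0 * area)
    } else 0L
    if (n_rec > 0) {
      t2 <- bind_rows(t2, tibble(
        plot_id = pid, block_id = sub$block_id[1],
        treatment = sub$treatment[1], census = "t1",
        species_id = sample(pool$species_id, n_rec, replace = TRUE,
                            prob = pool$proportion),
        x = runif(n_rec, 0, config$window[["width"]]),
        y = runif(n_rec, 0, config$window[["height"]])
      ))
    }
    if (nrow(t2) == 0) emptied <- c(emptied, pid)
    t2$census <- "t2"
    survivors[[pid]] <- t2
  }
  if (length(emptied) > 0) {
    warn(paste0("plot(s) emptied entirely at t2: ",
                paste(emptied, collapse = ", ")))
  }
  grass_experiment(bind_rows(df, bind_rows(survivors)),
                   window = config$window, light_map = config$light_map,
                   require_paired = FALSE)
}

#' Generate a complete synthetic experiment
#'
#' Composes [build_species_pool()] → [simulate_initial_census()] →
#' [simulate_dynamics()] under the block layout (each block contains one
#' plot per shading treatment; 48 plots under defaults). Identical configs
#' and seeds give identical experiments.
#'
#' @param config A [sim_config()].
#' @return A two-census [grass_experiment()].
#' @examples
#' exp <- generate_experiment(sim_config(n_blocks = 2, lambda0 = 50, seed = 7))
#' dplyr::count(tibble::as_tibble(exp), census)
#' @export
generate_experiment <- function(config = sim_config()) {
  pool <- build_species_pool(config)
  t1 <- simulate_initial_census(pool, config)
  simulate_dynamics(t1, pool, config)
}
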