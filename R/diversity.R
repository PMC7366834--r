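#' Diversity indices of an abundance vector
#'
#' Shannon–Wiener diversity H = −Σ pᵢ ln pᵢ (nats), Simpson diversity
#' D = 1 − Σ pᵢ², and Pielou's evenness J = H / ln(richness). J is undefined
#' (returned as `NA`) for a single-species community.
#'
#' @param counts Named non-negative abundance vector with positive total
#'   (as from [abundance_vector()]).
#' @return One-row tibble: `richness`, `shannon`, `simpson`, `pielou`.
#' @examples
#' diversity_indices(c(A = 1, B = 1, C = 1, D = 1)) # H = log(4), J = 1
#' @export
diversity_indices <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0 || sum(counts) <= 0) {
    abort("`counts` must contain at least one individual",
          class = "grass_argument_error")
  }
  s <- length(counts)
  h <- as.numeric(vegan::diversity(counts, index = "shannon"))
  d <- as.numeric(vegan::diversity(counts, index = "simpson"))
  tibble(
    richness = s,
    shannon = h,
    simpson = d,
    pielou = if (s > 1) h / log(s) else NA_real_
  )
}

#' Per-plot diversity at each census
#'
#' @param experiment A [grass_experiment()].
#' @return Tibble with one row per plot × census: `plot_id`, `block_id`,
#'   `treatment`, `census`, `n_individuals`, and the [diversity_indices()]
#'   columns. Plots empty at a census get an `NA` row (flagged by
#'   `n_individuals = 0`).
#' @export
plot_diversity <- function(experiment) {
  df <- as_tibble(experiment)
  keys <- distinct(df, .data$plot_id, .data$block_id, .data$treatment)
  grid <- tidyr::expand_grid(keys, census = sort(unique(df$census)))
  purrr::pmap_dfr(grid, function(plot_id, block_id, treatment, census) {
    sub <- df[df$plot_id == plot_id & df$census == census, , drop = FALSE]
    idx <- if (nrow(sub) > 0) {
      diversity_indices(abundance_vector(sub))
    } else {
      tibble(richness = NA_integer_, shannon = NA_real_,
             simpson = NA_real_, pielou = NA_real_)
    }
    tibble(plot_id = plot_id, block_id = block_id, treatment = treatment,
           census = census, n_individuals = nrow(sub), idx)
  })
}

#' Per-treatment summary of diversity change
#'
#' For each plot, each index at t1 and t2 and its change (t2 − t1); then per
#' treatment the mean and standard error of the changes across plots.
#'
#' @param experiment A [grass_experiment()] with both censuses.
#' @return List with `plots` (per-plot values and changes) and `treatments`
#'   (per treatment × index: `mean_change`, `se_change`, `n_plots`).
#' @export
diversity_change_summary <- function(experiment) {
  idx_cols <- c("richness", "shannon", "simpson", "pielou")
  pd <- plot_diversity(experiment)
  wide <- tidyr::pivot_wider(
    pd, id_cols = c("plot_id", "block_id", "treatment"),
    names_from = "census",
    values_from = all_of(c("n_individuals", idx_cols))
  )
  for (col in idx_cols) {
    wide[[paste0("d_", col)]] <-
      wide[[paste0(col, "_t2")]] - wide[[paste0(col, "_t1")]]
  }
  long <- tidyr::pivot_longer(
    wide[c("plot_id", "treatment", paste0("d_", idx_cols))],
    cols = all_of(paste0("d_", idx_cols)),
    names_to = "index", values_to = "change", names_prefix = "d_"
  )
  treatments <- summarise(
    group_by(long, .data$treatment, .data$index),
    mean_change = mean(.data$change, na.rm = TRUE),
    se_change = sd(.data$change, na.rm = TRUE) /
      sqrt(sum(!is.na(.data$change))),
    n_plots = sum(!is.na(.data$change)),
    .groups = "drop"
  )
  list(plots = wide, treatments = treatments)
}
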