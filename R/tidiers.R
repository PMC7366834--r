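#' Tidy a grass_ttest
#'
#' @param x A `grass_ttest` from [one_sample_ttest()] or
#'   [two_sample_ttest()].
#' @param ... Unused.
#' @return One-row tibble: `type`, `estimate`, `statistic`, `df`,
#'   `p_value`, `std_error`, `n` (plus group means for two-sample tests).
#' @method tidy grass_ttest
#' @export
tidy.grass_ttest <- function(x, ...) {
  out <- tibble(type = x$type, estimate = x$estimate,
                statistic = x$statistic, df = x$df, p_value = x$p_value,
                std_error = x$se, n = x$n)
  if (!is.null(x$group_means)) {
    out$mean_a <- x$group_means[["a"]]
    out$mean_b <- x$group_means[["b"]]
  }
  out
}

#' @rdname tidy.grass_ttest
#' @method glance grass_ttest
#' @export
glance.grass_ttest <- function(x, ...) tidy(x, ...)

#' Tidy the illumination regression
#'
#' @param x A `grass_lightreg` from [regress_delta_on_light()].
#' @param ... Unused.
#' @return `tidy()`: one-row tibble with `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`; `glance()` adds residual df and sigma.
#' @method tidy grass_lightreg
#' @export
tidy.grass_lightreg <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         p_value = x$p_value, n = x$n, aggregate = x$aggregate)
}

#' @rdname tidy.grass_lightreg
#' @method glance grass_lightreg
#' @export
glance.grass_lightreg <- function(x, ...) {
  sm <- summary(x$model)
  mutate(tidy(x), sigma = sm$sigma, df_residual = x$model$df.residual)
}
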