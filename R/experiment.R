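#' Construct a mapped two-census experiment
#'
#' A `grass_experiment` is a tibble of mapped individuals — one row per plant
#' per census — together with the plot window geometry and the treatment →
#' illumination map. It is the unit every analysis function in the package
#' consumes.
#'
#' @param individuals Data frame with columns `plot_id`, `block_id`,
#'   `treatment`, `census`, `species_id`, `x`, `y`. Coordinates are metres
#'   from the lower-left corner of the plot window. `census` must be `"t1"`
#'   or `"t2"`.
#' @param window Named numeric vector `c(width =, height =)` in metres,
#'   shared by all plots.
#' @param light_map Named numeric vector mapping each treatment name to its
#'   illumination in mol·m⁻²·d⁻¹.
#' @param require_paired If `TRUE` (default), every `plot_id` must appear at
#'   both censuses. Set `FALSE` for single-census (t1-only) experiments.
#'
#' @return A tibble of class `grass_experiment` carrying `window` and
#'   `light_map` as attributes (see [exp_window()], [exp_light_map()]).
#' @examples
#' ind <- tibble::tibble(
#'   plot_id = "p1", block_id = "b1", treatment = "strong",
#'   census = c("t1", "t1", "t2"), species_id = c("A", "B", "A"),
#'   x = c(0.2, 0.5, 0.2), y = c(0.1, 0.4, 0.1)
#' )
#' grass_experiment(ind, light_map = c(strong = 10), require_paired = TRUE)
#' @export
grass_experiment <- function(individuals,
                             window = c(width = 1.1, height = 0.9),
                             light_map = default_light_map(),
                             require_paired = TRUE) {
  required <- c("plot_id", "block_id", "treatment", "census", "species_id",
                "x", "y")
  missing_cols <- setdiff(required, names(individuals))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "grass_format_error")
  }
  if (!is.numeric(window) || length(window) != 2 ||
      !all(c("width", "height") %in% names(window)) ||
      any(window[c("width", "height")] <= 0)) {
    abort("`window` must be c(width = w, height = h) with w, h > 0",
          class = "grass_argument_error")
  }
  window <- window[c("width", "height")]

  ind <- as_tibble(individuals)[required]
  ind$x <- as.numeric(ind$x)
  ind$y <- as.numeric(ind$y)
  for (col in c("plot_id", "block_id", "treatment", "census", "species_id")) {
    ind[[col]] <- as.character(ind[[col]])
  }

  bad_census <- setdiff(unique(ind$census), c("t1", "t2"))
  if (length(bad_census) > 0) {
    abort(paste0("census labels must be 't1' or 't2'; found: ",
                 paste(bad_census, collapse = ", ")),
          class = "grass_format_error")
  }
  if (any(!nzchar(ind$species_id)) || anyNA(ind$species_id)) {
    abort("species_id must be non-empty", class = "grass_validation_error")
  }
  out_of_window <- which(
    is.na(ind$x) | is.na(ind$y) |
      ind$x < 0 | ind$x > window[["width"]] |
      ind$y < 0 | ind$y > window[["height"]]
  )
  if (length(out_of_window) > 0) {
    i <- out_of_window[1]
    abort(sprintf(
      "coordinate outside the %g x %g m window: plot '%s', row %d (x = %g, y = %g)",
      window[["width"]], window[["height"]], ind$plot_id[i], i, ind$x[i], ind$y[i]
    ), class = "grass_validation_error")
  }

  missing_treat <- setdiff(unique(ind$treatment), names(light_map))
  if (length(missing_treat) > 0) {
    abort(paste0("treatment(s) missing from light_map: ",
                 paste(missing_treat, collapse = ", ")),
          class = "grass_config_error")
  }

  if (require_paired) {
    t1_plots <- unique(ind$plot_id[ind$census == "t1"])
    t2_plots <- unique(ind$plot_id[ind$census == "t2"])
    unpaired <- c(setdiff(t1_plots, t2_plots), setdiff(t2_plots, t1_plots))
    if (length(unpaired) > 0) {
      abort(paste0("plot(s) present at only one census: ",
                   paste(unpaired, collapse = ", ")),
            class = "grass_pairing_error")
    }
  }

  new_grass_experiment(ind, window, light_map)
}

new_grass_experiment <- function(ind, window, light_map) {
  structure(ind,
            window = window,
            light_map = light_map,
            class = c("grass_experiment", class(tibble())))
}

#' Window and light map accessors
#'
#' @param experiment A [grass_experiment()].
#' @return `exp_window()`: named numeric `c(width, height)` in metres;
#'   `exp_light_map()`: named numeric of illuminations (mol·m⁻²·d⁻¹).
#' @export
exp_window <- function(experiment) attr(experiment, "window", exact = TRUE)

#' @rdname exp_window
#' @export
exp_light_map <- function(experiment) attr(experiment, "light_map", exact = TRUE)

#' Default treatment illumination map
#'
#' Strong shade is the measured understory value of 10 mol·m⁻²·d⁻¹; the
#' three lighter treatments are an assumed evenly spaced gradient
#' (no = 40, low = 30, moderate = 20), configurable everywhere they enter.
#'
#' @return Named numeric vector of illuminations in mol·m⁻²·d⁻¹.
#' @export
default_light_map <- function() {
  c(no = 40, low = 30, moderate = 20, strong = 10)
}

#' @export
print.grass_experiment <- function(x, ...) {
  w <- exp_window(x)
  cat(sprintf(
    "<grass_experiment> %d individuals | %d plot(s) | censuses: %s | window %g x %g m\n",
    nrow(x), length(unique(x$plot_id)),
    paste(sort(unique(x$census)), collapse = ", "),
    w[["width"]], w[["height"]]
  ))
  NextMethod()
}

census_columns <- function() {
  c("plot_id", "block_id", "treatment", "census", "species_id", "x", "y")
}

#' Read a census file
#'
#' Reads the package's delimited census format: a UTF-8 CSV with header
#' `plot_id,block_id,treatment,census,species_id,x,y` and dot decimal
#' separators. Window dimensions and the illumination map come from a JSON
#' metadata sidecar (`<path>.json`, as written by [write_census()]) when one
#' exists, otherwise from the `window` / `light_map` arguments.
#'
#' @param path Path to the CSV file.
#' @inheritParams grass_experiment
#' @return A validated [grass_experiment()]. Row order in the file never
#'   affects downstream results.
#' @seealso [write_census()]
#' @export
read_census <- function(path,
                        window = c(width = 1.1, height = 0.9),
                        light_map = default_light_map(),
                        require_paired = TRUE) {
  spec <- list(
    plot_id = readr::col_character(), block_id = readr::col_character(),
    treatment = readr::col_character(), census = readr::col_character(),
    species_id = readr::col_character(), x = readr::col_double(),
    y = readr::col_double()
  )
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  df <- readr::read_csv(path, col_types = do.call(
    readr::cols, c(spec[intersect(names(spec), header)],
                   .default = list(readr::col_character()))
  ))
  missing_cols <- setdiff(census_columns(), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("census file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "grass_format_error")
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$window)) {
      window <- c(width = as.numeric(meta$window[["width"]]),
                  height = as.numeric(meta$window[["height"]]))
    }
    if (!is.null(meta$light_map)) {
      light_map <- unlist(meta$light_map)
    }
  }
  grass_experiment(df, window = window, light_map = light_map,
                   require_paired = require_paired)
}

#' Write a census file
#'
#' Writes the experiment as CSV with a deterministic column order and row
#' sort (`plot_id`, `census`, `species_id`, `x`, `y`) so outputs are
#' diffable, plus a JSON metadata sidecar (`<path>.json`) recording the
#' window and light map so [read_census()] round-trips losslessly.
#'
#' @param experiment A [grass_experiment()].
#' Coordinates are serialized at fixed nanometre precision.
#'
#' @param path Output CSV path.
#' @param sidecar Write the metadata sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_census <- function(experiment, path, sidecar = TRUE) {
  df <- as_tibble(experiment)[census_columns()]
  df <- arrange(df, .data$plot_id, .data$census, .data$species_id,
                .data$x, .data$y)
  # nanometre-precision fixed format: byte-stable across write/read cycles
  df$x <- sprintf("%.9f", df$x)
  df$y <- sprintf("%.9f", df$y)
  readr::write_csv(df, path)
  if (sidecar) {
    w <- exp_window(experiment)
    meta <- list(window = list(width = w[["width"]], height = w[["height"]]),
                 light_map = as.list(exp_light_map(experiment)))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Species abundance vector of one community
#'
#' @param community Data frame of individuals (any rows of a
#'   [grass_experiment()] belonging to one plot/subplot at one census).
#' @return Named integer vector of per-species counts; species absent from
#'   the community are absent from the vector. Empty community → empty
#'   vector.
#' @examples
#' abundance_vector(data.frame(species_id = c("A", "A", "B")))
#' @export
abundance_vector <- function(community) {
  if (nrow(community) == 0) {
    return(setNames(integer(0), character(0)))
  }
  tab <- table(community$species_id)
  setNames(as.integer(tab), names(tab))
}

#' Plot-by-species abundance table
#'
#' Wide abundance matrix for one census, suitable for [vegan::vegdist()].
#'
#' @param experiment A [grass_experiment()] (or any individuals data frame).
#' @param census Census label to tabulate, `"t1"` or `"t2"`.
#' @param unit Column naming the community unit (default `"plot_id"`).
#' @return Tibble with one row per unit and one count column per species.
#' @export
abundance_table <- function(experiment, census, unit = "plot_id") {
  df <- as_tibble(experiment)
  df <- df[df$census == census, , drop = FALSE]
  counts <- count(df, .data[[unit]], .data$species_id)
  tidyr::pivot_wider(counts, names_from = "species_id", values_from = "n",
                     values_fill = 0L)
}

#' Split plots into a subplot grid
#'
#' Divides each plot window into `ncols` × `nrows` equal axis-aligned cells
#' (defaults give the 6-subplot layout of a 1.1 × 0.9 m plot). Cells are
#' half-open, `[x0, x1) × [y0, y1)`, closed on the plot's maximum edges, so
#' every individual lands in exactly one subplot. Subplot coordinates are
#' re-expressed relative to the subplot origin.
#'
#' @param experiment A [grass_experiment()].
#' @param ncols,nrows Grid dimensions, each ≥ 1 (default 3 × 2).
#' @return A tibble like `experiment` with extra columns `subplot_id`
#'   (`"<plot_id>:s<col><row>"`), `sub_x`, `sub_y`, and attribute
#'   `subplot_window` (the per-cell width/height).
#' @export
split_subplots <- function(experiment, ncols = 3, nrows = 2) {
  if (ncols < 1 || nrows < 1 || ncols != round(ncols) || nrows != round(nrows)) {
    abort("`ncols` and `nrows` must be integers >= 1",
          class = "grass_argument_error")
  }
  w <- exp_window(experiment)
  cw <- w[["width"]] / ncols
  ch <- w[["height"]] / nrows
  df <- as_tibble(experiment)
  col <- pmin(floor(df$x / cw), ncols - 1)   # max edge closes the last cell
  row <- pmin(floor(df$y / ch), nrows - 1)
  df$subplot_id <- sprintf("%s:s%d%d", df$plot_id, col + 1, row + 1)
  df$sub_x <- df$x - col * cw
  df$sub_y <- df$y - row * ch
  structure(df,
            subplot_window = c(width = cw, height = ch),
            subplot_grid = c(ncols = ncols, nrows = nrows))
}
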