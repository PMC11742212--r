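#' @importFrom ggplot2 autoplot ggplot aes
#' @export
ggplot2::autoplot

choropleth_base <- function(regions) {
  df <- regions_to_df(regions)
  if (identical(attr(regions, "kind"), "point")) {
    list(df = df, point = TRUE)
  } else {
    list(df = df, point = FALSE)
  }
}

choropleth <- function(regions, values, fill_name) {
  cb <- choropleth_base(regions)
  df <- dplyr::left_join(cb$df, values, by = "region_id")
  if (cb$point) {
    ggplot(df, aes(.data$lon, .data$lat, colour = .data$value)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::scale_colour_viridis_c(name = fill_name) +
      ggplot2::coord_quickmap() +
      ggplot2::theme_minimal()
  } else {
    ggplot(df, aes(.data$lon, .data$lat, group = .data$ring, fill = .data$value)) +
      ggplot2::geom_polygon(colour = "grey30", linewidth = 0.2) +
      ggplot2::scale_fill_viridis_c(name = fill_name) +
      ggplot2::coord_quickmap() +
      ggplot2::theme_minimal()
  }
}

#' Map external exposure concentrations by region
#'
#' Per-chemical choropleth (or point map) of the mean external
#' concentration (ug/m3).
#'
#' @param model A `risk_model`.
#' @param chemicals Chemicals to include; default the roster.
#' @return A ggplot object, faceted by chemical.
#' @export
plot_exposure <- function(model, chemicals = NULL) {
  stopifnot(inherits(model, "risk_model"))
  chemicals <- chemicals %||% model$roster
  values <- model$exposure |>
    dplyr::filter(.data$chemical_id %in% chemicals) |>
    dplyr::select("region_id", "chemical_id", value = "mean")
  cb <- choropleth_base(model$regions)
  df <- purrr::map(chemicals, function(ch) {
    dplyr::mutate(cb$df, chemical_id = ch)
  }) |>
    dplyr::bind_rows() |>
    dplyr::left_join(values, by = c("region_id", "chemical_id"))
  p <- if (cb$point) {
    ggplot(df, aes(.data$lon, .data$lat, colour = .data$value)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::scale_colour_viridis_c(name = "mean ug/m3")
  } else {
    ggplot(df, aes(.data$lon, .data$lat, group = .data$ring, fill = .data$value)) +
      ggplot2::geom_polygon(colour = "grey30", linewidth = 0.2) +
      ggplot2::scale_fill_viridis_c(name = "mean ug/m3")
  }
  p + ggplot2::facet_wrap(~chemical_id) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(title = "External exposure concentration",
      x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}

#' Plot fitted hill curves over the data
#'
#' One fitted curve per chemical (faceted by assay) with the observed
#' concentration-response points.
#'
#' @param model A `risk_model` (fitted), or a `hill_params` object plus
#'   `data`.
#' @param data Concentration-response data; defaults to the model's.
#' @return A ggplot object.
#' @export
plot_hill <- function(model, data = NULL) {
  if (inherits(model, "risk_model")) {
    fits <- model$hill_params
    data <- data %||% model$concresp
  } else {
    fits <- model
    if (is.null(data)) abort("`data` required when plotting bare hill fits")
  }
  fits <- dplyr::filter(tibble::as_tibble(fits), .data$converged)
  if (nrow(fits) == 0) abort("no converged fits to plot")
  curves <- fits |>
    dplyr::rowwise() |>
    dplyr::reframe(
      chemical_id = .data$chemical_id, assay_id = .data$assay_id,
      conc_um = 10^seq(.data$log10_AC50 - 3, .data$log10_AC50 + 3,
        length.out = 100),
      response = hill_response(.data$conc_um, .data$tp, .data$log10_AC50,
        .data$slope)
    )
  ggplot(curves, aes(.data$conc_um, .data$response, colour = .data$chemical_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = data, alpha = 0.4, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~assay_id) +
    ggplot2::labs(x = "concentration (uM)", y = "response (% activity)",
      colour = "chemical", title = "Fitted concentration-response curves") +
    ggplot2::theme_minimal()
}

#' Map mixture-response summaries by region
#'
#' Single-assay path: choropleth of a per-region quantile of the
#' metric. Multi-assay path (when the model carries a summary grid):
#' a panel grid with assay-level quantiles as rows and total summary
#' quantiles as columns.
#'
#' @param model A `risk_model` with results.
#' @param metric Metric to map when no summary grid is present.
#' @param quantile Per-region percentile for the single-assay path.
#' @return A ggplot object.
#' @export
plot_response <- function(model, metric = "GCA_Eff", quantile = 50) {
  stopifnot(inherits(model, "risk_model"))
  if (is.null(model$results)) {
    abort("no results to plot; run calc_response() first")
  }
  if (!is.null(model$summary)) {
    grid <- tibble::as_tibble(model$summary) |>
      dplyr::mutate(
        row = factor(sprintf("A-%g", .data$assay_quantile),
          levels = sprintf("A-%g", sort(unique(.data$assay_quantile)))),
        col = factor(sprintf("p = %g", .data$summary_quantile),
          levels = sprintf("p = %g", sort(unique(.data$summary_quantile))))
      )
    cb <- choropleth_base(model$regions)
    df <- dplyr::left_join(cb$df, grid, by = "region_id",
      relationship = "many-to-many")
    geom <- if (cb$point) {
      ggplot2::geom_point(aes(colour = .data$value), size = 3)
    } else {
      ggplot2::geom_polygon(aes(group = .data$ring, fill = .data$value),
        colour = "grey30", linewidth = 0.2)
    }
    return(
      ggplot(df, aes(.data$lon, .data$lat)) + geom +
        ggplot2::facet_grid(row ~ col) +
        ggplot2::scale_fill_viridis_c(name = unique(grid$metric)) +
        ggplot2::coord_quickmap() +
        ggplot2::labs(title = "Multi-assay risk summary",
          x = "longitude", y = "latitude") +
        ggplot2::theme_minimal()
    )
  }
  values <- region_summary(model, metric, quantile) |>
    dplyr::select("region_id", "value")
  choropleth(model$regions, values,
    sprintf("%s (q%g)", metric, quantile)) +
    ggplot2::labs(title = "Mixture response by region",
      x = "longitude", y = "latitude")
}

#' Kernel densities of sensitivity-analysis output
#'
#' One smoothed density of the propagated metric per varied component.
#'
#' @param model A `risk_model` with a `sensitivity` field, or a
#'   `sensitivity_result` tibble.
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(model) {
  sens <- if (inherits(model, "risk_model")) model$sensitivity else model
  if (is.null(sens)) abort("no sensitivity results; run run_sensitivity() first")
  ggplot(sens, aes(.data$value, colour = .data$component,
    fill = .data$component)) +
    ggplot2::geom_density(alpha = 0.2) +
    ggplot2::labs(x = unique(sens$metric), y = "density",
      title = "One-at-a-time sensitivity") +
    ggplot2::theme_minimal()
}

#' @method autoplot risk_model
#' @export
autoplot.risk_model <- function(object, type = c("response", "exposure",
                                                 "hill", "sensitivity"), ...) {
  type <- match.arg(type)
  switch(type,
    exposure = plot_exposure(object, ...),
    hill = plot_hill(object, ...),
    response = plot_response(object, ...),
    sensitivity = plot_sensitivity(object)
  )
}

#' @method autoplot hill_params
#' @export
autoplot.hill_params <- function(object, data, ...) plot_hill(object, data)

#' @method autoplot sensitivity_result
#' @export
autoplot.sensitivity_result <- function(object, ...) plot_sensitivity(object)

#' @export
plot.risk_model <- function(x, y, type = "response", ...) {
  print(autoplot(x, type = type, ...))
  invisible(x)
}

#' Describe a figure to render
#'
#' @param type One of `"exposure"`, `"hill"`, `"response"`,
#'   `"sensitivity"`.
#' @param path Output file; extension selects the device (`.png` or
#'   `.svg`).
#' @param width,height,dpi Device geometry (inches / dots per inch).
#' @param ... Passed to the underlying `plot_*` function.
#' @return A `figure_spec` list.
#' @export
figure_spec <- function(type, path, width = 7, height = 5, dpi = 150, ...) {
  type <- match.arg(type, c("exposure", "hill", "response", "sensitivity"))
  fmt <- tolower(tools::file_ext(path))
  if (!fmt %in% c("png", "svg")) abort("figure format must be png or svg")
  structure(
    list(type = type, path = path, width = width, height = height,
      dpi = dpi, args = list(...)),
    class = "figure_spec"
  )
}

#' Render a figure to disk
#'
#' @param model A `risk_model` with the fields the figure type needs.
#' @param spec A [figure_spec()].
#' @return The output path, invisibly.
#' @export
render_figure <- function(model, spec) {
  stopifnot(inherits(spec, "figure_spec"))
  p <- do.call(autoplot, c(list(model, type = spec$type), spec$args))
  dir.create(dirname(spec$path), recursive = TRUE, showWarnings = FALSE)
  ggplot2::ggsave(spec$path, p, width = spec$width, height = spec$height,
    dpi = spec$dpi)
  invisible(spec$path)
}
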