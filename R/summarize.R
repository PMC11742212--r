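#' Per-region quantiles of a mixture metric
#'
#' Empirical percentiles (linear interpolation between order
#' statistics) of one metric over the simulated individuals of each
#' region, pooled across assays when several are present. This is the
#' single-assay mapping path (e.g. the median mixture effect by
#' county).
#'
#' @param results A results tibble from [calc_response()] (or a
#'   `risk_model` holding one).
#' @param metric Column name, e.g. `"GCA_Eff"` or `"GCA_HQ"`.
#' @param quantiles Percentiles in [0, 100]; default 50.
#' @return Tibble `region_id`, `quantile`, `metric`, `value`.
#' @export
region_summary <- function(results, metric = "GCA_Eff", quantiles = 50) {
  results <- as_results(results)
  if (!metric %in% names(results)) {
    abort(sprintf("unknown metric `%s`", metric))
  }
  results |>
    dplyr::group_by(.data$region_id) |>
    dplyr::reframe(
      quantile = quantiles,
      metric = metric,
      value = percentile(.data[[metric]], quantiles)
    )
}

#' Nested multi-assay quantile summaries
#'
#' Two-level summarization of a metric for multi-assay risk maps: per
#' region, the q-th percentile of the metric over individuals is taken
#' within each assay (assay-level summary), then the p-th percentile of
#' those assay-level values is taken across assays (total summary) --
#' the "p total quantile of the q assay-level quantiles". Low p with a
#' high q reads as "even the most responsive assays stay below this
#' level in all but p% of endpoints".
#'
#' @inheritParams region_summary
#' @param assay_quantiles Percentiles q applied over individuals within
#'   each assay.
#' @param summary_quantiles Percentiles p applied across the
#'   assay-level values.
#' @return A `summary_grid` tibble: `region_id`, `assay_quantile`,
#'   `summary_quantile`, `metric`, `value`; values are non-decreasing
#'   in `assay_quantile` for fixed region and `summary_quantile`.
#' @export
summarize_multi_assay <- function(results, metric = "GCA_HQ",
                                  assay_quantiles = c(10, 50, 90),
                                  summary_quantiles = c(5, 10)) {
  results <- as_results(results)
  if (nrow(results) == 0) abort("empty results")
  if (!metric %in% names(results)) abort(sprintf("unknown metric `%s`", metric))
  assay_level <- results |>
    dplyr::group_by(.data$region_id, .data$assay_id) |>
    dplyr::reframe(
      assay_quantile = assay_quantiles,
      value = percentile(.data[[metric]], assay_quantiles)
    )
  grid <- assay_level |>
    dplyr::group_by(.data$region_id, .data$assay_quantile) |>
    dplyr::reframe(
      summary_quantile = summary_quantiles,
      metric = metric,
      value = percentile(.data$value, summary_quantiles)
    ) |>
    dplyr::arrange(.data$region_id, .data$summary_quantile, .data$assay_quantile)
  structure(grid, class = c("summary_grid", class(grid)))
}

as_results <- function(x) {
  if (inherits(x, "risk_model")) {
    if (is.null(x$results)) abort("model has no results; run calc_response() first")
    x$results
  } else {
    assert_columns(x, c("region_id", "assay_id", "individual"), "results")
    x
  }
}

#' Attach nested quantile summaries to a model
#'
#' @param model A `risk_model` with results.
#' @param metric Metric to summarize; default `"GCA_HQ"`.
#' @return The model with a `summary` field (a `summary_grid`).
#' @export
summarize_risk <- function(model, metric = "GCA_HQ") {
  stopifnot(inherits(model, "risk_model"))
  model$summary <- summarize_multi_assay(
    model, metric,
    assay_quantiles = model$config$assay_quantiles,
    summary_quantiles = model$config$summary_quantiles
  )
  model
}

sensitivity_components <- c("age", "obesity", "css_params", "fit_params", "C_ext")

# Hill parameters for the sensitivity analysis: either the MLE point
# estimates repeated, or per-replicate draws from independent
# Normal(MLE, se) truncated to valid ranges (tp > 0, slope in [0.3, 8]).
draw_fit_params <- function(fits, n, vary) {
  if (!vary) return(purrr::map(seq_len(n), function(i) fits))
  draws <- purrr::map(seq_len(nrow(fits)), function(i) {
    r <- fits[i, ]
    tibble::tibble(
      tp = rnorm_trunc(n, r$tp, r$se_tp %|NA|% 0, lower = 1e-6),
      log10_AC50 = rnorm(n, r$log10_AC50, r$se_log10_AC50 %|NA|% 0),
      slope = if (is.finite(r$se_slope)) {
        rnorm_trunc2(n, r$slope, r$se_slope, 0.3, 8)
      } else {
        rep(r$slope, n)
      }
    )
  })
  purrr::map(seq_len(n), function(j) {
    tibble::tibble(
      chemical_id = fits$chemical_id,
      assay_id = fits$assay_id,
      tp = purrr::map_dbl(draws, ~ .x$tp[j]),
      log10_AC50 = purrr::map_dbl(draws, ~ .x$log10_AC50[j]),
      slope = purrr::map_dbl(draws, ~ .x$slope[j]),
      converged = TRUE
    )
  })
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

#' One-at-a-time Monte Carlo sensitivity analysis
#'
#' Quantifies how much each pipeline component contributes to the
#' spread of a mixture metric: the named component is re-sampled from
#' its distribution while every other component is pinned to a central
#' value (age: region median age; obesity: weight class Normal;
#' inhalation rate: age-bracket mean; `C_ext`: exposure mean;
#' `css_params`: stratum-median Css; `fit_params`: maximum-likelihood
#' point estimates). When `fit_params` varies, hill parameters are
#' drawn per replicate from independent normals centered at the MLE
#' with the fitted standard errors, truncated to valid ranges.
#'
#' Components draw from dedicated RNG substreams, so varying one
#' component reproduces every other component's draws exactly; with
#' `component = "baseline"` everything is pinned and the output has
#' zero variance.
#'
#' @param model A `risk_model` (assembled; population not required).
#' @param component One of `"age"`, `"obesity"`, `"css_params"`,
#'   `"fit_params"`, `"C_ext"`, or `"baseline"`.
#' @param metric Metric to propagate, e.g. `"GCA_Eff"` (default) or
#'   `"GCA_HQ"`, `"IA_Eff"`, `"IA_HQ"`.
#' @param n Replicates per region; defaults to the config's
#'   `n_per_region`.
#' @return A `sensitivity_result` tibble: `component`, `region_id`,
#'   `assay_id`, `replicate`, `metric`, `value`.
#' @export
compute_sensitivity <- function(model, component, metric = "GCA_Eff",
                                n = NULL) {
  stopifnot(inherits(model, "risk_model"))
  if (!component %in% c(sensitivity_components, "baseline")) {
    abort(sprintf(
      "unknown sensitivity component `%s` (expected one of %s)",
      component, paste(c(sensitivity_components, "baseline"), collapse = ", ")
    ))
  }
  n <- as.integer(n %||% model$config$n_per_region)
  method <- sub("_.*$", "", metric)
  if (!method %in% c("GCA", "IA")) abort(sprintf("unknown metric `%s`", metric))
  vary <- intersect(component, c("age", "obesity", "css_params", "C_ext"))

  base <- model
  pops <- purrr::map(model$regions$region_id, function(rid) {
    simulate_region(
      rid, model$exposure, model$population_inputs, model$roster,
      n = n, seed = model$config$seed, vary = vary,
      age_breaks = model$config$age_breaks
    )
  })
  base$population <- bind_population(pops, model$roster)
  base$provenance$n_per_region <- n

  fits <- model$hill_params |>
    dplyr::filter(.data$converged, .data$chemical_id %in% model$roster)
  if (component == "fit_params") {
    cfg <- model$config
    param_draws <- with_substream(cfg$seed, "all", "fit_params",
      expr = draw_fit_params(fits, n, vary = TRUE))
    res <- purrr::map(split(base$population, base$population$region_id),
      function(p) {
        d_int <- calc_internal_dose(p$exposure[, model$roster, drop = FALSE],
          p$ir, cfg$time_days, cfg$dose_scaling)
        conc_all <- calc_invitro_concentration(d_int,
          p$css[, model$roster, drop = FALSE])
        purrr::map(sort(unique(fits$assay_id)), function(a) {
          purrr::map(seq_len(nrow(p)), function(i) {
            pa <- param_draws[[p$individual[i]]] |>
              dplyr::filter(.data$assay_id == a) |>
              dplyr::arrange(.data$chemical_id)
            cc <- conc_all[i, pa$chemical_id]
            value <- switch(metric,
              GCA_Eff = suppressWarnings(as.numeric(response_gca(cc, pa))),
              IA_Eff = response_ia(cc, pa),
              GCA_HQ = as.numeric(calc_hq(cc, pa, cfg$hq_percent, "GCA")),
              IA_HQ = as.numeric(calc_hq(cc, pa, cfg$hq_percent, "IA"))
            )
            tibble::tibble(region_id = p$region_id[i], assay_id = a,
              replicate = p$individual[i], value = value)
          }) |> dplyr::bind_rows()
        }) |> dplyr::bind_rows()
      }) |> dplyr::bind_rows()
    res <- dplyr::as_tibble(res)
  } else {
    base <- calc_response(base, methods = method)
    res <- base$results |>
      dplyr::select("region_id", "assay_id",
        replicate = "individual", value = dplyr::all_of(metric))
  }
  out <- res |>
    dplyr::mutate(component = component, metric = metric, .before = 1) |>
    dplyr::arrange(.data$region_id, .data$assay_id, .data$replicate)
  rownames(out) <- NULL
  structure(out, class = c("sensitivity_result", class(out)))
}

#' Run the full one-at-a-time sensitivity suite
#'
#' [compute_sensitivity()] for every component, stacked for plotting.
#'
#' @inheritParams compute_sensitivity
#' @param components Components to vary; default all five.
#' @return The model with a `sensitivity` field (stacked
#'   `sensitivity_result`).
#' @export
run_sensitivity <- function(model, metric = "GCA_Eff",
                            components = sensitivity_components, n = NULL) {
  res <- purrr::map(components, function(comp) {
    compute_sensitivity(model, comp, metric = metric, n = n)
  }) |>
    dplyr::bind_rows()
  model$sensitivity <- structure(res,
    class = c("sensitivity_result", class(tibble::tibble())))
  model
}
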