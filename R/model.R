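#' Analysis configuration
#'
#' Bundles the tunable parameters of a source-to-outcome analysis.
#'
#' @param seed Master RNG seed; all Monte Carlo substreams derive from it.
#' @param n_per_region Simulated individuals per region (>= 1).
#' @param time_days Exposure duration, days; default 1 (the Css scaling
#'   assumes steady state is reached within a day).
#' @param dose_scaling Unit conversion for internal dose, default `1e-3`
#'   (ug -> mg).
#' @param hq_percent Reference response level for hazard quotients, as a
#'   percent of the assay's reference maximum; default 10.
#' @param mixture_methods Subset of `c("GCA", "IA")`.
#' @param assay_quantiles Percentiles (0-100) summarizing individuals
#'   within each assay; default `c(10, 50, 90)`.
#' @param summary_quantiles Percentiles (0-100) summarizing across
#'   assays; default `c(5, 10)` (conservative lower-tail summaries).
#' @param fixed_slope Fit 2-parameter (slope = 1) hill curves; default
#'   `TRUE`.
#' @param age_breaks Lower bounds of the Css age groups.
#' @return A list of class `risk_config`.
#' @export
risk_config <- function(seed = 1L, n_per_region = 100L, time_days = 1,
                        dose_scaling = 1e-3, hq_percent = 10,
                        mixture_methods = c("GCA", "IA"),
                        assay_quantiles = c(10, 50, 90),
                        summary_quantiles = c(5, 10),
                        fixed_slope = TRUE,
                        age_breaks = c(0, 18, 45, 65)) {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(n_per_region, "n_per_region", 1)
  assert_scalar_number(time_days, "time_days", 0)
  assert_scalar_number(dose_scaling, "dose_scaling", 0)
  assert_scalar_number(hq_percent, "hq_percent")
  if (hq_percent <= 0 || hq_percent >= 100) {
    abort("`hq_percent` must lie strictly in (0, 100)")
  }
  mixture_methods <- match.arg(mixture_methods, c("GCA", "IA"), several.ok = TRUE)
  if (any(assay_quantiles < 0 | assay_quantiles > 100) ||
      any(summary_quantiles < 0 | summary_quantiles > 100)) {
    abort("quantile levels must lie in [0, 100]")
  }
  n_explicit <- !missing(n_per_region)
  structure(
    list(
      seed = as.integer(seed), n_per_region = as.integer(n_per_region),
      time_days = time_days, dose_scaling = dose_scaling,
      hq_percent = hq_percent, mixture_methods = mixture_methods,
      assay_quantiles = assay_quantiles, summary_quantiles = summary_quantiles,
      fixed_slope = isTRUE(fixed_slope), age_breaks = age_breaks
    ),
    class = "risk_config",
    n_per_region_explicit = n_explicit
  )
}

validate_exposure <- function(exposure, region_ids) {
  assert_columns(exposure, c("region_id", "chemical_id", "mean", "sd"),
    "exposure table")
  exposure <- dplyr::mutate(exposure,
    region_id = as.character(.data$region_id),
    chemical_id = trim_chem(.data$chemical_id))
  bad <- setdiff(exposure$region_id, region_ids)
  if (length(bad) > 0) {
    abort(sprintf("exposure references unknown region id(s): %s",
      paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(exposure[c("region_id", "chemical_id")])) {
    dup <- exposure[duplicated(exposure[c("region_id", "chemical_id")]), ]
    abort(sprintf("duplicate exposure rows for (%s, %s)",
      dup$region_id[1], dup$chemical_id[1]))
  }
  if (any(exposure$mean < 0) || any(exposure$sd < 0)) {
    abort("exposure mean and sd must be non-negative")
  }
  exposure
}

#' Assemble a source-to-outcome risk model
#'
#' Joins the region boundaries, exposure table, concentration-response
#' data, Css sample table and population inputs into one analysis
#' container. Hill curves are fitted (or taken from `hill_params` if
#' supplied), and the chemical roster is the three-way intersection of
#' (i) chemicals with exposure records, (ii) chemicals with at least one
#' converged hill fit, and (iii) chemicals with Css samples. Chemicals
#' dropped from any source are retained in the provenance with the
#' reason, never silently discarded.
#'
#' @param regions A region set from [read_regions()] (tibble with
#'   `region_id` and a `geometry` list-column).
#' @param exposure Exposure table: `region_id`, `chemical_id`, `mean`,
#'   `sd` (ug/m3).
#' @param concresp Concentration-response table for [fit_hill()].
#' @param css Long Css sample table (see [simulate_css()]).
#' @param population_inputs List with `age_dist`, `obesity`, `ir_table`
#'   data frames (Css table is attached internally).
#' @param config A [risk_config()].
#' @param hill_params Optional pre-fitted `hill_params`; fitted from
#'   `concresp` when `NULL`.
#' @return A list of class `risk_model` with fields `regions`,
#'   `exposure`, `concresp`, `hill_params`, `roster`, `population`
#'   (empty until [simulate_population()]), `results` (empty until
#'   [calc_response()]), `config` and `provenance`.
#' @export
assemble_model <- function(regions, exposure, concresp, css,
                           population_inputs, config = risk_config(),
                           hill_params = NULL) {
  stopifnot(inherits(config, "risk_config"))
  if (!is.data.frame(regions) || !all(c("region_id", "geometry") %in% names(regions))) {
    abort("`regions` must be a region set with region_id and geometry columns")
  }
  exposure <- validate_exposure(exposure, regions$region_id)
  assert_columns(css, c("chemical_id", "age_group", "weight_class", "sample_value"),
    "Css table")
  css <- dplyr::mutate(css, chemical_id = trim_chem(.data$chemical_id))
  if (is.null(hill_params)) {
    hill_params <- fit_hill(concresp, fixed_slope = config$fixed_slope)
  }

  chem_exposure <- unique(exposure$chemical_id)
  fit_ok <- hill_params |>
    dplyr::filter(.data$converged) |>
    dplyr::pull("chemical_id") |>
    unique()
  chem_css <- unique(css$chemical_id)
  roster <- sort(intersect(intersect(chem_exposure, fit_ok), chem_css))

  all_chems <- sort(unique(c(chem_exposure, unique(hill_params$chemical_id), chem_css)))
  dropped <- tibble::tibble(chemical_id = setdiff(all_chems, roster)) |>
    dplyr::mutate(reason = purrr::map_chr(.data$chemical_id, function(ch) {
      why <- c(
        if (!ch %in% chem_exposure) "no exposure record",
        if (!ch %in% fit_ok) "no converged concentration-response fit",
        if (!ch %in% chem_css) "no Css samples"
      )
      paste(why, collapse = "; ")
    }))
  if (length(roster) == 0) abort("no analyzable chemicals: the exposure, fitted-curve and Css chemical sets have empty intersection")
  for (i in seq_len(nrow(dropped))) {
    warn(sprintf("chemical %s dropped from roster: %s",
      dropped$chemical_id[i], dropped$reason[i]))
  }

  population_inputs$css <- css
  structure(
    list(
      regions = regions,
      exposure = exposure,
      concresp = concresp,
      hill_params = hill_params,
      roster = roster,
      population_inputs = population_inputs,
      population = NULL,
      results = NULL,
      summary = NULL,
      sensitivity = NULL,
      config = config,
      provenance = list(
        seed = config$seed,
        n_regions = nrow(regions),
        dropped_chemicals = dropped,
        n_per_region = NULL
      )
    ),
    class = "risk_model"
  )
}

field_dim <- function(x) {
  if (is.null(x)) return("empty")
  if (is.data.frame(x)) return(sprintf("%d x %d", nrow(x), ncol(x)))
  if (is.list(x)) return(sprintf("list of %d", length(x)))
  sprintf("length %d", length(x))
}

#' Console summary of a risk model
#'
#' Multi-line description of the model state: region count, simulated
#' individuals per region, and each field's name, class and dimensions
#' in a stable order. Pure function of the model state (no timestamps),
#' so the same model always summarizes to byte-identical text.
#'
#' @param model A `risk_model`.
#' @return A single character string (newline separated).
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "risk_model"))
  npr <- model$provenance$n_per_region
  header <- c(
    "<risk_model>",
    sprintf("  regions: %d (%s)", nrow(model$regions),
      attr(model$regions, "kind") %||% "area"),
    sprintf("  simulated individuals per region: %s",
      if (is.null(npr)) "none (population not simulated)" else npr),
    sprintf("  chemical roster: %d chemical(s)", length(model$roster)),
    sprintf("  dropped chemicals: %d", nrow(model$provenance$dropped_chemicals)),
    sprintf("  seed: %d", model$provenance$seed)
  )
  fields <- c("regions", "exposure", "concresp", "hill_params", "population",
    "results", "summary", "sensitivity")
  rows <- vapply(fields, function(f) {
    x <- model[[f]]
    sprintf("  %-12s %-12s %s", f,
      if (is.null(x)) "<empty>" else class(x)[1], field_dim(x))
  }, character(1))
  paste(c(header, "  fields:", rows), collapse = "\n")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(model_summary(x), "\n")
  invisible(x)
}

#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x$regions),
    n_chemicals = length(x$roster),
    n_assays = dplyr::n_distinct(x$hill_params$assay_id),
    n_converged_fits = sum(x$hill_params$converged),
    n_per_region = x$provenance$n_per_region %||% NA_integer_,
    has_results = !is.null(x$results),
    seed = x$provenance$seed
  )
}
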