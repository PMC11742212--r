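pipeline_keys <- c(
  "seed", "n_per_region", "time_days", "dose_scaling", "hq_percent",
  "mixture_methods", "assay_quantiles", "summary_quantiles", "fixed_slope",
  "age_breaks", "inputs", "output_dir", "figures", "sensitivity",
  "summary_metric", "sensitivity_metric"
)

stage <- function(name, quiet, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
  })
  if (!quiet) {
    message(sprintf("[%s] done in %.2fs", name,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  res
}

#' Run the end-to-end risk pipeline from a YAML configuration
#'
#' Executes assemble -> fit -> simulate -> respond -> summarize
#' (-> optional sensitivity) -> write (-> optional figures). The YAML
#' mirrors [risk_config()] one-to-one plus `inputs` (paths, relative to
#' the config file), `output_dir`, `figures` (logical, default off so
#' the written tree is byte-deterministic), `summary_metric`,
#' `sensitivity` (list of components) and `sensitivity_metric`.
#' Unknown keys are errors. With a fixed seed, two runs write
#' byte-identical output trees.
#'
#' @param config_path Path to the YAML configuration.
#' @param quiet Suppress per-stage log messages.
#' @return The finished `risk_model`, invisibly.
#' @export
run_pipeline <- function(config_path, quiet = FALSE) {
  cfg_raw <- yaml::read_yaml(config_path)
  unknown <- setdiff(names(cfg_raw), pipeline_keys)
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg_raw$inputs) || is.null(cfg_raw$output_dir)) {
    abort("configuration needs `inputs` and `output_dir`")
  }
  base_dir <- dirname(normalizePath(config_path))
  rel <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  cfg_args <- cfg_raw[intersect(names(cfg_raw), names(formals(risk_config)))]
  config <- do.call(risk_config, cfg_args)
  if (!quiet) message(sprintf("pipeline seed: %d", config$seed))

  inputs <- stage("load", quiet,
    load_inputs(purrr::map(cfg_raw$inputs, rel), quiet = quiet))
  model <- stage("assemble", quiet, assemble_model(
    regions = inputs$regions, exposure = inputs$exposure,
    concresp = inputs$concresp, css = inputs$css,
    population_inputs = inputs[c("age_dist", "obesity", "ir_table")],
    config = config
  ))
  model <- stage("simulate", quiet, simulate_population(model))
  model <- stage("respond", quiet, calc_response(model))
  summary_metric <- cfg_raw$summary_metric %||%
    if ("GCA" %in% config$mixture_methods) "GCA_HQ" else "IA_HQ"
  model <- stage("summarize", quiet, summarize_risk(model, summary_metric))
  sens <- cfg_raw$sensitivity %||% list()
  if (length(sens) > 0) {
    metric <- cfg_raw$sensitivity_metric %||%
      if ("GCA" %in% config$mixture_methods) "GCA_Eff" else "IA_Eff"
    model <- stage("sensitivity", quiet,
      run_sensitivity(model, metric = metric, components = unlist(sens)))
  }
  out_dir <- rel(cfg_raw$output_dir)
  stage("write", quiet, write_results(model, out_dir))
  if (isTRUE(cfg_raw$figures)) {
    stage("render", quiet, {
      fig_dir <- file.path(out_dir, "figures")
      for (type in c("exposure", "hill", "response",
        if (length(sens) > 0) "sensitivity")) {
        render_figure(model, figure_spec(type,
          path = file.path(fig_dir, paste0(type, ".png"))))
      }
    })
  }
  invisible(model)
}
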