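read_table_checked <- function(path, cols, what, col_types = NULL) {
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
    col_types = col_types)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s (%s) is missing column%s: %s", what, path,
      if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")))
  }
  df
}

#' Load and validate all pipeline inputs
#'
#' Reads the boundary GeoJSON and the CSV tables of a study, validates
#' their schemas, normalizes the CRS to WGS84 and logs row counts. CSV
#' dialect: UTF-8, comma separated, header row, "." decimal.
#'
#' @param paths Named list (or vector) with entries `boundaries`,
#'   `exposure`, `concresp`, `css`, `age_dist`, `obesity`, `ir_table`.
#' @param quiet Suppress row-count messages.
#' @return A list with the parsed `regions` tibble and typed tables,
#'   ready for [assemble_model()].
#' @export
load_inputs <- function(paths, quiet = FALSE) {
  needed <- c("boundaries", "exposure", "concresp", "css", "age_dist",
    "obesity", "ir_table")
  missing <- setdiff(needed, names(paths))
  if (length(missing) > 0) {
    abort(sprintf("`paths` is missing entries: %s", paste(missing, collapse = ", ")))
  }
  regions <- read_regions(paths$boundaries)
  exposure <- read_table_checked(paths$exposure,
    c("region_id", "chemical_id", "mean", "sd"), "exposure table",
    readr::cols(region_id = "c", chemical_id = "c"))
  concresp <- read_table_checked(paths$concresp,
    c("chemical_id", "assay_id", "conc_um", "response"),
    "concentration-response table", readr::cols(chemical_id = "c", assay_id = "c"))
  css <- read_table_checked(paths$css,
    c("chemical_id", "age_group", "weight_class", "sample_value"),
    "Css table", readr::cols(chemical_id = "c", age_group = "c", weight_class = "c"))
  age_dist <- read_table_checked(paths$age_dist,
    c("region_id", "age_low", "age_high", "proportion"), "age distribution",
    readr::cols(region_id = "c"))
  obesity <- read_table_checked(paths$obesity,
    c("region_id", "prev_mean", "prev_sd"), "obesity table",
    readr::cols(region_id = "c"))
  ir_table <- read_table_checked(paths$ir_table,
    c("age_low", "age_high", "ir_mean", "ir_sd"), "inhalation-rate table")
  out <- list(
    regions = regions, exposure = exposure, concresp = concresp, css = css,
    age_dist = age_dist, obesity = obesity, ir_table = ir_table
  )
  if (!quiet) {
    for (nm in setdiff(names(out), "regions")) {
      message(sprintf("loaded %s: %d rows", nm, nrow(out[[nm]])))
    }
    message(sprintf("loaded boundaries: %d region(s), kind = %s",
      nrow(regions), attr(regions, "kind")))
  }
  out
}

write_csv_sorted <- function(df, path, keys) {
  df <- dplyr::arrange(df, dplyr::across(dplyr::all_of(keys)))
  readr::write_csv(df, path, progress = FALSE)
  nrow(df)
}

flatten_population <- function(pop) {
  mats <- c("exposure", "css", "css_central")
  base <- dplyr::select(pop, !dplyr::all_of(mats))
  long <- purrr::map(mats, function(m) {
    df <- tibble::as_tibble(pop[[m]])
    df$region_id <- pop$region_id
    df$individual <- pop$individual
    tidyr::pivot_longer(df, !c("region_id", "individual"),
      names_to = "chemical_id", values_to = m)
  }) |>
    purrr::reduce(dplyr::left_join, by = c("region_id", "individual", "chemical_id"))
  dplyr::left_join(base, long, by = c("region_id", "individual"))
}

#' Write a model's tables to a results directory
#'
#' Deterministic serialization: fixed file set, sorted rows, fixed
#' column order, plus a `manifest.json` listing each file with its row
#' count and the MD5 of the serialized configuration. Writing the same
#' model twice produces byte-identical files.
#'
#' @param model A `risk_model`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_results <- function(model, out_dir) {
  stopifnot(inherits(model, "risk_model"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create `%s`", out_dir))
  files <- list()

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(model$config), cfg_path)
  files[["config.yaml"]] <- 1L

  write_regions(model$regions, file.path(out_dir, "boundaries.geojson"))
  files[["boundaries.geojson"]] <- nrow(model$regions)

  tabs <- list(
    "hill_params.csv" = list(tibble::as_tibble(model$hill_params),
      c("chemical_id", "assay_id")),
    "roster.csv" = list(tibble::tibble(chemical_id = model$roster), "chemical_id"),
    "dropped_chemicals.csv" = list(model$provenance$dropped_chemicals,
      "chemical_id"),
    "exposure.csv" = list(model$exposure, c("region_id", "chemical_id"))
  )
  if (!is.null(model$population)) {
    tabs[["population.csv"]] <- list(flatten_population(model$population),
      c("region_id", "individual", "chemical_id"))
  }
  if (!is.null(model$results)) {
    long <- tidyr::pivot_longer(model$results,
      !c("region_id", "assay_id", "individual"),
      names_to = "metric", values_to = "value")
    tabs[["results.csv"]] <- list(long,
      c("region_id", "assay_id", "individual", "metric"))
  }
  if (!is.null(model$summary)) {
    tabs[["summary_grid.csv"]] <- list(tibble::as_tibble(model$summary),
      c("region_id", "summary_quantile", "assay_quantile"))
  }
  if (!is.null(model$sensitivity)) {
    tabs[["sensitivity.csv"]] <- list(tibble::as_tibble(model$sensitivity),
      c("component", "region_id", "assay_id", "replicate"))
  }
  for (nm in names(tabs)) {
    files[[nm]] <- write_csv_sorted(tabs[[nm]][[1]], file.path(out_dir, nm),
      tabs[[nm]][[2]])
  }

  manifest <- list(
    seed = model$provenance$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = purrr::imap(files, function(rows, file) {
      list(file = file, rows = rows)
    }) |> unname()
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a synthetic study to disk in the load_inputs() layout
#'
#' Produces the CSV/GeoJSON bundle plus a ready-to-run `config.yaml`
#' for [run_pipeline()].
#'
#' @param study A `synthetic_study` from [gen_synthetic_study()].
#' @param dir Target directory.
#' @param config Optional [risk_config()] written into the pipeline
#'   config.
#' @return Named list of the paths written.
#' @export
write_study <- function(study, dir, config = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_regions(study$regions, p("boundaries.geojson"))
  readr::write_csv(study$exposure, p("exposure.csv"), progress = FALSE)
  readr::write_csv(study$concresp, p("concresp.csv"), progress = FALSE)
  readr::write_csv(study$css, p("css.csv"), progress = FALSE)
  readr::write_csv(study$age_dist, p("age_dist.csv"), progress = FALSE)
  readr::write_csv(study$obesity, p("obesity.csv"), progress = FALSE)
  readr::write_csv(study$ir_table, p("ir_table.csv"), progress = FALSE)
  cfg <- config %||% risk_config(seed = study$truth$seed)
  pipeline_cfg <- c(
    unclass(cfg),
    list(
      inputs = list(
        boundaries = "boundaries.geojson", exposure = "exposure.csv",
        concresp = "concresp.csv", css = "css.csv",
        age_dist = "age_dist.csv", obesity = "obesity.csv",
        ir_table = "ir_table.csv"
      ),
      output_dir = "results",
      figures = FALSE,
      sensitivity = list()
    )
  )
  yaml::write_yaml(pipeline_cfg, p("config.yaml"))
  paths <- list(
    boundaries = p("boundaries.geojson"), exposure = p("exposure.csv"),
    concresp = p("concresp.csv"), css = p("css.csv"),
    age_dist = p("age_dist.csv"), obesity = p("obesity.csv"),
    ir_table = p("ir_table.csv"), config = p("config.yaml")
  )
  invisible(paths)
}
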