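#' Generate a synthetic source-to-outcome study
#'
#' Builds a complete, internally consistent input bundle with known
#' ground truth: a grid of square area regions, an exposure table with
#' log-normal means (sd fixed at 30% of the mean), hill-curve truth per
#' chemical x assay, noisy concentration-response observations, a
#' long-format Css sample table, census-style age brackets, obesity
#' prevalences and an inhalation-rate table decreasing with age. The
#' bundle passes every input validation and exercises every pipeline
#' branch (multiple regions, partial assay coverage when `n_assays >=
#' 2` and `n_chems >= 2`, both weight classes). It emulates the shape
#' of regional air-toxics exposure and high-throughput screening data,
#' not their spatial autocorrelation or real curve shapes.
#'
#' @param n_regions,n_chems,n_assays Counts (>= 1).
#' @param n_conc Distinct concentrations per curve (>= 5), log-spaced
#'   at 2.5 decades around the true AC50, 3 replicates each.
#' @param noise_sd Gaussian response noise, % activity; default 3.
#' @param vary_slope If `TRUE`, true slopes are sampled in [0.8, 3];
#'   otherwise all slopes are 1.
#' @param seed Generator seed (regeneration is byte-identical).
#' @return A list of class `synthetic_study`: `regions`, `exposure`,
#'   `concresp`, `css`, `age_dist`, `obesity`, `ir_table`, and `truth`
#'   (`hill` tibble of true parameters, `exposure_mean`, `seed`).
#' @export
gen_synthetic_study <- function(n_regions = 5, n_chems = 4, n_assays = 2,
                                n_conc = 10, noise_sd = 3,
                                vary_slope = FALSE, seed = 1L) {
  if (any(c(n_regions, n_chems, n_assays, n_conc) < 1) || noise_sd < 0) {
    abort("counts must be >= 1 and noise_sd >= 0")
  }
  if (n_conc < 5) abort("`n_conc` must be >= 5 for fitting")
  with_substream(seed, "synthetic_study", expr = {
    region_ids <- sprintf("R%03d", seq_len(n_regions))
    chem_ids <- sprintf("%03d-%02d-%d", 100 + seq_len(n_chems),
      seq_len(n_chems), seq_len(n_chems) %% 10)
    assay_ids <- sprintf("ASSAY_%02d", seq_len(n_assays))

    # unit-square grid, row-major
    ncols <- ceiling(sqrt(n_regions))
    geoms <- purrr::map(seq_len(n_regions) - 1, function(i) {
      x <- i %% ncols
      y <- i %/% ncols
      ring <- rbind(
        c(x, y), c(x + 1, y), c(x + 1, y + 1), c(x, y + 1), c(x, y)
      )
      list(type = "Polygon", coords = list(ring))
    })
    regions <- set_boundaries(tibble::tibble(region_id = region_ids), geoms)

    exposure_mean <- matrix(
      exp(rnorm(n_regions * n_chems, log(5), 0.5)),
      n_regions, n_chems, dimnames = list(region_ids, chem_ids)
    )
    exposure <- tidyr::expand_grid(region_id = region_ids, chemical_id = chem_ids) |>
      dplyr::mutate(
        mean = exposure_mean[cbind(.data$region_id, .data$chemical_id)],
        sd = 0.3 * .data$mean
      )

    # assay coverage: assay 1 covers all chemicals; each later assay is
    # missing one chemical, so per-assay rosters differ from the global one
    coverage <- tidyr::expand_grid(assay_id = assay_ids, chemical_id = chem_ids)
    if (n_assays >= 2 && n_chems >= 2) {
      drop <- tibble::tibble(
        assay_id = assay_ids[-1],
        chemical_id = chem_ids[1 + (seq_len(n_assays - 1) - 1) %% n_chems]
      )
      coverage <- dplyr::anti_join(coverage, drop, by = c("assay_id", "chemical_id"))
    }
    truth <- coverage |>
      dplyr::mutate(
        tp = runif(dplyr::n(), 50, 120),
        log10_AC50 = runif(dplyr::n(), -1, 1),
        slope = if (vary_slope) runif(dplyr::n(), 0.8, 3) else 1
      )

    concresp <- truth |>
      dplyr::rowwise() |>
      dplyr::reframe(
        chemical_id = .data$chemical_id,
        assay_id = .data$assay_id,
        conc_um = rep(10^(.data$log10_AC50 + seq(-2.5, 2.5, length.out = n_conc)), 3),
        mu = hill_response(.data$conc_um, .data$tp, .data$log10_AC50, .data$slope)
      ) |>
      dplyr::mutate(response = .data$mu + rnorm(dplyr::n(), 0, noise_sd)) |>
      dplyr::select("chemical_id", "assay_id", "conc_um", "response")

    age_groups <- c("0-17", "18-44", "45-64", "65+")
    css <- tidyr::expand_grid(
      chemical_id = chem_ids, age_group = age_groups,
      weight_class = c("Normal", "Obese")
    )
    gm <- setNames(runif(n_chems, 1, 10), chem_ids)
    css <- css |>
      dplyr::rowwise() |>
      dplyr::reframe(
        chemical_id = .data$chemical_id, age_group = .data$age_group,
        weight_class = .data$weight_class,
        sample_value = exp(rnorm(50, log(gm[[.data$chemical_id]]), 0.3)) *
          ifelse(.data$weight_class == "Obese", 1.2, 1)
      )

    brackets <- tibble::tibble(
      age_low = c(0, 18, 45, 65, 85),
      age_high = c(17, 44, 64, 84, 99)
    )
    age_dist <- tidyr::expand_grid(region_id = region_ids,
      brackets) |>
      dplyr::group_by(.data$region_id) |>
      dplyr::mutate(
        proportion = {
          w <- stats::rgamma(dplyr::n(), shape = c(8, 14, 10, 6, 2))
          w / sum(w)
        }
      ) |>
      dplyr::ungroup()

    obesity <- tibble::tibble(
      region_id = region_ids,
      prev_mean = runif(n_regions, 0.25, 0.45),
      prev_sd = 0.02
    )

    ir_table <- tibble::tibble(
      age_low = c(0, 18, 45, 65),
      age_high = c(17, 44, 64, 99),
      ir_mean = c(0.45, 0.30, 0.25, 0.20), # m3/kg/day, decreasing with age
      ir_sd = c(0.08, 0.06, 0.05, 0.04)
    )

    structure(
      list(
        regions = regions, exposure = exposure, concresp = concresp,
        css = css, age_dist = age_dist, obesity = obesity,
        ir_table = ir_table,
        truth = list(hill = truth, exposure_mean = exposure_mean, seed = seed)
      ),
      class = "synthetic_study"
    )
  })
}

#' Generate hill curves with known truth
#'
#' Standalone curve generator for fit-recovery studies: `n_curves`
#' hill truths (tp in [50, 120], log10 AC50 in [-1, 1]) observed at
#' `n_conc` log-spaced concentrations x `n_rep` replicates with
#' Gaussian noise whose sd is `noise_frac` of each curve's top.
#'
#' @param n_curves Number of curves.
#' @param n_conc,n_rep Design size per curve.
#' @param noise_frac Noise sd as a fraction of tp; default 0.05.
#' @param vary_slope Sample slopes in [0.8, 3] instead of 1.
#' @param seed RNG seed.
#' @return List with `data` (a concentration-response tibble) and
#'   `truth` (per-curve parameters).
#' @export
gen_hill_curves <- function(n_curves = 100, n_conc = 10, n_rep = 3,
                            noise_frac = 0.05, vary_slope = FALSE, seed = 1L) {
  with_substream(seed, "hill_curves", expr = {
    truth <- tibble::tibble(
      chemical_id = sprintf("CHEM%04d", seq_len(n_curves)),
      assay_id = "ASSAY_01",
      tp = runif(n_curves, 50, 120),
      log10_AC50 = runif(n_curves, -1, 1),
      slope = if (vary_slope) runif(n_curves, 0.8, 3) else 1
    )
    data <- truth |>
      dplyr::rowwise() |>
      dplyr::reframe(
        chemical_id = .data$chemical_id, assay_id = .data$assay_id,
        conc_um = rep(10^(.data$log10_AC50 + seq(-2.5, 2.5, length.out = n_conc)),
          n_rep),
        response = hill_response(.data$conc_um, .data$tp, .data$log10_AC50,
          .data$slope) + rnorm(n_conc * n_rep, 0, noise_frac * .data$tp)
      )
    list(data = data, truth = truth)
  })
}

#' Assemble a model directly from a synthetic study
#'
#' @param study A `synthetic_study`.
#' @param config A [risk_config()]; its seed defaults to the study seed.
#' @return A `risk_model`.
#' @export
assemble_synthetic <- function(study, config = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  config <- config %||% risk_config(seed = study$truth$seed)
  assemble_model(
    regions = study$regions,
    exposure = study$exposure,
    concresp = study$concresp,
    css = study$css,
    population_inputs = list(
      age_dist = study$age_dist, obesity = study$obesity,
      ir_table = study$ir_table
    ),
    config = config
  )
}
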