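#' Simulate ages from a bracketed age distribution
#'
#' Draws a bracket multinomially by its population proportion, then an
#' integer age uniformly within the bracket (inclusive). The top
#' open-ended bracket of census-style tables should be encoded with a
#' finite `age_high` (the bundled generator uses 85-99 for "85+").
#'
#' @param age_dist Data frame with columns `age_low`, `age_high`
#'   (integer years, inclusive) and `proportion` (summing to 1).
#' @param n Number of individuals.
#' @return Integer vector of ages, length `n`.
#' @export
simulate_age <- function(age_dist, n) {
  assert_columns(age_dist, c("age_low", "age_high", "proportion"), "age distribution")
  if (abs(sum(age_dist$proportion) - 1) > 1e-9) {
    abort("age bracket proportions must sum to 1")
  }
  if (any(age_dist$age_high < age_dist$age_low)) {
    abort("age brackets must have age_high >= age_low")
  }
  if (n == 0L) return(integer(0))
  idx <- sample.int(nrow(age_dist), n, replace = TRUE, prob = age_dist$proportion)
  lo <- age_dist$age_low[idx]
  hi <- age_dist$age_high[idx]
  as.integer(lo + floor(runif(n) * (hi - lo + 1)))
}

#' Simulate obesity status
#'
#' Two-stage draw: one region-level prevalence from
#' Normal(`prev_mean`, `prev_sd`) truncated to [0, 1] (propagating the
#' survey uncertainty in the prevalence estimate), then an independent
#' Bernoulli per individual.
#'
#' @param prev_mean Prevalence estimate in [0, 1].
#' @param prev_sd Standard deviation of the prevalence estimate.
#' @param n Number of individuals.
#' @return Character vector of weight classes, `"Normal"` or `"Obese"`.
#' @export
simulate_obesity <- function(prev_mean, prev_sd, n) {
  assert_scalar_number(prev_mean, "prev_mean", 0, 1)
  assert_scalar_number(prev_sd, "prev_sd", 0)
  if (n == 0L) return(character(0))
  p_star <- rnorm_trunc2(1, prev_mean, prev_sd, 0, 1)
  ifelse(rbinom(n, 1L, p_star) == 1L, "Obese", "Normal")
}

match_ir_bracket <- function(ages, ir_table) {
  idx <- vapply(ages, function(a) {
    j <- which(a >= ir_table$age_low & a <= ir_table$age_high)
    if (length(j) == 0) {
      abort(sprintf("no inhalation-rate bracket covers age %d", a))
    }
    j[1]
  }, integer(1))
  idx
}

#' Simulate inhalation rates by age
#'
#' Per individual, a draw from Normal(`ir_mean`, `ir_sd`) of the age
#' bracket covering the individual's age, truncated below at 0. Rates
#' are per kg body weight (m3/kg/day), so the internal-dose step needs
#' no separate body-weight division.
#'
#' @param ages Integer ages.
#' @param ir_table Data frame with `age_low`, `age_high`, `ir_mean`,
#'   `ir_sd` (m3/kg/day).
#' @return Numeric vector of inhalation rates, length `length(ages)`.
#' @export
simulate_inhalation_rate <- function(ages, ir_table) {
  assert_columns(ir_table, c("age_low", "age_high", "ir_mean", "ir_sd"),
    "inhalation-rate table")
  if (any(ir_table$ir_mean <= 0)) abort("`ir_mean` must be positive")
  if (length(ages) == 0L) return(numeric(0))
  idx <- match_ir_bracket(ages, ir_table)
  rnorm_trunc(length(ages), ir_table$ir_mean[idx], ir_table$ir_sd[idx])
}

#' Simulate external exposure concentrations
#'
#' One column per chemical; each individual's concentration is an
#' independent draw from Normal(mean, sd) truncated below at 0, with
#' (mean, sd) taken from the region's exposure record for that
#' chemical. The mean/sd pairs typically come from an upstream
#' geospatial exposure model; no spatial correlation is added here.
#'
#' @param exposure Data frame with columns `chemical_id`, `mean`, `sd`
#'   (ug/m3) for one region.
#' @param n Number of individuals.
#' @return Matrix `n x n_chemicals` (ug/m3), columns named by chemical.
#' @export
simulate_exposure <- function(exposure, n) {
  assert_columns(exposure, c("chemical_id", "mean", "sd"), "exposure table")
  if (any(exposure$mean < 0) || any(exposure$sd < 0)) {
    abort("exposure mean and sd must be non-negative")
  }
  chems <- trim_chem(exposure$chemical_id)
  if (anyDuplicated(chems)) abort("duplicate chemical in region exposure records")
  out <- vapply(
    seq_along(chems),
    function(j) rnorm_trunc(n, exposure$mean[j], exposure$sd[j]),
    numeric(n)
  )
  out <- matrix(out, nrow = n, ncol = length(chems))
  colnames(out) <- chems
  out
}

#' Age-group label for toxicokinetic strata
#'
#' @param ages Integer ages.
#' @param breaks Lower bounds of the age groups (default
#'   `c(0, 18, 45, 65)` giving groups 0-17, 18-44, 45-64, 65+).
#' @return Character labels, e.g. `"18-44"`, `"65+"`.
#' @export
css_age_group <- function(ages, breaks = c(0, 18, 45, 65)) {
  labs <- c(
    paste0(breaks[-length(breaks)], "-", breaks[-1] - 1),
    paste0(breaks[length(breaks)], "+")
  )
  labs[findInterval(ages, breaks)]
}

#' Bootstrap steady-state plasma concentrations
#'
#' For each individual x chemical, resamples one Css value uniformly
#' with replacement from the pre-simulated sample vector of the
#' individual's (age group, weight class) stratum. Also returns the
#' stratum medians used as central values by the sensitivity analysis.
#'
#' @param css_table Long data frame with `chemical_id`, `age_group`,
#'   `weight_class` (`"Normal"`/`"Obese"`), `sample_value`
#'   (uM per mg/kg/day, positive).
#' @param ages Integer ages.
#' @param weight_class Character weight classes, same length as `ages`.
#' @param chemicals Chemical ids to draw for.
#' @param age_breaks Passed to [css_age_group()].
#' @return List with `draws` (matrix individuals x chemicals) and
#'   `central` (matrix of stratum medians, same shape).
#' @export
simulate_css <- function(css_table, ages, weight_class, chemicals,
                         age_breaks = c(0, 18, 45, 65)) {
  assert_columns(css_table,
    c("chemical_id", "age_group", "weight_class", "sample_value"), "Css table")
  if (any(css_table$sample_value <= 0) || any(!is.finite(css_table$sample_value))) {
    abort("Css samples must be finite and positive")
  }
  n <- length(ages)
  grp <- css_age_group(ages, age_breaks)
  draws <- matrix(0, n, length(chemicals), dimnames = list(NULL, chemicals))
  central <- draws
  strata <- split(
    css_table$sample_value,
    list(trim_chem(css_table$chemical_id), css_table$age_group,
      css_table$weight_class),
    sep = "\r", drop = TRUE
  )
  key <- function(chem, g, w) paste(chem, g, w, sep = "\r")
  for (j in seq_along(chemicals)) {
    for (stratum in unique(paste(grp, weight_class, sep = "\r"))) {
      rows <- which(paste(grp, weight_class, sep = "\r") == stratum)
      parts <- strsplit(stratum, "\r", fixed = TRUE)[[1]]
      sv <- strata[[key(chemicals[j], parts[1], parts[2])]]
      if (is.null(sv)) {
        abort(sprintf(
          "no Css samples for chemical %s, age group %s, weight class %s",
          chemicals[j], parts[1], parts[2]
        ))
      }
      draws[rows, j] <- sv[sample.int(length(sv), length(rows), replace = TRUE)]
      central[rows, j] <- median(sv)
    }
  }
  list(draws = draws, central = central)
}

# Analytic median age of a bracketed age distribution (uniform within
# bracket); the "central value" used when the age component is pinned.
median_age <- function(age_dist) {
  cum <- cumsum(age_dist$proportion)
  i <- which(cum >= 0.5)[1]
  before <- if (i == 1) 0 else cum[i - 1]
  frac <- (0.5 - before) / age_dist$proportion[i]
  as.integer(round(age_dist$age_low[i] +
    frac * (age_dist$age_high[i] - age_dist$age_low[i])))
}

# Simulate one region's population. `vary` lists the stochastic
# components that draw from their distributions; the rest are pinned to
# central values (region median age, weight class Normal, bracket-mean
# inhalation rate, exposure mean, stratum-median Css). Each component
# consumes a dedicated RNG substream keyed by (seed, region, component)
# so re-running with a different `vary` set never perturbs another
# component's draws.
simulate_region <- function(region_id, exposure, population_inputs, chemicals,
                            n, seed, vary = c("age", "obesity", "ir", "C_ext",
                                              "css_params"),
                            age_breaks = c(0, 18, 45, 65)) {
  age_dist <- dplyr::filter(population_inputs$age_dist, .data$region_id == !!region_id)
  obesity <- dplyr::filter(population_inputs$obesity, .data$region_id == !!region_id)
  if (nrow(age_dist) == 0 || nrow(obesity) != 1) {
    abort(sprintf("incomplete population inputs for region %s", region_id))
  }
  ir_table <- population_inputs$ir_table
  exp_region <- exposure |>
    dplyr::filter(.data$region_id == !!region_id) |>
    dplyr::arrange(match(.data$chemical_id, chemicals))
  exp_region <- exp_region[exp_region$chemical_id %in% chemicals, , drop = FALSE]
  if (!setequal(exp_region$chemical_id, chemicals)) {
    abort(sprintf("region %s lacks exposure records for some roster chemicals",
      region_id))
  }

  ages <- if ("age" %in% vary) {
    with_substream(seed, region_id, "age", expr = simulate_age(age_dist, n))
  } else {
    rep(median_age(age_dist), n)
  }
  weight_class <- if ("obesity" %in% vary) {
    with_substream(seed, region_id, "obesity",
      expr = simulate_obesity(obesity$prev_mean, obesity$prev_sd, n))
  } else {
    rep("Normal", n)
  }
  ir <- if ("ir" %in% vary) {
    with_substream(seed, region_id, "ir",
      expr = simulate_inhalation_rate(ages, ir_table))
  } else {
    ir_table$ir_mean[match_ir_bracket(ages, ir_table)]
  }
  exposure_draws <- if ("C_ext" %in% vary) {
    with_substream(seed, region_id, "C_ext",
      expr = simulate_exposure(exp_region, n))
  } else {
    matrix(rep(exp_region$mean, each = n), n,
      dimnames = list(NULL, exp_region$chemical_id))
  }
  css <- with_substream(seed, region_id, "css",
    expr = simulate_css(population_inputs$css, ages, weight_class, chemicals,
      age_breaks))
  css_draws <- if ("css_params" %in% vary) css$draws else css$central
  css_central <- css$central[, chemicals, drop = FALSE]

  tibble::tibble(
    region_id = region_id,
    individual = seq_len(n),
    age = ages,
    weight_class = weight_class,
    ir = ir,
    exposure = exposure_draws[, chemicals, drop = FALSE],
    css = css_draws[, chemicals, drop = FALSE],
    css_central = css_central
  )
}

#' Simulate region-specific populations for a risk model
#'
#' Monte Carlo simulation of `n_per_region` individuals in every region:
#' age (bracketed census-style distribution), obesity status (two-stage
#' prevalence + Bernoulli), inhalation rate (age-bracket normal),
#' external exposure (truncated normal per chemical) and bootstrap Css
#' draws from the pre-simulated toxicokinetic sample table. All draws
#' are non-negative and the exposure/Css matrices have one column per
#' roster chemical.
#'
#' Randomness is organized as deterministic substreams keyed by
#' (model seed, region, component): regions can be simulated in any
#' order, and the sensitivity analysis can re-draw one component while
#' reproducing every other component's draws bit-for-bit.
#'
#' @param model A `risk_model` from [assemble_model()].
#' @param n_per_region Individuals per region; defaults to the model
#'   config (point-geometry region sets default to 1 per location).
#' @return The model with a `population` tibble (one row per
#'   individual, matrix-columns `exposure`, `css`, `css_central`).
#' @export
simulate_population <- function(model, n_per_region = NULL) {
  stopifnot(inherits(model, "risk_model"))
  point_default <- identical(attr(model$regions, "kind"), "point") &&
    !isTRUE(attr(model$config, "n_per_region_explicit"))
  n <- n_per_region %||% (if (point_default) 1L else model$config$n_per_region)
  if (!is.numeric(n) || n < 1) abort("`n_per_region` must be >= 1")
  n <- as.integer(n)
  pops <- purrr::map(model$regions$region_id, function(rid) {
    simulate_region(
      rid, model$exposure, model$population_inputs, model$roster,
      n = n, seed = model$config$seed,
      age_breaks = model$config$age_breaks
    )
  })
  model$population <- bind_population(pops, model$roster)
  model$provenance$n_per_region <- n
  model
}

# bind_rows drops dimnames on matrix columns; every region uses the
# roster column order, so they can be restored afterwards.
bind_population <- function(pops, roster) {
  pop <- dplyr::bind_rows(pops)
  for (mcol in c("exposure", "css", "css_central")) {
    colnames(pop[[mcol]]) <- roster
  }
  pop
}
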