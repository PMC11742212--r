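fake_results <- function(values_by_assay, region = "R001") {
  purrr::imap(values_by_assay, function(v, a) {
    tibble::tibble(region_id = region, assay_id = a,
      individual = seq_along(v), GCA_Eff = v)
  }) |> dplyr::bind_rows()
}

test_that("nested quantiles match a hand computation", {
  res <- fake_results(list(A1 = rep(1, 10), A2 = rep(3, 10)))
  grid <- summarize_multi_assay(res, "GCA_Eff", assay_quantiles = 50,
    summary_quantiles = 50)
  expect_equal(grid$value, 2) # median of the two assay medians {1, 3}
  const <- fake_results(list(A1 = rep(7, 5), A2 = rep(7, 5), A3 = rep(7, 5)))
  g2 <- summarize_multi_assay(const, "GCA_Eff", c(10, 50, 90), c(5, 95))
  expect_true(all(g2$value == 7))
})

test_that("single-assay grids collapse to the assay-level quantile", {
  set.seed(40)
  res <- fake_results(list(A1 = rnorm(50, 10)))
  grid <- summarize_multi_assay(res, "GCA_Eff", c(10, 50, 90), c(5, 50, 95))
  for (q in c(10, 50, 90)) {
    expected <- manual_percentile(res$GCA_Eff, q)
    expect_equal(grid$value[grid$assay_quantile == q],
      rep(expected, 3), tolerance = 1e-12)
  }
})

test_that("the grid equals a brute-force two-pass percentile on random matrices", {
  set.seed(41)
  for (rep in 1:20) {
    mat <- matrix(rexp(50 * 5), 50, 5) # individuals x assays
    res <- fake_results(purrr::map(setNames(1:5, paste0("A", 1:5)),
      ~ mat[, .x]))
    aq <- sort(sample(0:100, 3))
    sq <- sort(sample(0:100, 2))
    grid <- summarize_multi_assay(res, "GCA_Eff", aq, sq)
    for (q in aq) {
      assay_vals <- apply(mat, 2, manual_percentile, p = q)
      for (p in sq) {
        got <- grid$value[grid$assay_quantile == q & grid$summary_quantile == p]
        expect_equal(got, manual_percentile(assay_vals, p), tolerance = 1e-12)
      }
    }
    # monotone in the assay-level quantile for each (region, p)
    mono <- grid |>
      dplyr::arrange(summary_quantile, assay_quantile) |>
      dplyr::group_by(region_id, summary_quantile) |>
      dplyr::summarize(ok = !is.unsorted(value), .groups = "drop")
    expect_true(all(mono$ok))
  }
  empty <- tibble::tibble(region_id = character(), assay_id = character(),
    individual = integer(), GCA_Eff = numeric())
  expect_error(summarize_multi_assay(empty, "GCA_Eff"), "empty")
})

test_that("region_summary gives per-region percentiles and edge quantiles", {
  res <- tibble::tibble(region_id = "R001", assay_id = "A1",
    individual = 1:5, GCA_Eff = c(1, 2, 3, 4, 5))
  expect_equal(region_summary(res, "GCA_Eff", 50)$value, 3)
  expect_equal(region_summary(res, "GCA_Eff", c(0, 100))$value, c(1, 5))
  expect_error(region_summary(res, "nope"), "unknown metric")
  # agreement with the multi-assay path when there is one assay
  set.seed(42)
  res2 <- fake_results(list(A1 = runif(30)))
  rs <- region_summary(res2, "GCA_Eff", c(10, 90))
  grid <- summarize_multi_assay(res2, "GCA_Eff", c(10, 90), 50)
  expect_equal(sort(rs$value), sort(grid$value), tolerance = 1e-12)
})

test_that("pinning every component reproduces a zero-variance baseline", {
  model <- tiny_model(seed = 43, n_per_region = 10)
  base <- compute_sensitivity(model, "baseline", n = 8)
  per_group <- base |>
    dplyr::group_by(region_id, assay_id) |>
    dplyr::summarize(v = stats::var(value), .groups = "drop")
  expect_true(all(per_group$v == 0))
})

test_that("varying one component moves the output without touching other streams", {
  model <- tiny_model(seed = 44, n_per_region = 10)
  base <- compute_sensitivity(model, "baseline", n = 12)
  for (comp in c("age", "obesity", "css_params", "fit_params", "C_ext")) {
    res <- compute_sensitivity(model, comp, n = 12)
    v <- res |>
      dplyr::group_by(region_id, assay_id) |>
      dplyr::summarize(v = stats::var(value), .groups = "drop")
    expect_gt(max(v$v), 0)
  }
  # with exposure spread removed, varying C_ext reproduces the baseline
  flat <- model
  flat$exposure$sd <- 0
  res0 <- compute_sensitivity(flat, "C_ext", n = 12)
  base0 <- compute_sensitivity(flat, "baseline", n = 12)
  expect_equal(res0$value, base0$value, tolerance = 1e-12)
  expect_error(compute_sensitivity(model, "weather"), "unknown sensitivity")
})

test_that("age variation propagates through distinct Css strata", {
  study <- tiny_study(seed = 45)
  # two brackets mapping to different Css age groups
  study$age_dist <- tidyr::expand_grid(
    region_id = study$regions$region_id,
    tibble::tibble(age_low = c(5, 70), age_high = c(10, 80),
      proportion = c(0.5, 0.5))
  )
  model <- suppressWarnings(assemble_synthetic(study,
    risk_config(seed = 45, n_per_region = 10)))
  res <- compute_sensitivity(model, "age", n = 30)
  v <- res |>
    dplyr::group_by(region_id, assay_id) |>
    dplyr::summarize(v = stats::var(value), .groups = "drop")
  expect_true(all(v$v > 0))
})

test_that("weight-class densities join results to the population with no orphans", {
  model <- tiny_model(seed = 46, n_per_region = 12) |>
    simulate_population() |>
    calc_response()
  joined <- dplyr::inner_join(
    model$results,
    dplyr::select(model$population, region_id, individual, weight_class),
    by = c("region_id", "individual")
  )
  expect_equal(nrow(joined), nrow(model$results))
  expect_true(all(c("Normal", "Obese") %in% joined$weight_class))
})
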