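test_that("hill_response matches direct arithmetic and its limits", {
  # half-max at AC50 by definition
  expect_equal(hill_response(1, tp = 100, log10_AC50 = 0), 50)
  # tp=100, AC50=1, slope=2 at conc 10: 100 / (1 + 10^-2)
  expect_equal(hill_response(10, tp = 100, log10_AC50 = 0, slope = 2),
    100 / (1 + 1e-2))
  expect_lt(hill_response(1e-10, 100, 0), 1e-6)
  expect_equal(hill_response(1e12, 100, 0), 100, tolerance = 1e-9)
  expect_error(hill_response(0, 100, 0), "positive")
  expect_error(hill_response(-1, 100, 0), "positive")
})

test_that("hill_inverse is the exact algebraic inverse", {
  expect_equal(hill_inverse(50, tp = 100, log10_AC50 = 0), 1)
  # slope 1, E = 0.1 tp  ->  AC50 * E / (tp - E) = AC50 / 9
  expect_equal(hill_inverse(10, tp = 100, log10_AC50 = 0), 1 / 9)
  expect_error(hill_inverse(100, tp = 100, log10_AC50 = 0), "between")
  expect_error(hill_inverse(0, tp = 100, log10_AC50 = 0), "between")
})

test_that("inverse-then-forward round-trips across random parameters", {
  set.seed(101)
  for (i in 1:200) {
    tp <- runif(1, 20, 150)
    l10 <- runif(1, -2, 2)
    slope <- runif(1, 0.4, 5)
    e <- runif(1, 1e-4, 1 - 1e-4) * tp
    conc <- hill_inverse(e, tp, l10, slope)
    expect_equal(hill_response(conc, tp, l10, slope), e, tolerance = 1e-10)
  }
})

test_that("fit_hill recovers noiseless truth to high precision", {
  conc <- 10^seq(-2, 2, length.out = 10)
  data <- tibble::tibble(
    chemical_id = "X", assay_id = "A", conc_um = conc,
    response = hill_response(conc, 100, 0, 1)
  )
  fit <- fit_hill(data)
  expect_equal(fit$tp, 100, tolerance = 1e-3)
  expect_equal(fit$log10_AC50, 0, tolerance = 1e-3)
})

test_that("fit_hill flags degenerate and undersized inputs", {
  flat <- tibble::tibble(chemical_id = "X", assay_id = "A",
    conc_um = 10^seq(-2, 2, length.out = 8), response = 0)
  fit <- fit_hill(flat)
  expect_false(fit$converged)
  few <- tibble::tibble(chemical_id = "X", assay_id = "A",
    conc_um = c(1, 2, 3, 4), response = c(1, 2, 3, 4))
  expect_error(fit_hill(few), "fewer than 5")
})

test_that("stochastic replicates recover hill truth within tolerance", {
  gen <- gen_hill_curves(n_curves = 120, n_conc = 10, n_rep = 3,
    noise_frac = 0.05, seed = 7)
  fits <- fit_hill(gen$data)
  j <- dplyr::inner_join(tibble::as_tibble(fits), gen$truth,
    by = c("chemical_id", "assay_id"), suffix = c("", ".true"))
  expect_gt(mean(fits$converged), 0.95)
  expect_lt(median(abs(j$tp - j$tp.true) / j$tp.true), 0.05)
  expect_lt(median(abs(j$log10_AC50 - j$log10_AC50.true)), 0.1)
})

test_that("fit is invariant to row order and likelihood doubles on duplication", {
  gen <- gen_hill_curves(n_curves = 3, seed = 3)
  f1 <- fit_hill(gen$data)
  shuffled <- gen$data[sample(nrow(gen$data)), ]
  f2 <- fit_hill(shuffled)
  expect_equal(f1$tp, f2$tp, tolerance = 1e-7)
  expect_equal(f1$log10_AC50, f2$log10_AC50, tolerance = 1e-7)
  doubled <- dplyr::bind_rows(gen$data, gen$data)
  f3 <- fit_hill(doubled)
  expect_equal(f3$tp, f1$tp, tolerance = 1e-6)
  expect_equal(f3$loglik, 2 * f1$loglik, tolerance = 1e-6)
})

test_that("3-parameter fit agrees with 2-parameter fit on slope-1 data", {
  gen <- gen_hill_curves(n_curves = 20, noise_frac = 0.03, seed = 5)
  f2 <- tibble::as_tibble(fit_hill(gen$data, fixed_slope = TRUE))
  f3 <- tibble::as_tibble(fit_hill(gen$data, fixed_slope = FALSE))
  ok <- f3$converged & f2$converged
  ci_covers_1 <- abs(f3$slope[ok] - 1) <= 1.96 * f3$se_slope[ok]
  expect_gt(mean(ci_covers_1), 0.8)
  idx <- which(ok)[ci_covers_1]
  expect_equal(f2$tp[idx], f3$tp[idx], tolerance = 0.15)
})

test_that("true-model AIC beats the misspecified fixed-slope fit on steep curves", {
  gen <- gen_hill_curves(n_curves = 60, noise_frac = 0.05, vary_slope = TRUE,
    seed = 13)
  steep <- gen$truth$chemical_id[gen$truth$slope > 1.8]
  data <- dplyr::filter(gen$data, chemical_id %in% steep)
  f_free <- tibble::as_tibble(fit_hill(data, fixed_slope = FALSE))
  f_fix <- tibble::as_tibble(fit_hill(data, fixed_slope = TRUE))
  j <- dplyr::inner_join(f_free, f_fix, by = c("chemical_id", "assay_id"),
    suffix = c(".free", ".fix"))
  expect_gte(mean(j$aic.free <= j$aic.fix), 0.9)
})

test_that("tidy and glance give broom-shaped summaries", {
  gen <- gen_hill_curves(n_curves = 2, seed = 9)
  fits <- fit_hill(gen$data)
  td <- tidy(fits)
  expect_named(td, c("chemical_id", "assay_id", "term", "estimate", "std.error"))
  expect_equal(nrow(td), 2 * 3)
  gl <- glance(fits)
  expect_true(all(c("AIC", "logLik", "sigma", "df") %in% names(gl)))
  expect_equal(gl$df, rep(3L, 2))
})
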