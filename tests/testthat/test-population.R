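test_that("simulate_age draws inside brackets with the right frequencies", {
  one <- tibble::tibble(age_low = 0, age_high = 4, proportion = 1)
  set.seed(1)
  ages <- simulate_age(one, 500)
  expect_true(all(ages %in% 0:4))
  expect_identical(simulate_age(one, 0), integer(0))

  two <- tibble::tibble(age_low = c(0, 50), age_high = c(0, 50),
    proportion = c(0.5, 0.5))
  set.seed(2)
  ages <- simulate_age(two, 10000)
  expect_true(abs(mean(ages == 0) - 0.5) < 0.02) # binomial MC bound
  bad <- tibble::tibble(age_low = 0, age_high = 10, proportion = 0.7)
  expect_error(simulate_age(bad, 5), "sum to 1")
})

test_that("age bracket frequencies pass a chi-square goodness-of-fit check", {
  dist <- tibble::tibble(
    age_low = c(0, 18, 45, 65), age_high = c(17, 44, 64, 99),
    proportion = c(0.2, 0.35, 0.3, 0.15)
  )
  set.seed(3)
  ages <- simulate_age(dist, 1e5)
  obs <- table(cut(ages, c(-1, 17, 44, 64, 99)))
  p <- stats::chisq.test(obs, p = dist$proportion)$p.value
  expect_gt(p, 0.01)
})

test_that("simulate_obesity respects degenerate and stochastic prevalences", {
  set.seed(4)
  expect_true(all(simulate_obesity(0, 0, 50) == "Normal"))
  expect_true(all(simulate_obesity(1, 0, 50) == "Obese"))
  frac <- mean(simulate_obesity(0.35, 0, 10000) == "Obese")
  expect_lt(abs(frac - 0.35), 0.015)
  expect_error(simulate_obesity(1.2, 0, 5), "prev_mean")
})

test_that("inhalation rates follow the age bracket's distribution", {
  ir <- tibble::tibble(age_low = c(0, 18), age_high = c(17, 99),
    ir_mean = c(0.45, 0.3), ir_sd = c(0, 0.05))
  set.seed(5)
  expect_equal(simulate_inhalation_rate(c(3L, 10L), ir), c(0.45, 0.45))
  draws <- simulate_inhalation_rate(rep(30L, 10000), ir)
  expect_lt(abs(mean(draws) - 0.3), 0.005)
  expect_true(all(draws >= 0))
  expect_error(simulate_inhalation_rate(200L, ir), "age 200")
})

test_that("exposure draws are truncated normals per chemical", {
  exp_tab <- tibble::tibble(chemical_id = c("A", "B"), mean = c(0, 2),
    sd = c(0, 0.5))
  set.seed(6)
  draws <- simulate_exposure(exp_tab, 10000)
  expect_identical(colnames(draws), c("A", "B"))
  expect_true(all(draws[, "A"] == 0))
  expect_lt(abs(mean(draws[, "B"]) - 2), 0.03)
  expect_true(all(draws >= 0))
  const <- simulate_exposure(tibble::tibble(chemical_id = "A", mean = 3, sd = 0), 5)
  expect_true(all(const == 3))
  expect_error(
    simulate_exposure(tibble::tibble(chemical_id = "A", mean = -1, sd = 0), 5),
    "non-negative")
})

test_that("Css bootstrap resamples only from the matching stratum", {
  css <- tidyr::expand_grid(
    chemical_id = "A", age_group = c("0-17", "18-44", "45-64", "65+"),
    weight_class = c("Normal", "Obese")
  ) |>
    dplyr::mutate(samples = list(c(1, 2, 3, 4))) |>
    tidyr::unnest(samples) |>
    dplyr::rename(sample_value = samples)
  set.seed(7)
  res <- simulate_css(css, ages = rep(30L, 10000), weight_class = rep("Normal", 10000),
    chemicals = "A")
  expect_true(all(res$draws %in% c(1, 2, 3, 4)))
  expect_lt(abs(mean(res$draws) - 2.5), 0.02)
  expect_equal(unique(as.numeric(res$central)), 2.5)

  single <- tibble::tibble(chemical_id = "A", age_group = "18-44",
    weight_class = "Normal", sample_value = 7)
  res1 <- simulate_css(single, ages = c(20L, 30L),
    weight_class = c("Normal", "Normal"), chemicals = "A")
  expect_true(all(res1$draws == 7) && all(res1$central == 7))
  expect_error(
    simulate_css(single, ages = 70L, weight_class = "Obese", chemicals = "A"),
    "age group 65\\+")
})

test_that("population simulation is seed-deterministic and order-independent", {
  model <- tiny_model(seed = 11, n_per_region = 20)
  m1 <- simulate_population(model)
  m2 <- simulate_population(model)
  expect_identical(m1$population, m2$population)
  # per-region substreams: simulating a single region reproduces its slice
  rid <- model$regions$region_id[2]
  solo <- toxrisk:::simulate_region(
    rid, model$exposure, model$population_inputs, model$roster,
    n = 20, seed = model$config$seed, age_breaks = model$config$age_breaks
  )
  slice <- dplyr::filter(m1$population, region_id == rid)
  expect_equal(solo$age, slice$age)
  expect_equal(solo$ir, slice$ir)
  expect_equal(unname(solo$exposure), unname(slice$exposure))
  expect_true(all(m1$population$ir >= 0))
  expect_true(all(m1$population$exposure >= 0) && all(m1$population$css > 0))
})

test_that("css age groups label the default strata", {
  expect_equal(css_age_group(c(0L, 17L, 18L, 44L, 45L, 64L, 65L, 99L)),
    c("0-17", "0-17", "18-44", "18-44", "45-64", "45-64", "65+", "65+"))
})
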