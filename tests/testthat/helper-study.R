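# Shared fixtures built in code (no files): a small assembled model and
# independent oracles used across test files.

tiny_study <- function(seed = 42, ...) {
  gen_synthetic_study(n_regions = 3, n_chems = 3, n_assays = 2,
    n_conc = 8, noise_sd = 2, seed = seed, ...)
}

tiny_model <- function(seed = 42, n_per_region = 25, ...) {
  suppressWarnings(assemble_synthetic(
    tiny_study(seed = seed, ...),
    risk_config(seed = seed, n_per_region = n_per_region)
  ))
}

# Independent slope-1 GCA oracle: solves sum(C_i / f_i^{-1}(E)) = 1
# numerically with the signed inverse (partial-agonist extension), on a
# bracket that always contains the root.
gca_root_oracle <- function(concs, tp, ac50) {
  g <- function(e) sum(concs * (tp - e) / (ac50 * e)) - 1
  upper <- sum(concs * tp / ac50) + 1
  stats::uniroot(g, c(1e-14, upper), tol = 1e-14)$root
}

# Independent nested-percentile oracle: sort-based linear interpolation
# (no call to the package's percentile helper).
manual_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

random_hill_params <- function(k) {
  tibble::tibble(
    tp = runif(k, 50, 120),
    log10_AC50 = runif(k, -1, 1),
    slope = 1
  )
}
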