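#' Hill concentration-response function
#'
#' Evaluates the tcpl-style hill curve
#' \deqn{f(c) = tp / (1 + 10^{(\log_{10}AC_{50} - \log_{10}c)\,slope})}
#' where `tp` is the maximal response (% activity), `AC50` the
#' half-maximal concentration (uM) and `slope` the hill coefficient.
#'
#' @param conc Concentration(s) in uM, strictly positive.
#' @param tp Top (maximal response, % activity), > 0.
#' @param log10_AC50 log10 of the half-maximal concentration (uM).
#' @param slope Hill coefficient, > 0. Defaults to 1 (the two-parameter
#'   variant used by the closed-form concentration-addition path).
#' @return Response in % activity, same length as `conc`; values lie in
#'   (0, tp) and increase strictly with concentration.
#' @examples
#' hill_response(1, tp = 100, log10_AC50 = 0)   # half-max: 50
#' hill_response(10, tp = 100, log10_AC50 = 0, slope = 2)
#' @export
hill_response <- function(conc, tp, log10_AC50, slope = 1) {
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    abort("`conc` must be finite and strictly positive")
  }
  if (any(tp <= 0) || any(slope <= 0)) {
    abort("`tp` and `slope` must be positive")
  }
  tp / (1 + 10^((log10_AC50 - log10(conc)) * slope))
}

#' Invert a hill curve
#'
#' Concentration (uM) at which the hill curve reaches a given effect:
#' \eqn{f^{-1}(E) = AC_{50} (E / (tp - E))^{1/slope}}. Needed by
#' generalized concentration addition and by hazard-quotient search.
#'
#' @param effect Effect in % activity, strictly inside (0, tp).
#' @inheritParams hill_response
#' @return Concentration in uM.
#' @export
hill_inverse <- function(effect, tp, log10_AC50, slope = 1) {
  if (any(!is.finite(effect)) || any(effect <= 0) || any(effect >= tp)) {
    abort("`effect` must lie strictly between 0 and `tp`")
  }
  10^log10_AC50 * (effect / (tp - effect))^(1 / slope)
}

# Negative log-likelihood of the Gaussian hill model; par is
# (tp, log10_AC50[, slope], log_sigma) depending on fixed_slope.
hill_nll <- function(par, log10_conc, resp, fixed_slope) {
  tp <- par[1]
  l10ac50 <- par[2]
  slope <- if (fixed_slope) 1 else par[3]
  log_sigma <- par[length(par)]
  mu <- tp / (1 + 10^((l10ac50 - log10_conc) * slope))
  n <- length(resp)
  sigma2 <- exp(2 * log_sigma)
  n * log_sigma + sum((resp - mu)^2) / (2 * sigma2) + n * log(2 * pi) / 2
}

fit_hill_one <- function(log10_conc, resp, fixed_slope) {
  n <- length(resp)
  out <- list(
    tp = NA_real_, log10_AC50 = NA_real_,
    slope = if (fixed_slope) 1 else NA_real_, log_sigma = NA_real_,
    se_tp = NA_real_, se_log10_AC50 = NA_real_, se_slope = NA_real_,
    converged = FALSE, loglik = NA_real_, aic = NA_real_
  )
  if (sd(resp) < 1e-12 || max(resp) <= 0) {
    return(out) # flat or non-positive data: degenerate, not an error
  }
  tp_hi <- 1.5 * max(resp)
  lo <- c(1e-6, min(log10_conc) - 3, if (!fixed_slope) 0.3)
  hi <- c(tp_hi, max(log10_conc) + 3, if (!fixed_slope) 8)
  start <- c(
    min(max(max(resp), 1e-3), tp_hi), median(log10_conc),
    if (!fixed_slope) 1
  )
  # sigma is profiled out (sigma_hat^2 = SS/n), leaving a bounded
  # least-squares problem solved by Levenberg-Marquardt
  resid_fn <- function(par) {
    slope <- if (fixed_slope) 1 else par[3]
    resp - par[1] / (1 + 10^((par[2] - log10_conc) * slope))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, lower = lo, upper = hi, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-14, ptol = 1e-14, gtol = 1e-14
      )
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(out)
  theta <- fit$par
  ss <- sum(resid_fn(theta)^2)
  log_sigma <- 0.5 * log(ss / n)
  par_full <- c(theta, log_sigma)
  nll <- hill_nll(par_full, log10_conc, resp, fixed_slope)
  k_mean <- length(theta)
  out$tp <- theta[1]
  out$log10_AC50 <- theta[2]
  if (!fixed_slope) out$slope <- theta[3]
  out$log_sigma <- log_sigma
  out$loglik <- -nll
  out$aic <- 2 * (k_mean + 1) - 2 * out$loglik

  grad <- tryCatch(
    pracma::grad(hill_nll, par_full,
      log10_conc = log10_conc, resp = resp, fixed_slope = fixed_slope
    ),
    error = function(e) rep(Inf, length(par_full))
  )
  hess <- tryCatch(
    pracma::hessian(hill_nll, par_full,
      log10_conc = log10_conc, resp = resp, fixed_slope = fixed_slope
    ),
    error = function(e) NULL
  )
  pd <- !is.null(hess) && all(is.finite(hess)) &&
    all(eigen(hess, symmetric = TRUE, only.values = TRUE)$values > 0)
  # boundary solutions are not interior optima of the likelihood
  at_bound <- any(theta - lo < 1e-6 * pmax(1, abs(lo))) ||
    any(hi - theta < 1e-6 * pmax(1, abs(hi)))
  out$converged <- fit$info %in% 1:3 && pd && !at_bound &&
    sqrt(sum(grad^2)) < 1e-6 * max(1, abs(nll))
  if (pd) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc)[seq_len(k_mean)] > 0)) {
      ses <- sqrt(diag(vc))
      out$se_tp <- ses[1]
      out$se_log10_AC50 <- ses[2]
      if (!fixed_slope) out$se_slope <- ses[3]
    } else {
      out$converged <- FALSE
    }
  }
  if (out$converged && (!is.finite(out$se_tp) || !is.finite(out$se_log10_AC50))) {
    out$converged <- FALSE
  }
  out
}

#' Fit hill models to concentration-response data
#'
#' Maximum-likelihood fit of a hill curve to every (chemical, assay)
#' group of a concentration-response table, under independent Gaussian
#' residuals with a free scale parameter. The two-parameter variant
#' (`fixed_slope = TRUE`, the default) fixes the hill coefficient at 1,
#' which is the variant required by the closed-form generalized
#' concentration addition solution; the three-parameter variant
#' estimates the slope inside [0.3, 8].
#'
#' Standard errors come from the inverse observed information. A fit is
#' flagged `converged = FALSE` when the optimizer fails, the gradient of
#' the negative log-likelihood is not numerically zero, the observed
#' information is not positive definite, the solution sits on a box
#' bound, or the responses are degenerate (all identical); such curves
#' are excluded from the analysis roster downstream.
#'
#' @param data Data frame with columns `chemical_id`, `assay_id`,
#'   `conc_um` (concentration, uM, linear scale) and `response`
#'   (% activity). At least 5 distinct concentrations per curve.
#' @param fixed_slope If `TRUE` (default) fit the 2-parameter hill with
#'   slope fixed at 1; otherwise estimate the slope.
#' @return A tibble of class `hill_params` with one row per
#'   (chemical, assay): estimates `tp`, `log10_AC50`, `slope`,
#'   `log_sigma`, standard errors, `converged`, `loglik` and `aic`.
#' @seealso [hill_response()], [hill_inverse()], [tidy.hill_params()]
#' @export
fit_hill <- function(data, fixed_slope = TRUE) {
  assert_columns(data, c("chemical_id", "assay_id", "conc_um", "response"),
    "concentration-response data")
  if (any(!is.finite(data$conc_um)) || any(data$conc_um <= 0)) {
    abort("`conc_um` must be finite and positive")
  }
  if (any(!is.finite(data$response))) abort("`response` must be finite")
  data <- dplyr::mutate(data, chemical_id = trim_chem(.data$chemical_id))
  fits <- data |>
    dplyr::group_by(.data$chemical_id, .data$assay_id) |>
    dplyr::group_modify(function(df, key) {
      if (dplyr::n_distinct(df$conc_um) < 5) {
        abort(sprintf(
          "curve (%s, %s) has fewer than 5 distinct concentrations",
          key$chemical_id, key$assay_id
        ))
      }
      tibble::as_tibble(fit_hill_one(log10(df$conc_um), df$response, fixed_slope))
    }) |>
    dplyr::ungroup()
  structure(fits, class = c("hill_params", class(fits)), fixed_slope = fixed_slope)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy hill fits into one row per parameter
#'
#' @param x A `hill_params` tibble from [fit_hill()].
#' @param ... Unused.
#' @return A tibble with columns `chemical_id`, `assay_id`, `term`,
#'   `estimate`, `std.error`.
#' @method tidy hill_params
#' @export
tidy.hill_params <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::rowwise() |>
    dplyr::reframe(
      chemical_id = .data$chemical_id,
      assay_id = .data$assay_id,
      term = c("tp", "log10_AC50", "slope"),
      estimate = c(.data$tp, .data$log10_AC50, .data$slope),
      std.error = c(.data$se_tp, .data$se_log10_AC50, .data$se_slope)
    )
}

#' One-row-per-curve fit summary
#'
#' @inheritParams tidy.hill_params
#' @return A tibble with `chemical_id`, `assay_id`, `converged`,
#'   `logLik`, `AIC`, `sigma` and `df` (free parameters incl. the
#'   residual scale).
#' @method glance hill_params
#' @export
glance.hill_params <- function(x, ...) {
  k <- if (isTRUE(attr(x, "fixed_slope"))) 3L else 4L
  tibble::as_tibble(x) |>
    dplyr::transmute(
      .data$chemical_id, .data$assay_id, .data$converged,
      logLik = .data$loglik, AIC = .data$aic,
      sigma = exp(.data$log_sigma), df = k
    )
}
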