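#' Internal dose from inhaled air concentration
#'
#' Converts an external air concentration to an internal dose rate,
#' \eqn{D = C_{ext} \cdot IR \cdot t \cdot s}. The inhalation rate is
#' carried per kg body weight (m3/kg/day), so body weight needs no
#' explicit division; the default scaling `1e-3` converts ug to mg.
#'
#' @param c_ext External concentration, ug/m3 (vector or matrix over
#'   individuals x chemicals).
#' @param ir Inhalation rate, m3/kg/day (scalar or per individual).
#' @param time_days Exposure duration in days; defaults to 1, matching
#'   the steady-state assumption of the plasma-concentration scaling.
#' @param dose_scaling Unit conversion factor, default `1e-3` (ug -> mg).
#' @return Internal dose in mg/kg/day with the shape of `c_ext`.
#' @examples
#' calc_internal_dose(10, ir = 0.2)  # 0.002 mg/kg/day
#' @export
calc_internal_dose <- function(c_ext, ir, time_days = 1, dose_scaling = 1e-3) {
  if (any(c_ext < 0, na.rm = FALSE) || any(ir < 0) || any(time_days < 0) ||
      any(dose_scaling < 0)) {
    abort("all dose inputs must be non-negative")
  }
  c_ext * ir * time_days * dose_scaling
}

#' In-vitro-equivalent concentration
#'
#' Scales an internal dose rate to an in-vitro-equivalent medium
#' concentration by multiplying with the steady-state plasma
#' concentration per unit dose rate (Css), elementwise over
#' individuals x chemicals.
#'
#' @param d_int Internal dose, mg/kg/day (vector or matrix).
#' @param css Css, uM per mg/kg/day, same shape as `d_int` (or scalar).
#' @return Concentration in uM.
#' @export
calc_invitro_concentration <- function(d_int, css) {
  if (any(d_int < 0) || any(css < 0)) abort("inputs must be non-negative")
  if (!is.null(dim(d_int)) && !is.null(dim(css)) &&
      !identical(dim(d_int), dim(css))) {
    abort("`d_int` and `css` have mismatched dimensions")
  }
  if (is.null(dim(d_int)) && is.null(dim(css)) &&
      length(css) > 1L && length(d_int) != length(css)) {
    abort("`d_int` and `css` have mismatched lengths")
  }
  d_int * css
}

check_mixture_params <- function(concs, params) {
  assert_columns(params, c("tp", "log10_AC50", "slope"), "hill parameters")
  if (nrow(params) != length(concs)) {
    abort("`concs` and `params` must have one entry per chemical")
  }
  if (any(!is.finite(concs)) || any(concs < 0)) {
    abort("`concs` must be finite and non-negative")
  }
  if ("converged" %in% names(params) && !all(params$converged)) {
    abort("all mixture components must have converged hill fits")
  }
  invisible(params)
}

#' Generalized concentration addition mixture effect
#'
#' Joint effect `E` of a chemical mixture under generalized
#' concentration addition, the solution of
#' \eqn{\sum_i C_i / f_i^{-1}(E) = 1} where \eqn{f_i^{-1}} is the
#' inverse hill curve of component i. With all slopes equal to 1 the
#' solution is closed-form,
#' \deqn{E = \frac{\sum_i C_i\,tp_i/AC50_i}{1 + \sum_i C_i/AC50_i},}
#' which extends concentration addition to partial agonists (the
#' inverse may be evaluated beyond a component's own maximum). With
#' non-unit slopes the inverse is only defined below each component's
#' top, so `E` is found by root bracketing on (0, min tp); if no root
#' exists in that interval the boundary value is returned with a
#' warning and attribute `flagged = TRUE`.
#'
#' @param concs Non-negative concentrations, uM, one per chemical.
#' @param params Data frame of hill parameters with columns `tp`,
#'   `log10_AC50`, `slope` (one row per chemical).
#' @return Mixture effect in % activity (scalar).
#' @examples
#' params <- data.frame(tp = c(100, 100), log10_AC50 = c(0, 0), slope = 1)
#' response_gca(c(1, 1), params)  # 200/3
#' @export
response_gca <- function(concs, params) {
  check_mixture_params(concs, params)
  if (all(concs == 0)) return(0)
  ac50 <- 10^params$log10_AC50
  if (all(abs(params$slope - 1) < 1e-12)) {
    return(sum(concs * params$tp / ac50) / (1 + sum(concs / ac50)))
  }
  # general-slope path: the LHS of sum(C_i / f_i^{-1}(E)) - 1 decreases
  # monotonically in E from +Inf on (0, min tp)
  top <- min(params$tp)
  g <- function(e) {
    inv <- ac50 * (e / (params$tp - e))^(1 / params$slope)
    sum(concs / inv) - 1
  }
  upper <- top * (1 - 1e-12)
  if (g(upper) > 0) {
    warn("generalized concentration addition: no root below the smallest top; returning the boundary")
    return(structure(upper, flagged = TRUE))
  }
  lower <- top * 1e-15
  while (g(lower) < 0) lower <- lower / 10
  stats::uniroot(g, c(lower, upper), tol = 1e-13 * top)$root
}

#' Independent action mixture effect
#'
#' Combines normalized single-chemical effects multiplicatively:
#' \deqn{E = E_{ref}\Big(1 - \prod_i (1 - f_i(C_i)/E_{ref})\Big)}
#' with reference maximum `e_ref` defaulting to the largest top among
#' the components, which keeps every survival factor in [0, 1].
#'
#' @inheritParams response_gca
#' @param e_ref Reference maximal response (% activity); default
#'   `max(params$tp)`.
#' @return Mixture effect in % activity; lies between the largest
#'   single-chemical effect and `e_ref`.
#' @export
response_ia <- function(concs, params, e_ref = max(params$tp)) {
  check_mixture_params(concs, params)
  if (e_ref <= 0) abort("`e_ref` must be positive")
  eff <- ifelse(
    concs > 0,
    hill_response(pmax(concs, .Machine$double.xmin), params$tp,
      params$log10_AC50, params$slope),
    0
  )
  if (any(eff > e_ref + 1e-12)) {
    abort("single-chemical effect exceeds `e_ref`")
  }
  e_ref * (1 - prod(1 - pmin(eff, e_ref) / e_ref))
}

#' Mixture hazard quotient
#'
#' Unitless ratio comparing the mixture's concentration vector to the
#' concentration (at fixed component ratio) that produces a reference
#' response. The reference response is `hq_percent`% of the reference
#' maximum `e_ref` (largest top among components). The scalar `s*`
#' solving `response(s * concs) = (hq_percent/100) * e_ref` is found by
#' monotone bracketing on log10 s in [-12, 12] and the hazard quotient
#' is `1/s*`: values above 1 mean the mixture already exceeds the
#' reference response. If the target response is unreachable at any
#' scaling, 0 is returned with attribute `flagged = TRUE`.
#'
#' The alternative hazard-index convention
#' \eqn{\sum_i C_i / EC_{p,i}} is available via
#' `convention = "hazard_index"` (slope-wise per-component inversion;
#' components whose top lies below the reference response contribute
#' 0 with a flag).
#'
#' @inheritParams response_gca
#' @param hq_percent Reference response level as a percent of `e_ref`,
#'   in (0, 100); default 10 ("HQ.10").
#' @param method Mixture model used for the response: `"GCA"` or `"IA"`.
#' @param convention `"fixed_ratio"` (default, whole-mixture inversion)
#'   or `"hazard_index"`.
#' @return Non-negative scalar hazard quotient; homogeneous of degree 1
#'   in `concs`.
#' @examples
#' params <- data.frame(tp = 100, log10_AC50 = 0, slope = 1)
#' calc_hq(1, params, hq_percent = 10)  # 9
#' @export
calc_hq <- function(concs, params, hq_percent = 10, method = c("GCA", "IA"),
                    convention = c("fixed_ratio", "hazard_index")) {
  method <- match.arg(method)
  convention <- match.arg(convention)
  check_mixture_params(concs, params)
  if (!is.finite(hq_percent) || hq_percent <= 0 || hq_percent >= 100) {
    abort("`hq_percent` must lie strictly between 0 and 100")
  }
  if (all(concs == 0)) return(0)
  e_ref <- max(params$tp)
  target <- hq_percent / 100 * e_ref
  if (convention == "hazard_index") {
    ok <- params$tp > target
    if (any(!ok)) {
      warn("hazard_index: components with top below the reference response contribute 0")
    }
    ecp <- rep(Inf, nrow(params))
    ecp[ok] <- hill_inverse(target, params$tp[ok], params$log10_AC50[ok],
      params$slope[ok])
    hq <- sum(concs / ecp)
    if (any(!ok)) attr(hq, "flagged") <- TRUE
    return(hq)
  }
  resp_at <- function(log10_s) {
    cs <- 10^log10_s * concs
    if (method == "GCA") {
      suppressWarnings(as.numeric(response_gca(cs, params)))
    } else {
      response_ia(cs, params)
    }
  }
  f <- function(log10_s) resp_at(log10_s) - target
  if (f(12) < 0) {
    return(structure(0, flagged = TRUE)) # target unreachable as s -> Inf
  }
  if (f(-12) > 0) {
    return(structure(1e12, flagged = TRUE))
  }
  s_star <- stats::uniroot(f, c(-12, 12), tol = 1e-10, maxiter = 200)$root
  10^(-s_star)
}
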