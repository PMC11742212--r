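#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn .data
#' @importFrom stats median pnorm qnorm quantile rbinom rnorm runif sd setNames
#' @importFrom utils head
NULL

# Draw from Normal(mean, sd) truncated below at `lower` by inverse-CDF
# sampling; exact for sd = 0 (returns the clamped mean).
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  stopifnot(length(mean) %in% c(1L, n), length(sd) %in% c(1L, n))
  if (n == 0L) return(numeric(0))
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- pmax(mean, lower)
  pos <- sd > 0
  if (any(pos)) {
    p0 <- pnorm(lower, mean[pos], sd[pos])
    u <- runif(sum(pos), min = p0, max = 1)
    out[pos] <- qnorm(u, mean[pos], sd[pos])
    # guard against qnorm(1 - eps) overshoot at extreme truncation
    out[pos] <- pmax(out[pos], lower)
  }
  out
}

# Normal(mean, sd) truncated to [lower, upper]; scalar n use only.
rnorm_trunc2 <- function(n, mean, sd, lower, upper) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  p <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  pmin(pmax(qnorm(p, mean, sd), lower), upper)
}

# Deterministic child seed for a (region, component) RNG substream:
# a polynomial string hash over (seed, keys) folded into [0, 2^31 - 2],
# so substreams are reproducible and independent of the order regions
# are simulated in. The modulus is a prime below 2^31.
substream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "\r")
  bytes <- utf8ToInt(key)
  h <- 17
  for (b in bytes) {
    h <- (h * 1031 + b) %% 2147483629
  }
  as.integer(h)
}

# Run `expr` under a dedicated RNG substream, restoring the caller's state.
with_substream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, ...))
  expr
}

# Empirical percentile (0-100 scale) with linear interpolation between
# order statistics (stats::quantile type 7).
percentile <- function(x, p) {
  stopifnot(all(p >= 0 & p <= 100))
  unname(quantile(x, probs = p / 100, type = 7, names = FALSE))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

trim_chem <- function(x) stringr::str_trim(as.character(x))
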