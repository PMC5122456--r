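#' Geometric mean
#'
#' Geometric mean of strictly positive values, computed on the log scale.
#' This is the default "average" used throughout the package for ratios,
#' which are multiplicative quantities.
#'
#' @param x numeric vector, all values > 0.
#' @param na.rm drop `NA` values before averaging.
#' @return a single number.
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0, na.rm = TRUE)) {
    abort("geometric mean requires strictly positive values")
  }
  exp(mean(log(x)))
}

## checks a scalar numeric config field; `name` appears in the error so a
## misconfigured simulation names the offending field
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("configuration error: `%s` must be a single number", name))
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    abort(sprintf(
      "configuration error: `%s` = %s outside valid range %s%s, %s]",
      name, format(x), if (strict_lower) "(" else "[", format(lower), format(upper)
    ))
  }
  if (integerish && x != round(x)) {
    abort(sprintf("configuration error: `%s` must be an integer", name))
  }
  invisible(x)
}

check_range2 <- function(x, name, lower = -Inf, integerish = TRUE) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2]) {
    abort(sprintf(
      "configuration error: `%s` must be c(min, max) with min <= max", name
    ))
  }
  if (any(x < lower)) {
    abort(sprintf("configuration error: `%s` must be >= %s", name, lower))
  }
  if (integerish && any(x != round(x))) {
    abort(sprintf("configuration error: `%s` must be integers", name))
  }
  invisible(x)
}

## run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

## deterministic largest-remainder apportionment of n items to categories
## with the given weights; used so planted cohort fractions are exact by
## construction rather than binomially noisy
apportion <- function(n, weights) {
  w <- weights / sum(weights)
  raw <- n * w
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## uniform integer draw from [range[1], range[2]], safe against base
## sample()'s scalar expansion when the range collapses to one value
sample_range <- function(range, n = 1L) {
  if (range[1] == range[2]) {
    rep(as.integer(range[1]), n)
  } else {
    sample(seq(range[1], range[2]), n, replace = TRUE)
  }
}
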