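# Internal numerical helpers shared across the generator and analysis code.

#' Truncated normal draws
#'
#' Draws from Normal(mean, sd) conditioned on `x > lower`, via inverse-CDF
#' sampling.  Used throughout the synthetic-data generator so that volumes,
#' densities, speeds and times can never be non-positive.
#'
#' @param n number of draws.
#' @param mean,sd moments of the parent normal; `sd = 0` returns `mean`
#'   exactly.
#' @param lower lower truncation bound (exclusive).
#' @return numeric vector of length `n`, all values `> lower`.
#' @keywords internal
#' @noRd
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  stopifnot(n >= 0, sd >= 0)
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean < lower) {
      abort("Degenerate truncated normal: sd = 0 and mean <= lower bound.",
            class = "spindlescale_error_params")
    }
    return(rep(mean, n))
  }
  p_lo <- pnorm(lower, mean, sd)
  if (p_lo >= 1 - 1e-12) {
    abort("Truncation bound leaves essentially no probability mass.",
          class = "spindlescale_error_params")
  }
  u <- runif(n, p_lo, 1)
  qnorm(u, mean, sd)
}

#' Smooth soft-minimum
#'
#' `softmin(x, cap, scale)` approaches `min(x, cap)` as `scale -> 0` while
#' staying smooth; used for the saturating centrosome-volume law, where the
#' data show an upper limit rather than a hard kink.
#'
#' @keywords internal
#' @noRd
softmin <- function(x, cap, scale) {
  if (is.null(cap) || !is.finite(cap)) return(x)
  stopifnot(scale > 0)
  lo <- pmin(x, cap)
  hi <- pmax(x, cap)
  lo - scale * log1p(exp(-(hi - lo) / scale))
}

#' Deterministic seed fan-out
#'
#' One user-facing seed is split into per-stage seeds by a fixed affine rule
#' modulo 2^31 - 1, so that independent pipeline stages use decorrelated but
#' reproducible streams.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return integer sub-seed in [1, 2^31 - 2].
#' @export
#' @examples
#' split_seed(1, "cells")
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(stage) == 1)
  h <- sum(utf8ToInt(as.character(stage)) * (seq_along(utf8ToInt(as.character(stage))) %% 7 + 1))
  as.integer((abs(seed) %% 65011 * 32611 + h * 10007 + 17) %% (2^31 - 1) + 1)
}

# Run `expr` under a local RNG seeded with `seed`; the caller's RNG state is
# untouched.  `seed = NULL` uses the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

stop_if_not_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("`", what, "` must be strictly positive and finite."),
          class = "spindlescale_error_params")
  }
  invisible(x)
}
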