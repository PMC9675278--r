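# Truncated-normal machinery used by the MtI cohort generator.
#
# MtI values live on the closed interval [0, 100].  Group summaries in
# methylation studies are reported as mean +/- SD, so the generator needs a
# bounded two-parameter family whose *post-truncation* moments can be set to
# the reported values.  We use a normal distribution truncated to [lo, hi]
# and solve numerically for the parent (mu, sigma).

#' Moments of a truncated normal distribution
#'
#' Mean and standard deviation of a normal(mu, sigma) restricted to
#' `[lo, hi]`.
#'
#' @param mu,sigma parent-normal parameters (`sigma > 0`).
#' @param lo,hi truncation bounds.
#' @return Numeric vector `c(mean, sd)` of the truncated distribution.
#' @keywords internal
truncnorm_moments <- function(mu, sigma, lo = 0, hi = 100) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  if (!is.finite(Z) || Z < 1e-300) {
    return(c(NaN, NaN))
  }
  r <- (dnorm(a) - dnorm(b)) / Z
  m <- mu + sigma * r
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z - r^2)
  c(m, sqrt(pmax(v, 0)))
}

#' Calibrate a truncated normal to target post-truncation moments
#'
#' Finds parent parameters (mu, sigma) such that the normal truncated to
#' `[lo, hi]` has the requested mean and standard deviation.  Uses
#' Nelder-Mead on the squared moment error; an infeasible (mean, sd) pair
#' (e.g. an SD larger than any `[lo, hi]`-truncated normal can attain) is
#' reported as a calibration error.
#'
#' @param target_mean,target_sd desired moments after truncation.
#' @param lo,hi truncation bounds.
#' @param tol maximum tolerated residual on either moment.
#' @return List with elements `mu`, `sigma`, `lo`, `hi`.
#' @examples
#' p <- calibrate_truncnorm(51.0, 23.2)
#' truncnorm_moments(p$mu, p$sigma)  # ~ c(51.0, 23.2)
#' @export
calibrate_truncnorm <- function(target_mean, target_sd, lo = 0, hi = 100,
                                tol = 1e-4) {
  stopifnot(is.numeric(target_mean), is.numeric(target_sd), hi > lo)
  if (target_mean < lo || target_mean > hi) {
    stop("calibration error: target_mean ", target_mean,
         " outside [", lo, ", ", hi, "]")
  }
  if (target_sd <= 0) {
    stop("calibration error: target_sd must be > 0")
  }
  obj <- function(par) {
    mm <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    if (any(!is.finite(mm))) return(1e12)
    (mm[1] - target_mean)^2 + (mm[2] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 10000, reltol = 1e-15))
  mu <- fit$par[1]
  sigma <- exp(fit$par[2])
  mm <- truncnorm_moments(mu, sigma, lo, hi)
  if (any(!is.finite(mm)) || max(abs(mm - c(target_mean, target_sd))) > tol) {
    stop("calibration error: no [", lo, ", ", hi, "]-truncated normal ",
         "attains mean ", target_mean, " and sd ", target_sd)
  }
  list(mu = mu, sigma = sigma, lo = lo, hi = hi)
}

# Inverse-CDF draw from the truncated normal, n values from the current RNG
# stream.  Kept internal; callers manage seeding.
rtruncnorm_ <- function(n, mu, sigma, lo, hi) {
  plo <- pnorm((lo - mu) / sigma)
  phi <- pnorm((hi - mu) / sigma)
  x <- mu + sigma * qnorm(plo + runif(n) * (phi - plo))
  pmin(pmax(x, lo), hi)
}

# Deterministic per-unit substream seed.  Mixing the top-level seed with the
# unit index means adding units to a cohort never perturbs earlier draws.
# The multiplier is the golden-ratio Weyl constant; the modulus keeps the
# result a valid 32-bit seed.
substream_seed <- function(seed, index, stream = 0L) {
  ((seed %% 2147483647) + 2654435769 * index + 97003 * stream) %% 2147483647
}

# Run `expr` under a fixed substream seed, restoring the caller's RNG state.
with_substream <- function(seed, index, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, index, stream))
  expr
}
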