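#' Wald (inverse-Gaussian) first-passage density
#'
#' Density of the first-passage time of a single-boundary diffusion with
#' drift `gamma`, moment-to-moment diffusion SD `sigma` and threshold
#' `alpha`. This is the building block of all racing accumulators in the
#' timed racing diffusion model: each accumulator's finishing time is Wald
#' distributed, and a zero-drift accumulator is legal (its passage
#' probability is still 1, with a heavy right tail).
#'
#' @param t Time in seconds; vectorized. The density is 0 for `t <= 0`.
#' @param gamma Drift rate (evidence units per second), `>= 0`.
#' @param sigma Diffusion standard deviation, `> 0`.
#' @param alpha Threshold, `> 0`.
#' @return Numeric vector of densities (1/s), finite and non-negative.
#' @examples
#' wald_pdf(0.5, gamma = 2, sigma = 1, alpha = 1)
#' @export
wald_pdf <- function(t, gamma, sigma, alpha = 1) {
  check_wald_pars(gamma, sigma, alpha)
  out <- numeric(length(t))
  pos <- !is.na(t) & t > 0
  tp <- t[pos]
  out[pos] <- alpha / (sigma * sqrt(2 * pi * tp^3)) *
    exp(-(alpha - gamma * tp)^2 / (2 * sigma^2 * tp))
  out[is.na(t)] <- NA_real_
  out
}

#' Wald (inverse-Gaussian) first-passage distribution function
#'
#' Probability that the accumulator has crossed threshold by time `t`. The
#' `exp(2 * alpha * gamma / sigma^2)` factor is evaluated in log space so the
#' function does not overflow for large drift-threshold products.
#'
#' @inheritParams wald_pdf
#' @return Probability vector, non-decreasing in `t`, with limit 1.
#' @examples
#' wald_cdf(1, gamma = 0, sigma = 1, alpha = 1)  # 2 * pnorm(-1)
#' @export
wald_cdf <- function(t, gamma, sigma, alpha = 1) {
  check_wald_pars(gamma, sigma, alpha)
  out <- numeric(length(t))
  pos <- !is.na(t) & t > 0
  tp <- t[pos]
  srt <- sigma * sqrt(tp)
  term1 <- pnorm((gamma * tp - alpha) / srt)
  lterm2 <- 2 * alpha * gamma / sigma^2 +
    pnorm(-(gamma * tp + alpha) / srt, log.p = TRUE)
  out[pos] <- pmin(1, term1 + exp(lterm2))
  out[is.na(t)] <- NA_real_
  out
}

# log survivor log P(T > t), stable deep in the right tail; used by the
# R-level race density
wald_lsurv <- function(t, gamma, sigma, alpha = 1) {
  out <- numeric(length(t))
  pos <- !is.na(t) & t > 0
  tp <- t[pos]
  srt <- sigma * sqrt(tp)
  la <- pnorm((alpha - gamma * tp) / srt, log.p = TRUE)
  lb <- 2 * alpha * gamma / sigma^2 +
    pnorm(-(gamma * tp + alpha) / srt, log.p = TRUE)
  d <- lb - la
  ls <- rep(-Inf, length(d))
  ok <- is.finite(d) & d < 0
  ls[ok] <- la[ok] + log1mexp(d[ok])
  out[pos] <- ls
  out[is.na(t)] <- NA_real_
  out
}

# log(1 - exp(x)) for x <= 0
log1mexp <- function(x) {
  out <- numeric(length(x))
  hi <- x > -log(2)
  out[hi] <- log(-expm1(x[hi]))
  out[!hi] <- log1p(-exp(x[!hi]))
  out
}

check_wald_pars <- function(gamma, sigma, alpha) {
  if (!is.numeric(sigma) || any(sigma <= 0)) {
    abort("`sigma` must be > 0.", class = "mindrace_domain_error")
  }
  if (!is.numeric(alpha) || any(alpha <= 0)) {
    abort("`alpha` must be > 0.", class = "mindrace_domain_error")
  }
  if (!is.numeric(gamma) || any(gamma < 0)) {
    abort("`gamma` must be >= 0.", class = "mindrace_domain_error")
  }
  invisible(NULL)
}
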