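#' Latent mind-wandering mean from a linked TRDM parameter
#'
#' The joint model binds one TRDM parameter per participant (generically
#' `omega`) to the mean of the latent Thurstonian mind-wandering continuum
#' through a group-level scaling coefficient: `psi = omega * beta`. The
#' parameter enters untransformed.
#'
#' @param omega Linked TRDM parameter value(s).
#' @param beta Group-level scaling coefficient.
#' @return Latent mean(s) `psi`.
#' @examples
#' link_mean(0.8, -0.41)
#' @export
link_mean <- function(omega, beta) {
  stopifnot(is.numeric(omega), is.numeric(beta))
  omega * beta
}

check_cutpoints <- function(cutpoints) {
  if (length(cutpoints) != 3 || any(!is.finite(cutpoints)) ||
      any(diff(cutpoints) <= 0)) {
    abort("`cutpoints` must be three strictly increasing finite values.",
          class = "mindrace_domain_error")
  }
  invisible(cutpoints)
}

#' Thought-probe response probabilities
#'
#' Probability of each of the four Likert responses under the Thurstonian
#' (ordinal probit) model: a latent sample `z ~ N(psi, epsilon)` is binned
#' by three strictly ordered cut points, and the bin determines the
#' response. Probabilities are telescoping normal-CDF differences and sum
#' to 1.
#'
#' @param psi Latent mean (typically [link_mean()] of the linked TRDM
#'   parameter); vectorized.
#' @param cutpoints Numeric vector of three strictly increasing cut points.
#' @param epsilon Latent SD, `> 0`. Fixed to 1 by convention: the scaling
#'   coefficient, cut points and latent SD are jointly unidentified under a
#'   common rescaling, so the latent scale is pinned at 1.
#' @return If `psi` is scalar, a probability 4-vector; otherwise a matrix
#'   with one row per element of `psi`.
#' @examples
#' probe_probs(0, cutpoints = c(-1, 0, 1))
#' @export
probe_probs <- function(psi, cutpoints, epsilon = 1) {
  check_cutpoints(cutpoints)
  if (!is.numeric(epsilon) || epsilon <= 0) {
    abort("`epsilon` must be > 0.", class = "mindrace_domain_error")
  }
  z <- outer(psi, cutpoints, function(m, l) pnorm((l - m) / epsilon))
  p <- cbind(z[, 1], z[, 2] - z[, 1], z[, 3] - z[, 2], 1 - z[, 3])
  colnames(p) <- paste0("p", 1:4)
  if (length(psi) == 1) p[1, ] else p
}

#' Log-probability of an observed probe response
#'
#' Numerically stable for extreme latent means: tail bins are evaluated
#' from log normal CDFs rather than by subtracting probabilities near 1.
#'
#' @param response Integer Likert response(s) in 1..4.
#' @inheritParams probe_probs
#' @return Log-probability vector.
#' @export
probe_loglik <- function(response, psi, cutpoints, epsilon = 1) {
  check_cutpoints(cutpoints)
  if (any(!response %in% 1:4)) {
    abort("Probe responses must be integers in 1..4.",
          class = "mindrace_data_error")
  }
  n <- max(length(response), length(psi))
  response <- rep_len(response, n)
  psi <- rep_len(psi, n)
  lo <- c(-Inf, cutpoints)[response]
  hi <- c(cutpoints, Inf)[response]
  a <- (lo - psi) / epsilon
  b <- (hi - psi) / epsilon
  # reflect so that the interval lies in the lower tail, then telescope in
  # log space
  flip <- a + b > 0
  tmp_a <- ifelse(flip, -b, a)
  b <- ifelse(flip, -a, b)
  a <- tmp_a
  lb <- pnorm(b, log.p = TRUE)
  out <- ifelse(
    a == -Inf, lb,
    lb + log1mexp(pnorm(a, log.p = TRUE) - lb)
  )
  pmax(out, -1e300)
}

#' Simulate thought-probe responses
#'
#' Draws `z ~ N(psi, epsilon)` and bins by the cut points.
#'
#' @param n Number of probe responses to draw.
#' @inheritParams probe_probs
#' @param seed Optional integer seed.
#' @return Integer vector of responses in 1..4.
#' @examples
#' table(simulate_probes(1000, 0, c(-1, 0, 1), seed = 1))
#' @export
simulate_probes <- function(n, psi, cutpoints, epsilon = 1, seed = NULL) {
  check_cutpoints(cutpoints)
  if (!is.null(seed)) set.seed(seed)
  z <- rnorm(n, mean = psi, sd = epsilon)
  findInterval(z, cutpoints) + 1L
}

#' @rdname simulate_probes
#' @export
simulate_probe <- function(psi, cutpoints, epsilon = 1, seed = NULL) {
  simulate_probes(1L, psi, cutpoints, epsilon, seed)
}
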