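PAR_NAMES <- c("gamma_go_go", "gamma_go_nogo", "gamma_nogo_nogo",
               "gamma_timer", "sigma_e", "sigma_t", "tau_e")

#' Participant-level TRDM parameters
#'
#' Bundles the seven estimated parameters of the timed racing diffusion
#' model together with its fixed constants. The evidence process races a go
#' and a nogo accumulator (common diffusion SD `sigma_e`, threshold 1,
#' finishing times shifted by the non-decision time `tau_e`); a parallel
#' timing accumulator (drift `gamma_timer`, SD `sigma_t`, threshold 1,
#' onset 0) represents the time one is willing to commit to a decision and,
#' if it wins the race, triggers a guess that is go with probability
#' `guess_go_prob` (1 by default: guesses are biased toward the habitual go
#' response). The nogo accumulator's drift on go stimuli is fixed at 0.
#'
#' @param gamma_go_go Drift of the go accumulator on go stimuli (>= 0).
#' @param gamma_go_nogo Drift of the go accumulator on nogo stimuli (>= 0);
#'   larger values generate more commission errors.
#' @param gamma_nogo_nogo Drift of the nogo accumulator on nogo stimuli
#'   (>= 0); larger values generate more successful withholds.
#' @param gamma_timer Drift of the timing accumulator (>= 0).
#' @param sigma_e Diffusion SD of both evidence accumulators (> 0).
#' @param sigma_t Diffusion SD of the timing accumulator (> 0).
#' @param tau_e Evidence non-decision time in seconds (>= 0).
#' @param guess_go_prob Probability that a timer-triggered guess is go, in
#'   `[0, 1]`.
#' @return An object of class `trdm_params`.
#' @examples
#' p <- trdm_params(4.5, 2.5, 3.5, 2.5, 1, 0.5, 0.15)
#' @export
trdm_params <- function(gamma_go_go, gamma_go_nogo, gamma_nogo_nogo,
                        gamma_timer, sigma_e, sigma_t, tau_e,
                        guess_go_prob = 1) {
  p <- list(
    gamma_go_go = gamma_go_go, gamma_go_nogo = gamma_go_nogo,
    gamma_nogo_nogo = gamma_nogo_nogo, gamma_timer = gamma_timer,
    sigma_e = sigma_e, sigma_t = sigma_t, tau_e = tau_e,
    gamma_nogo_go = 0, alpha_e = 1, alpha_t = 1, tau_t = 0,
    guess_go_prob = guess_go_prob
  )
  rates <- c(gamma_go_go, gamma_go_nogo, gamma_nogo_nogo, gamma_timer)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    abort("All drift rates must be finite and >= 0.",
          class = "mindrace_domain_error")
  }
  if (!is.finite(sigma_e) || sigma_e <= 0 || !is.finite(sigma_t) || sigma_t <= 0) {
    abort("`sigma_e` and `sigma_t` must be > 0.",
          class = "mindrace_domain_error")
  }
  if (!is.finite(tau_e) || tau_e < 0) {
    abort("`tau_e` must be >= 0.", class = "mindrace_domain_error")
  }
  if (guess_go_prob < 0 || guess_go_prob > 1) {
    abort("`guess_go_prob` must lie in [0, 1].",
          class = "mindrace_domain_error")
  }
  structure(p, class = "trdm_params")
}

#' @export
print.trdm_params <- function(x, ...) {
  cat("TRDM parameters (alpha_e = alpha_t = 1, tau_t = 0, gamma_nogo|go = 0)\n")
  v <- unlist(x[PAR_NAMES])
  print(round(v, 4))
  cat("guess_go_prob:", x$guess_go_prob, "\n")
  invisible(x)
}

par_vector <- function(params) {
  unlist(params[PAR_NAMES], use.names = FALSE)
}

check_stimulus <- function(stimulus) {
  if (!is.character(stimulus) || length(stimulus) != 1 ||
      !stimulus %in% c("go", "nogo")) {
    abort('`stimulus` must be "go" or "nogo".', class = "mindrace_domain_error")
  }
  stimulus
}

stim_rates <- function(params, stimulus) {
  if (stimulus == "go") {
    c(go = params$gamma_go_go, nogo = params$gamma_nogo_go)
  } else {
    c(go = params$gamma_go_nogo, nogo = params$gamma_nogo_nogo)
  }
}

#' Defective density of a go response
#'
#' Density (with respect to clock time from stimulus onset) of observing a
#' go response at time `t`. A go response arises either because the go
#' evidence accumulator wins the race while the timer is still running, or
#' because the timer wins and triggers a go-biased guess; the density is the
#' sum of the two paths and integrates to the overall go-response
#' probability (not to 1, hence defective). Below the non-decision time the
#' evidence accumulators cannot have finished, so only the timer path
#' contributes (this is how the model produces very fast, premature
#' responses).
#'
#' @param t Clock time in seconds; vectorized.
#' @param params A [trdm_params()] object.
#' @param stimulus `"go"` or `"nogo"`.
#' @return Vector of defective densities (1/s).
#' @examples
#' p <- trdm_params(4.5, 2.5, 3.5, 2.5, 1, 0.5, 0.15)
#' go_response_density(c(0.2, 0.4, 0.8), p, "go")
#' @export
go_response_density <- function(t, params, stimulus) {
  stopifnot(inherits(params, "trdm_params"))
  check_stimulus(stimulus)
  g <- stim_rates(params, stimulus)
  q <- params$guess_go_prob
  te <- t - params$tau_e
  ev_pdf <- wald_pdf(pmax(te, 0), g[["go"]], params$sigma_e)
  ev_pdf[te <= 0] <- 0
  s_nogo <- exp(wald_lsurv(te, g[["nogo"]], params$sigma_e))
  s_go <- exp(wald_lsurv(te, g[["go"]], params$sigma_e))
  s_tm <- exp(wald_lsurv(t, params$gamma_timer, params$sigma_t))
  tm_pdf <- wald_pdf(t, params$gamma_timer, params$sigma_t)
  out <- ev_pdf * s_nogo * s_tm + q * tm_pdf * s_go * s_nogo
  out[!is.na(t) & t <= 0] <- 0
  out
}

#' Probability that a response is withheld
#'
#' Probability that no go response is emitted on a trial: the nogo
#' accumulator wins the race (integrated by quadrature on a log-time axis),
#' plus, when `guess_go_prob < 1`, the timer winning and guessing nogo.
#' Equals `1 - integral of go_response_density` up to quadrature tolerance.
#'
#' @inheritParams go_response_density
#' @param method `"quadrature"` (default) integrates the withheld paths
#'   directly with an adaptive rule on `u = log(t)`; `"complement"` computes
#'   one minus the integrated go-response density.
#' @param abs_tol Absolute quadrature tolerance.
#' @return A probability in `[0, 1]`.
#' @examples
#' p <- trdm_params(4.5, 2.5, 3.5, 2.5, 1, 0.5, 0.15)
#' nogo_response_prob(p, "nogo")
#' @export
nogo_response_prob <- function(params, stimulus,
                               method = c("quadrature", "complement"),
                               abs_tol = 1e-6) {
  stopifnot(inherits(params, "trdm_params"))
  check_stimulus(stimulus)
  method <- match.arg(method)
  if (method == "complement") {
    fgo <- integrate_log_axis(
      function(t) go_response_density(t, params, stimulus), abs_tol,
      split_times = char_times(params, stimulus))
    return(min(1, max(0, 1 - fgo)))
  }
  g <- stim_rates(params, stimulus)
  q <- params$guess_go_prob
  f_nogo_wins <- function(u) {
    # u is evidence-process time; clock time is u + tau_e
    wald_pdf(u, g[["nogo"]], params$sigma_e) *
      exp(wald_lsurv(u, g[["go"]], params$sigma_e)) *
      exp(wald_lsurv(u + params$tau_e, params$gamma_timer, params$sigma_t))
  }
  p <- integrate_log_axis(f_nogo_wins, abs_tol,
                          split_times = char_times(params, stimulus))
  if (q < 1) {
    f_timer_nogo <- function(t) {
      te <- t - params$tau_e
      (1 - q) * wald_pdf(t, params$gamma_timer, params$sigma_t) *
        exp(wald_lsurv(te, g[["go"]], params$sigma_e)) *
        exp(wald_lsurv(te, g[["nogo"]], params$sigma_e))
    }
    p <- p + integrate_log_axis(f_timer_nogo, abs_tol,
                                split_times = char_times(params, stimulus))
  }
  min(1, max(0, p))
}

# adaptive quadrature of f over (0, Inf) on the substituted axis u = log(t);
# wide fixed bounds cover the heavy zero-drift tails. `split_times` marks
# characteristic first-passage times so sharply peaked densities (fast,
# low-noise accumulators) are not missed by the adaptive rule.
integrate_log_axis <- function(f, abs_tol = 1e-6, split_times = NULL) {
  g <- function(u) f(exp(u)) * exp(u)
  lo <- log(1e-7)
  hi <- log(1e9)
  pts <- split_times[is.finite(split_times) & split_times > 0]
  pts <- log(sort(unique(c(pts, pts / 2, pts * 2))))
  pts <- pts[pts > lo & pts < hi]
  edges <- unique(c(lo, pts, hi))
  total <- 0
  for (i in seq_len(length(edges) - 1)) {
    res <- tryCatch(
      integrate(g, lower = edges[i], upper = edges[i + 1],
                abs.tol = abs_tol, rel.tol = abs_tol, subdivisions = 400L),
      error = function(e) {
        abort(paste0("Quadrature failed to converge: ", conditionMessage(e)),
              class = "mindrace_numerical_error")
      }
    )
    total <- total + res$value
  }
  total
}

# characteristic passage times of the three racers, used as quadrature
# split points
char_times <- function(params, stimulus) {
  g <- stim_rates(params, stimulus)
  ts <- c(1 / g[["go"]], 1 / g[["nogo"]], 1 / params$gamma_timer)
  c(ts, ts + params$tau_e, params$tau_e)
}

#' Log-likelihood of observed SART trials
#'
#' Per-trial log-likelihood under the TRDM: the log defective go-response
#' density at the observed RT for go responses, and the log withheld
#' probability for withheld trials. Zero-density observations return a large
#' negative sentinel rather than `-Inf` so that samplers can reject
#' gracefully.
#'
#' @param trials A data frame with columns `stimulus` (`"go"`/`"nogo"`),
#'   `response` (`"go"`/`"withheld"`) and `rt` (seconds, `NA` for withheld
#'   trials).
#' @param params A [trdm_params()] object.
#' @return Numeric vector of per-trial log-likelihood contributions.
#' @export
trial_loglik <- function(trials, params) {
  stopifnot(inherits(params, "trdm_params"))
  trials <- tibble::as_tibble(trials)
  if (!all(c("stimulus", "response", "rt") %in% names(trials))) {
    abort("`trials` needs columns stimulus, response, rt.",
          class = "mindrace_data_error")
  }
  bad_wh <- trials$response == "withheld" & !is.na(trials$rt)
  if (any(bad_wh)) {
    abort("Withheld trials must not carry an RT.",
          class = "mindrace_data_error")
  }
  bad_go <- trials$response == "go" & (is.na(trials$rt) | trials$rt <= 0)
  if (any(bad_go)) {
    abort("Go responses require a positive RT.",
          class = "mindrace_data_error")
  }
  out <- numeric(nrow(trials))
  for (s in c("go", "nogo")) {
    idx <- trials$stimulus == s & trials$response == "go"
    if (any(idx)) {
      out[idx] <- log(go_response_density(trials$rt[idx], params, s))
    }
    idxw <- trials$stimulus == s & trials$response == "withheld"
    if (any(idxw)) {
      out[idxw] <- log(nogo_response_prob(params, s))
    }
  }
  pmax(out, -1e300)
}

#' Simulate TRDM trials
#'
#' Draws first-passage times for the go and nogo evidence accumulators
#' (shifted by `tau_e`) and the timing accumulator (unshifted) and returns
#' the race winner's outcome per trial. A timer win emits a go response with
#' probability `guess_go_prob`. Exact ties are broken uniformly at random.
#'
#' @param n Number of trials.
#' @inheritParams go_response_density
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `stimulus`, `response` and `rt`.
#' @examples
#' p <- trdm_params(4.5, 2.5, 3.5, 2.5, 1, 0.5, 0.15)
#' simulate_trials(5, p, "nogo", seed = 1)
#' @export
simulate_trials <- function(n, params, stimulus, seed = NULL) {
  stopifnot(inherits(params, "trdm_params"))
  check_stimulus(stimulus)
  if (!is.null(seed)) set.seed(seed)
  sim <- cpp_simulate_trials(as.integer(n), par_vector(params),
                             stimulus == "go", params$guess_go_prob)
  tibble::tibble(
    stimulus = stimulus,
    response = ifelse(sim$response == 1L, "go", "withheld"),
    rt = sim$rt
  )
}

#' @rdname simulate_trials
#' @export
simulate_trial <- function(params, stimulus, seed = NULL) {
  simulate_trials(1L, params, stimulus, seed = seed)
}
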