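# shared fixtures, built in code

default_pars <- function(...) {
  args <- list(gamma_go_go = 4.5, gamma_go_nogo = 2.5, gamma_nogo_nogo = 3.5,
               gamma_timer = 2.5, sigma_e = 1, sigma_t = 0.5, tau_e = 0.15)
  args[names(list(...))] <- list(...)
  do.call(trdm_params, args)
}

# random but reproducible parameter sets spanning the plausible SART regime
random_pars <- function(n, seed = 42) {
  set.seed(seed)
  purrr::map(seq_len(n), function(i) {
    trdm_params(runif(1, 1, 7), runif(1, 0.2, 4), runif(1, 0.2, 5),
                runif(1, 0.5, 4), runif(1, 0.4, 1.6), runif(1, 0.15, 1),
                runif(1, 0.05, 0.3))
  })
}

tiny_design <- function(n_participants = 4, n_go = 60, n_nogo = 12,
                        n_probes = 8) {
  # relaxed spacing so very short sessions remain feasible
  sart_design(1, n_participants = n_participants, n_go_trials = n_go,
              n_nogo_trials = n_nogo, n_probes = n_probes,
              min_nogo_gap = 2, min_probe_gap = 3)
}

# a fake fit with known draws, for diagnostics / posterior-summary tests:
# draws_list is a named list of iterations x chains matrices
fake_fit <- function(draws_list, ids = NULL) {
  pars <- names(draws_list)
  nk <- nrow(draws_list[[1]])
  m <- ncol(draws_list[[1]])
  draws <- array(NA_real_, c(nk, m, length(pars)),
                 dimnames = list(NULL, paste0("chain", seq_len(m)), pars))
  for (p in pars) draws[, , p] <- draws_list[[p]]
  structure(list(
    draws = draws, par_names = pars,
    pack = list(ids = ids %||% integer(0)),
    n_participants = length(ids %||% integer(0))
  ), class = "mindrace_fit")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# one small fitted model, computed once and reused across test files
.fit_cache <- new.env(parent = emptyenv())

cached_small_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    study <- simulate_study(tiny_design(5, 100, 20, 10), seed = 301)
    .fit_cache$study <- study
    .fit_cache$fit <- suppressWarnings(fit_joint(
      study, control = mcmc_control(chains = 3, iter = 800, burn = 400),
      seed = 302
    ))
  }
  list(fit = .fit_cache$fit, study = .fit_cache$study)
}
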