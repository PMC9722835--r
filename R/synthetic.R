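#' SART experimental design
#'
#' Design constants for the two sustained-attention experiments the package
#' emulates, or a custom design. Experiment 1: 19 participants, 640 go + 80
#' nogo trials, 20 thought probes, digits 1-9 with target digit 3.
#' Experiment 2: 192 participants, 1000 go + 24 nogo trials, 24 probes,
#' digits 0-9 with target digit 3, and responses slower than 1.5 s removed.
#' Nogo trials and probes are pseudo-randomly placed subject to minimum
#' spacing constraints (the spacing windows are configurable; defaults are 3
#' trials between nogo stimuli and 10 trials between probes).
#'
#' @param experiment 1 or 2, or `NULL` for a fully custom design.
#' @param n_participants,n_go_trials,n_nogo_trials,n_probes Design counts;
#'   override the experiment defaults when supplied.
#' @param digit_set,target_digit Stimulus digits and the nogo target digit.
#' @param min_nogo_gap,min_probe_gap Minimum spacing, in trials, between
#'   consecutive nogo stimuli / probes (`>= 1`).
#' @param rt_ceiling Optional RT ceiling in seconds; responses slower than
#'   this are removed (as in Experiment 2), `NA` for none.
#' @return An object of class `sart_design`.
#' @examples
#' sart_design(1)
#' @export
sart_design <- function(experiment = NULL,
                        n_participants = NULL, n_go_trials = NULL,
                        n_nogo_trials = NULL, n_probes = NULL,
                        digit_set = NULL, target_digit = 3,
                        min_nogo_gap = 3, min_probe_gap = 10,
                        rt_ceiling = NULL) {
  base <- if (is.null(experiment)) {
    list(n_participants = NULL, n_go_trials = NULL, n_nogo_trials = NULL,
         n_probes = NULL, digit_set = 1:9, rt_ceiling = NA_real_)
  } else if (identical(as.numeric(experiment), 1)) {
    list(n_participants = 19L, n_go_trials = 640L, n_nogo_trials = 80L,
         n_probes = 20L, digit_set = 1:9, rt_ceiling = NA_real_)
  } else if (identical(as.numeric(experiment), 2)) {
    list(n_participants = 192L, n_go_trials = 1000L, n_nogo_trials = 24L,
         n_probes = 24L, digit_set = 0:9, rt_ceiling = 1.5)
  } else {
    abort("`experiment` must be 1, 2 or NULL.",
          class = "mindrace_domain_error")
  }
  d <- list(
    n_participants = as.integer(n_participants %||% base$n_participants),
    n_go_trials = as.integer(n_go_trials %||% base$n_go_trials),
    n_nogo_trials = as.integer(n_nogo_trials %||% base$n_nogo_trials),
    n_probes = as.integer(n_probes %||% base$n_probes),
    digit_set = digit_set %||% base$digit_set,
    target_digit = target_digit,
    min_nogo_gap = as.integer(min_nogo_gap),
    min_probe_gap = as.integer(min_probe_gap),
    rt_ceiling = rt_ceiling %||% base$rt_ceiling
  )
  counts <- c(d$n_participants, d$n_go_trials, d$n_nogo_trials, d$n_probes)
  if (any(is.na(counts)) || any(counts <= 0)) {
    abort("All design counts must be supplied and positive.",
          class = "mindrace_domain_error")
  }
  if (d$min_nogo_gap < 1 || d$min_probe_gap < 1) {
    abort("Spacing gaps must be >= 1 trial.", class = "mindrace_domain_error")
  }
  if (!d$target_digit %in% d$digit_set) {
    abort("`target_digit` must be a member of `digit_set`.",
          class = "mindrace_domain_error")
  }
  structure(d, class = "sart_design")
}

#' @export
print.sart_design <- function(x, ...) {
  cat("SART design:", x$n_participants, "participants,",
      x$n_go_trials, "go +", x$n_nogo_trials, "nogo trials,",
      x$n_probes, "probes\n")
  cat("  digits {", paste(x$digit_set, collapse = ","), "}, target",
      x$target_digit, "; min nogo gap", x$min_nogo_gap,
      ", min probe gap", x$min_probe_gap, "\n")
  if (!is.na(x$rt_ceiling)) cat("  RT ceiling:", x$rt_ceiling, "s\n")
  invisible(x)
}

# uniform draw of k sorted positions in 1..n with pairwise spacing >= gap,
# via the standard bijection onto unconstrained combinations
sample_spaced_positions <- function(n, k, gap, what = "events") {
  slack <- n - (k - 1L) * (gap - 1L)
  if (slack < k) {
    abort(
      sprintf("Cannot place %d %s in %d trials with minimum gap %d.",
              k, what, n, gap),
      class = "mindrace_domain_error"
    )
  }
  y <- sort(sample.int(slack, k))
  y + (seq_len(k) - 1L) * (gap - 1L)
}

#' Generate a pseudo-random SART stimulus sequence
#'
#' Places the design's nogo trials and probe positions uniformly at random
#' among all admissible configurations: exact go/nogo counts, no two nogo
#' trials closer than `min_nogo_gap`, no two probes closer than
#' `min_probe_gap`. Probes are placed independently of the stimulus
#' sequence (and of simulated performance).
#'
#' @param design A [sart_design()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per trial: `trial`, `stimulus`, `digit`,
#'   and `probe_after` (logical: a thought probe follows this trial).
#' @export
generate_stimulus_sequence <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sart_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_go_trials + design$n_nogo_trials
  nogo_pos <- sample_spaced_positions(n, design$n_nogo_trials,
                                      design$min_nogo_gap, "nogo trials")
  probe_pos <- sample_spaced_positions(n, design$n_probes,
                                       design$min_probe_gap, "probes")
  stimulus <- rep("go", n)
  stimulus[nogo_pos] <- "nogo"
  go_digits <- setdiff(design$digit_set, design$target_digit)
  digit <- sample(go_digits, n, replace = TRUE)
  digit[nogo_pos] <- design$target_digit
  tibble::tibble(
    trial = seq_len(n),
    stimulus = stimulus,
    digit = digit,
    probe_after = seq_len(n) %in% probe_pos
  )
}

#' Group-level generating hyperparameters
#'
#' Group means and SDs of the seven participant-level TRDM parameters.
#' Participant values are drawn from normal distributions truncated to the
#' parameter domain (non-negative). The defaults describe a typical SART
#' population: fast habitual go processing (`gamma_go_go`), weaker and
#' widely varying nogo-stimulus rates (so commission errors average near
#' one half with large individual differences), a timer on the second
#' scale, unit evidence volatility, and a non-decision time near 150 ms.
#'
#' @param mean,sd Named numeric vectors over the seven parameters
#'   (`gamma_go_go`, `gamma_go_nogo`, `gamma_nogo_nogo`, `gamma_timer`,
#'   `sigma_e`, `sigma_t`, `tau_e`).
#' @return An object of class `trdm_hyper`: a tibble with columns
#'   `parameter`, `mean`, `sd`.
#' @examples
#' trdm_hyper()
#' @export
trdm_hyper <- function(
    mean = c(gamma_go_go = 4.5, gamma_go_nogo = 2.5, gamma_nogo_nogo = 3.8,
             gamma_timer = 2.5, sigma_e = 1, sigma_t = 0.5, tau_e = 0.15),
    sd = c(gamma_go_go = 0.8, gamma_go_nogo = 0.7, gamma_nogo_nogo = 1.4,
           gamma_timer = 0.6, sigma_e = 0.2, sigma_t = 0.15, tau_e = 0.04)) {
  mean <- mean[PAR_NAMES]
  sd <- sd[PAR_NAMES]
  if (any(is.na(mean)) || any(is.na(sd)) || any(sd <= 0)) {
    abort("Hyperparameters must cover all seven parameters with sd > 0.",
          class = "mindrace_domain_error")
  }
  structure(
    tibble::tibble(parameter = PAR_NAMES, mean = unname(mean), sd = unname(sd)),
    class = c("trdm_hyper", "tbl_df", "tbl", "data.frame")
  )
}

# truncated-normal draws on [0, Inf) by inverse-CDF
rtruncnorm_pos <- function(n, mean, sd) {
  p0 <- pnorm(0, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Draw participant parameter vectors from the group distribution
#'
#' @param hyper A [trdm_hyper()] object.
#' @param n_participants Number of participants.
#' @param seed Optional integer seed.
#' @return A tibble with a `participant` column and one column per TRDM
#'   parameter, drawn from the truncated group normals.
#' @export
sample_group_params <- function(hyper, n_participants, seed = NULL) {
  stopifnot(inherits(hyper, "trdm_hyper"))
  if (!is.null(seed)) set.seed(seed)
  draws <- purrr::map2(hyper$mean, hyper$sd,
                       ~ rtruncnorm_pos(n_participants, .x, .y))
  names(draws) <- hyper$parameter
  dplyr::bind_cols(
    tibble::tibble(participant = seq_len(n_participants)),
    tibble::as_tibble(draws)
  )
}

params_row_to_trdm <- function(row, guess_go_prob = 1) {
  trdm_params(row$gamma_go_go, row$gamma_go_nogo, row$gamma_nogo_nogo,
              row$gamma_timer, row$sigma_e, row$sigma_t, row$tau_e,
              guess_go_prob = guess_go_prob)
}

#' Simulate a full joint-model study
#'
#' Generates a complete SART + thought-probe dataset under the hierarchical
#' generative model: participant TRDM parameters are drawn from the group
#' distribution, choices and RTs are simulated from the racing-diffusion
#' process trial by trial, and probe responses are drawn from the
#' Thurstonian model with latent mean `psi_i = omega_i * beta`, where
#' `omega` is the linked parameter named in `spec`. When the design carries
#' an RT ceiling the slower responses are removed, mirroring the
#' Experiment-2 procedure. The returned ground truth suffices to recompute
#' the exact joint log-likelihood of the generated data.
#'
#' @param design A [sart_design()].
#' @param hyper A [trdm_hyper()] with the group means and SDs.
#' @param spec A [joint_spec()] holding the link target, `beta` and cut
#'   points. The default binds `gamma_nogo_nogo` with `beta = -0.4` and cut
#'   points placed to produce the interior-peaked ("bow") probe profile
#'   typical of thought-probe data.
#' @param guess_go_prob Timer guess bias (see [trdm_params()]).
#' @param seed Optional integer seed.
#' @return An object of class `sart_study`: a list with `data` (tibble in
#'   the trial/probe CSV dialect: `participant`, `trial`, `stimulus`,
#'   `response`, `rt`, `probe_response`), `truth` (participant parameters,
#'   latent means and the generating spec/hyper), `design`, and
#'   `filter_report` when an RT ceiling was applied.
#' @examples
#' study <- simulate_study(sart_design(1, n_participants = 2,
#'                                     n_go_trials = 40, n_nogo_trials = 5,
#'                                     n_probes = 4),
#'                         seed = 1)
#' head(study$data)
#' @export
simulate_study <- function(design = sart_design(1),
                           hyper = trdm_hyper(),
                           spec = joint_spec("gamma_nogo_nogo", beta = -0.4,
                                             cutpoints = c(-2.2, -1.2, -0.3)),
                           guess_go_prob = 1,
                           seed = NULL) {
  stopifnot(inherits(design, "sart_design"), inherits(hyper, "trdm_hyper"),
            inherits(spec, "joint_spec"))
  if (!is.null(seed)) set.seed(seed)
  params <- sample_group_params(hyper, design$n_participants)
  omega <- params[[spec$link_target]]
  psi <- link_mean(omega, spec$beta)

  one_participant <- function(i) {
    seq_tbl <- generate_stimulus_sequence(design)
    p <- params_row_to_trdm(params[i, ], guess_go_prob)
    trials <- seq_tbl
    trials$response <- NA_character_
    trials$rt <- NA_real_
    for (s in c("go", "nogo")) {
      idx <- which(trials$stimulus == s)
      sim <- cpp_simulate_trials(length(idx), par_vector(p), s == "go",
                                 guess_go_prob)
      trials$response[idx] <- ifelse(sim$response == 1L, "go", "withheld")
      trials$rt[idx] <- sim$rt
    }
    trial_rows <- tibble::tibble(
      participant = i, trial = trials$trial, stimulus = trials$stimulus,
      response = trials$response, rt = trials$rt,
      probe_response = NA_integer_
    )
    probe_trials <- trials$trial[trials$probe_after]
    resp <- simulate_probes(length(probe_trials), psi[i], spec$cutpoints,
                            spec$epsilon)
    probe_rows <- tibble::tibble(
      participant = i, trial = probe_trials, stimulus = NA_character_,
      response = NA_character_, rt = NA_real_, probe_response = resp
    )
    dplyr::arrange(
      dplyr::bind_rows(trial_rows, probe_rows),
      .data$trial, !is.na(.data$probe_response)
    )
  }

  data <- purrr::map_dfr(seq_len(design$n_participants), one_participant)
  filter_report <- NULL
  if (!is.na(design$rt_ceiling)) {
    filtered <- filter_slow_trials(data, cutoff = design$rt_ceiling)
    data <- filtered$data
    filter_report <- filtered$report
  }
  truth <- list(
    params = dplyr::mutate(params, omega = omega, psi = psi),
    hyper = hyper, spec = spec, guess_go_prob = guess_go_prob, seed = seed
  )
  structure(
    list(data = data, truth = truth, design = design,
         filter_report = filter_report),
    class = "sart_study"
  )
}

#' @export
print.sart_study <- function(x, ...) {
  cat("Synthetic SART study:", x$design$n_participants, "participants,",
      sum(!is.na(x$data$stimulus)), "trials,",
      sum(!is.na(x$data$probe_response)), "probes\n")
  cat("  link:", x$truth$spec$link_target, " beta:", x$truth$spec$beta, "\n")
  invisible(x)
}
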