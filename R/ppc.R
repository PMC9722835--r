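#' Quantile-averaged group RT percentiles
#'
#' Computes each percentile within participant and then averages across
#' participants, which preserves the shape of individual RT distributions
#' better than pooling all RTs before taking quantiles. Participants
#' without any RT are excluded and their count reported as an attribute.
#'
#' @param rts A data frame with columns `participant` and `rt` (only
#'   non-missing RTs are used).
#' @param percentiles Percentiles in (0, 100).
#' @return A tibble with `percentile` and `value` (the group average), with
#'   attribute `n_excluded`.
#' @export
quantile_average <- function(rts, percentiles = c(10, 30, 50, 70, 90)) {
  if (any(percentiles <= 0) || any(percentiles >= 100)) {
    abort("`percentiles` must lie strictly between 0 and 100.",
          class = "mindrace_domain_error")
  }
  rts <- tibble::as_tibble(rts)
  all_ids <- unique(rts$participant)
  rts <- dplyr::filter(rts, !is.na(.data$rt))
  per_part <- rts |>
    dplyr::group_by(.data$participant) |>
    dplyr::reframe(percentile = percentiles,
                   value = unname(quantile(.data$rt, percentiles / 100)))
  out <- per_part |>
    dplyr::group_by(.data$percentile) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  if (nrow(out) == 0) {
    out <- tibble::tibble(percentile = percentiles, value = NA_real_)
  }
  attr(out, "n_excluded") <- length(setdiff(all_ids, unique(per_part$participant)))
  out
}

#' Commission-error summary
#'
#' Per-participant proportion of go responses on nogo (target) trials, with
#' the group mean and range. Participants without nogo trials are excluded
#' and counted.
#'
#' @param data A SART tibble (or `sart_study`).
#' @return A one-row tibble: `mean`, `min`, `max`, `n_participants`,
#'   `n_excluded`, plus a `by_participant` tibble attribute.
#' @export
commission_error_stats <- function(data) {
  if (inherits(data, "sart_study")) data <- data$data
  trials <- sart_trials(data)
  nogo <- dplyr::filter(trials, .data$stimulus == "nogo")
  if (nrow(nogo) == 0) {
    abort("Dataset has no nogo trials.", class = "mindrace_data_error")
  }
  by_part <- nogo |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(prop = mean(.data$response == "go"), .groups = "drop")
  n_all <- dplyr::n_distinct(trials$participant)
  out <- tibble::tibble(
    mean = mean(by_part$prop), min = min(by_part$prop),
    max = max(by_part$prop),
    n_participants = nrow(by_part),
    n_excluded = n_all - nrow(by_part)
  )
  attr(out, "by_participant") <- by_part
  out
}

# summary statistics of one dataset, in the shape of the descriptive-
# adequacy panels: quantile-averaged RT percentiles by stimulus class,
# response proportions, and group-average probe-response proportions
ppc_stats <- function(data, percentiles = c(10, 30, 50, 70, 90)) {
  trials <- sart_trials(data)
  probes <- sart_probes(data)
  stats <- list()
  for (s in c("go", "nogo")) {
    qa <- quantile_average(
      dplyr::filter(trials, .data$stimulus == s, .data$response == "go"),
      percentiles
    )
    stats[[paste0("rt_", s)]] <- tibble::tibble(
      statistic = paste0("rt_p", qa$percentile, "_", s), value = qa$value
    )
    pr <- trials |>
      dplyr::filter(.data$stimulus == s) |>
      dplyr::group_by(.data$participant) |>
      dplyr::summarise(p = mean(.data$response == "go"), .groups = "drop")
    stats[[paste0("prop_", s)]] <- tibble::tibble(
      statistic = paste0("prop_go_", s), value = mean(pr$p)
    )
  }
  if (nrow(probes) > 0) {
    pp <- probes |>
      dplyr::group_by(.data$participant) |>
      dplyr::reframe(option = 1:4,
                     prop = tabulate(.data$response, 4) / dplyr::n()) |>
      dplyr::group_by(.data$option) |>
      dplyr::summarise(prop = mean(.data$prop), .groups = "drop")
    stats$probes <- tibble::tibble(
      statistic = paste0("probe_prop_", pp$option), value = pp$prop
    )
  }
  dplyr::bind_rows(stats)
}

# per-participant probe-response proportions (for the individual-level
# descriptive-adequacy panel)
probe_props_by_participant <- function(data) {
  probes <- sart_probes(data)
  probes |>
    dplyr::group_by(.data$participant) |>
    dplyr::reframe(option = 1:4,
                   prop = tabulate(.data$response, 4) / dplyr::n())
}

#' Posterior-predictive simulation
#'
#' For each of `n_draws` retained posterior draws, simulates a full dataset
#' with the same per-participant trial and probe counts as the fitted data
#' (trials from the racing-diffusion process, probes from the Thurstonian
#' model with the linked latent mean), and summarizes each simulated
#' dataset with the descriptive-adequacy statistics: quantile-averaged RT
#' percentiles by stimulus class, response proportions, and probe-response
#' proportions (group level and per participant). The 2.5/97.5 predictive
#' percentiles form the 95% credible bands.
#'
#' @param fit A `mindrace_fit`.
#' @param n_draws Number of posterior draws to simulate from (500 default);
#'   must not exceed the number of retained draws.
#' @param seed Optional integer seed.
#' @return An object of class `mindrace_ppc`: `summary` (observed value,
#'   predictive band and coverage per statistic), `draws` (per-draw
#'   statistics), `participant_probes` (observed and mean predicted probe
#'   proportions per participant and response option).
#' @export
posterior_predict <- function(fit, n_draws = 500, seed = NULL) {
  stopifnot(inherits(fit, "mindrace_fit"))
  n_avail <- dim(fit$draws)[1] * dim(fit$draws)[2]
  if (n_draws > n_avail) {
    abort(sprintf("`n_draws` (%d) exceeds available draws (%d).",
                  n_draws, n_avail), class = "mindrace_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n_avail, n_draws)
  trials <- sart_trials(fit$data)
  design_counts <- trials |>
    dplyr::group_by(.data$participant, .data$stimulus) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "stimulus", values_from = "n",
                       values_fill = 0L)
  if (!"nogo" %in% names(design_counts)) design_counts$nogo <- 0L
  if (!"go" %in% names(design_counts)) design_counts$go <- 0L
  probe_counts <- rowSums(fit$pack$probe_counts)
  ids <- fit$pack$ids
  design_counts <- design_counts[match(ids, design_counts$participant), ]
  link_col <- match(fit$link, PAR_NAMES)

  # flatten draws to (iteration, chain) pairs
  nk <- dim(fit$draws)[1]
  one_draw <- function(d) {
    it <- (d - 1) %% nk + 1
    ch <- (d - 1) %/% nk + 1
    v <- fit$draws[it, ch, ]
    lam <- unname(v[c("lambda_1", "lambda_2", "lambda_3")])
    beta <- unname(v[["beta"]])
    sim <- purrr::map_dfr(seq_along(ids), function(i) {
      pv <- unname(v[paste0(PAR_NAMES, "[", ids[i], "]")])
      rows <- list()
      for (s in c("go", "nogo")) {
        ns <- design_counts[[s]][i]
        if (ns > 0) {
          tr <- cpp_simulate_trials(ns, pv, s == "go", fit$guess_go_prob)
          rows[[s]] <- tibble::tibble(
            participant = ids[i], trial = NA_integer_, stimulus = s,
            response = ifelse(tr$response == 1L, "go", "withheld"),
            rt = tr$rt, probe_response = NA_integer_
          )
        }
      }
      np <- probe_counts[i]
      if (np > 0) {
        psi <- pv[link_col] * beta
        resp <- simulate_probes(np, psi, lam, fit$epsilon)
        rows$probes <- tibble::tibble(
          participant = ids[i], trial = NA_integer_,
          stimulus = NA_character_, response = NA_character_, rt = NA_real_,
          probe_response = resp
        )
      }
      dplyr::bind_rows(rows)
    })
    sim
  }

  obs_stats <- ppc_stats(fit$data)
  obs_pp <- probe_props_by_participant(fit$data)
  stat_draws <- vector("list", n_draws)
  pp_draws <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    sim <- one_draw(idx[d])
    stat_draws[[d]] <- dplyr::mutate(ppc_stats(sim), draw = d)
    pp_draws[[d]] <- dplyr::mutate(probe_props_by_participant(sim), draw = d)
  }
  stat_draws <- dplyr::bind_rows(stat_draws)
  pp_pred <- dplyr::bind_rows(pp_draws) |>
    dplyr::group_by(.data$participant, .data$option) |>
    dplyr::summarise(predicted = mean(.data$prop), .groups = "drop")
  summary <- stat_draws |>
    dplyr::group_by(.data$statistic) |>
    dplyr::summarise(
      lower = unname(quantile(.data$value, 0.025, na.rm = TRUE)),
      upper = unname(quantile(.data$value, 0.975, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::left_join(obs_stats, by = "statistic") |>
    dplyr::rename(observed = "value") |>
    dplyr::mutate(inside = .data$observed >= .data$lower &
                    .data$observed <= .data$upper) |>
    dplyr::relocate("statistic", "observed", "lower", "upper", "inside")
  participant_probes <- dplyr::left_join(
    dplyr::rename(obs_pp, observed = "prop"), pp_pred,
    by = c("participant", "option")
  )
  structure(
    list(summary = summary, draws = stat_draws,
         participant_probes = participant_probes,
         n_draws = n_draws, link = fit$link, label = fit$label),
    class = "mindrace_ppc"
  )
}

#' @export
print.mindrace_ppc <- function(x, ...) {
  cat("Posterior-predictive check (", x$n_draws, " draws): ", x$label,
      "\n", sep = "")
  inside <- mean(x$summary$inside, na.rm = TRUE)
  cat(sprintf("  %.0f%% of summary statistics inside the 95%% predictive band\n",
              100 * inside))
  print(x$summary, n = 20)
  invisible(x)
}

#' Posterior Spearman correlation with an observed statistic
#'
#' Rank-correlates an observed per-participant statistic (for example the
#' commission-error proportion or the mean probe response) with each
#' posterior draw of a participant-level TRDM parameter vector; the point
#' estimate is the posterior mean of the Spearman coefficient and the
#' interval the 2.5/97.5 percentiles of its draws. Ties use average ranks.
#'
#' @param fit A `mindrace_fit` with at least 3 participants.
#' @param stat A data frame with columns `participant` and `value`, or a
#'   numeric vector ordered as `fit$pack$ids`.
#' @param parameter Participant-level TRDM parameter name.
#' @return A one-row tibble: `parameter`, `estimate`, `conf.low`,
#'   `conf.high`, `n_draws`.
#' @export
spearman_posterior <- function(fit, stat, parameter = "gamma_nogo_nogo") {
  stopifnot(inherits(fit, "mindrace_fit"))
  if (fit$n_participants < 3) {
    abort("Need at least 3 participants.", class = "mindrace_domain_error")
  }
  if (is.data.frame(stat)) {
    stat <- stat$value[match(fit$pack$ids, stat$participant)]
  }
  if (length(stat) != fit$n_participants || any(is.na(stat))) {
    abort("`stat` must provide one value per fitted participant.",
          class = "mindrace_data_error")
  }
  if (length(unique(stat)) == 1) {
    warn("Observed statistic is constant; Spearman correlation undefined.")
    return(tibble::tibble(parameter = parameter, estimate = NA_real_,
                          conf.low = NA_real_, conf.high = NA_real_,
                          n_draws = 0L))
  }
  mat <- participant_draws(fit, parameter)
  rs <- apply(mat, 1, function(v) {
    if (length(unique(v)) == 1) NA_real_ else
      cor(stat, v, method = "spearman")
  })
  rs <- rs[!is.na(rs)]
  tibble::tibble(
    parameter = parameter, estimate = mean(rs),
    conf.low = unname(quantile(rs, 0.025)),
    conf.high = unname(quantile(rs, 0.975)),
    n_draws = length(rs)
  )
}
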