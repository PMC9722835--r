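LINK_TARGETS <- c("gamma_nogo_nogo", "gamma_go_nogo", "gamma_timer",
                  "gamma_go_go", "sigma_e", "sigma_t")

LINK_LABELS <- c(
  gamma_nogo_nogo = "Executive control & selective attention to rare events",
  gamma_go_nogo   = "Executive control & failure of selective attention to rare events",
  sigma_e         = "Volatility of task-relevant information processing",
  gamma_timer     = "Executive control & selective attention to temporal information",
  gamma_go_go     = "Selective attention to common events",
  sigma_t         = "Volatility of temporal processing"
)

#' The six candidate link targets
#'
#' Names of the TRDM parameters that may be bound to the latent
#' mind-wandering mean. Non-decision time is deliberately excluded: there is
#' no a priori hypothesis associating it with mind wandering.
#'
#' @return Character vector of six parameter names.
#' @export
link_targets <- function() LINK_TARGETS

#' Specify a joint-model variant
#'
#' A joint-model variant binds exactly one TRDM parameter (`link_target`,
#' the generic `omega`) to the mean of the latent Thurstonian continuum via
#' `psi = omega * beta`, together with the group-level self-report
#' parameters. Six variants are possible, one per admissible target; each
#' carries the psychological hypothesis it operationalizes as its label.
#'
#' @param link_target One of [link_targets()].
#' @param beta Group-level scaling coefficient.
#' @param cutpoints Three strictly increasing cut points.
#' @param epsilon Latent SD (fixed at 1 by the identification convention).
#' @param label Optional label; defaults to the hypothesis name.
#' @return An object of class `joint_spec`.
#' @examples
#' joint_spec("gamma_nogo_nogo", beta = -0.4, cutpoints = c(-2.2, -1.2, -0.3))
#' @export
joint_spec <- function(link_target, beta = 0,
                       cutpoints = c(-1, 0, 1), epsilon = 1,
                       label = NULL) {
  if (!is.character(link_target) || length(link_target) != 1 ||
      !link_target %in% LINK_TARGETS) {
    abort(
      paste0("`link_target` must be one of: ",
             paste(LINK_TARGETS, collapse = ", "), "."),
      class = "mindrace_domain_error"
    )
  }
  check_cutpoints(cutpoints)
  structure(
    list(
      link_target = link_target,
      beta = beta,
      cutpoints = cutpoints,
      epsilon = epsilon,
      label = label %||% unname(LINK_LABELS[link_target])
    ),
    class = "joint_spec"
  )
}

#' @rdname joint_spec
#' @param ... Passed on to [joint_spec()].
#' @export
make_variant <- function(link_target, ...) joint_spec(link_target, ...)

#' All six joint-model variants
#'
#' @inheritParams joint_spec
#' @return Named list of six `joint_spec` objects.
#' @export
joint_variants <- function(beta = 0, cutpoints = c(-1, 0, 1), epsilon = 1) {
  specs <- lapply(LINK_TARGETS, joint_spec, beta = beta,
                  cutpoints = cutpoints, epsilon = epsilon)
  setNames(specs, LINK_TARGETS)
}

#' @export
print.joint_spec <- function(x, ...) {
  cat("Joint-model variant:", x$label, "\n")
  cat("  linked parameter (omega):", x$link_target, "\n")
  cat("  beta:", x$beta, " cutpoints:", paste(round(x$cutpoints, 3),
                                              collapse = ", "), "\n")
  invisible(x)
}

#' Joint log-likelihood for one participant
#'
#' Sum of the TRDM trial log-likelihoods and the thought-probe
#' log-likelihoods, with the latent probe mean set by the participant's
#' linked parameter: `psi = omega * beta`. The two data streams are
#' conditionally independent given the participant's parameters, so the
#' joint log-likelihood is additive; with no probes it reduces exactly to
#' the TRDM-only log-likelihood.
#'
#' @param trials Data frame of the participant's trials (see
#'   [trial_loglik()]).
#' @param probes Data frame with a `response` column of Likert responses in
#'   1..4 (zero rows allowed).
#' @param params A [trdm_params()] object for this participant.
#' @param spec A [joint_spec()].
#' @return Scalar joint log-likelihood.
#' @export
participant_joint_loglik <- function(trials, probes, params, spec) {
  stopifnot(inherits(spec, "joint_spec"), inherits(params, "trdm_params"))
  trials <- tibble::as_tibble(trials)
  probes <- tibble::as_tibble(probes)
  if ("participant" %in% names(trials) && "participant" %in% names(probes)) {
    ids <- unique(c(trials$participant, probes$participant))
    if (length(ids) > 1) {
      abort("Trials and probes must belong to a single participant.",
            class = "mindrace_data_error")
    }
  }
  ll <- sum(trial_loglik(trials, params))
  if (nrow(probes) > 0) {
    omega <- params[[spec$link_target]]
    psi <- link_mean(omega, spec$beta)
    ll <- ll + sum(probe_loglik(probes$response, psi, spec$cutpoints,
                                spec$epsilon))
  }
  ll
}

`%||%` <- function(x, y) if (is.null(x)) y else x
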