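#' DIC from deviance draws
#'
#' Deviance Information Criterion from posterior deviance draws and the
#' deviance at the posterior parameter means (the plug-in): `pD = Dbar -
#' D(theta_bar)` and `DIC = Dbar + pD = 2 Dbar - D(theta_bar)`. Lower is
#' preferred.
#'
#' @param deviance_draws Numeric vector of posterior deviance draws,
#'   `D(theta) = -2 * log-likelihood`.
#' @param deviance_at_mean Deviance at the posterior parameter means.
#' @return A one-row tibble of class `dic_result`: `dbar`, `d_at_mean`,
#'   `p_d`, `dic`.
#' @examples
#' dic_from_deviance(c(10, 12, 14), 11)  # DIC = 13, pD = 1
#' @export
dic_from_deviance <- function(deviance_draws, deviance_at_mean) {
  stopifnot(is.numeric(deviance_draws), length(deviance_draws) > 0,
            is.numeric(deviance_at_mean), length(deviance_at_mean) == 1)
  dbar <- mean(deviance_draws)
  p_d <- dbar - deviance_at_mean
  structure(
    tibble::tibble(dbar = dbar, d_at_mean = deviance_at_mean,
                   p_d = p_d, dic = dbar + p_d),
    class = c("dic_result", "tbl_df", "tbl", "data.frame")
  )
}

#' DIC of a fitted joint model
#'
#' Conditional-focus DIC for the hierarchical joint model: the deviance is
#' `-2` times the joint (TRDM + probe) log-likelihood conditional on the
#' participant-level parameters, averaged over post-burn-in draws, and the
#' plug-in deviance is evaluated at the per-parameter posterior means of
#' all sampled participant- and group-level parameters.
#'
#' @param fit A `mindrace_fit`.
#' @return A `dic_result` tibble (see [dic_from_deviance()]).
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "mindrace_fit"))
  dev_draws <- as.vector(-2 * (fit$ll[, , 1] + fit$ll[, , 2]))
  link_col <- match(fit$link, PAR_NAMES) - 1L
  part_names <- paste0(rep(PAR_NAMES, fit$n_participants), "[",
                       rep(fit$pack$ids, each = 7), "]")
  # plug-in deviance at the per-parameter posterior means, evaluated per
  # chain and averaged: identical to the pooled-mean plug-in when chains
  # agree, and still a sensible plug-in when they have not yet merged
  d_chain <- vapply(seq_len(dim(fit$draws)[2]), function(m) {
    post_mean <- apply(fit$draws[, m, , drop = FALSE], 3, mean)
    theta_bar <- matrix(post_mean[part_names],
                        nrow = fit$n_participants, ncol = 7, byrow = TRUE)
    lam <- post_mean[c("lambda_1", "lambda_2", "lambda_3")]
    ll_bar <- cpp_joint_logliks(fit$pack, theta_bar, post_mean[["beta"]],
                                unname(lam), link_col, fit$guess_go_prob,
                                fit$epsilon)
    -2 * sum(ll_bar)
  }, numeric(1))
  dic_from_deviance(dev_draws, mean(d_chain))
}

#' Compare joint-model variants by DIC
#'
#' Ranks fitted variants in ascending DIC order with differences
#' zero-referenced to the preferred (lowest-DIC) model, mirroring a
#' six-variant comparison table: one row per variant with its hypothesis
#' label, DIC, delta DIC, effective parameters, and the posterior mean and
#' 95% credible interval of the scaling coefficient `beta`. All fits must
#' be to the same dataset. Exact DIC ties are broken by label order and
#' flagged.
#'
#' @param fits A list of `mindrace_fit` objects (at least two).
#' @return A tibble with columns `label`, `link`, `dic`, `delta_dic`,
#'   `p_d`, `beta_mean`, `beta_lower`, `beta_upper`, `tied`.
#' @export
compare_dic <- function(fits) {
  if (!is.list(fits) || length(fits) < 2 ||
      !all(purrr::map_lgl(fits, inherits, "mindrace_fit"))) {
    abort("`fits` must be a list of at least two mindrace_fit objects.",
          class = "mindrace_domain_error")
  }
  sig <- purrr::map(fits, function(f) f$pack[c("rt_go", "rt_ng", "wh_go",
                                               "wh_ng", "probe_counts")])
  if (!all(purrr::map_lgl(sig[-1], identical, sig[[1]]))) {
    abort("All fits must be estimated on the same dataset.",
          class = "mindrace_data_error")
  }
  rows <- purrr::map_dfr(fits, function(f) {
    d <- dic(f)
    b <- draw_vector(f, "beta")
    tibble::tibble(
      label = f$label, link = f$link, dic = d$dic, p_d = d$p_d,
      beta_mean = mean(b),
      beta_lower = unname(quantile(b, 0.025)),
      beta_upper = unname(quantile(b, 0.975))
    )
  })
  rank_dic(rows)
}

# ascending DIC with zero-referenced differences; exact ties broken by
# label order and flagged
rank_dic <- function(rows) {
  rows <- dplyr::arrange(rows, .data$dic, .data$label)
  rows$delta_dic <- rows$dic - min(rows$dic)
  rows$tied <- duplicated(rows$dic) | duplicated(rows$dic, fromLast = TRUE)
  dplyr::relocate(rows, "label", dplyr::any_of("link"), "dic", "delta_dic")
}
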