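#' Descriptive-adequacy panels for a posterior-predictive check
#'
#' Observed summary statistics (dots) against the 95% posterior-predictive
#' bands (ranges): quantile-averaged RT percentiles by stimulus class,
#' go-response proportions per stimulus class, and group-average probe
#' response proportions.
#'
#' @param object A `mindrace_ppc` from [posterior_predict()].
#' @param ... Unused.
#' @return A ggplot object faceted by panel.
#' @method autoplot mindrace_ppc
#' @export
autoplot.mindrace_ppc <- function(object, ...) {
  s <- object$summary
  num <- function(v) suppressWarnings(as.numeric(v))
  parse_stat <- function(df) {
    dplyr::mutate(df,
      panel = dplyr::case_when(
        grepl("^rt_p", .data$statistic) ~ "RT percentiles (s)",
        grepl("^prop_go_", .data$statistic) ~ "Go-response proportion",
        TRUE ~ "Probe-response proportion"
      ),
      series = dplyr::case_when(
        grepl("_nogo$", .data$statistic) ~ "nogo (target)",
        grepl("_go$", .data$statistic) ~ "go (non-target)",
        TRUE ~ "probes"
      ),
      x = dplyr::case_when(
        grepl("^rt_p", .data$statistic) ~
          num(sub("^rt_p(\\d+)_.*$", "\\1", .data$statistic)),
        grepl("^prop_go_", .data$statistic) ~
          as.numeric(grepl("_nogo$", .data$statistic)) + 1,
        TRUE ~ num(sub("^probe_prop_", "", .data$statistic))
      )
    )
  }
  s <- parse_stat(s)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$x, colour = .data$series)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lower,
                                         ymax = .data$upper),
                            linewidth = 1.2, alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 2) +
    ggplot2::facet_wrap(~ .data$panel, scales = "free") +
    ggplot2::labs(
      x = NULL, y = NULL, colour = NULL,
      title = paste0("Posterior-predictive check: ", object$label),
      subtitle = "dots: observed; bars: 95% predictive interval"
    ) +
    ggplot2::theme_minimal()
}

#' Individual-level probe fit
#'
#' Observed against posterior-predicted probe-response proportions per
#' participant, one panel per response option, with the identity line.
#' Points on the identity line indicate perfect prediction.
#'
#' @param ppc A `mindrace_ppc`.
#' @return A ggplot object.
#' @export
plot_probe_fit <- function(ppc) {
  stopifnot(inherits(ppc, "mindrace_ppc"))
  df <- dplyr::mutate(ppc$participant_probes,
                      option = paste0("response ", .data$option))
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~ .data$option, nrow = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "observed proportion", y = "predicted proportion",
                  title = "Individual-level probe-response fit") +
    ggplot2::theme_minimal()
}
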