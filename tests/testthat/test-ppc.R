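# Posterior-predictive checking and the interpretation statistics.

test_that("quantile averaging averages within-participant percentiles", {
  d <- tibble::tibble(
    participant = rep(1:2, each = 3),
    rt = c(0.3, 0.4, 0.5, 0.5, 0.6, 0.7)
  )
  qa <- quantile_average(d, 50)
  expect_equal(qa$value, 0.5)  # medians 0.4 and 0.6
  # identical participants: group vector equals the individual vector
  d2 <- tibble::tibble(participant = rep(1:3, each = 5),
                       rt = rep(c(0.2, 0.3, 0.4, 0.6, 1.0), 3))
  qa2 <- quantile_average(d2)
  expect_equal(qa2$value,
               unname(quantile(c(0.2, 0.3, 0.4, 0.6, 1.0),
                               c(.1, .3, .5, .7, .9))))
  expect_true(all(diff(qa2$value) >= 0))
  expect_error(quantile_average(d, c(0, 50)),
               class = "mindrace_domain_error")
})

test_that("quantile averaging differs from pooling on skewed data", {
  # participant 2 is much slower: pooling mixes distributions, quantile
  # averaging does not
  set.seed(2)
  d <- tibble::tibble(
    participant = rep(1:2, each = 200),
    rt = c(rexp(200, 10) + 0.2, rexp(200, 1) + 0.5)
  )
  qa <- quantile_average(d)
  pooled <- unname(quantile(d$rt, c(.1, .3, .5, .7, .9)))
  expect_gt(max(abs(qa$value - pooled)), 0.05)
  # two-step oracle: mean of independently computed per-participant values
  manual <- (quantile(d$rt[d$participant == 1], c(.1, .3, .5, .7, .9)) +
               quantile(d$rt[d$participant == 2], c(.1, .3, .5, .7, .9))) / 2
  expect_equal(qa$value, unname(manual), tolerance = 1e-12)
})

test_that("participants without responses are excluded and counted", {
  d <- tibble::tibble(participant = c(1, 1, 2), rt = c(0.3, 0.5, NA))
  qa <- quantile_average(d, 50)
  expect_equal(attr(qa, "n_excluded"), 1)
  expect_equal(qa$value, 0.4)
})

test_that("commission-error statistics count go responses to targets", {
  d <- tibble::tibble(
    participant = rep(1:2, each = 10), trial = rep(1:10, 2),
    stimulus = rep(c(rep("go", 5), rep("nogo", 5)), 2),
    response = c(rep("go", 5), "go", rep("withheld", 4),
                 rep("go", 5), rep("go", 4), "withheld"),
    rt = NA_real_, probe_response = NA_integer_
  )
  d$rt[d$response == "go"] <- 0.3
  ce <- commission_error_stats(d)
  expect_equal(ce$mean, mean(c(0.2, 0.8)))
  expect_equal(c(ce$min, ce$max), c(0.2, 0.8))
  # all-withheld dataset has zero commission errors
  d0 <- dplyr::mutate(d, response = "withheld", rt = NA_real_)
  expect_equal(commission_error_stats(d0)$mean, 0)
  # brute-force counting oracle on a simulated set
  study <- simulate_study(tiny_design(), seed = 31)
  ce2 <- commission_error_stats(study$data)
  tr <- sart_trials(study$data)
  manual <- tapply(tr$response[tr$stimulus == "nogo"] == "go",
                   tr$participant[tr$stimulus == "nogo"], mean)
  expect_equal(ce2$mean, mean(manual), tolerance = 1e-12)
  expect_equal(ce2$min, min(manual))
  expect_equal(ce2$max, max(manual))
})

test_that("posterior Spearman correlation handles concordance and ties", {
  ids <- 1:4
  base <- c(1, 2, 3, 4)
  mk_draws <- function(v, nk = 50, m = 2) {
    matrix(rep(v, each = nk * m), nk, m)
  }
  dl <- list()
  for (i in seq_along(ids)) {
    dl[[paste0("gamma_nogo_nogo[", ids[i], "]")]] <- mk_draws(base[i])
  }
  fit <- fake_fit(dl, ids = ids)
  # perfectly concordant in every draw
  r <- spearman_posterior(fit, tibble::tibble(participant = ids,
                                              value = c(10, 20, 30, 40)))
  expect_equal(r$estimate, 1)
  expect_equal(c(r$conf.low, r$conf.high), c(1, 1))
  # perfectly discordant
  r2 <- spearman_posterior(fit, tibble::tibble(participant = ids,
                                               value = c(40, 30, 20, 10)))
  expect_equal(r2$estimate, -1)
  # tied observed ranks: average-rank formula computed by hand
  stat <- c(1, 1, 2, 3)  # ranks 1.5, 1.5, 3, 4
  manual <- cor(c(1.5, 1.5, 3, 4), rank(base))  # Pearson on average ranks
  r3 <- spearman_posterior(fit, tibble::tibble(participant = ids,
                                               value = stat))
  expect_equal(r3$estimate, manual, tolerance = 1e-12)
  # constant statistic is undefined, reported as such
  expect_warning(
    r4 <- spearman_posterior(fit, tibble::tibble(participant = ids,
                                                 value = rep(1, 4))),
    "constant"
  )
  expect_true(is.na(r4$estimate))
})

test_that("posterior prediction reproduces itself and validates n_draws", {
  cs <- cached_small_fit()
  expect_error(posterior_predict(cs$fit, n_draws = 1e6),
               class = "mindrace_domain_error")
  p1 <- posterior_predict(cs$fit, n_draws = 30, seed = 5)
  p2 <- posterior_predict(cs$fit, n_draws = 30, seed = 5)
  expect_equal(p1$summary, p2$summary)
  expect_s3_class(p1, "mindrace_ppc")
  # bands are proper intervals and proportions normalize per draw
  expect_true(all(p1$summary$lower <= p1$summary$upper, na.rm = TRUE))
  probe_draws <- dplyr::filter(p1$draws,
                               grepl("^probe_prop_", .data$statistic))
  totals <- tapply(probe_draws$value, probe_draws$draw, sum)
  expect_equal(as.numeric(totals), rep(1, length(totals)),
               tolerance = 1e-12)
  # RT percentile draws are monotone within draw
  rtg <- dplyr::filter(p1$draws, grepl("^rt_p\\d+_go$", .data$statistic))
  for (dd in unique(rtg$draw)) {
    v <- rtg$value[rtg$draw == dd][order(as.numeric(
      sub("^rt_p(\\d+)_go$", "\\1", rtg$statistic[rtg$draw == dd])))]
    expect_true(all(diff(v) >= 0))
  }
})

test_that("predictive probe proportions reproduce an interior-peaked bow", {
  # generating cut points wide in the interior produce the bow; the
  # predictive distribution from a refit must reproduce it
  cs <- cached_small_fit()
  ppc <- posterior_predict(cs$fit, n_draws = 60, seed = 9)
  probe_mean <- ppc$draws |>
    dplyr::filter(grepl("^probe_prop_", .data$statistic)) |>
    dplyr::group_by(.data$statistic) |>
    dplyr::summarise(m = mean(.data$value))
  expect_equal(nrow(probe_mean), 4)
  expect_equal(sum(probe_mean$m), 1, tolerance = 1e-9)
  # interior options dominate the extremes on average, as generated
  expect_gt(probe_mean$m[2] + probe_mean$m[3],
            probe_mean$m[1] + probe_mean$m[4])
})

test_that("plots build without error", {
  cs <- cached_small_fit()
  ppc <- posterior_predict(cs$fit, n_draws = 20, seed = 3)
  expect_s3_class(ggplot2::autoplot(ppc), "ggplot")
  expect_s3_class(plot_probe_fit(ppc), "ggplot")
})
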