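# Synthetic-data generator: designs, spacing constraints, group draws, and
# the full generative joint model.

test_that("experiment designs carry the study constants", {
  d1 <- sart_design(1)
  expect_equal(d1$n_participants, 19L)
  expect_equal(d1$n_go_trials, 640L)
  expect_equal(d1$n_nogo_trials, 80L)
  expect_equal(d1$n_probes, 20L)
  expect_equal(d1$digit_set, 1:9)
  expect_equal(d1$target_digit, 3)
  expect_true(is.na(d1$rt_ceiling))
  d2 <- sart_design(2)
  expect_equal(d2$n_participants, 192L)
  expect_equal(d2$n_go_trials, 1000L)
  expect_equal(d2$n_nogo_trials, 24L)
  expect_equal(d2$n_probes, 24L)
  expect_equal(d2$digit_set, 0:9)
  expect_equal(d2$rt_ceiling, 1.5)
  expect_error(sart_design(1, n_participants = 0),
               class = "mindrace_domain_error")
  expect_error(sart_design(3), class = "mindrace_domain_error")
  expect_error(sart_design(1, target_digit = 0),
               class = "mindrace_domain_error")
})

test_that("stimulus sequences have exact counts and respect spacing", {
  d <- sart_design(1)
  seq1 <- generate_stimulus_sequence(d, seed = 1)
  expect_equal(nrow(seq1), 720)
  expect_equal(sum(seq1$stimulus == "nogo"), 80)
  expect_true(all(seq1$digit[seq1$stimulus == "nogo"] == 3))
  expect_true(all(seq1$digit[seq1$stimulus == "go"] != 3))
  expect_identical(seq1, generate_stimulus_sequence(d, seed = 1))
  for (s in 1:100) {
    sq <- generate_stimulus_sequence(d, seed = s)
    expect_gte(min(diff(which(sq$stimulus == "nogo"))), d$min_nogo_gap)
    expect_gte(min(diff(which(sq$probe_after))), d$min_probe_gap)
    expect_equal(sum(sq$probe_after), 20)
  }
  expect_error(
    generate_stimulus_sequence(
      sart_design(1, n_go_trials = 10, n_nogo_trials = 10, min_nogo_gap = 5)
    ),
    class = "mindrace_domain_error"
  )
})

test_that("spaced placement is uniform over admissible configurations", {
  # mapping constrained positions back to the unconstrained combination
  # space must give uniform occupancy, checked by chi-square
  n <- 60; k <- 8; gap <- 3
  slack <- n - (k - 1) * (gap - 1)
  set.seed(10)
  counts <- numeric(slack)
  n_seeds <- 500
  for (s in seq_len(n_seeds)) {
    x <- mindrace:::sample_spaced_positions(n, k, gap)
    y <- x - (seq_len(k) - 1) * (gap - 1)
    counts[y] <- counts[y] + 1
  }
  expected <- n_seeds * k / slack
  chisq <- sum((counts - expected)^2 / expected)
  expect_lt(chisq, qchisq(0.999, df = slack - 1))
})

test_that("group draws respect domains and truncated-normal moments", {
  hy <- trdm_hyper()
  ps <- sample_group_params(hy, 4000, seed = 2)
  expect_true(all(as.matrix(ps[, -1]) >= 0))
  # truncated-normal moment oracle: E[X] = mu + sd * phi(a) / (1 - Phi(a)),
  # a = -mu / sd, for truncation at zero
  for (j in seq_len(7)) {
    mu <- hy$mean[j]; s <- hy$sd[j]
    a <- -mu / s
    m_th <- mu + s * dnorm(a) / (1 - pnorm(a))
    expect_equal(mean(ps[[hy$parameter[j]]]), m_th, tolerance = 0.05)
  }
  # vanishing group SDs collapse all participants onto the means
  hy0 <- trdm_hyper(sd = setNames(rep(1e-9, 7), hy$parameter))
  ps0 <- sample_group_params(hy0, 5, seed = 3)
  expect_equal(ps0$gamma_go_go, rep(hy$mean[1], 5), tolerance = 1e-6)
  expect_identical(sample_group_params(hy, 6, seed = 9),
                   sample_group_params(hy, 6, seed = 9))
})

test_that("generated studies satisfy the record invariants", {
  study <- simulate_study(tiny_design(), seed = 5)
  expect_silent(validate_sart(study$data))
  tr <- sart_trials(study$data)
  expect_true(all(is.na(tr$rt[tr$response == "withheld"])))
  expect_true(all(tr$rt[tr$response == "go"] > 0))
  expect_equal(nrow(sart_probes(study$data)), 4 * 8)
  # ground truth reproduces the participant count and the linked mean
  expect_equal(nrow(study$truth$params), 4)
  expect_equal(study$truth$params$psi,
               study$truth$params$gamma_nogo_nogo * -0.4)
  expect_identical(simulate_study(tiny_design(), seed = 5)$data, study$data)
})

test_that("rt ceiling in the design is applied as removal with a report", {
  d <- sart_design(1, n_participants = 3, n_go_trials = 100,
                   n_nogo_trials = 10, n_probes = 5, rt_ceiling = 0.35)
  study <- simulate_study(d, seed = 8)
  expect_false(is.null(study$filter_report))
  expect_true(all(sart_trials(study$data)$rt <= 0.35, na.rm = TRUE))
  expect_gt(study$filter_report$n_removed, 0)
})

test_that("link direction propagates into observable correlations", {
  # strongly negative beta with the nogo-rate link: participants reporting
  # more mind wandering make more commission errors
  big <- sart_design(1, n_participants = 40, n_go_trials = 150,
                     n_nogo_trials = 30, n_probes = 15)
  study <- simulate_study(
    big, spec = joint_spec("gamma_nogo_nogo", beta = -0.8,
                           cutpoints = c(-4.5, -2.8, -1.2)),
    seed = 13
  )
  ce <- attr(commission_error_stats(study$data), "by_participant")
  probes <- sart_probes(study$data) |>
    dplyr::group_by(participant) |>
    dplyr::summarise(m = mean(response))
  expect_gt(cor(ce$prop, probes$m, method = "spearman"), 0.3)

  # beta = 0 severs the link: correlation near zero on average over seeds
  cors <- purrr::map_dbl(1:10, function(s) {
    st0 <- simulate_study(
      big, spec = joint_spec("gamma_nogo_nogo", beta = 0,
                             cutpoints = c(-1, 0, 1)),
      seed = 100 + s
    )
    ce0 <- attr(commission_error_stats(st0$data), "by_participant")
    pr0 <- sart_probes(st0$data) |>
      dplyr::group_by(participant) |>
      dplyr::summarise(m = mean(response))
    cor(ce0$prop, pr0$m, method = "spearman")
  })
  expect_lt(abs(mean(cors)), 0.15)
})
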