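# Hierarchical Bayesian estimation: priors, sampler contracts, diagnostics.

test_that("prior density respects domains and closed forms", {
  pr <- trdm_priors()
  grp <- list(
    mean = setNames(c(2, 2, 2, 2, 1, 1, 0.2), mindrace:::PAR_NAMES),
    sd = setNames(rep(0.5, 7), mindrace:::PAR_NAMES),
    beta = 0, cutpoints = c(-1, 0, 1)
  )
  one <- tibble::as_tibble(as.list(setNames(grp$mean,
                                            mindrace:::PAR_NAMES)))
  lp_center <- log_prior(grp, one, pr)
  # a participant far from the group mean is less probable
  far <- one
  far$gamma_nogo_nogo <- grp$mean[["gamma_nogo_nogo"]] + 3 * 0.5
  expect_gt(lp_center, log_prior(grp, far, pr))
  # negative evidence-noise value hits the sentinel
  bad <- one
  bad$sigma_e <- -0.5
  expect_equal(log_prior(grp, bad, pr), -1e300)
  grp_bad <- grp
  grp_bad$sd[1] <- -1
  expect_equal(log_prior(grp_bad, one, pr), -1e300)
  # closed-form check at one point: difference of two participant values
  # equals the truncated-normal log-density difference
  two <- dplyr::bind_rows(one, far)
  d_direct <- log_prior(grp, two, pr) - log_prior(grp, one, pr)
  d_formula <- dnorm(far$gamma_nogo_nogo, grp$mean[["gamma_nogo_nogo"]],
                     0.5, log = TRUE) -
    pnorm(0, grp$mean[["gamma_nogo_nogo"]], 0.5, lower.tail = FALSE,
          log.p = TRUE) +
    sum(dnorm(unlist(one), grp$mean, 0.5, log = TRUE) -
          pnorm(0, grp$mean, 0.5, lower.tail = FALSE, log.p = TRUE)) -
    dnorm(one$gamma_nogo_nogo, grp$mean[["gamma_nogo_nogo"]], 0.5,
          log = TRUE) +
    pnorm(0, grp$mean[["gamma_nogo_nogo"]], 0.5, lower.tail = FALSE,
          log.p = TRUE)
  expect_equal(d_direct, d_formula, tolerance = 1e-9)
})

test_that("sampler runs on a tiny dataset and is seed-deterministic", {
  study <- simulate_study(tiny_design(2, 30, 10, 6), seed = 41)
  ctl <- mcmc_control(chains = 2, iter = 150, burn = 80)
  f1 <- suppressWarnings(fit_joint(study, control = ctl, seed = 7))
  f2 <- suppressWarnings(fit_joint(study, control = ctl, seed = 7))
  expect_identical(f1$draws, f2$draws)
  expect_s3_class(f1, "mindrace_fit")
  d <- diagnostics(f1, parameters = c("beta", "mu_gamma_go_go"))
  expect_true(all(is.finite(d$rhat)))
  expect_true(all(d$ess > 0))
  # stored log-likelihoods are reproducible from stored draws
  i <- 5; ch <- 1
  v <- f1$draws[i, ch, ]
  th <- matrix(v[paste0(rep(mindrace:::PAR_NAMES, 2), "[",
                        rep(f1$pack$ids, each = 7), "]")],
               nrow = 2, byrow = TRUE)
  ll <- mindrace:::cpp_joint_logliks(
    f1$pack, th, v[["beta"]],
    unname(v[c("lambda_1", "lambda_2", "lambda_3")]),
    match(f1$link, mindrace:::PAR_NAMES) - 1L, 1, 1
  )
  expect_equal(sum(ll[, 1]), unname(f1$ll[i, ch, 1]), tolerance = 1e-8)
  expect_equal(sum(ll[, 2]), unname(f1$ll[i, ch, 2]), tolerance = 1e-8)
})

test_that("single-chain fits report R-hat as unavailable", {
  study <- simulate_study(tiny_design(2, 30, 10, 6), seed = 43)
  f <- suppressWarnings(fit_joint(
    study, control = mcmc_control(chains = 1, iter = 120, burn = 60),
    seed = 3
  ))
  d <- diagnostics(f, parameters = "beta")
  expect_true(is.na(d$rhat))
  expect_false(is.na(d$ess))
})

test_that("diagnostics react to agreement and disagreement between chains", {
  # constant identical chains: R-hat exactly 1 by convention
  const <- fake_fit(list(theta = matrix(1.7, 200, 3)))
  d_const <- diagnostics(const)
  expect_identical(d_const$rhat, 1)
  # well-mixed white noise: R-hat near 1, ESS near the draw count
  set.seed(8)
  wn <- fake_fit(list(theta = matrix(rnorm(600 * 3), 600, 3)))
  d_wn <- diagnostics(wn)
  expect_lt(d_wn$rhat, 1.02)
  expect_gt(d_wn$ess, 0.75 * 600 * 3)
  # chains drawn from shifted distributions: R-hat far above threshold
  shift <- fake_fit(list(theta = cbind(rnorm(300), rnorm(300) + 5,
                                       rnorm(300))))
  expect_gt(diagnostics(shift)$rhat, 1.1)
})

test_that("non-convergence is flagged loudly, not silently", {
  study <- simulate_study(tiny_design(2, 30, 10, 6), seed = 47)
  expect_warning(
    fit_joint(study, control = mcmc_control(chains = 3, iter = 60, burn = 20),
              seed = 5),
    "R-hat"
  )
})

test_that("fitting an empty dataset returns the prior", {
  empty <- tibble::tibble(
    participant = integer(), trial = integer(), stimulus = character(),
    response = character(), rt = numeric(), probe_response = integer()
  )
  f <- fit_joint(empty, control = mcmc_control(chains = 3, iter = 4000,
                                               burn = 1000), seed = 9)
  b <- mindrace:::draw_vector(f, "beta")
  # beta prior is N(0, 2)
  expect_lt(abs(mean(b)), 0.2)
  expect_equal(sd(b), 2, tolerance = 0.15)
  # group SD prior is half-normal(1): mean sqrt(2/pi)
  s <- mindrace:::draw_vector(f, "sd_gamma_go_go")
  expect_equal(mean(s), sqrt(2 / pi), tolerance = 0.12)
})

test_that("posterior credible intervals for beta cover zero under no link", {
  # simulation-based check: data generated with beta = 0 should rarely
  # exclude zero from the 90% interval
  cover <- purrr::map_lgl(1:12, function(r) {
    study <- simulate_study(
      tiny_design(4, 60, 12, 8),
      spec = joint_spec("gamma_nogo_nogo", beta = 0,
                        cutpoints = c(-1, 0, 1)),
      seed = 500 + r
    )
    f <- suppressWarnings(fit_joint(
      study, control = mcmc_control(chains = 3, iter = 500, burn = 250),
      seed = 600 + r
    ))
    ci <- quantile(mindrace:::draw_vector(f, "beta"), c(0.05, 0.95))
    ci[1] <= 0 && 0 <= ci[2]
  })
  expect_gte(mean(cover), 0.75)
})

test_that("doubling trials per participant contracts the posterior", {
  # the halved dataset is a subset of the full one, so the generating
  # participants are identical and only the amount of data differs
  study <- simulate_study(tiny_design(4, 240, 48, 8), seed = 71)
  half <- study$data |>
    dplyr::group_by(participant, stimulus) |>
    dplyr::filter(is.na(stimulus) | dplyr::row_number() <= dplyr::n() / 2) |>
    dplyr::ungroup()
  drift_sd <- function(data, seed) {
    f <- suppressWarnings(fit_joint(
      data, control = mcmc_control(chains = 3, iter = 700, burn = 350),
      seed = seed
    ))
    td <- tidy(f, pars = "participant")
    mean(td$sd[grepl("^gamma_(go_go|nogo_nogo)\\[", td$parameter)])
  }
  sd_small <- drift_sd(half, 81)
  sd_big <- drift_sd(study$data, 81)
  expect_lt(sd_big, sd_small)
})

test_that("fit validates its inputs", {
  study <- simulate_study(tiny_design(2, 30, 10, 6), seed = 51)
  expect_error(fit_joint(study, link = "tau_e"),
               class = "mindrace_domain_error")
  expect_error(mcmc_control(iter = 100, burn = 100))
})
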