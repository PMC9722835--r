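# The TRDM race: defective go-response density, withheld probability,
# trial likelihood and trial simulator.

test_that("parameter constructor enforces domains and fixed constants", {
  p <- default_pars()
  expect_s3_class(p, "trdm_params")
  expect_identical(p$gamma_nogo_go, 0)
  expect_identical(p$alpha_e, 1)
  expect_identical(p$alpha_t, 1)
  expect_identical(p$tau_t, 0)
  expect_error(default_pars(sigma_e = 0), class = "mindrace_domain_error")
  expect_error(default_pars(gamma_timer = -1), class = "mindrace_domain_error")
  expect_error(default_pars(tau_e = -0.1), class = "mindrace_domain_error")
  expect_error(trdm_params(1, 1, 1, 1, 1, 1, 0.1, guess_go_prob = 1.2),
               class = "mindrace_domain_error")
})

test_that("below the non-decision time only the timer path contributes", {
  p <- default_pars(tau_e = 0.2)
  t <- 0.05
  timer_only <- p$guess_go_prob *
    wald_pdf(t, p$gamma_timer, p$sigma_t, 1)
  expect_equal(go_response_density(t, p, "go"), timer_only, tolerance = 1e-12)
  expect_equal(go_response_density(t, p, "nogo"), timer_only,
               tolerance = 1e-12)
})

test_that("a degenerate fast timer concentrates mass at its passage time", {
  p <- default_pars(gamma_timer = 100, sigma_t = 0.01)
  expect_lt(nogo_response_prob(p, "nogo"), 1e-4)
  # nearly all mass within a narrow window around alpha_t / gamma_t = 0.01
  pin <- integrate(function(t) go_response_density(t, p, "nogo"),
                   0.005, 0.015, abs.tol = 1e-8)$value
  expect_gt(pin, 0.99)
})

test_that("go density matches a normalized histogram of simulated races", {
  p <- trdm_params(4, 1, 3, 1, 1, 1, 0.2)
  set.seed(7)
  n <- 2e5
  sim <- simulate_trials(n, p, "nogo")
  rts <- sim$rt[!is.na(sim$rt)]
  breaks <- c(0.05, 0.15, 0.25, 0.35, 0.5, 0.7, 1, 1.5, 2.5)
  for (b in seq_len(length(breaks) - 1)) {
    p_bin <- integrate(function(t) go_response_density(t, p, "nogo"),
                       breaks[b], breaks[b + 1], abs.tol = 1e-9)$value
    emp <- mean(!is.na(sim$rt) & sim$rt > breaks[b] & sim$rt <= breaks[b + 1])
    se <- sqrt(p_bin * (1 - p_bin) / n)
    expect_lt(abs(emp - p_bin), 3 * se + 1e-4)
  }
})

test_that("withheld probability behaves at structural limits", {
  # overwhelming nogo accumulator wins essentially always (slow timer so
  # the race is decided by the evidence process)
  p_hi <- default_pars(gamma_nogo_nogo = 1000, gamma_timer = 0.5,
                       sigma_t = 0.2)
  expect_gt(nogo_response_prob(p_hi, "nogo"), 0.999)
  # identical racers with the timer disabled split evenly
  p_sym <- trdm_params(2, 2, 2, 0, 1, 1e-6, 0.1)
  expect_equal(nogo_response_prob(p_sym, "nogo"), 0.5, tolerance = 1e-3)
})

test_that("withheld probability agrees with simulation and the complement", {
  p <- trdm_params(4, 1, 3, 1, 1, 1, 0.2)
  q <- nogo_response_prob(p, "nogo")
  expect_equal(q, nogo_response_prob(p, "nogo", method = "complement"),
               tolerance = 1e-4)
  set.seed(11)
  n <- 2e5
  sim <- simulate_trials(n, p, "nogo")
  emp <- mean(sim$response == "withheld")
  expect_lt(abs(emp - q), 3 * sqrt(q * (1 - q) / n))
})

test_that("normalization and monotonicity hold across random parameters", {
  for (p in random_pars(5)) {
    for (s in c("go", "nogo")) {
      fgo <- integrate(function(t) go_response_density(t, p, s), 0, Inf,
                       abs.tol = 1e-8, subdivisions = 500)$value
      expect_equal(fgo + nogo_response_prob(p, s), 1, tolerance = 1e-4)
    }
  }
  # raising the nogo rate strictly raises the withheld probability
  probs <- purrr::map_dbl(c(1, 2, 3, 4), function(g) {
    nogo_response_prob(default_pars(gamma_nogo_nogo = g), "nogo")
  })
  expect_true(all(diff(probs) > 0))
})

test_that("trial log-likelihood assembles outcomes and validates data", {
  p <- default_pars()
  trials <- tibble::tibble(
    stimulus = c("go", "nogo", "nogo"),
    response = c("go", "withheld", "go"),
    rt = c(0.35, NA, 0.28)
  )
  ll <- trial_loglik(trials, p)
  expect_equal(ll[1], log(go_response_density(0.35, p, "go")))
  expect_equal(ll[2], log(nogo_response_prob(p, "nogo")))
  expect_equal(ll[3], log(go_response_density(0.28, p, "nogo")))
  # near-certain withholding has log-likelihood near zero
  p_sure <- default_pars(gamma_nogo_nogo = 1000, gamma_timer = 0.5,
                         sigma_t = 0.2)
  ll_sure <- trial_loglik(tibble::tibble(stimulus = "nogo",
                                         response = "withheld", rt = NA),
                          p_sure)
  expect_gt(ll_sure, -1e-3)
  expect_error(
    trial_loglik(tibble::tibble(stimulus = "go", response = "withheld",
                                rt = 0.3), p),
    class = "mindrace_data_error"
  )
  expect_error(
    trial_loglik(tibble::tibble(stimulus = "go", response = "go", rt = -0.2),
                 p),
    class = "mindrace_data_error"
  )
})

test_that("summed log-likelihood peaks near the generating parameters", {
  p <- default_pars()
  set.seed(21)
  trials <- dplyr::bind_rows(simulate_trials(1500, p, "go"),
                             simulate_trials(1500, p, "nogo"))
  grid_ll <- function(field, values) {
    purrr::map_dbl(values, function(v) {
      args <- list(v); names(args) <- field
      sum(trial_loglik(trials, do.call(default_pars, args)))
    })
  }
  g_nn <- c(1.5, 2.5, 3.5, 4.5, 5.5)
  expect_equal(g_nn[which.max(grid_ll("gamma_nogo_nogo", g_nn))], 3.5)
  g_gg <- c(2.5, 3.5, 4.5, 5.5, 6.5)
  expect_equal(g_gg[which.max(grid_ll("gamma_go_go", g_gg))], 4.5)
})

test_that("simulator is reproducible and respects degenerate parameters", {
  p <- default_pars()
  a <- simulate_trials(50, p, "go", seed = 5)
  b <- simulate_trials(50, p, "go", seed = 5)
  expect_identical(a, b)
  p_nogo <- default_pars(gamma_nogo_nogo = 1000, gamma_timer = 0.5,
                         sigma_t = 0.2)
  sim <- simulate_trials(5000, p_nogo, "nogo", seed = 6)
  expect_gt(mean(sim$response == "withheld"), 0.995)
  expect_true(all(is.na(sim$rt[sim$response == "withheld"])))
  expect_true(all(sim$rt[sim$response == "go"] > 0))
})

test_that("C++ likelihood path matches the R reference implementation", {
  for (p in random_pars(3, seed = 77)) {
    pv <- unlist(p[c("gamma_go_go", "gamma_go_nogo", "gamma_nogo_nogo",
                     "gamma_timer", "sigma_e", "sigma_t", "tau_e")])
    tt <- c(0.05, 0.2, 0.35, 0.6, 1.2)
    for (s in c("go", "nogo")) {
      expect_equal(mindrace:::cpp_go_density(tt, pv, s == "go", 1),
                   go_response_density(tt, p, s), tolerance = 1e-10)
      expect_equal(mindrace:::cpp_withheld_prob(pv, s == "go", 1),
                   nogo_response_prob(p, s), tolerance = 1e-5)
    }
  }
})
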