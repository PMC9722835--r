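#' MCMC sampler settings
#'
#' @param chains Number of chains (3 by default).
#' @param iter Total iterations per chain.
#' @param burn Burn-in iterations discarded from the front (half by
#'   default). Proposal scales adapt only during burn-in.
#' @param thin Thinning interval for retained draws.
#' @param rhat_threshold Convergence is flagged (not silently ignored) when
#'   any group-level split R-hat exceeds this value.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 3, iter = 5000, burn = floor(iter / 2),
                         thin = 1, rhat_threshold = 1.1) {
  stopifnot(chains >= 1, iter > burn, burn >= 0, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burn = as.integer(burn), thin = as.integer(thin),
                 rhat_threshold = rhat_threshold),
            class = "mcmc_control")
}

#' Weakly informative prior settings
#'
#' Group-level location parameters have truncated-normal priors on the
#' parameter domain; group SDs and cut-point increments have half-normal
#' priors; the scaling coefficient and first cut point are normal. The
#' defaults are weakly informative for the second-scale RT regime of the
#' SART: drift-rate locations N(2, 3) on `[0, Inf)`, diffusion SDs
#' N(1, 2) on `(0, Inf)`, non-decision time N(0.2, 0.3) on `[0, Inf)`,
#' `beta ~ N(0, 2)`, `lambda_1 ~ N(-1, 2)`, half-normal(1) group SDs and
#' cut-point increments.
#'
#' @param group_mean_mean,group_mean_sd Named 7-vectors over the TRDM
#'   parameters for the group-location priors.
#' @param group_sd_scale Half-normal scale of the group SDs.
#' @param beta,lambda1 Length-2 vectors (mean, sd) of normal priors.
#' @param incr_scale Half-normal scale of the two cut-point increments.
#' @return A list of class `trdm_priors`.
#' @export
trdm_priors <- function(
    group_mean_mean = c(gamma_go_go = 2, gamma_go_nogo = 2,
                        gamma_nogo_nogo = 2, gamma_timer = 2,
                        sigma_e = 1, sigma_t = 1, tau_e = 0.2),
    group_mean_sd = c(gamma_go_go = 3, gamma_go_nogo = 3,
                      gamma_nogo_nogo = 3, gamma_timer = 3,
                      sigma_e = 2, sigma_t = 2, tau_e = 0.3),
    group_sd_scale = 1,
    beta = c(0, 2),
    lambda1 = c(-1, 2),
    incr_scale = 1) {
  structure(list(
    group_mean_mean = group_mean_mean[PAR_NAMES],
    group_mean_sd = group_mean_sd[PAR_NAMES],
    group_sd_scale = group_sd_scale,
    beta = beta, lambda1 = lambda1, incr_scale = incr_scale
  ), class = "trdm_priors")
}

# truncated-normal log density on [0, Inf)
ldtnorm <- function(x, mean, sd) {
  out <- dnorm(x, mean, sd, log = TRUE) -
    pnorm(0, mean, sd, lower.tail = FALSE, log.p = TRUE)
  out[x < 0] <- -Inf
  out
}

#' Hierarchical prior log-density
#'
#' Log density of participant-level TRDM parameters under the truncated
#' group normals, plus the hyperpriors on the group-level parameters.
#' Out-of-domain values return a large negative sentinel.
#'
#' @param group List with `mean` and `sd` (named 7-vectors of group
#'   locations/SDs) and optionally `beta` and `cutpoints`.
#' @param params Data frame of participant parameter values (one column per
#'   TRDM parameter), or `NULL` for the hyperprior alone.
#' @param priors A [trdm_priors()] object.
#' @return Scalar log-density.
#' @export
log_prior <- function(group, params = NULL, priors = trdm_priors()) {
  mu <- group$mean[PAR_NAMES]
  s <- group$sd[PAR_NAMES]
  if (any(is.na(mu)) || any(is.na(s))) {
    abort("`group$mean` and `group$sd` must cover all seven parameters.",
          class = "mindrace_domain_error")
  }
  if (any(s <= 0) || any(mu < 0)) return(-1e300)
  lp <- sum(ldtnorm(mu, priors$group_mean_mean, priors$group_mean_sd)) +
    sum(dnorm(s, 0, priors$group_sd_scale, log = TRUE) + log(2))
  if (!is.null(group$beta)) {
    lp <- lp + dnorm(group$beta, priors$beta[1], priors$beta[2], log = TRUE)
  }
  if (!is.null(group$cutpoints)) {
    cp <- group$cutpoints
    if (any(diff(cp) <= 0)) return(-1e300)
    lp <- lp + dnorm(cp[1], priors$lambda1[1], priors$lambda1[2], log = TRUE) +
      sum(dnorm(diff(cp), 0, priors$incr_scale, log = TRUE) + log(2))
  }
  if (!is.null(params)) {
    th <- as.matrix(tibble::as_tibble(params)[PAR_NAMES])
    if (any(th < 0) || any(th[, c("sigma_e", "sigma_t")] <= 0)) return(-1e300)
    n <- nrow(th)
    lp <- lp + sum(ldtnorm(th, matrix(mu, n, 7, byrow = TRUE),
                           matrix(s, n, 7, byrow = TRUE)))
  }
  max(lp, -1e300)
}

# ---- data packing -----------------------------------------------------------

pack_sart <- function(data) {
  trials <- sart_trials(data)
  probes <- sart_probes(data)
  ids <- sort(unique(c(trials$participant, probes$participant)))
  n <- length(ids)
  idx <- match(trials$participant, ids)
  pidx <- match(probes$participant, ids)
  go_resp <- trials$response == "go"
  stim_go <- trials$stimulus == "go"
  split_rts <- function(keep) {
    rts <- trials$rt[keep]
    f <- factor(idx[keep], levels = seq_len(n))
    lst <- split(rts, f)
    list(rt = unlist(lst, use.names = FALSE),
         off = c(0L, cumsum(lengths(lst))))
  }
  sg <- split_rts(go_resp & stim_go)
  sn <- split_rts(go_resp & !stim_go)
  wh_go <- tabulate(idx[!go_resp & stim_go], nbins = n)
  wh_ng <- tabulate(idx[!go_resp & !stim_go], nbins = n)
  pc <- matrix(0L, n, 4)
  for (k in 1:4) pc[, k] <- tabulate(pidx[probes$response == k], nbins = n)
  list(ids = ids, n = n,
       rt_go = as.numeric(sg$rt), off_go = as.integer(sg$off),
       rt_ng = as.numeric(sn$rt), off_ng = as.integer(sn$off),
       wh_go = as.integer(wh_go), wh_ng = as.integer(wh_ng),
       probe_counts = pc)
}

# ---- sampler internals ------------------------------------------------------

# participant-level log prior (truncated group normals) + log Jacobian of
# the log-scale parameterization, by participant
part_lprior <- function(theta, X, mu, s) {
  n <- nrow(theta)
  lp <- ldtnorm(theta, matrix(mu, n, 7, byrow = TRUE),
                matrix(s, n, 7, byrow = TRUE))
  rowSums(lp) + rowSums(X)
}

group_from_state <- function(G) {
  lam1 <- G[16]
  lam <- c(lam1, lam1 + exp(G[17]), lam1 + exp(G[17]) + exp(G[18]))
  list(mu = G[1:7], s = exp(G[8:14]), beta = G[15], lambda = lam)
}

hyper_lprior <- function(G, priors) {
  mu <- G[1:7]
  if (any(mu < 0)) return(-Inf)
  ls <- G[8:14]
  s <- exp(ls)
  sum(ldtnorm(mu, priors$group_mean_mean, priors$group_mean_sd)) +
    sum(dnorm(s, 0, priors$group_sd_scale, log = TRUE) + log(2) + ls) +
    dnorm(G[15], priors$beta[1], priors$beta[2], log = TRUE) +
    dnorm(G[16], priors$lambda1[1], priors$lambda1[2], log = TRUE) +
    dnorm(exp(G[17]), 0, priors$incr_scale, log = TRUE) + log(2) + G[17] +
    dnorm(exp(G[18]), 0, priors$incr_scale, log = TRUE) + log(2) + G[18]
}

# single-participant slice of a packed dataset
pack_slice <- function(pack, i) {
  list(
    rt_go = pack$rt_go[seq_len(pack$off_go[i + 1] - pack$off_go[i]) +
                         pack$off_go[i]],
    off_go = c(0L, pack$off_go[i + 1] - pack$off_go[i]),
    rt_ng = pack$rt_ng[seq_len(pack$off_ng[i + 1] - pack$off_ng[i]) +
                         pack$off_ng[i]],
    off_ng = c(0L, pack$off_ng[i + 1] - pack$off_ng[i]),
    wh_go = pack$wh_go[i], wh_ng = pack$wh_ng[i],
    probe_counts = pack$probe_counts[i, , drop = FALSE]
  )
}

init_state <- function(pack, data, priors, guess_go_prob = 1) {
  n <- pack$n
  trials <- sart_trials(data)
  th <- matrix(NA_real_, n, 7, dimnames = list(NULL, PAR_NAMES))
  lam_dummy <- c(-1, 0, 1)
  for (i in seq_len(n)) {
    tr <- trials[trials$participant == pack$ids[i], ]
    rts <- tr$rt[!is.na(tr$rt)]
    m_rt <- if (length(rts) > 0) mean(rts) else 0.4
    tau0 <- if (length(rts) > 0) {
      max(0.03, 0.5 * unname(quantile(rts, 0.05)))
    } else 0.1
    ggg0 <- 1 / max(m_rt - tau0, 0.08)
    n_ng <- sum(tr$stimulus == "nogo")
    comm <- if (n_ng > 0) {
      sum(tr$stimulus == "nogo" & tr$response == "go") / n_ng
    } else 0.5
    comm <- min(max(comm, 0.05), 0.95)
    start <- c(ggg0, max(0.3, ggg0 * comm * 0.7),
               max(0.3, ggg0 * (1 - comm)), max(0.5, 0.6 * ggg0),
               1, 0.5, tau0)
    # polish to the participant-level posterior mode (TRDM stream plus a
    # weak pull toward the prior locations); a common data-driven starting
    # point keeps all chains and all variant fits in the same mode, which
    # stabilizes short-run DIC comparisons
    slice <- pack_slice(pack, i)
    neg_obj <- function(x) {
      thx <- matrix(exp(x), 1, 7)
      ll <- cpp_joint_logliks(slice, thx, 0, lam_dummy, 0L,
                              guess_go_prob, 1)[1, 1]
      reg <- sum(dnorm(exp(x), priors$group_mean_mean,
                       2 * priors$group_mean_sd, log = TRUE) + x)
      -(max(ll, -1e300) + reg)
    }
    opt <- tryCatch(
      optim(log(start), neg_obj, method = "Nelder-Mead",
            control = list(maxit = 400, reltol = 1e-7)),
      error = function(e) NULL
    )
    th[i, ] <- if (!is.null(opt) && all(is.finite(opt$par))) {
      exp(opt$par)
    } else start
  }
  # jitter per chain happens at the caller
  mu0 <- if (n > 0) colMeans(th) else unname(priors$group_mean_mean)
  pc <- pack$probe_counts
  tot <- sum(pc)
  cum <- if (tot > 0) cumsum(colSums(pc))[1:3] / tot else c(0.25, 0.5, 0.75)
  cum <- pmin(pmax(cum, 0.02), 0.98)
  lam0 <- qnorm(cum)
  lam0 <- cummax(lam0 + c(0, 1e-3, 2e-3))  # guarantee strict ordering
  list(theta = th, mu = mu0, sd = pmax(0.3 * mu0, 0.05),
       beta = 0, lambda = lam0)
}

#' Data-driven starting values for the sampler
#'
#' Computes the starting state [fit_joint()] uses: per-participant TRDM
#' values polished to the participant-level posterior mode (racing-diffusion
#' stream plus a weak pull toward the prior locations), group summaries of
#' those values, and cut points matched to the pooled probe frequencies.
#' The initialization does not depend on the link target, so one call can
#' seed all six variant fits of the same dataset.
#'
#' @inheritParams fit_joint
#' @return An object of class `mindrace_init`.
#' @export
fit_init <- function(data, priors = trdm_priors(), guess_go_prob = 1) {
  if (inherits(data, "sart_study")) data <- data$data
  data <- validate_sart(data)
  pack <- pack_sart(data)
  init <- init_state(pack, data, priors, guess_go_prob)
  structure(c(init, list(ids = pack$ids)), class = "mindrace_init")
}

#' Fit a joint-model variant by hierarchical Bayesian MCMC
#'
#' Samples participant-level TRDM parameters and group-level parameters
#' (group locations/SDs of the seven TRDM parameters, the scaling
#' coefficient `beta`, and three cut points) from their joint posterior
#' under one of the six linking variants. The sampler is blocked Metropolis
#' within Gibbs: each participant's 7-vector is updated on the log scale
#' with a mixture of differential-evolution proposals (differences of other
#' chains' states, standard for hierarchical evidence-accumulation models)
#' and adaptive random-walk proposals; group-location/SD pairs and the
#' self-report block are updated with adaptive random walks. Proposal
#' scales adapt during burn-in only. All seeds and settings are recorded in
#' the returned object, and the fit is deterministic under a fixed seed.
#'
#' @param data A [simulate_study()] result, or a tibble in the SART dialect.
#' @param link Which TRDM parameter is bound to the latent probe mean; one
#'   of [link_targets()].
#' @param control A [mcmc_control()].
#' @param priors A [trdm_priors()].
#' @param guess_go_prob Timer guess bias, fixed (not estimated).
#' @param epsilon Latent self-report SD, fixed at 1 by the identification
#'   convention.
#' @param seed Integer seed.
#' @param init Optional [fit_init()] result (computed from `data` when
#'   missing); one initialization can seed all six variant fits.
#' @return An object of class `mindrace_fit` with retained draws
#'   (iterations x chains x parameters), per-draw log-likelihoods by stream
#'   and log-priors, sampler metadata, and a convergence flag (non-silent:
#'   a warning is raised when any group-level R-hat exceeds the threshold).
#' @export
fit_joint <- function(data, link = "gamma_nogo_nogo",
                      control = mcmc_control(), priors = trdm_priors(),
                      guess_go_prob = 1, epsilon = 1, seed = 1,
                      init = NULL) {
  if (inherits(data, "sart_study")) data <- data$data
  data <- validate_sart(data)
  spec_check <- joint_spec(link)  # validates the link target
  pack <- pack_sart(data)
  n <- pack$n
  link_col <- match(link, PAR_NAMES) - 1L
  set.seed(seed)

  ctl <- control
  M <- ctl$chains
  if (is.null(init)) {
    init <- init_state(pack, data, priors, guess_go_prob)
  } else {
    stopifnot(inherits(init, "mindrace_init"))
    if (!identical(init$ids, pack$ids)) {
      abort("`init` was computed for a different dataset.",
            class = "mindrace_data_error")
    }
  }

  # chain states
  X <- vector("list", M)       # n x 7 log-scale participant params
  G <- vector("list", M)       # 18-vector group state
  ll <- vector("list", M)      # n x 2 (trdm, probe) log-likelihoods
  lpp <- vector("list", M)     # participant prior + Jacobian
  lhyp <- numeric(M)
  for (m in seq_len(M)) {
    thm <- init$theta * exp(matrix(rnorm(n * 7, 0, 0.08), n, 7))
    Xm <- log(thm)
    mu0 <- pmax(init$mu * exp(rnorm(7, 0, 0.05)), 1e-3)
    sd0 <- init$sd * exp(rnorm(7, 0, 0.05))
    lam0 <- init$lambda + rnorm(1, 0, 0.05)
    G[[m]] <- c(mu0, log(sd0), init$beta + rnorm(1, 0, 0.05), lam0[1],
                log(pmax(diff(lam0), 1e-3)))
    X[[m]] <- Xm
    grp <- group_from_state(G[[m]])
    ll[[m]] <- if (n > 0) {
      cpp_joint_logliks(pack, thm, grp$beta, grp$lambda, link_col,
                        guess_go_prob, epsilon)
    } else matrix(numeric(0), 0, 2)
    lpp[[m]] <- if (n > 0) part_lprior(thm, Xm, grp$mu, grp$s) else numeric(0)
    lhyp[m] <- hyper_lprior(G[[m]], priors)
  }

  # adaptive proposal scales (log scale)
  ls_part <- rep(log(0.5), M)
  ls_musd <- matrix(log(0.5), 7, M)
  ls_probe <- rep(log(0.5), M)
  ls_scale <- matrix(log(0.15), 7, M)
  ls_ridge <- rep(log(0.5), M)
  de_gamma <- 2.38 / sqrt(2 * 7)
  # running posterior moments (pooled over chains) scale each proposal
  # component, so parameters with very different posterior widths mix well
  mom <- list(cnt = 0,
              mX = if (n > 0) matrix(0, n, 7) else NULL,
              vX = if (n > 0) matrix(0, n, 7) else NULL,
              mG = numeric(18), vG = numeric(18))
  sd_X <- if (n > 0) matrix(0.15, n, 7) else NULL
  sd_G <- rep(0.15, 18)
  update_moments <- function() {
    for (m in seq_len(M)) {
      mom$cnt <<- mom$cnt + 1
      if (n > 0) {
        d <- X[[m]] - mom$mX
        mom$mX <<- mom$mX + d / mom$cnt
        mom$vX <<- mom$vX + d * (X[[m]] - mom$mX)
      }
      dg <- G[[m]] - mom$mG
      mom$mG <<- mom$mG + dg / mom$cnt
      mom$vG <<- mom$vG + dg * (G[[m]] - mom$mG)
    }
    if (mom$cnt > 50) {
      if (n > 0) sd_X <<- sqrt(mom$vX / (mom$cnt - 1)) + 0.01
      sd_G <<- sqrt(mom$vG / (mom$cnt - 1)) + 0.01
    }
  }

  keep_iters <- seq.int(ctl$burn + 1L, ctl$iter, by = ctl$thin)
  n_keep <- length(keep_iters)
  par_names <- c(paste0("mu_", PAR_NAMES), paste0("sd_", PAR_NAMES),
                 "beta", "lambda_1", "lambda_2", "lambda_3")
  if (n > 0) {
    # participant-major order, matching as.vector(t(theta))
    par_names <- c(par_names,
                   as.vector(outer(PAR_NAMES, pack$ids,
                                   function(p, i) paste0(p, "[", i, "]"))))
  }
  P <- length(par_names)
  draws <- array(NA_real_, c(n_keep, M, P),
                 dimnames = list(NULL, paste0("chain", seq_len(M)), par_names))
  ll_out <- array(NA_real_, c(n_keep, M, 2),
                  dimnames = list(NULL, NULL, c("trdm", "probe")))
  lp_out <- matrix(NA_real_, n_keep, M)

  keep_row <- 0L
  for (it in seq_len(ctl$iter)) {
    adapting <- it <= ctl$burn
    rate <- if (adapting) min(0.25, 5 / sqrt(it)) else 0
    for (m in seq_len(M)) {
      grp <- group_from_state(G[[m]])
      # --- participant block (skipped when the dataset is empty) ---
      if (n > 0) {
        use_de <- M >= 3 && runif(1) < 0.5 && it > ctl$burn / 4
        if (use_de) {
          others <- sample(setdiff(seq_len(M), m), 2)
          prop <- X[[m]] + de_gamma * (X[[others[1]]] - X[[others[2]]]) +
            matrix(runif(n * 7, -1e-3, 1e-3), n, 7)
        } else {
          prop <- X[[m]] + exp(ls_part[m]) * sd_X * matrix(rnorm(n * 7), n, 7)
        }
        thp <- exp(prop)
        llp <- cpp_joint_logliks(pack, thp, grp$beta, grp$lambda, link_col,
                                 guess_go_prob, epsilon)
        lppp <- part_lprior(thp, prop, grp$mu, grp$s)
        delta <- rowSums(llp) + lppp - rowSums(ll[[m]]) - lpp[[m]]
        acc <- log(runif(n)) < delta
        if (any(acc)) {
          X[[m]][acc, ] <- prop[acc, ]
          ll[[m]][acc, ] <- llp[acc, ]
          lpp[[m]][acc] <- lppp[acc]
        }
        if (adapting && !use_de) {
          ls_part[m] <- ls_part[m] + rate * (mean(acc) - 0.234)
        }
      }
      theta <- exp(X[[m]])
      # --- group location/SD blocks, one per TRDM parameter ---
      for (k in 1:7) {
        gprop <- G[[m]]
        step <- exp(ls_musd[k, m]) * sd_G[c(k, 7 + k)] * rnorm(2)
        gprop[c(k, 7 + k)] <- gprop[c(k, 7 + k)] + step
        lh_new <- hyper_lprior(gprop, priors)
        ok <- is.finite(lh_new)
        if (ok) {
          old_k <- ldtnorm(theta[, k], G[[m]][k], exp(G[[m]][7 + k]))
          new_k <- ldtnorm(theta[, k], gprop[k], exp(gprop[7 + k]))
          delta <- sum(new_k) - sum(old_k) + lh_new - lhyp[m]
          if (is.finite(delta) && log(runif(1)) < delta) {
            G[[m]] <- gprop
            lhyp[m] <- lh_new
            if (n > 0) lpp[[m]] <- lpp[[m]] + new_k - old_k
            acc1 <- TRUE
          } else acc1 <- FALSE
        } else acc1 <- FALSE
        if (adapting) {
          ls_musd[k, m] <- ls_musd[k, m] + rate * (as.numeric(acc1) - 0.35)
        }
      }
      # --- self-report block: beta, lambda1, log increments ---
      gprop <- G[[m]]
      gprop[15:18] <- gprop[15:18] + exp(ls_probe[m]) * sd_G[15:18] * rnorm(4)
      lh_new <- hyper_lprior(gprop, priors)
      grp_new <- group_from_state(gprop)
      if (n > 0) {
        omega <- theta[, link_col + 1L]
        probe_new <- cpp_probe_logliks(pack$probe_counts, omega,
                                       grp_new$beta, grp_new$lambda, epsilon)
        delta <- sum(probe_new) - sum(ll[[m]][, 2]) + lh_new - lhyp[m]
      } else {
        probe_new <- numeric(0)
        delta <- lh_new - lhyp[m]
      }
      if (is.finite(delta) && log(runif(1)) < delta) {
        G[[m]] <- gprop
        lhyp[m] <- lh_new
        if (n > 0) ll[[m]][, 2] <- probe_new
        acc2 <- TRUE
      } else acc2 <- FALSE
      if (adapting) {
        ls_probe[m] <- ls_probe[m] + rate * (as.numeric(acc2) - 0.25)
      }
      # --- mirror jump for the self-report block: the probe likelihood has
      # a competing reflected mode (beta and the cut points negated and
      # reversed); an involution proposal lets chains hop between the two
      # and consolidate in the dominant one ---
      if (n > 0 && runif(1) < 0.2) {
        gprop <- G[[m]]
        lam3 <- gprop[16] + exp(gprop[17]) + exp(gprop[18])
        gprop[15] <- -gprop[15]              # beta -> -beta
        gprop[16] <- -lam3                   # lambda_1 -> -lambda_3
        gprop[17:18] <- G[[m]][c(18, 17)]    # increments swap
        lh_new <- hyper_lprior(gprop, priors)
        grp_new <- group_from_state(gprop)
        omega <- theta[, link_col + 1L]
        probe_new <- cpp_probe_logliks(pack$probe_counts, omega,
                                       grp_new$beta, grp_new$lambda, epsilon)
        delta <- sum(probe_new) - sum(ll[[m]][, 2]) + lh_new - lhyp[m]
        if (is.finite(delta) && log(runif(1)) < delta) {
          G[[m]] <- gprop
          lhyp[m] <- lh_new
          ll[[m]][, 2] <- probe_new
        }
      }
      # --- ridge translation for the self-report block: (beta, cut points)
      # are nearly flat along lambda ~ lambda0 + mean(omega) * beta, so a
      # joint shift moves chains along that direction quickly ---
      if (n > 0) {
        omega <- theta[, link_col + 1L]
        om_bar <- max(mean(omega), 1e-6)
        dlt <- exp(ls_ridge[m]) * rnorm(1)
        gprop <- G[[m]]
        gprop[15] <- gprop[15] + dlt / om_bar  # beta
        gprop[16] <- gprop[16] + dlt           # lambda_1 (increments fixed)
        lh_new <- hyper_lprior(gprop, priors)
        grp_new <- group_from_state(gprop)
        probe_new <- cpp_probe_logliks(pack$probe_counts, omega,
                                       grp_new$beta, grp_new$lambda, epsilon)
        delta <- sum(probe_new) - sum(ll[[m]][, 2]) + lh_new - lhyp[m]
        acc4 <- is.finite(delta) && log(runif(1)) < delta
        if (acc4) {
          G[[m]] <- gprop
          lhyp[m] <- lh_new
          ll[[m]][, 2] <- probe_new
        }
        if (adapting) {
          ls_ridge[m] <- ls_ridge[m] + rate * (as.numeric(acc4) - 0.3)
        }
      }
      # --- funnel scale move: jointly rescale one parameter's group
      # location/SD and all participant values (beta counter-scales when
      # the parameter is the link target, leaving the latent probe means
      # unchanged); this walks along the slow hierarchical direction ---
      if (n > 0) {
        k <- sample.int(7, 1)
        dlt <- exp(ls_scale[k, m]) * rnorm(1)
        gprop <- G[[m]]
        gprop[k] <- gprop[k] * exp(dlt)      # mu_k (natural scale)
        gprop[7 + k] <- gprop[7 + k] + dlt   # log s_k
        logJ <- dlt
        if (k == link_col + 1L) {
          gprop[15] <- gprop[15] * exp(-dlt) # beta counter-scales
          logJ <- logJ - dlt
        }
        lh_new <- hyper_lprior(gprop, priors)
        acc3 <- FALSE
        if (is.finite(lh_new)) {
          Xp <- X[[m]]
          Xp[, k] <- Xp[, k] + dlt
          thp <- exp(Xp)
          grp_new <- group_from_state(gprop)
          llp <- cpp_joint_logliks(pack, thp, grp_new$beta, grp_new$lambda,
                                   link_col, guess_go_prob, epsilon)
          lppp <- part_lprior(thp, Xp, grp_new$mu, grp_new$s)
          delta <- sum(llp) + sum(lppp) + lh_new -
            sum(ll[[m]]) - sum(lpp[[m]]) - lhyp[m] + logJ
          if (is.finite(delta) && log(runif(1)) < delta) {
            X[[m]] <- Xp
            ll[[m]] <- llp
            lpp[[m]] <- lppp
            G[[m]] <- gprop
            lhyp[m] <- lh_new
            acc3 <- TRUE
          }
        }
        if (adapting) {
          ls_scale[k, m] <- ls_scale[k, m] + rate * (as.numeric(acc3) - 0.3)
        }
      }
    }
    if (adapting && it > 20) update_moments()
    if (it > ctl$burn && (it - ctl$burn - 1L) %% ctl$thin == 0L) {
      keep_row <- keep_row + 1L
      for (m in seq_len(M)) {
        grp <- group_from_state(G[[m]])
        row <- c(grp$mu, grp$s, grp$beta, grp$lambda)
        if (n > 0) row <- c(row, as.vector(t(exp(X[[m]]))))
        draws[keep_row, m, ] <- row
        ll_out[keep_row, m, ] <- if (n > 0) colSums(ll[[m]]) else c(0, 0)
        lp_out[keep_row, m] <- lhyp[m] +
          (if (n > 0) sum(lpp[[m]]) else 0)
      }
    }
  }

  fit <- structure(list(
    draws = draws, ll = ll_out, lp = lp_out,
    link = link, label = unname(LINK_LABELS[link]),
    pack = pack, data = data, n_participants = n,
    guess_go_prob = guess_go_prob, epsilon = epsilon,
    control = ctl, priors = priors, seed = seed,
    par_names = par_names
  ), class = "mindrace_fit")

  grp_pars <- par_names[1:18]
  diag <- diagnostics(fit, parameters = grp_pars)
  fit$convergence <- list(
    max_rhat = suppressWarnings(max(diag$rhat, na.rm = TRUE)),
    threshold = ctl$rhat_threshold,
    converged = all(is.na(diag$rhat)) ||
      max(diag$rhat, na.rm = TRUE) < ctl$rhat_threshold
  )
  if (!fit$convergence$converged) {
    warn(sprintf(
      "Maximum group-level R-hat %.3f exceeds threshold %.2f; treat estimates with caution.",
      fit$convergence$max_rhat, ctl$rhat_threshold))
  }
  fit
}

#' @export
print.mindrace_fit <- function(x, ...) {
  cat("Joint TRDM + self-report fit:", x$label, "\n")
  cat("  link:", x$link, " participants:", x$n_participants, "\n")
  cat("  chains:", x$control$chains, " iterations:", x$control$iter,
      "(burn-in", x$control$burn, ")\n")
  cat("  max group-level R-hat:", round(x$convergence$max_rhat, 3),
      if (x$convergence$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

# ---- diagnostics ------------------------------------------------------------

split_rhat <- function(mat) {
  # mat: iterations x chains
  n <- nrow(mat)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  w <- mean(apply(sub, 2, var))
  b <- half * var(colMeans(sub))
  if (!is.finite(w) || w == 0) return(if (b == 0 || !is.finite(b)) 1 else Inf)
  vp <- (half - 1) / half * w + b / half
  sqrt(vp / w)
}

ess_basic <- function(mat) {
  n <- nrow(mat)
  m <- ncol(mat)
  if (n < 4) return(NA_real_)
  w <- mean(apply(mat, 2, var))
  if (!is.finite(w) || w == 0) return(NA_real_)
  b <- if (m > 1) n * var(colMeans(mat)) else 0
  vp <- (n - 1) / n * w + (if (m > 1) b / n else w / n)
  # chain-averaged autocovariances via FFT
  max_lag <- min(n - 1, 1000)
  acov <- matrix(0, max_lag + 1, m)
  for (j in seq_len(m)) {
    x <- mat[, j] - mean(mat[, j])
    nfft <- 2^ceiling(log2(2 * n))
    f <- stats::fft(c(x, rep(0, nfft - n)))
    ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:(max_lag + 1)] / nfft
    acov[, j] <- ac / n
  }
  rho <- 1 - (w - rowMeans(acov)) / vp
  # Geyer initial monotone positive sequence on paired sums
  tau <- 1
  t <- 1
  prev_pair <- Inf
  while (t + 1 <= max_lag) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2
  }
  min(m * n / tau, m * n)
}

#' Convergence diagnostics
#'
#' Split-chain R-hat and effective sample size per parameter. With a single
#' chain, R-hat is unavailable and reported as `NA`.
#'
#' @param fit A `mindrace_fit`.
#' @param parameters Optional character vector of parameter names (defaults
#'   to all).
#' @return A tibble with columns `parameter`, `rhat`, `ess`.
#' @export
diagnostics <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "mindrace_fit"))
  pars <- parameters %||% fit$par_names
  single <- dim(fit$draws)[2] < 2
  purrr::map_dfr(pars, function(p) {
    mat <- fit$draws[, , p, drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
    tibble::tibble(
      parameter = p,
      rhat = if (single) NA_real_ else split_rhat(mat),
      ess = ess_basic(mat)
    )
  })
}

# ---- broom-style methods ----------------------------------------------------

#' Tidy posterior summaries
#'
#' @param x A `mindrace_fit`.
#' @param pars `"group"` (default), `"participant"`, or `"all"`.
#' @param conf_level Credible-interval level.
#' @param ... Unused.
#' @return A tibble with posterior mean, SD, credible bounds, R-hat and ESS
#'   per parameter.
#' @method tidy mindrace_fit
#' @export
tidy.mindrace_fit <- function(x, pars = c("group", "participant", "all"),
                              conf_level = 0.95, ...) {
  pars <- match.arg(pars)
  sel <- switch(pars,
    group = x$par_names[1:18],
    participant = setdiff(x$par_names, x$par_names[1:18]),
    all = x$par_names
  )
  a <- (1 - conf_level) / 2
  diag <- diagnostics(x, parameters = sel)
  est <- purrr::map_dfr(sel, function(p) {
    v <- as.vector(x$draws[, , p])
    tibble::tibble(parameter = p, mean = mean(v), sd = sd(v),
                   conf.low = unname(quantile(v, a)),
                   conf.high = unname(quantile(v, 1 - a)))
  })
  dplyr::left_join(est, diag, by = "parameter")
}

#' One-row fit summary
#'
#' @param x A `mindrace_fit`.
#' @param ... Unused.
#' @return A one-row tibble: variant, data size, draw counts, mean joint
#'   deviance, worst group-level R-hat and convergence flag.
#' @method glance mindrace_fit
#' @export
glance.mindrace_fit <- function(x, ...) {
  dev <- -2 * (x$ll[, , 1] + x$ll[, , 2])
  tibble::tibble(
    link = x$link,
    n_participants = x$n_participants,
    chains = x$control$chains,
    draws = dim(x$draws)[1] * dim(x$draws)[2],
    mean_deviance = mean(dev),
    max_rhat = x$convergence$max_rhat,
    converged = x$convergence$converged
  )
}

# posterior draws of one parameter as an (iterations * chains) vector
draw_vector <- function(fit, parameter) {
  as.vector(fit$draws[, , parameter])
}

# matrix of participant-level draws for one TRDM parameter:
# (iterations * chains) x participants
participant_draws <- function(fit, parameter) {
  cols <- paste0(parameter, "[", fit$pack$ids, "]")
  out <- sapply(cols, function(p) as.vector(fit$draws[, , p]))
  matrix(out, ncol = length(cols), dimnames = list(NULL, cols))
}
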