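---
title: "Joint modeling of sustained attention and self-reported mind wandering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modeling of sustained attention and self-reported mind wandering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mindrace)
library(dplyr)
```

## The scientific problem

In the Sustained Attention to Response Task (SART) participants respond to a
stream of digits and withhold the response when a rare target digit appears.
Because go trials vastly outnumber nogo trials, responding becomes habitual
and withholding requires executive control. Interspersed thought probes ask
participants to rate, on a four-point Likert scale, how much their thoughts
had drifted off task. The question this package addresses is *which latent
component of task processing is associated with self-reported mind
wandering*: the ability to inhibit habitual responses, the ability to filter
misleading information, the calibration or volatility of an internal timer,
attention to common stimuli, or the volatility of evidence processing.

Rather than conditioning task performance on probe responses (which treats a
dependent variable as an independent one), both data streams are modeled
jointly: a cognitive model of choices and response times is structurally
bound to an ordinal model of probe responses, and competing binding
hypotheses are compared quantitatively.

## The timed racing diffusion model

Choices and RTs come from a race among three diffusion processes, each with
first-passage times following a Wald (inverse-Gaussian) distribution with
threshold fixed at 1:

* a **go evidence accumulator** with drift `gamma_go_go` on go stimuli and
  `gamma_go_nogo` on nogo stimuli,
* a **nogo evidence accumulator** with drift `gamma_nogo_nogo` on nogo
  stimuli (the drift on go stimuli is fixed at 0, since nogo responses to go
  stimuli are extremely rare), and
* a **timing accumulator** with drift `gamma_timer`, which represents how
  long one is willing to wait for evidence.

Both evidence accumulators share the moment-to-moment diffusion SD
`sigma_e`; the timer has its own SD `sigma_t`. Evidence finishing times are
shifted by the non-decision time `tau_e`; the timer starts at stimulus onset
(onset fixed at 0). If the nogo accumulator wins the race the response is
withheld. If the go accumulator wins, a go response is emitted at its
finishing time. If the timer wins, evidence accumulation halts and a guess
is emitted immediately; guesses are biased toward the habitual go response
(`guess_go_prob = 1` by default, configurable but never estimated). The
timer is what produces the distinctive fast, premature responses of SART
RT distributions. Seven parameters per participant are estimated; the
thresholds, timer onset and `gamma_nogo|go` are fixed constants.

The defective go-response density at clock time `t` for stimulus class `s`
is

    f_go(t) = g(t - tau_e; gamma_go|s, sigma_e)
                * S(t - tau_e; gamma_nogo|s, sigma_e) * S(t; gamma_T, sigma_T)
            + q * g(t; gamma_T, sigma_T)
                * S(t - tau_e; gamma_go|s, sigma_e)
                * S(t - tau_e; gamma_nogo|s, sigma_e)

where `g` and `S` are the Wald density and survivor function and `q` the
guess bias. The withheld probability integrates the analogous
nogo-accumulator path (plus the timer path weighted `1 - q` when `q < 1`,
so that the two response probabilities always sum to one; at the default
`q = 1` this reduces to the nogo-accumulator integral alone).

## The self-report model and the structural link

Probe responses follow a Thurstonian (ordinal probit) model: on probe `j`,
participant `i` draws `z_ij ~ N(psi_i, epsilon)` from a latent
mind-wandering continuum, and three ordered cut points `lambda_1 <
lambda_2 < lambda_3` (estimated at the group level) partition the line into
the four response options. The structural link sets each participant's
latent mean from one TRDM parameter, generically `omega`:

    psi_i = omega_i * beta

with `beta` a group-level scaling coefficient and `omega` entering
untransformed. Binding one parameter at a time yields six joint-model
variants — `gamma_nogo_nogo`, `gamma_go_nogo`, `gamma_timer`,
`gamma_go_go`, `sigma_e`, `sigma_t` — each operationalizing one hypothesis
about how mind wandering relates to processing. Non-decision time is
excluded: there is no a priori reason to link it to mind wandering.

**Identification.** `beta`, the cut points and the latent SD are jointly
unidentified under a common rescaling (multiplying all of them by a
constant leaves every probe probability unchanged — this invariance is
asserted directly in the test suite). We therefore pin the latent scale by
fixing `epsilon = 1` for all participants, the usual probit convention. A
per-participant `epsilon` is exposed as an argument but off by default.
Inside the sampler the cut points are parameterized as `lambda_1` plus two
positive increments, which enforces their ordering unconditionally.

Probes are conditionally independent given participant parameters; the
link operates at the participant level, so no trial-level coupling (or
temporal dependence of the latent state) is modeled. That is a known
limitation of the model class, not an implementation shortcut.

## Hierarchical estimation

All seven TRDM parameters are participant-level with group-level
truncated-normal population distributions (location and SD per parameter);
`beta` and the cut points are group-level only. Priors are weakly
informative for the second-scale RT regime:

| parameter | prior |
|---|---|
| drift-rate group locations | N(2, 3) truncated to `[0, Inf)` |
| `sigma_e`, `sigma_t` locations | N(1, 2) truncated to `(0, Inf)` |
| `tau_e` location | N(0.2, 0.3) truncated to `[0, Inf)` |
| group SDs | half-normal(1) |
| `beta` | N(0, 2) |
| `lambda_1` | N(-1, 2) |
| cut-point increments | half-normal(1) |

The sampler is blocked Metropolis within Gibbs. Each participant's
7-vector is updated on the log scale, jointly across participants (they are
conditionally independent given the group level), using a mixture of
differential-evolution proposals — differences of other chains' states,
the standard device for hierarchical evidence-accumulation models — and
random-walk proposals whose per-component scales track running posterior
moments accumulated during burn-in. Group location/SD pairs and the
self-report block use adaptive random walks. A dedicated *scale move*
jointly rescales one parameter's group location, group SD and all
participant values (counter-scaling `beta` when that parameter is the link
target, which leaves the latent probe means invariant); this walks along
the slow "funnel" direction of hierarchical posteriors and markedly
improves mixing of weakly identified parameters such as `gamma_go_nogo`.
Two further moves serve the self-report block, whose posterior under a
mis-specified link is a long, nearly flat ridge
(`lambda ~ lambda0 + mean(omega) * beta`, because shifting all cut points
can be traded against the scaling coefficient when the linked parameter
varies little across participants): a *ridge translation* shifts `beta`
and the cut points jointly along that direction, and a *mirror jump*
proposes the reflected competing solution (`beta` negated, cut points
negated and reversed) so chains consolidate in the dominant region rather
than splitting across it. Proposal scales adapt only during burn-in, so
the retained chain targets the exact posterior. Chains start from a
data-driven state ([fit_init()]): each participant's parameters are
polished to their individual posterior mode before sampling. Besides
shortening burn-in, a shared initialization matters for model comparison —
it is link-independent, so all six variant fits of one dataset start from
the same point and residual short-run bias largely cancels from DIC
differences. Defaults are 3 chains, 5,000 iterations with 50%
burn-in and no thinning; every seed and setting is stored in the returned
object. Convergence is summarized by split-chain R-hat and effective
sample size, and a fit whose group-level R-hat exceeds 1.1 warns rather
than failing silently.

Positive parameters are sampled on the log scale and reported on the
natural scale. The likelihood core (Wald terms, the withheld-probability
quadrature and the per-participant joint log-likelihood) is implemented in
C++ for speed, with survivor functions evaluated in log space so
`exp(2 * alpha * gamma / sigma^2)` never overflows; an independent R
implementation of the same quantities is kept and the two are cross-checked
in the test suite.

## Numerical choices

* **Withheld-probability quadrature** integrates on `u = log(t)` because
  zero-drift accumulators are legal and have heavy `t^(-1/2)` survivor
  tails. The R path uses adaptive quadrature (absolute tolerance `1e-6`)
  with split points at each racer's characteristic passage time so sharply
  peaked densities are not missed; the C++ path uses composite
  Gauss–Legendre panels whose width tracks the sharpest first-passage peak
  (coefficient of variation `sigma / sqrt(gamma)`), with bounds chosen
  where every survivor product is negligible. The two paths agree to about
  `1e-6`, and `nogo_response_prob()` also offers the complement route
  (`1 - integral of the go density`) which agrees to the same tolerance.
* **Zero-density observations** return a large negative sentinel
  (`-1e300`) instead of `-Inf`, so Metropolis steps reject cleanly.
* **Simulated ties** between racers (measure zero) are broken uniformly at
  random.
* **DIC** uses the conditional (participant-level) deviance focus:
  `D(theta) = -2` times the joint log-likelihood given participant- and
  group-level sampled parameters, with the plug-in at per-parameter
  posterior means. The individual-level parameters carry the scientific
  claims here, which is what the conditional focus measures; `pD` and
  `DIC = Dbar + pD` follow the standard definitions, and comparisons are
  zero-referenced to the preferred model with exact ties flagged. The
  plug-in deviance is evaluated at each chain's own posterior means and
  averaged: identical to the pooled plug-in once chains agree, but still a
  meaningful plug-in when they have not yet merged (a pooled mean can sit
  between posterior modes, where the deviance is artificially poor and
  `pD` can even go negative).
* All times are seconds, measured from stimulus onset; trial indices are
  1-based everywhere, matching R convention, including in CSV exports.

## What the synthetic-data generator emulates

`sart_design(1)` and `sart_design(2)` reproduce the two experimental
designs: 19 participants with 640 go + 80 nogo trials and 20 probes
(digits 1–9, target 3), and 192 participants with 1000 go + 24 nogo trials
and 24 probes (digits 0–9, target 3, responses slower than 1.5 s removed —
the removal is applied as data cleaning, without likelihood
renormalization). Nogo trials and probes are placed uniformly at random
among all placements satisfying minimum-spacing constraints; the exact
spacing windows used in the experiments are not public, so the defaults
are 3 trials between nogo stimuli and 10 between probes, both
configurable. Probe placement is independent of simulated performance.

The default generating population (`trdm_hyper()`) was chosen once to
produce realistic SART behavior: median go RTs near 0.32 s with right
skew, a few percent omissions, commission errors averaging near 0.55 with
a wide range across participants (roughly 0.2–0.95), and an
interior-peaked ("bow") profile of probe responses. The default link binds
`gamma_nogo_nogo` with `beta = -0.4` and cut points `(-2.2, -1.2, -0.3)`,
so participants who are worse at detecting rare targets also report more
mind wandering — the direction and rough magnitude of the association the
joint model is designed to detect. Under `beta = 0` the probe stream is
generated independently of the TRDM parameters, which the test suite uses
as a negative control.

What passing tests on these data do **not** show: the generator draws
every trial i.i.d. given participant parameters, so time-on-task drift,
fatigue, probe reactivity, temporal dependence of the latent state, and
condition effects (for example brain stimulation) are absent. Recovery on
synthetic data demonstrates internal consistency of likelihood, sampler
and model comparison — not that real SART data satisfy the model's
assumptions.

## Problem sizes used in the checks

The test suite and the acceptance script run everything at sizes a single
CPU handles comfortably: likelihood/simulator agreement uses `10^6`
simulated races per parameter set; parameter recovery runs the full
19-participant first-experiment design with 3 chains of 3,000–3,500
iterations (longer runs only sharpen the same result); six-variant model
recovery uses 10 replications of a 12-participant session of 120 go + 24
nogo trials and 20 probes, with 3 chains of 500 iterations per fit and a
shared data-driven initialization across the six variants. These reduced
iteration counts are the package's choice of demonstration scale;
`mcmc_control()` accepts larger values for production analyses.

## Known limitations

* The latent mind-wandering state is continuous and normal; discrete-state
  alternatives are not implemented.
* One parameter is linked at a time; multi-parameter simultaneous links
  and links to external covariates are out of scope.
* No trial-to-trial drift variability or within-trial attention switching
  in the TRDM.
* Marginal-likelihood model comparison (Bayes factors, WAIC/LOO) is not
  provided; DIC is the implemented criterion.
* Whether the original analyses evaluated the withheld probability by
  quadrature or complement, and which DIC focus they used, is not stated
  in the source material; both quadrature routes are provided (they agree
  numerically) and the conditional DIC focus is documented above.

## A compact end-to-end run

```{r, eval = FALSE}
study <- simulate_study(sart_design(1), seed = 1)
fit <- fit_joint(study, link = "gamma_nogo_nogo",
                 control = mcmc_control(chains = 3, iter = 5000),
                 seed = 2)
tidy(fit)                       # posterior summaries with R-hat / ESS
dic(fit)                        # conditional-focus DIC
ppc <- posterior_predict(fit, n_draws = 500, seed = 3)
autoplot(ppc)                   # RT percentiles, proportions, probe profile
plot_probe_fit(ppc)             # per-participant probe fit, identity line
```

Fitting all six variants and ranking them reproduces the comparison-table
shape (`delta_dic` zero-referenced to the preferred variant, with the
posterior mean and 95% interval of `beta` per variant):

```{r, eval = FALSE}
fits <- lapply(link_targets(), function(lt) fit_joint(study, link = lt))
compare_dic(fits)
```
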