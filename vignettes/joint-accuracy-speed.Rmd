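---
title: "Joint modeling of response accuracy and response times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modeling of response accuracy and response times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Computer-based tests record, for every person--item encounter, whether the
answer was correct and how long it took. `jirt` fits the hierarchical
Bayesian joint model in which both data types measure latent person traits
— ability through the accuracy data, working speed through the times —
and in which the association between the two is modeled at the person and
item level rather than cell by cell.

## The model

**Accuracy component.** The probability that person $i$ answers item $k$
correctly follows the two-parameter normal-ogive model
$$P(Y_{ik}=1\mid\theta_i,a_k,b_k)=\Phi(a_k\theta_i-b_k),$$
with discrimination $a_k>0$ and difficulty $b_k$. An equivalent bracketed
convention $\Phi\!\big(a_k(\theta_i-\tilde b_k)\big)$ puts the difficulty
on the ability scale (`par1 = TRUE`; the two agree when
$b_k=a_k\tilde b_k$). The three-parameter extension adds a guessing
probability $c_k$:
$P(Y_{ik}=1)=c_k+(1-c_k)\Phi(a_k\theta_i-b_k)$.

**Response-time component.** Log response times are normal,
$$RT_{ik}=\lambda_k-\varphi_k\zeta_i+\varepsilon_{ik},\qquad
\varepsilon_{ik}\sim N(0,\sigma^2_{k}),$$
with time intensity $\lambda_k$ (average log time demand), time
discrimination $\varphi_k>0$ (item-specific sensitivity of the time to
working speed $\zeta_i$), and an item-specific residual variance. Two
alternative conventions are supported: the bracketed form
$\varphi_k(\tilde\lambda_k-\zeta_i)$ (`par2 = TRUE`), and the `WL`
parameterization in which the time discrimination is the reciprocal of the
residual standard deviation and the mean reduces to $\lambda_k-\zeta_i$.
`WL` and `par2` are mutually exclusive by construction.

**Population structure.** Persons are exchangeable draws from
$(\theta_i,\zeta_i)\sim N_2(\mu_P,\Sigma_P)$; items from
$(a_k,b_k,\varphi_k,\lambda_k)\sim N_4(\mu_I,\Sigma_I)$ with $a_k,\varphi_k$
restricted positive. The speed--accuracy relation of interest is the
off-diagonal of $\Sigma_P$; item-side covariances describe, e.g., whether
time-intensive items are also difficult. Hyperpriors are inverse-Wishart
for both covariance matrices and normal--inverse-Wishart for
$(\mu_I,\Sigma_I)$ with prior sample size $\kappa=1$ (vaguely
informative). Guessing probabilities get a Beta(20, 80) prior — prior
guessing proportion $1/5$ with SD $0.04$. Person and item means can be
regressed on dummy-coded explanatory variables (`XPA`, `XPT` for ability
and speed; `XIA`, `XIT` for difficulty and time intensity); predictors for
the discriminations are deliberately not supported, since their variance
is typically very small.

## Estimation

All parameters are sampled by Gibbs sampling with data augmentation: a
latent continuous propensity $Z_{ik}=a_k\theta_i-b_k+e_{ik}$,
$e_{ik}\sim N(0,1)$, is introduced so that the probit likelihood becomes
a normal linear model. The update order within an iteration is fixed:
augmentation → person block → item block → residual variances → guessing
→ hyperparameters → identification → imputation. Any valid order leaves
the stationary distribution unchanged; fixing one makes runs exactly
reproducible given a seed.

The full conditionals are standard conjugate forms and are derived, not
quoted: truncated-normal augmentation (positive for non-guessed correct
responses, negative for incorrect ones), bivariate-normal person updates
combining the probit and log-normal likelihood contributions with the
$N_2(\mu_P,\Sigma_P)$ prior, a systematic scan of univariate conditionals
for $(a_k,b_k,\varphi_k,\lambda_k)$ under the $N_4$ prior, inverse-gamma
updates for $\sigma^2_k$ (prior shape 1, rate 0.1 — vague, configurable),
Beta--Bernoulli updates for guessing, and normal--inverse-Wishart updates
for the population blocks. The item block uses a scan of univariate
conditionals rather than one joint 4-variate draw so that the positivity
restrictions and the bracketed (nonlinear-in-parameters) conventions are
handled exactly; the scan is itself a valid Gibbs step. Truncated normal
draws use the inverse-CDF in whichever tail keeps full floating-point
accuracy, so extreme propensities do not degenerate.

With guessing active, a latent indicator classifies each correct response
as a correct random guess or a response generated by the IRT process,
with conditional odds $c_k : (1-c_k)\Phi(a_k\theta_i-b_k)$; guessed-correct
cells are uninformative for the IRT likelihood and drop out of the person
and item updates.

**Identification.** The latent scales are fixed by rescaling every
iteration so that $\prod_k a_k = 1$ and $\prod_k \varphi_k = 1$, with
compensating transformations of persons and hyperparameters that leave
the likelihood invariant. For the location, `ident = 1` shifts so that
$\sum_k b_k = 0$ and $\sum_k \lambda_k = 0$ — under the non-bracketed
forms the compensating shifts are item-specific,
$b_k \leftarrow b_k + a_k d$ with $d=-\sum b_k/\sum a_k$, which is the
exact likelihood-invariant transformation — while `ident = 2` (default)
fixes $\mu_\theta=\mu_\zeta=0$. Recentring is applied per iteration (a
design choice: the constraints then hold on every stored draw, which is
also what the invariant tests assert). Probit-scale item estimates can be
converted to the logistic scale and back with the usual factor 1.7
(`probit_logistic_transform()`).

**Missing data.** Two kinds of missingness are distinguished. Cells
flagged missing by design (`MBDY`/`MBDT` masks, 0 = missing by design)
are excluded from every likelihood term and never imputed. All other
missing cells are treated as missing at random and refreshed each
iteration from their posterior predictive distributions (Bernoulli for
accuracy, normal for log times). A person with no observed data at all is
rejected unless covered by the design masks. Raw (unlogged) times can be
supplied with `log_rt = FALSE`; non-positive times become missing, since
a zero recorded time cannot be distinguished from a skipped item.

## Model fit

With `residual = TRUE`, person-fit, item-fit and residual diagnostics are
accumulated inside the chain after `XGresid` iterations, so every
statistic is averaged over posterior draws (an interpretation choice: the
extremeness probabilities are computed by MCMC accumulation over the
posterior rather than by prior-predictive integration).

* **Accuracy person fit.** The negative log-likelihood of a pattern is
  standardized by its conditional mean
  $\sum_k[-p\ln p-(1-p)\ln(1-p)]$ and SD
  $\sqrt{\sum_k p(1-p)\ln(p/(1-p))^2}$ — the classical standardized
  log-likelihood construction, which is approximately standard normal.
  At the 5% level the critical value is $1.645$. Reported: the posterior
  mean standardized statistic (`PFl`), its significance probability
  (`PFlp`), and the posterior probability the pattern is extreme
  (`EAPCP2`). Under guessing, only non-guessed cells enter.
* **Time person fit.** $\sum_k(rt_{ik}-(\lambda_k-\varphi_k\zeta_i))^2/
  \sigma^2_k$ is chi-square with as many degrees of freedom as observed
  cells (missing cells reduce the degrees of freedom; they are never
  imputed into fit statistics — fit should reflect observed data only).
  For 170 items the 5% critical value is 201.4. Reported: `lZPT`, `lZP`,
  `EAPCP1`; the joint flag `EAPCP3` averages the draw-wise product of the
  two extremeness indicators, so it can never exceed either margin.
* **Residuals.** Accuracy residuals are Rao-Blackwellized truncated-normal
  conditional means. One printed form of the conditional outlier
  probability can exceed one for large thresholds; the implementation
  uses the self-consistent truncated-normal tail (verified by Monte Carlo
  against draws of the truncated latent variable in the test suite), and
  the corresponding conditional mean uses the matching normalizer
  $\Phi(a_k\theta_i-b_k)$ for correct responses. Time residuals
  $rt_{ik}-(\lambda_k-\varphi_k\zeta_i)$ are flagged through
  $\Phi(-C-\epsilon/\sigma)+1-\Phi(C-\epsilon/\sigma)$ with $C = 2$ by
  default. Per item, a Kolmogorov--Smirnov statistic compares the
  standardized time residuals with the standard normal; `EAPKS` is the
  posterior probability that the test rejects at the configured level.
  The latent-residual analogues (`EAPKSA`, `lZPA`) are reported for
  completeness but have essentially no power, because the augmented
  residuals are constructed to be marginally normal.

## Differential working speed

`jirtq()` replaces the constant speed with a latent growth trajectory
over the solve order of the items:
$$RT_{ik}=\lambda_k-\varphi_k\big(\zeta_{0i}+\zeta_{1i}X_{ik}+
\zeta_{2i}X_{ik}^2\big)+\varepsilon_{ik},$$
where $X_{ik}=(\text{position}-1)/K$ is an equidistant time scale on
$[0,(K-1)/K]$ with the first item solved at 0 (administration order by
default, or a solve-order matrix via `build_time_scale()`). Ability and
the speed components are jointly normal with speed means fixed at zero.
By default the covariance among the speed components is restricted to
zero — their dependence is carried by the time discriminations — which is
implemented through the conjugate factorization
$p(\zeta)\,p(\theta\mid\zeta)$: independent inverse-gamma variances for
the components and a normal regression of ability on them, giving free
ability--speed covariances with zero speed--speed covariances. When all
time discriminations are fixed at one (`td = FALSE`), `full_cov = TRUE`
frees the whole covariance matrix under an inverse-Wishart prior.

Identification differs from the constant-speed default because the speed
location is already anchored by the zero means of the growth components:
the difficulties are centered ($\sum b_k=0$, with the compensating
ability shift) while the mean ability is free, and both discrimination
products are fixed at one. The item block uses the same hierarchical
$N_4(\mu_I,\Sigma_I)$ population prior as the constant-speed sampler —
a deliberate choice so that with trend and quadratic components disabled
the sampler reproduces the constant-speed model exactly up to Monte Carlo
error (the nesting is asserted in the test suite by mapping draws into a
common identification frame). Entirely missing records are allowed here:
they receive prior-driven draws, and their posterior person means shrink
to the population averages.

## The synthetic-data generator

`jirt_sim()` draws persons and items from the hierarchical model itself
and generates data cell-independently given the parameters, so parameter
recovery, calibration of the fit statistics and the small-instance
quadrature comparisons are all testable without external data. Defaults
emulate a large operational licensure exam: mean discrimination 1.19,
mean difficulty $-0.70$, mean time discrimination 1.03, mean time
intensity 3.96 log-seconds, item SDs and signs of the item correlations
to match (easier items more discriminating, difficult items more
time-intensive), residual variances inverse-gamma with mean 0.26, and a
Beta(20, 80) guessing distribution. Person variances default to 1
(ability) and 0.25 (speed) with correlation 0.4; the speed variance is
chosen so that times are informative about speed at realistic test
lengths while remaining small relative to the residual noise, as
operational data show. Positivity of the drawn discriminations is
enforced by redrawing the whole 4-vector, which preserves the joint
normal shape conditionally on the positive orthant; for the default
means and variances rejections are rare. A degenerate (positive
semi-definite) covariance is accepted and reproduces its mean exactly.

What the generator does **not** emulate: within-person strategy shifts
other than the quadratic speed trajectory, rapid-guessing mixtures on the
time side, censoring from time limits, local dependence between
neighboring items, and non-lognormal time tails. Passing recovery and
calibration tests therefore demonstrates internal consistency of the
estimator under its own assumptions, not robustness to these
misspecifications — the fit tools exist precisely to flag such patterns
in real data.

## Numerical choices and problem sizes

Tolerances and sizes used in the shipped checks are the package's own
choices: recovery studies use 500 persons, 20 items and 3000 draws with
20 replicates (enough for four-Monte-Carlo-SE bias bounds on the item
locations); calibration uses 800 persons and 30 items; the brute-force
quadrature comparison uses three persons and three items on a grid of
step 0.04 over $[-6,6]^2$ with 30000 Gibbs draws, where agreement within
0.02 is attainable given both quadrature and Monte Carlo error. The
default burn-in is 10% of the run; summaries discard it before computing
EAPs and SDs. Chains should be long enough for an effective sample size
of about 400 (`ess()`, `mcse()`), at which point the Monte Carlo standard
error is 5% of the posterior SD. Degenerate inputs are handled
explicitly: all-correct or all-incorrect items are kept (the population
prior regularizes them, with a warning), constant chains make the ESS
undefined rather than infinite, and ties or tiny samples in the KS check
warn.

## Limitations

Accuracy data are binary only; hierarchies deeper than persons and items,
hidden-state switching and speed-moderated discriminations are out of
scope. The single-chain Geweke check cannot prove convergence; for
multi-chain diagnostics, run the sampler repeatedly with different seeds
(starting values are random, seed-controlled) and compare chains with
generic MCMC tooling on the exported CSV draws.

## A worked example

```{r, eval = FALSE}
library(jirt)
sim <- jirt_sim(N = 500, K = 20, seed = 1)
fit <- jirt(sim$Y, sim$RT, XG = 3000, seed = 2, truth = sim)
summary(fit)              # item EAP/SD, population means, covariances
person_fit(jirt(sim$Y, sim$RT, XG = 2000, XGresid = 1000,
                residual = TRUE, seed = 3))
```
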