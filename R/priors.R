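#' Prior and hyperprior settings for the joint model
#'
#' Collects the hyperprior constants: inverse-Wishart degrees of freedom
#' and scale matrices for the person and item covariance matrices, the
#' normal-inverse-Wishart prior mean `mu0` and prior sample size `kappa`
#' for the item means (`kappa = 1` gives a vaguely informative prior),
#' the Beta shapes for the guessing probabilities (default `c(20, 80)`:
#' prior guessing proportion 1/5 with SD 0.04), a vague inverse-gamma
#' prior for the residual log-time variances, and the (large) prior
#' variance of regression coefficients for explanatory variables.
#'
#' @param nu_P,V_P inverse-Wishart df and scale for the 2x2 person
#'   covariance.
#' @param nu_I,V_I inverse-Wishart df and scale for the 4x4 item
#'   covariance.
#' @param mu0 prior mean of the item parameter means (a, b, phi, lambda).
#' @param kappa prior number of measurements for the item means.
#' @param guess_shape Beta shape pair for the guessing prior.
#' @param sigma2_shape,sigma2_rate inverse-gamma shape and rate for the
#'   residual variances.
#' @param beta_var prior variance of regression coefficients.
#' @return an object of class `jirt_prior`.
#' @export
jirt_prior <- function(nu_P = 3, V_P = diag(2), nu_I = 5, V_I = diag(4),
                       mu0 = c(1, 0, 1, 3.7), kappa = 1,
                       guess_shape = c(20, 80),
                       sigma2_shape = 1, sigma2_rate = 0.1,
                       beta_var = 100) {
  stopifnot(nu_P > 1, nu_I > 3, kappa > 0, all(guess_shape > 0),
            sigma2_shape > 0, sigma2_rate > 0, beta_var > 0,
            length(mu0) == 4)
  check_spd(V_P, 2, "V_P", strict = TRUE)
  check_spd(V_I, 4, "V_I", strict = TRUE)
  structure(list(nu_P = nu_P, V_P = V_P, nu_I = nu_I, V_I = V_I,
                 mu0 = mu0, kappa = kappa, guess_shape = guess_shape,
                 sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate,
                 beta_var = beta_var),
            class = "jirt_prior")
}

#' Settings for the person-fit, item-fit and residual diagnostics
#'
#' @param alpha significance level of the fit tests (default 0.05). The
#'   accuracy person-fit statistic is referred to the standard normal, so
#'   the default critical value is `qnorm(0.95) = 1.645`; the
#'   response-time statistic is referred to a chi-square whose degrees of
#'   freedom equal the number of observed cells in the pattern.
#' @param C_resid threshold (in residual SD units) beyond which a
#'   residual is counted as extreme (default 2).
#' @param flag_probability posterior probability above which a pattern is
#'   reported as aberrant (default 0.95).
#' @param ks_min_n minimum number of residuals for the per-item
#'   Kolmogorov-Smirnov normality check.
#' @return an object of class `jirt_fitconfig`.
#' @export
jirt_fitconfig <- function(alpha = 0.05, C_resid = 2,
                           flag_probability = 0.95, ks_min_n = 10) {
  stopifnot(alpha > 0, alpha < 1, C_resid > 0,
            flag_probability > 0, flag_probability <= 1, ks_min_n >= 2)
  structure(list(alpha = alpha, C_ra = stats::qnorm(1 - alpha),
                 C_resid = C_resid, flag_probability = flag_probability,
                 ks_min_n = ks_min_n),
            class = "jirt_fitconfig")
}
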