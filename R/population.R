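#' Population specification for the joint model
#'
#' Bundles the population (level-2) distributions used by the simulator:
#' a bivariate normal for the person parameters (ability, speed), a
#' 4-variate normal for the item parameters (discrimination, difficulty,
#' time discrimination, time intensity) with positivity enforced on the
#' discriminations, an inverse-gamma for the residual log-time variances
#' and a Beta distribution for guessing probabilities.
#'
#' Defaults are chosen to look like a large operational licensure exam:
#' mean discrimination about 1.19, mean time intensity about 3.96
#' log-seconds, ability-speed correlation 0.4, residual log-time variance
#' with mean 0.26, and a Beta(20, 80) guessing distribution (mean 1/5,
#' SD 0.04).
#'
#' @param mu_P length-2 person mean (ability, speed).
#' @param Sigma_P 2x2 person covariance matrix (symmetric positive definite).
#' @param mu_I length-4 item mean (a, b, phi, lambda).
#' @param Sigma_I 4x4 item covariance matrix (symmetric positive definite).
#' @param sigma2_shape,sigma2_scale inverse-gamma shape/scale for the
#'   residual variances; the default has mean `scale/(shape-1) = 0.26`.
#' @param guess_shape length-2 Beta shape parameters for guessing.
#' @return an object of class `jirt_popspec`.
#' @export
jirt_popspec <- function(mu_P = c(0, 0),
                         Sigma_P = matrix(c(1, 0.2, 0.2, 0.25), 2, 2),
                         mu_I = c(1.19, -0.70, 1.03, 3.96),
                         Sigma_I = default_item_cov(),
                         sigma2_shape = 5, sigma2_scale = 1.04,
                         guess_shape = c(20, 80)) {
  check_spd(Sigma_P, 2, "Sigma_P")
  check_spd(Sigma_I, 4, "Sigma_I")
  stopifnot(length(mu_P) == 2, length(mu_I) == 4,
            sigma2_shape > 0, sigma2_scale > 0, all(guess_shape > 0))
  structure(list(mu_P = mu_P, Sigma_P = Sigma_P, mu_I = mu_I,
                 Sigma_I = Sigma_I, sigma2_shape = sigma2_shape,
                 sigma2_scale = sigma2_scale, guess_shape = guess_shape),
            class = "jirt_popspec")
}

# Item covariance built from the default SDs and the correlation pattern of
# a typical operational dataset: easier items discriminate better, the
# less time-intensive items are more time-discriminating, difficult items
# are more time-intensive, and the two discrimination types are positively
# related.
default_item_cov <- function() {
  s <- sqrt(c(0.32, 0.27, 0.05, 0.11))
  R <- matrix(c(1, -0.43, 0.49, 0,
                -0.43, 1, 0, 0.46,
                0.49, 0, 1, -0.40,
                0, 0.46, -0.40, 1), 4, 4)
  diag(s) %*% R %*% diag(s)
}

check_spd <- function(S, d, name, strict = FALSE) {
  if (!is.matrix(S) || nrow(S) != d || ncol(S) != d)
    stop(sprintf("'%s' must be a %dx%d matrix", name, d, d))
  if (max(abs(S - t(S))) > 1e-8)
    stop(sprintf("'%s' must be symmetric", name))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  tol <- if (strict) 0 else -1e-10 * max(abs(ev), 1)
  if (min(ev) <= tol)
    stop(sprintf("'%s' must be positive %sdefinite", name,
                 if (strict) "" else "semi-"))
  invisible(TRUE)
}

# Draw n rows from N(mu, Sigma); Cholesky with an eigendecomposition
# fallback so that positive semi-definite (degenerate) covariances work.
rmvnorm_chol <- function(n, mu, Sigma) {
  d <- length(mu)
  L <- tryCatch(chol(Sigma), error = function(e) {
    ed <- eigen(Sigma, symmetric = TRUE)
    t(ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors)))
  })
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% L, 2, mu, "+")
}

#' Draw person parameters from the population distribution
#'
#' Independent draws of (ability, speed) from the bivariate normal person
#' distribution of a [jirt_popspec()].
#'
#' @param N number of persons (>= 1).
#' @param spec a `jirt_popspec`.
#' @param seed optional integer seed for reproducibility.
#' @return an `N x 2` matrix with columns `theta` and `zeta`.
#' @export
draw_persons <- function(N, spec = jirt_popspec(), seed = NULL) {
  stopifnot(N >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- rmvnorm_chol(N, spec$mu_P, spec$Sigma_P)
  colnames(out) <- c("theta", "zeta")
  out
}

#' Draw item parameters from the population distribution
#'
#' Draws (a, b, phi, lambda) from the 4-variate normal item distribution
#' of a [jirt_popspec()]. Positivity of the discrimination `a` and the
#' time discrimination `phi` is enforced by redrawing the full 4-vector
#' until both are positive, which preserves the joint normal shape
#' conditionally on the positive orthant; with means near 1 and small
#' variances rejections are rare. Residual variances are drawn from the
#' configured inverse-gamma, and (when `guess = TRUE`) guessing
#' probabilities from the Beta guessing distribution.
#'
#' @param K number of items (>= 2).
#' @param spec a `jirt_popspec`.
#' @param guess draw guessing probabilities? Default `FALSE` (c = 0).
#' @param seed optional integer seed.
#' @return a data.frame with columns `a`, `b`, `phi`, `lambda`, `sigma2`, `c`.
#' @export
draw_items <- function(K, spec = jirt_popspec(), guess = FALSE, seed = NULL) {
  stopifnot(K >= 2)
  if (!is.null(seed)) set.seed(seed)
  U <- matrix(NA_real_, K, 4)
  todo <- rep(TRUE, K)
  while (any(todo)) {
    U[todo, ] <- rmvnorm_chol(sum(todo), spec$mu_I, spec$Sigma_I)
    todo <- U[, 1] <= 0 | U[, 3] <= 0
  }
  sigma2 <- 1 / stats::rgamma(K, shape = spec$sigma2_shape,
                              rate = spec$sigma2_scale)
  cc <- if (guess) stats::rbeta(K, spec$guess_shape[1], spec$guess_shape[2])
        else rep(0, K)
  data.frame(a = U[, 1], b = U[, 2], phi = U[, 3], lambda = U[, 4],
             sigma2 = sigma2, c = cc)
}
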