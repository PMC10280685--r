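#' Success probability under the normal-ogive item response model
#'
#' Evaluates the probability of a correct response for the two- or
#' three-parameter normal-ogive (probit) model. Two equivalent bracketing
#' conventions for the mean term are supported: the default places the
#' difficulty on the propensity scale, `P = c + (1 - c) * pnorm(a * theta - b)`;
#' with `par1 = TRUE` the difficulty is on the ability scale,
#' `P = c + (1 - c) * pnorm(a * (theta - b))`. The two conventions agree
#' when the propensity-scale difficulty equals `a` times the ability-scale
#' difficulty.
#'
#' @param theta person ability (vector recycled against the item parameters).
#' @param a item discrimination, must be positive.
#' @param b item difficulty; its scale depends on `par1`.
#' @param c guessing probability in `[0, 1)`; default 0 (two-parameter model).
#' @param par1 logical; `TRUE` uses the bracketed (ability-scale) convention.
#' @return numeric vector of probabilities in `[c, 1)`.
#' @examples
#' success_probability(0, a = 1, b = 0)        # 0.5
#' success_probability(-10, a = 1, b = 0, c = 0.2)  # lower asymptote 0.2
#' @export
success_probability <- function(theta, a, b, c = 0, par1 = FALSE) {
  if (!all(is.finite(theta), is.finite(a), is.finite(b), is.finite(c)))
    stop("non-finite arguments to success_probability()")
  if (any(a <= 0)) stop("discrimination 'a' must be positive")
  if (any(c < 0 | c >= 1)) stop("guessing 'c' must lie in [0, 1)")
  eta <- if (par1) a * (theta - b) else a * theta - b
  c + (1 - c) * stats::pnorm(eta)
}

#' Expected log response time under the log-normal model
#'
#' Mean of the log response time given working speed and item parameters.
#' Under the default convention the mean is `lambda - phi * zeta`; with
#' `par2 = TRUE` the time intensity is on the speed scale and the mean is
#' `phi * (lambda - zeta)`; with `wl = TRUE` the time discrimination is the
#' reciprocal of the residual standard deviation and the mean reduces to
#' `lambda - zeta`.
#'
#' @param zeta person working speed.
#' @param phi item time discrimination, positive.
#' @param lambda item time intensity (log-seconds); its scale depends on the
#'   convention flags.
#' @param par2 logical; bracketed (speed-scale) convention for the intensity.
#' @param wl logical; reciprocal-error-SD parameterization. Mutually
#'   exclusive with `par2`.
#' @return numeric vector of expected log response times.
#' @examples
#' expected_log_rt(0, phi = 1.3, lambda = 4)   # 4
#' expected_log_rt(0.5, phi = 1, lambda = 4)   # 3.5
#' @export
expected_log_rt <- function(zeta, phi, lambda, par2 = FALSE, wl = FALSE) {
  if (!all(is.finite(zeta), is.finite(phi), is.finite(lambda)))
    stop("non-finite arguments to expected_log_rt()")
  if (any(phi <= 0)) stop("time discrimination 'phi' must be positive")
  if (par2 && wl) stop("'par2' and 'wl' are mutually exclusive")
  if (wl) return(lambda - zeta)
  if (par2) return(phi * (lambda - zeta))
  lambda - phi * zeta
}

#' Transform item parameters between the probit and logistic scales
#'
#' Uses the logistic scale factor 1.7: going from the probit to the
#' logistic scale divides the discrimination by 1.7 and multiplies the
#' difficulty by 1.7; the reverse direction inverts this, so a round trip
#' is the identity.
#'
#' @param a discrimination (positive).
#' @param b difficulty.
#' @param to either "logistic" (from probit) or "probit" (from logistic).
#' @return list with components `a` and `b` on the target scale.
#' @examples
#' probit_logistic_transform(1.7, 1, to = "logistic")  # a = 1, b = 1.7
#' @export
probit_logistic_transform <- function(a, b, to = c("logistic", "probit")) {
  to <- match.arg(to)
  if (!all(is.finite(a), is.finite(b)))
    stop("non-finite arguments to probit_logistic_transform()")
  if (any(a <= 0)) stop("discrimination 'a' must be positive")
  D <- 1.7
  if (to == "logistic") list(a = a / D, b = b * D) else list(a = a * D, b = b / D)
}
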