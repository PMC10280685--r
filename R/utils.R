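# Internal numerical helpers shared by the samplers.

# Draw standard-normal variates truncated to (lo, Inf), vectorized and
# stable in the far tails: below 0 use the lower-tail inverse CDF, above 0
# work in the upper tail where pnorm/qnorm keep full relative accuracy.
rtnorm_lower <- function(lo) {
  n <- length(lo)
  u <- stats::runif(n)
  z <- numeric(n)
  lt <- lo <= 0
  if (any(lt)) {
    p <- stats::pnorm(lo[lt])
    z[lt] <- stats::qnorm(p + u[lt] * (1 - p))
  }
  if (any(!lt)) {
    q <- stats::pnorm(lo[!lt], lower.tail = FALSE)
    z[!lt] <- stats::qnorm(u[!lt] * q, lower.tail = FALSE)
  }
  # guard against qnorm returning Inf for truncation points beyond ~1e2
  bad <- !is.finite(z)
  if (any(bad)) z[bad] <- lo[bad] + 1 / pmax(lo[bad], 1)
  z
}

# One draw from the inverse-Wishart IW(nu, V): Sigma^{-1} ~ Wishart(nu, V^{-1}),
# so E[Sigma] = V / (nu - p - 1).
rinvwishart <- function(nu, V) {
  p <- nrow(V)
  if (nu <= p - 1) stop("inverse-Wishart degrees of freedom too small")
  W <- stats::rWishart(1, df = nu, Sigma = solve(V))[, , 1]
  Sinv <- solve(W)
  (Sinv + t(Sinv)) / 2
}

# Draw from N(m, solve(P)) given precision matrix P and h with m = solve(P, h).
rmvnorm_prec <- function(h, P) {
  R <- chol(P)
  m <- backsolve(R, backsolve(R, h, transpose = TRUE))
  m + backsolve(R, stats::rnorm(length(h)))
}

clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a
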