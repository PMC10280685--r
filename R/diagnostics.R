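# Single-chain MCMC output diagnostics: effective sample size by Geyer's
# initial-positive-sequence estimator, Monte Carlo standard errors, and a
# Geweke-style mean-difference convergence check.

#' Effective sample size of an MCMC chain
#'
#' Estimates the autocorrelation time with the initial-positive-sequence
#' truncation (sums of adjacent autocovariance pairs are accumulated
#' while they remain positive) and returns `n * gamma0 / sigma2`, the
#' number of independent draws carrying the same information about the
#' mean. A rule of thumb is to aim for an effective sample size of 400,
#' at which point the Monte Carlo standard error is 5% of the posterior
#' SD.
#'
#' @param chain numeric vector, length at least 100.
#' @return the estimated effective sample size (capped at the chain
#'   length).
#' @export
ess <- function(chain) {
  n <- length(chain)
  if (n < 100) stop("chain too short for an ESS estimate (need >= 100)")
  if (stats::sd(chain) == 0) {
    warning("constant chain: ESS undefined")
    return(NA_real_)
  }
  lag_max <- min(n - 1, 2000L)
  ac <- stats::acf(chain, lag.max = lag_max, type = "covariance",
                   plot = FALSE, demean = TRUE)$acf[, 1, 1]
  g0 <- ac[1]
  # pair sums Gamma_m = gamma_{2m} + gamma_{2m+1}
  m_max <- floor((length(ac) - 1) / 2)
  sig2 <- -g0
  for (m in 0:m_max) {
    G <- ac[2 * m + 1] + if (2 * m + 2 <= length(ac)) ac[2 * m + 2] else 0
    if (G <= 0) break
    sig2 <- sig2 + 2 * G
  }
  sig2 <- max(sig2, g0 / n)
  min(n * g0 / sig2, n)
}

#' Monte Carlo standard error of a posterior mean
#'
#' `MCSE = posterior SD / sqrt(ESS)`; by construction the ratio
#' `MCSE / SD` equals `1 / sqrt(ESS)` for every chain.
#'
#' @param chain numeric vector.
#' @return list with `mcse`, `ess`, `sd` and the naive standard error
#'   `sd / sqrt(n)`.
#' @export
mcse <- function(chain) {
  e <- ess(chain)
  s <- stats::sd(chain)
  list(mcse = s / sqrt(e), ess = e, sd = s,
       naive_se = s / sqrt(length(chain)))
}

#' Geweke-style single-chain convergence check
#'
#' Compares the mean of the first fraction of the chain with the mean of
#' the last fraction; the standardization uses the autocorrelation-
#' adjusted variance of each segment. Values of |z| above ~2 hint at
#' non-convergence.
#'
#' @param chain numeric vector.
#' @param frac1,frac2 fractions used for the early and late windows.
#' @return the z statistic.
#' @export
geweke <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  n <- length(chain)
  x1 <- chain[seq_len(max(floor(n * frac1), 50))]
  x2 <- chain[(n - max(floor(n * frac2), 50) + 1):n]
  seg_var <- function(x) {
    e <- tryCatch(ess(x), warning = function(w) NA_real_,
                  error = function(e) NA_real_)
    if (is.na(e)) return(NA_real_)
    stats::var(x) / e
  }
  v1 <- seg_var(x1); v2 <- seg_var(x2)
  (mean(x1) - mean(x2)) / sqrt(v1 + v2)
}

#' Chain diagnostics table for a fitted joint model
#'
#' ESS, Monte Carlo SE, naive SE and the Geweke z for the item-parameter
#' and hyperparameter chains (after burn-in).
#'
#' @param object a `jirt` fit.
#' @param pars which chain blocks to include.
#' @return a data.frame, one row per scalar chain.
#' @export
chain_diagnostics <- function(object,
                              pars = c("b", "lambda", "a", "phi",
                                       "sigma2", "mu_I", "Sigma_P")) {
  stopifnot(inherits(object, "jirt") || inherits(object, "jirtq"))
  keep <- retained_iterations(object$XG, object$burnin)
  rows <- list()
  for (p in pars) {
    ch <- object$draws[[p]]
    if (is.null(ch)) next
    if (length(dim(ch)) == 3) {
      d <- dim(ch)
      for (i in seq_len(d[2])) for (j in i:d[3]) {
        x <- ch[keep, i, j]
        m <- mcse(x)
        rows[[length(rows) + 1]] <- data.frame(
          parameter = sprintf("%s[%d,%d]", p, i, j), mean = mean(x),
          sd = m$sd, naive_se = m$naive_se, mcse = m$mcse, ess = m$ess,
          geweke_z = geweke(x))
      }
    } else {
      for (j in seq_len(ncol(ch))) {
        x <- ch[keep, j]
        m <- mcse(x)
        rows[[length(rows) + 1]] <- data.frame(
          parameter = sprintf("%s[%d]", p, j), mean = mean(x),
          sd = m$sd, naive_se = m$naive_se, mcse = m$mcse, ess = m$ess,
          geweke_z = geweke(x))
      }
    }
  }
  do.call(rbind, rows)
}

# iterations retained after discarding the burn-in percentage
retained_iterations <- function(XG, burnin) {
  drop <- floor(XG * burnin / 100)
  if (drop >= XG) stop("burn-in discards every iteration")
  (drop + 1):XG
}
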