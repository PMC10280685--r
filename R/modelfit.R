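# Person-fit, item-fit, residual and distributional diagnostics. The
# statistics are evaluated per MCMC draw inside the sampler (accumulation
# starts after XGresid iterations); the standalone functions below expose
# the same computations for a single parameter configuration.

#' Accuracy person-fit statistic (standardized log-likelihood)
#'
#' The negative log-likelihood of a binary response pattern under the
#' two-parameter normal-ogive model, standardized by its conditional mean
#' `sum(-p log p - (1-p) log(1-p))` and conditional SD
#' `sqrt(sum(p (1-p) log(p/(1-p))^2))`, which makes it approximately
#' standard normal; large values indicate misfit. Cells with `NA` in `y`
#' are dropped. Under a guessing model, pass only the non-guessed cells.
#'
#' @param y 0/1 response vector (NA allowed).
#' @param p success probabilities of the same length.
#' @return list with `statistic` (the negative log-likelihood),
#'   `standardized` and `tail_probability` (standard-normal upper tail of
#'   the standardized value).
#' @export
person_fit_ra <- function(y, p) {
  keep <- !is.na(y)
  if (!any(keep)) {
    warning("no usable responses for the accuracy person-fit statistic")
    return(list(statistic = NA_real_, standardized = NA_real_,
                tail_probability = NA_real_))
  }
  y <- y[keep]; p <- clamp_prob(p[keep])
  l <- -sum(y * log(p) + (1 - y) * log(1 - p))
  m <- sum(-p * log(p) - (1 - p) * log(1 - p))
  v <- sum(p * (1 - p) * (log(p / (1 - p)))^2)
  ls <- if (v > 0) (l - m) / sqrt(v) else 0
  list(statistic = l, standardized = ls,
       tail_probability = stats::pnorm(ls, lower.tail = FALSE))
}

#' Response-time person-fit statistic (sum of squared standardized errors)
#'
#' `sum((rt - (lambda - phi * zeta))^2 / sigma2)` over observed cells;
#' given the parameters it is chi-square distributed with as many degrees
#' of freedom as observed cells. Missing cells reduce the degrees of
#' freedom; they are never imputed into the statistic.
#'
#' @param rt log response-time vector (NA allowed).
#' @param zeta person speed (scalar).
#' @param lambda,phi,sigma2 item parameter vectors.
#' @return list with `statistic`, `df` and `tail_probability` (upper
#'   chi-square tail).
#' @export
person_fit_rt <- function(rt, zeta, lambda, phi, sigma2) {
  keep <- !is.na(rt)
  if (!any(keep)) {
    warning("no observed response times for the person-fit statistic")
    return(list(statistic = NA_real_, df = 0L, tail_probability = NA_real_))
  }
  r <- rt[keep] - (lambda[keep] - phi[keep] * zeta)
  stat <- sum(r^2 / sigma2[keep])
  df <- sum(keep)
  list(statistic = stat, df = df,
       tail_probability = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Conditional expectation and outlier probability of a latent accuracy residual
#'
#' Rao-Blackwellized residual for the probit model: the latent propensity
#' is `a * theta - b + e` with standard-normal `e`, so conditionally on a
#' correct response `e` is truncated to `e > b - a * theta` and on an
#' incorrect response to `e < b - a * theta`. Returns the truncated-normal
#' conditional mean and the conditional probability that `|e| > C`.
#'
#' @param y 0/1 response (vectorized).
#' @param theta ability; `a`, `b` item parameters.
#' @param C outlier threshold (default 2).
#' @return list with `expected_residual` and `outlier_probability`.
#' @export
latent_residual <- function(y, theta, a, b, C = 2) {
  t0 <- b - a * theta
  num1 <- stats::pnorm(t0, lower.tail = FALSE)   # P(e > t0)
  num0 <- stats::pnorm(t0)                       # P(e < t0)
  e1 <- stats::dnorm(t0) / pmax(num1, 1e-300)
  e0 <- -stats::dnorm(t0) / pmax(num0, 1e-300)
  er <- ifelse(y == 1, e1, e0)
  p1 <- (stats::pnorm(pmax(C, t0), lower.tail = FALSE) +
           pmax(0, stats::pnorm(-C) - stats::pnorm(t0))) / pmax(num1, 1e-300)
  p0 <- (stats::pnorm(pmin(-C, t0)) +
           pmax(0, stats::pnorm(t0) - stats::pnorm(C))) / pmax(num0, 1e-300)
  pr <- ifelse(y == 1, p1, p0)
  list(expected_residual = er, outlier_probability = pmin(pmax(pr, 0), 1))
}

#' Outlier probability of a response-time residual
#'
#' For residual `eps = rt - (lambda - phi * zeta)` the probability that a
#' replicate residual exceeds `C` residual-SD units in absolute value:
#' `pnorm(-C - eps/sigma) + 1 - pnorm(C - eps/sigma)`.
#'
#' @param eps residual(s) on the log-time scale.
#' @param sigma residual SD(s).
#' @param C threshold in SD units (default 2).
#' @return probability vector in `[0, 1]`.
#' @export
rt_residual_prob <- function(eps, sigma, C = 2) {
  z <- eps / sigma
  stats::pnorm(-C - z) + stats::pnorm(C - z, lower.tail = FALSE)
}

#' Kolmogorov-Smirnov check of response-time residual normality
#'
#' Compares the empirical distribution of standardized residuals to the
#' standard normal; the supremum distance is referred to the Kolmogorov
#' distribution.
#'
#' @param resid residual vector (NA dropped).
#' @param sigma residual SD used for standardization (scalar or vector).
#' @param min_n minimum sample size; below it a warning is issued.
#' @return list with `D` and `p_value`.
#' @export
ks_resid <- function(resid, sigma = 1, min_n = 10) {
  x <- resid / sigma
  x <- x[!is.na(x)]
  if (length(x) < min_n)
    warning("fewer than ", min_n, " residuals for the KS check")
  if (length(x) < 2 || stats::sd(x) == 0) {
    warning("degenerate residual vector in the KS check")
    return(list(D = NA_real_, p_value = NA_real_))
  }
  kt <- suppressWarnings(stats::ks.test(x, "pnorm"))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Joint aberrance probability from per-draw flags
#'
#' Averages the product of per-draw accuracy and response-time extremeness
#' indicators: the posterior probability that both patterns are flagged.
#'
#' @param ra_flags,rt_flags 0/1 vectors (or matrices draws x persons) of
#'   per-draw flags.
#' @return the posterior probability (vector over persons if matrices).
#' @export
joint_person_flag <- function(ra_flags, rt_flags) {
  if (is.matrix(ra_flags)) colMeans(ra_flags * rt_flags)
  else mean(ra_flags * rt_flags)
}

# ---- in-sampler accumulation ------------------------------------------

fit_acc_init <- function(N, K) {
  zN <- numeric(N); zK <- numeric(K); zNK <- matrix(0, N, K)
  list(n = 0L, PFl = zN, PFlp = zN, Fy = zN, lZPT = zN, lZP = zN,
       Ft = zN, Fty = zN, lZPA = zN,
       IFl = zK, IFlp = zK, lZI = zK, KS = zK, KSA = zK, ksn = zK,
       ksnA = zK, EAPl0 = zNK, resid = zNK, residA = zNK, eres = zNK)
}

# One accumulation pass; uses originally observed cells only (design
# decision: fit statistics reflect observed data, never imputations).
fit_accumulate <- function(acc, st, cfg) {
  N <- st$N; K <- st$K
  E <- ra_mean(st)
  P <- clamp_prob(stats::pnorm(E))
  MRA <- st$obsY & (st$S == 1)
  Yl <- st$Y
  L <- (Yl * log(P) + (1 - Yl) * log(1 - P)) * MRA
  m <- (-P * log(P) - (1 - P) * log(1 - P)) * MRA
  v <- (P * (1 - P) * log(P / (1 - P))^2) * MRA

  # persons, accuracy
  li <- -rowSums(L)
  lsi <- (li - rowSums(m)) / sqrt(pmax(rowSums(v), 1e-12))
  Fy <- as.numeric(lsi > cfg$C_ra)
  # persons, response time
  rp <- rt_mean_parts(st)
  Res <- (st$RT - (matrix(rp$lamw, N, K, byrow = TRUE) -
                     outer(st$zeta, rp$phieff))) * st$obsT
  R2s <- Res^2 / matrix(st$sigma2, N, K, byrow = TRUE)
  lt <- rowSums(R2s * st$obsT)
  dfi <- rowSums(st$obsT)
  pt <- stats::pchisq(lt, pmax(dfi, 1), lower.tail = FALSE)
  Ft <- as.numeric(lt > stats::qchisq(1 - cfg$alpha, pmax(dfi, 1)))

  acc$PFl <- acc$PFl + lsi
  acc$PFlp <- acc$PFlp + stats::pnorm(lsi, lower.tail = FALSE)
  acc$Fy <- acc$Fy + Fy
  acc$lZPT <- acc$lZPT + lt
  acc$lZP <- acc$lZP + pt
  acc$Ft <- acc$Ft + Ft
  acc$Fty <- acc$Fty + Fy * Ft

  # items, accuracy: same construction over columns
  lk <- -colSums(L)
  lsk <- (lk - colSums(m)) / sqrt(pmax(colSums(v), 1e-12))
  acc$IFl <- acc$IFl + lsk
  acc$IFlp <- acc$IFlp + stats::pnorm(lsk, lower.tail = FALSE)
  # items, response time
  ltk <- colSums(R2s * st$obsT)
  dfk <- colSums(st$obsT)
  acc$lZI <- acc$lZI +
    as.numeric(ltk > stats::qchisq(1 - cfg$alpha, pmax(dfk, 1)))

  # cell-level quantities
  acc$EAPl0 <- acc$EAPl0 + L
  Sd <- matrix(sqrt(st$sigma2), N, K, byrow = TRUE)
  acc$resid <- acc$resid +
    rt_residual_prob(Res, Sd, cfg$C_resid) * st$obsT
  lr <- latent_residual(st$Y, st$theta,
                        rep(1, N) %o% st$a,
                        if (st$par1) rep(1, N) %o% (st$a * st$b)
                        else rep(1, N) %o% st$b,
                        C = cfg$C_resid)
  acc$residA <- acc$residA + lr$outlier_probability * MRA
  acc$eres <- acc$eres + lr$expected_residual * MRA

  # latent (augmented) accuracy residuals: low-power checks
  Zr <- (st$Z - E) * MRA
  ltA <- rowSums(Zr^2)
  dfA <- rowSums(MRA)
  acc$lZPA <- acc$lZPA + stats::pchisq(ltA, pmax(dfA, 1), lower.tail = FALSE)

  # per-item KS checks of residual normality
  for (k in seq_len(K)) {
    ok <- st$obsT[, k]
    if (sum(ok) >= 10) {
      kt <- suppressWarnings(stats::ks.test(Res[ok, k] / sqrt(st$sigma2[k]),
                                            "pnorm"))
      acc$KS[k] <- acc$KS[k] + as.numeric(kt$p.value <= cfg$alpha)
      acc$ksn[k] <- acc$ksn[k] + 1
    }
    okA <- MRA[, k]
    if (sum(okA) >= 10) {
      kt <- suppressWarnings(stats::ks.test(st$Z[okA, k] - E[okA, k],
                                            "pnorm"))
      acc$KSA[k] <- acc$KSA[k] + as.numeric(kt$p.value <= cfg$alpha)
      acc$ksnA[k] <- acc$ksnA[k] + 1
    }
  }
  acc$n <- acc$n + 1L
  acc
}

fit_acc_finalize <- function(acc) {
  n <- acc$n
  if (n == 0L) return(NULL)
  out <- list(
    PFl = acc$PFl / n, PFlp = acc$PFlp / n, EAPCP2 = acc$Fy / n,
    lZPT = acc$lZPT / n, lZP = acc$lZP / n, EAPCP1 = acc$Ft / n,
    EAPCP3 = acc$Fty / n, lZPA = acc$lZPA / n,
    IFl = acc$IFl / n, IFlp = acc$IFlp / n, lZI = acc$lZI / n,
    EAPKS = ifelse(acc$ksn > 0, acc$KS / pmax(acc$ksn, 1), NA_real_),
    EAPKSA = ifelse(acc$ksnA > 0, acc$KSA / pmax(acc$ksnA, 1), NA_real_),
    EAPl0 = acc$EAPl0 / n, EAPresid = acc$resid / n,
    EAPresidA = acc$residA / n, latent_residual = acc$eres / n,
    ndraws = n)
  class(out) <- "jirt_fitreport"
  out
}

#' Extract the person-fit report of a fitted joint model
#'
#' Requires a fit run with `residual = TRUE`. Returns, per person: the
#' posterior mean standardized accuracy person-fit statistic (`PFl`), its
#' posterior significance probability (`PFlp`), the response-time
#' statistic (`lZPT`) and its significance probability (`lZP`), and the
#' posterior probabilities that the response-time pattern (`EAPCP1`), the
#' accuracy pattern (`EAPCP2`) or both (`EAPCP3`) are extreme at the
#' configured level.
#'
#' @param object a `jirt` fit with a residual analysis.
#' @return a data.frame with one row per person.
#' @export
person_fit <- function(object) {
  stopifnot(inherits(object, "jirt"))
  if (is.null(object$fit))
    stop("fit was run without residual = TRUE")
  f <- object$fit
  data.frame(PFl = f$PFl, PFlp = f$PFlp, lZPT = f$lZPT, lZP = f$lZP,
             lZPA = f$lZPA, EAPCP1 = f$EAPCP1, EAPCP2 = f$EAPCP2,
             EAPCP3 = f$EAPCP3)
}

#' Extract the item-fit report of a fitted joint model
#'
#' Requires a fit run with `residual = TRUE`. Returns, per item: the
#' standardized accuracy item-fit statistic (`IFl`) and its significance
#' probability (`IFlp`), the posterior probability of an extreme
#' response-time item pattern (`lZI`), and the posterior probabilities of
#' non-normal response-time (`EAPKS`) and latent accuracy (`EAPKSA`)
#' residuals. The latent-residual checks are reported for completeness
#' but have little power.
#'
#' @param object a `jirt` fit with a residual analysis.
#' @return a data.frame with one row per item.
#' @export
item_fit <- function(object) {
  stopifnot(inherits(object, "jirt"))
  if (is.null(object$fit))
    stop("fit was run without residual = TRUE")
  f <- object$fit
  data.frame(IFl = f$IFl, IFlp = f$IFlp, lZI = f$lZI,
             EAPKS = f$EAPKS, EAPKSA = f$EAPKSA)
}
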