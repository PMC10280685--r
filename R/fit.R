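#' Fit the Bayesian joint model for response accuracy and response times
#'
#' Estimates, by data-augmentation Gibbs sampling, the hierarchical joint
#' model in which a normal-ogive (probit) item response model describes
#' the binary accuracy matrix `Y` and a log-normal model describes the
#' log response-time matrix `RT`. Persons carry an ability and a constant
#' working speed with a bivariate normal population distribution; items
#' carry a discrimination, difficulty, time discrimination and time
#' intensity with a 4-variate normal population distribution and a
#' normal-inverse-Wishart hyperprior. Each iteration performs, in order:
#' augmentation of latent response propensities (and guessing
#' indicators), the person block, the item block, residual variances,
#' guessing probabilities, hyperparameters, the identification
#' transformation, and imputation of missing-at-random cells.
#'
#' Identification: under both rules the scale of the latent variables is
#' fixed by rescaling so that the product of the discriminations and of
#' the time discriminations is one on every stored draw. `ident = 1`
#' additionally shifts so that the difficulties and time intensities sum
#' to zero (with compensating shifts of the person parameters, leaving
#' the likelihood invariant); `ident = 2` instead fixes the population
#' means of ability and speed at zero.
#'
#' @param Y `N x K` binary accuracy matrix (`NA` allowed).
#' @param RT `N x K` matrix of log response times (`NA` allowed). Use
#'   `log_rt = FALSE` to pass raw positive times, which are then
#'   log-transformed (non-positive times become `NA`).
#' @param XG total number of MCMC iterations (default 1000), including
#'   burn-in.
#' @param burnin burn-in percentage of `XG` (default 10); used by
#'   `summary()` and the posterior-mean extractors.
#' @param ident identification rule, 1 or 2 (default 2), see Details.
#' @param guess include a guessing parameter (3PL accuracy model)?
#' @param par1 bracketed (ability-scale) difficulty convention?
#' @param par2 bracketed (speed-scale) time-intensity convention?
#' @param td estimate time discriminations? `FALSE` fixes them at one.
#' @param WL reciprocal-error-SD time parameterization (the time
#'   discrimination is `1/sigma_k`); mutually exclusive with `par2`.
#' @param residual run the person-fit / item-fit / residual analysis
#'   alongside estimation? Accumulation starts after `XGresid` draws.
#' @param XGresid number of iterations before residual accumulation
#'   starts (default 1000).
#' @param XPA,XPT optional person predictor matrices (ability, speed);
#'   categorical predictors must be dummy coded. Under `ident = 2` they
#'   must not contain an intercept column.
#' @param XIA,XIT optional item predictor matrices (difficulty, time
#'   intensity).
#' @param MBDY,MBDT optional missing-by-design 0/1 indicator matrices
#'   (0 = missing by design); such cells are excluded from all
#'   likelihood terms and never imputed.
#' @param alpha,beta,phi,lambda optional length-`K` vectors of fixed item
#'   parameters; fixed parameters are never updated.
#' @param sigma2 optional length-`K` vector of fixed residual variances.
#' @param SigmaP optional fixed 2x2 person covariance (known-population
#'   mode, useful for validation studies).
#' @param muP optional fixed person mean vector.
#' @param prior a [jirt_prior()].
#' @param fitcfg a [jirt_fitconfig()].
#' @param log_rt is `RT` already on the log scale? Default `TRUE`.
#' @param seed optional integer seed; all randomness (starting values
#'   included) is reproducible given the seed.
#' @param verbose print progress every 10% of iterations?
#' @param truth optional `jirt_sim` object; stored so that `summary()`
#'   can show generating values next to the estimates.
#' @return an object of class `jirt` with components `draws` (per-
#'   iteration chains for all parameter blocks), the data and masks, the
#'   configuration, and (when `residual = TRUE`) a `fit` report; see
#'   [summary.jirt()], [coef.jirt()], [person_fit()], [item_fit()].
#' @examples
#' sim <- jirt_sim(60, 8, seed = 2)
#' fit <- jirt(sim$Y, sim$RT, XG = 200, seed = 2)
#' coef(fit)[1:3, ]
#' @export
jirt <- function(Y, RT, XG = 1000, burnin = 10, ident = 2, guess = FALSE,
                 par1 = FALSE, par2 = FALSE, td = TRUE, WL = FALSE,
                 residual = FALSE, XGresid = 1000,
                 XPA = NULL, XPT = NULL, XIA = NULL, XIT = NULL,
                 MBDY = NULL, MBDT = NULL,
                 alpha = NULL, beta = NULL, phi = NULL, lambda = NULL,
                 sigma2 = NULL, SigmaP = NULL, muP = NULL,
                 prior = jirt_prior(), fitcfg = jirt_fitconfig(),
                 log_rt = TRUE, seed = NULL, verbose = FALSE,
                 truth = NULL) {
  cl <- match.call()
  if (XG <= 0) stop("'XG' must be a positive integer")
  if (burnin < 0 || burnin >= 100) stop("'burnin' must be in [0, 100)")
  if (!ident %in% 1:2) stop("'ident' must be 1 or 2")
  if (WL && par2) stop("'WL' and 'par2' are mutually exclusive")
  if (residual && XG <= XGresid)
    stop("'XG' must exceed 'XGresid' when residual = TRUE")
  if (!is.null(seed)) set.seed(seed)

  if (!log_rt) {
    RT <- as.matrix(RT)
    RT[!is.na(RT) & RT <= 0] <- NA
    RT <- log(RT)
  }
  dat <- prepare_jirt_data(Y, RT, MBDY, MBDT)
  N <- dat$N; K <- dat$K

  st <- init_jirt_state(dat, ident = ident, guess = guess, par1 = par1,
                        par2 = par2, td = td, WL = WL,
                        XPA = XPA, XPT = XPT, XIA = XIA, XIT = XIT,
                        alpha = alpha, beta = beta, phi = phi,
                        lambda = lambda, sigma2 = sigma2,
                        SigmaP = SigmaP, muP = muP, prior = prior)

  dr <- alloc_jirt_draws(XG, N, K, st)
  acc <- if (residual) fit_acc_init(N, K) else NULL

  step <- max(1L, floor(XG / 10))
  for (g in seq_len(XG)) {
    st <- sample_augmented_responses(st)
    st <- sample_person_parameters(st)
    st <- sample_item_parameters(st)
    st <- sample_sigma2(st)
    if (st$guess) st <- sample_guessing(st)
    st <- sample_hyperparameters(st)
    st <- apply_identification(st)
    st <- impute_missing(st)
    # chain storage is inlined: routing it through a helper would force a
    # copy of the (large) draw matrices at every iteration
    dr$a[g, ] <- st$a; dr$b[g, ] <- st$b
    dr$phi[g, ] <- st$phi; dr$lambda[g, ] <- st$lambda
    dr$sigma2[g, ] <- st$sigma2
    dr$theta[g, ] <- st$theta; dr$zeta[g, ] <- st$zeta
    dr$mu_P[g, ] <- st$mu_P; dr$Sigma_P[g, , ] <- st$Sigma_P
    dr$mu_I[g, ] <- st$mu_I; dr$Sigma_I[g, , ] <- st$Sigma_I
    if (!is.null(dr$c)) dr$c[g, ] <- st$cg
    if (!is.null(dr$beta_PA)) dr$beta_PA[g, ] <- st$beta_PA
    if (!is.null(dr$beta_PT)) dr$beta_PT[g, ] <- st$beta_PT
    if (!is.null(dr$beta_IA)) dr$beta_IA[g, ] <- st$beta_IA
    if (!is.null(dr$beta_IT)) dr$beta_IT[g, ] <- st$beta_IT
    if (residual && g > XGresid)
      acc <- fit_accumulate(acc, st, fitcfg)
    if (verbose && g %% step == 0)
      message(sprintf("iteration %d / %d", g, XG))
  }

  out <- list(call = cl, draws = dr, N = N, K = K, XG = XG,
              burnin = burnin, ident = ident, guess = guess, par1 = par1,
              par2 = par2, td = td, WL = WL, residual = residual,
              XGresid = XGresid, prior = prior, fitcfg = fitcfg,
              Y = dat$Y0, RT = dat$RT0, obsY = dat$obsY, obsT = dat$obsT,
              WY = dat$WY, WT = dat$WT, seed = seed, truth = truth,
              fit = if (residual) fit_acc_finalize(acc) else NULL)
  class(out) <- "jirt"
  out
}

# ---- data preparation --------------------------------------------------

prepare_jirt_data <- function(Y, RT, MBDY = NULL, MBDT = NULL) {
  Y <- as.matrix(Y); RT <- as.matrix(RT)
  storage.mode(Y) <- "double"; storage.mode(RT) <- "double"
  if (!identical(dim(Y), dim(RT)))
    stop("'Y' and 'RT' must have identical dimensions")
  bad <- !is.na(Y) & !(Y %in% c(0, 1))
  if (any(bad)) stop("'Y' must contain only 0, 1 or NA")
  N <- nrow(Y); K <- ncol(Y)
  if (K < 2) stop("at least two items are required")
  for (nm in c("MBDY", "MBDT")) {
    m <- get(nm)
    if (!is.null(m) && !identical(dim(as.matrix(m)), dim(Y)))
      stop(sprintf("'%s' must match the data dimensions", nm))
  }
  WY <- if (is.null(MBDY)) matrix(1, N, K) else (as.matrix(MBDY) != 0) * 1
  WT <- if (is.null(MBDT)) matrix(1, N, K) else (as.matrix(MBDT) != 0) * 1
  Y[WY == 0] <- NA; RT[WT == 0] <- NA
  obsY <- !is.na(Y) & WY == 1
  obsT <- !is.na(RT) & WT == 1
  # reject rows/columns with no usable information not covered by design
  no_info_row <- rowSums(obsY) + rowSums(obsT) == 0
  if (any(no_info_row)) {
    covered <- rowSums(WY) + rowSums(WT) == 0
    if (any(no_info_row & !covered))
      stop("person(s) ", paste(which(no_info_row & !covered), collapse = ", "),
           " have no observed responses; use missing-by-design masks ",
           "if this is intended")
  }
  no_info_col <- colSums(obsY) + colSums(obsT) == 0
  if (any(no_info_col))
    stop("item(s) ", paste(which(no_info_col), collapse = ", "),
         " have no observed responses")
  degen <- colSums(Y == 1, na.rm = TRUE) == 0 |
    colSums(Y == 0, na.rm = TRUE) == 0
  if (any(degen))
    warning("item(s) ", paste(which(degen), collapse = ", "),
            " are all-correct or all-incorrect; the prior regularizes them")
  list(Y = Y, RT = RT, Y0 = Y, RT0 = RT, WY = WY, WT = WT,
       obsY = obsY, obsT = obsT, N = N, K = K)
}

# ---- state initialization ---------------------------------------------

init_jirt_state <- function(dat, ident, guess, par1, par2, td, WL,
                            XPA, XPT, XIA, XIT, alpha, beta, phi, lambda,
                            sigma2, SigmaP, muP, prior) {
  N <- dat$N; K <- dat$K
  chk_vec <- function(v, nm) {
    if (!is.null(v) && length(v) != K)
      stop(sprintf("'%s' must have length K = %d", nm, K))
    v
  }
  alpha <- chk_vec(alpha, "alpha"); beta <- chk_vec(beta, "beta")
  phi <- chk_vec(phi, "phi"); lambda <- chk_vec(lambda, "lambda")
  sigma2 <- chk_vec(sigma2, "sigma2")
  for (nm in c("XPA", "XPT")) {
    m <- get(nm)
    if (!is.null(m) && nrow(as.matrix(m)) != N)
      stop(sprintf("'%s' must have N rows", nm))
  }
  for (nm in c("XIA", "XIT")) {
    m <- get(nm)
    if (!is.null(m) && nrow(as.matrix(m)) != K)
      stop(sprintf("'%s' must have K rows", nm))
  }

  pbar <- colMeans(dat$Y, na.rm = TRUE)
  pbar[is.na(pbar)] <- 0.5
  pbar <- pmin(pmax(pbar, 0.05), 0.95)
  rtbar <- colMeans(dat$RT, na.rm = TRUE)
  rtbar[is.na(rtbar)] <- mean(dat$RT, na.rm = TRUE)

  # random starting values (seed-controlled by the caller)
  ry <- rowMeans(dat$Y, na.rm = TRUE); ry[is.na(ry)] <- mean(pbar)
  rt_i <- rowMeans(dat$RT, na.rm = TRUE); rt_i[is.na(rt_i)] <- mean(rtbar)
  theta <- as.vector(scale(ry)) + stats::rnorm(N, 0, 0.3)
  theta[is.na(theta)] <- stats::rnorm(sum(is.na(theta)))
  zeta <- as.vector(scale(-rt_i)) * 0.3 + stats::rnorm(N, 0, 0.1)
  zeta[is.na(zeta)] <- stats::rnorm(sum(is.na(zeta)), 0, 0.3)

  st <- list(
    N = N, K = K, Y = dat$Y, RT = dat$RT, WY = dat$WY, WT = dat$WT,
    obsY = dat$obsY, obsT = dat$obsT,
    marY = is.na(dat$Y) & dat$WY == 1, marT = is.na(dat$RT) & dat$WT == 1,
    ident = ident, guess = guess, par1 = par1, par2 = par2, td = td,
    WL = WL, prior = prior,
    theta = theta, zeta = zeta,
    a = alpha %||% exp(stats::rnorm(K, 0, 0.15)),
    b = beta %||% (stats::qnorm(1 - pbar) + stats::rnorm(K, 0, 0.1)),
    phi = phi %||% (if (td && !WL) exp(stats::rnorm(K, 0, 0.1)) else rep(1, K)),
    lambda = lambda %||% (rtbar + stats::rnorm(K, 0, 0.1)),
    sigma2 = sigma2 %||% pmax(apply(dat$RT, 2, stats::var, na.rm = TRUE),
                              0.05),
    cg = rep(if (guess) prior$guess_shape[1] / sum(prior$guess_shape) else 0,
             K),
    fix_a = !is.null(alpha), fix_b = !is.null(beta),
    fix_phi = !is.null(phi) || !td || WL, fix_lambda = !is.null(lambda),
    fix_sigma2 = !is.null(sigma2), fix_SigmaP = !is.null(SigmaP),
    fix_muP = !is.null(muP) || ident == 2,
    mu_P = muP %||% c(0, 0),
    Sigma_P = SigmaP %||% diag(c(1, 1)),
    mu_I = prior$mu0, Sigma_I = prior$V_I,
    XPA = if (is.null(XPA)) NULL else as.matrix(XPA),
    XPT = if (is.null(XPT)) NULL else as.matrix(XPT),
    XIA = if (is.null(XIA)) NULL else as.matrix(XIA),
    XIT = if (is.null(XIT)) NULL else as.matrix(XIT),
    beta_PA = if (is.null(XPA)) NULL else rep(0, ncol(as.matrix(XPA))),
    beta_PT = if (is.null(XPT)) NULL else rep(0, ncol(as.matrix(XPT))),
    beta_IA = if (is.null(XIA)) NULL else rep(0, ncol(as.matrix(XIA))),
    beta_IT = if (is.null(XIT)) NULL else rep(0, ncol(as.matrix(XIT))),
    S = matrix(1, N, K))
  st$sigma2[is.na(st$sigma2)] <- 0.5
  if (WL) {
    st$phi <- 1 / sqrt(st$sigma2)
    st$fix_phi <- TRUE
  }
  if (!is.null(sigma2) && WL) st$phi <- 1 / sqrt(sigma2)

  # initial imputation of missing-at-random cells
  if (any(st$marY)) {
    Pb <- matrix(pbar, N, K, byrow = TRUE)
    st$Y[st$marY] <- stats::rbinom(sum(st$marY), 1, Pb[st$marY])
  }
  if (any(st$marT)) {
    Mb <- matrix(rtbar, N, K, byrow = TRUE)
    Sb <- matrix(sqrt(st$sigma2), N, K, byrow = TRUE)
    st$RT[st$marT] <- Mb[st$marT] + stats::rnorm(sum(st$marT)) * Sb[st$marT]
  }
  # missing-by-design cells keep placeholder values; the WY/WT masks keep
  # them out of every sufficient statistic
  st$Y[is.na(st$Y)] <- 0
  st$RT[is.na(st$RT)] <- mean(rtbar)
  st
}

# working-scale quantities: the sampler's likelihood algebra is written in
# the non-bracketed forms; the bracketed conventions enter through these.
ra_mean <- function(st) {
  bw <- if (st$par1) st$a * st$b else st$b
  outer(st$theta, st$a) - matrix(bw, st$N, st$K, byrow = TRUE)
}
rt_mean_parts <- function(st) {
  lamw <- if (st$par2) st$phi * st$lambda else st$lambda
  phieff <- if (st$WL) rep(1, st$K) else st$phi
  list(lamw = lamw, phieff = phieff)
}

# ---- Gibbs blocks ------------------------------------------------------

# Latent response propensities (and guessing indicators). Z is truncated
# normal around the propensity mean: positive for non-guessed correct
# responses, negative for incorrect ones. With guessing, the indicator
# that a correct response was generated by the IRT process (rather than
# guessed) has odds (1-c)Phi : c; guessed-correct cells are uninformative
# for the IRT likelihood and drop out of the person and item updates.
sample_augmented_responses <- function(st) {
  E <- ra_mean(st)
  N <- st$N; K <- st$K
  if (st$guess) {
    Pirt <- stats::pnorm(E)
    Cm <- matrix(st$cg, N, K, byrow = TRUE)
    p_s1 <- (1 - Cm) * Pirt / (Cm + (1 - Cm) * Pirt)
    S <- matrix(1, N, K)
    cor1 <- st$WY == 1 & st$Y == 1
    S[cor1] <- stats::rbinom(sum(cor1), 1, clamp_prob(p_s1[cor1]))
    st$S <- S
  } else st$S <- matrix(1, N, K)
  Z <- E
  up <- st$WY == 1 & st$Y == 1 & st$S == 1     # Z > 0
  dn <- st$WY == 1 & st$Y == 0                 # Z < 0
  Z[up] <- E[up] + rtnorm_lower(-E[up])
  Z[dn] <- E[dn] - rtnorm_lower(E[dn])
  off <- !(up | dn)                    # guessed-correct: unconstrained
  if (any(off)) Z[off] <- E[off] + stats::rnorm(sum(off))
  st$Z <- Z
  st$E <- E
  st
}

# Person block: (theta_i, zeta_i) from its bivariate-normal full
# conditional combining the probit likelihood (through Z), the log-RT
# likelihood, and the bivariate normal population prior.
sample_person_parameters <- function(st) {
  N <- st$N; K <- st$K
  WRA <- st$WY * st$S
  rp <- rt_mean_parts(st)
  bw <- if (st$par1) st$a * st$b else st$b
  Bw <- matrix(bw, N, K, byrow = TRUE)
  Itheta <- drop(WRA %*% (st$a^2))
  htheta <- drop((WRA * (st$Z + Bw)) %*% st$a)
  wk <- rp$phieff / st$sigma2
  Izeta <- drop(st$WT %*% (rp$phieff * wk))
  Lw <- matrix(rp$lamw, N, K, byrow = TRUE)
  hzeta <- drop((st$WT * (Lw - st$RT)) %*% wk)

  MuP <- person_prior_means(st)
  Pp <- solve(st$Sigma_P)
  p11 <- Pp[1, 1]; p12 <- Pp[1, 2]; p22 <- Pp[2, 2]
  h1 <- htheta + p11 * MuP[, 1] + p12 * MuP[, 2]
  h2 <- hzeta + p12 * MuP[, 1] + p22 * MuP[, 2]
  q11 <- Itheta + p11; q22 <- Izeta + p22
  det <- q11 * q22 - p12^2
  if (any(det <= 0)) stop("singular precision in the person block")
  V11 <- q22 / det; V22 <- q11 / det; V12 <- -p12 / det
  m1 <- V11 * h1 + V12 * h2
  m2 <- V12 * h1 + V22 * h2
  th <- m1 + sqrt(V11) * stats::rnorm(N)
  cv <- V12 / V11
  ze <- m2 + cv * (th - m1) + sqrt(pmax(V22 - V12^2 / V11, 0)) *
    stats::rnorm(N)
  st$theta <- th; st$zeta <- ze
  st
}

person_prior_means <- function(st) {
  mA <- if (!is.null(st$XPA)) drop(st$XPA %*% st$beta_PA) + st$mu_P[1]
        else rep(st$mu_P[1], st$N)
  mT <- if (!is.null(st$XPT)) drop(st$XPT %*% st$beta_PT) + st$mu_P[2]
        else rep(st$mu_P[2], st$N)
  cbind(mA, mT)
}

item_prior_means <- function(st) {
  M <- matrix(st$mu_I, st$K, 4, byrow = TRUE)
  if (!is.null(st$XIA)) M[, 2] <- M[, 2] + drop(st$XIA %*% st$beta_IA)
  if (!is.null(st$XIT)) M[, 4] <- M[, 4] + drop(st$XIT %*% st$beta_IT)
  M
}

# Item block: a systematic scan of the univariate full conditionals of
# (a_k, b_k, phi_k, lambda_k) under the 4-variate normal population prior
# (its conditional moments are recomputed against the current values of
# the other components), with the discriminations drawn from positive-
# truncated conditionals. A scan of univariate conditionals is used
# rather than a joint draw so that the positivity restrictions and the
# bracketed (nonlinear-in-parameters) conventions are handled exactly.
sample_item_parameters <- function(st) {
  N <- st$N; K <- st$K
  act <- if (st$WL) c(1, 2, 4) else c(1, 2, 3, 4)
  Sa <- st$Sigma_I[act, act, drop = FALSE]
  cond <- lapply(seq_along(act), function(j) {
    oth <- seq_along(act)[-j]
    w <- solve(Sa[oth, oth, drop = FALSE], Sa[oth, j])
    v <- Sa[j, j] - sum(Sa[j, oth] * w)
    list(w = w, v = max(v, 1e-12), oth = act[oth])
  })
  names(cond) <- as.character(act)
  MU <- item_prior_means(st)
  WRA <- st$WY * st$S

  for (k in seq_len(K)) {
    iy <- which(WRA[, k] == 1)
    it <- which(st$WT[, k] == 1)
    zk <- st$Z[iy, k]; thk <- st$theta[iy]
    rtk <- st$RT[it, k]; zek <- st$zeta[it]
    u <- c(st$a[k], st$b[k], st$phi[k], st$lambda[k])
    muk <- MU[k, ]
    cprior <- function(j) {
      cj <- cond[[as.character(j)]]
      m <- muk[j] + sum(cj$w * (u[cj$oth] - muk[cj$oth]))
      c(m, cj$v)
    }
    draw_norm <- function(likprec, likh, pr, positive = FALSE) {
      prec <- likprec + 1 / pr[2]
      m <- (likh + pr[1] / pr[2]) / prec
      s <- 1 / sqrt(prec)
      if (positive) m + s * rtnorm_lower(-m / s)
      else stats::rnorm(1, m, s)
    }
    if (!st$fix_a) {
      x <- if (st$par1) thk - u[2] else thk
      ystar <- if (st$par1) zk else zk + u[2]
      u[1] <- draw_norm(sum(x^2), sum(x * ystar), cprior(1), positive = TRUE)
    }
    if (!st$fix_b) {
      if (st$par1) {
        r <- u[1] * thk - zk     # = a * btilde - e
        u[2] <- draw_norm(length(iy) * u[1]^2, u[1] * sum(r), cprior(2))
      } else {
        u[2] <- draw_norm(length(iy), sum(u[1] * thk - zk), cprior(2))
      }
    }
    s2 <- st$sigma2[k]
    if (!st$fix_phi) {
      x <- if (st$par2) u[4] - zek else zek
      ystar <- if (st$par2) rtk else u[4] - rtk
      u[3] <- draw_norm(sum(x^2) / s2, sum(x * ystar) / s2, cprior(3),
                        positive = TRUE)
    }
    if (!st$fix_lambda) {
      if (st$WL) {
        u[4] <- draw_norm(length(it) / s2, sum(rtk + zek) / s2, cprior(4))
      } else if (st$par2) {
        u[4] <- draw_norm(length(it) * u[3]^2 / s2,
                          u[3] * sum(rtk + u[3] * zek) / s2, cprior(4))
      } else {
        u[4] <- draw_norm(length(it) / s2, sum(rtk + u[3] * zek) / s2,
                          cprior(4))
      }
    }
    st$a[k] <- u[1]; st$b[k] <- u[2]; st$phi[k] <- u[3]; st$lambda[k] <- u[4]
  }
  st
}

# Residual log-time variances from their conjugate inverse-gamma
# conditionals; under WL the implied time discrimination is 1/sigma_k.
sample_sigma2 <- function(st) {
  if (st$fix_sigma2) return(st)
  rp <- rt_mean_parts(st)
  M <- matrix(rp$lamw, st$N, st$K, byrow = TRUE) -
    outer(st$zeta, rp$phieff)
  R2 <- st$WT * (st$RT - M)^2
  ssr <- colSums(R2)
  n <- colSums(st$WT)
  st$sigma2 <- 1 / stats::rgamma(st$K,
                                 shape = st$prior$sigma2_shape + n / 2,
                                 rate = st$prior$sigma2_rate + ssr / 2)
  if (st$WL) st$phi <- 1 / sqrt(st$sigma2)
  st
}

# Guessing probabilities from their Beta-Bernoulli conditionals.
sample_guessing <- function(st) {
  g <- st$prior$guess_shape
  guessed <- colSums(st$WY * (st$Y == 1) * (st$S == 0))
  not_g <- colSums(st$WY * st$S)
  st$cg <- stats::rbeta(st$K, g[1] + guessed, g[2] + not_g)
  st
}

# Hyperparameters: person covariance (inverse-Wishart), person means or
# regression coefficients, item mean/covariance (normal-inverse-Wishart)
# and item regression coefficients.
sample_hyperparameters <- function(st) {
  pr <- st$prior
  P <- cbind(st$theta, st$zeta)

  if (!is.null(st$XPA) || !is.null(st$XPT))
    st <- sample_person_betas(st, P)
  MuP <- person_prior_means(st)
  if (!st$fix_muP && is.null(st$XPA) && is.null(st$XPT)) {
    # ident = 1: flat prior for the person means given Sigma_P
    st$mu_P <- drop(colMeans(P)) +
      drop(rmvnorm_chol(1, c(0, 0), st$Sigma_P / st$N))
    MuP <- person_prior_means(st)
  }
  if (!st$fix_SigmaP) {
    Rp <- P - MuP
    st$Sigma_P <- rinvwishart(pr$nu_P + st$N, pr$V_P + crossprod(Rp))
  }

  U <- cbind(st$a, st$b, st$phi, st$lambda)
  pred <- matrix(0, st$K, 4)
  if (!is.null(st$XIA)) pred[, 2] <- drop(st$XIA %*% st$beta_IA)
  if (!is.null(st$XIT)) pred[, 4] <- drop(st$XIT %*% st$beta_IT)
  hy <- sample_item_hyper(U - pred, pr)
  st$Sigma_I <- hy$Sigma_I
  st$mu_I <- hy$mu_I
  if (!is.null(st$XIA) || !is.null(st$XIT))
    st <- sample_item_betas(st, U)
  st
}

# normal-inverse-Wishart conjugate update for the item population
sample_item_hyper <- function(U0, pr) {
  K <- nrow(U0); kap <- pr$kappa
  xbar <- colMeans(U0)
  Sc <- crossprod(sweep(U0, 2, xbar))
  d0 <- xbar - pr$mu0
  Vn <- pr$V_I + Sc + (kap * K / (kap + K)) * tcrossprod(d0)
  Sigma_I <- rinvwishart(pr$nu_I + K, Vn)
  mun <- (kap * pr$mu0 + K * xbar) / (kap + K)
  list(Sigma_I = Sigma_I,
       mu_I = drop(rmvnorm_chol(1, mun, Sigma_I / (kap + K))))
}

sample_person_betas <- function(st, P) {
  Km <- solve(st$Sigma_P)
  XA <- st$XPA; XT <- st$XPT
  pA <- if (is.null(XA)) 0 else ncol(XA)
  pT <- if (is.null(XT)) 0 else ncol(XT)
  p <- pA + pT
  Prec <- diag(1 / st$prior$beta_var, p)
  h <- numeric(p)
  th <- P[, 1] - st$mu_P[1]; ze <- P[, 2] - st$mu_P[2]
  if (pA > 0) {
    Prec[1:pA, 1:pA] <- Prec[1:pA, 1:pA] + Km[1, 1] * crossprod(XA)
    h[1:pA] <- Km[1, 1] * crossprod(XA, th) + Km[1, 2] * crossprod(XA, ze)
  }
  if (pT > 0) {
    jj <- (pA + 1):p
    Prec[jj, jj] <- Prec[jj, jj] + Km[2, 2] * crossprod(XT)
    h[jj] <- Km[2, 2] * crossprod(XT, ze) + Km[1, 2] * crossprod(XT, th)
  }
  if (pA > 0 && pT > 0) {
    C <- Km[1, 2] * crossprod(XA, XT)
    Prec[1:pA, (pA + 1):p] <- Prec[1:pA, (pA + 1):p] + C
    Prec[(pA + 1):p, 1:pA] <- Prec[(pA + 1):p, 1:pA] + t(C)
  }
  bdraw <- rmvnorm_prec(h, Prec)
  if (pA > 0) st$beta_PA <- bdraw[1:pA]
  if (pT > 0) st$beta_PT <- bdraw[(pA + 1):p]
  st
}

sample_item_betas <- function(st, U) {
  Km <- solve(st$Sigma_I)
  pb <- if (is.null(st$XIA)) 0 else ncol(st$XIA)
  pl <- if (is.null(st$XIT)) 0 else ncol(st$XIT)
  p <- pb + pl
  Prec <- diag(1 / st$prior$beta_var, p)
  h <- numeric(p)
  R <- sweep(U, 2, st$mu_I)          # K x 4 residuals about the grand means
  for (k in seq_len(st$K)) {
    D <- matrix(0, 4, p)
    if (pb > 0) D[2, 1:pb] <- st$XIA[k, ]
    if (pl > 0) D[4, (pb + 1):p] <- st$XIT[k, ]
    Prec <- Prec + t(D) %*% Km %*% D
    h <- h + drop(t(D) %*% Km %*% R[k, ])
  }
  bdraw <- rmvnorm_prec(h, Prec)
  if (pb > 0) st$beta_IA <- bdraw[1:pb]
  if (pl > 0) st$beta_IT <- bdraw[(pb + 1):p]
  st
}

# Identification transformation; leaves the likelihood invariant and is
# applied every iteration so the constraints hold on every stored draw.
apply_identification <- function(st) {
  if (any(st$a <= 0) || any(st$phi <= 0))
    stop("invalid state: non-positive discrimination")
  tI <- rep(1, 4); tP <- rep(1, 2)
  if (!st$fix_a) {
    A <- exp(mean(log(st$a)))
    st$a <- st$a / A
    st$theta <- st$theta * A
    tP[1] <- A; tI[1] <- 1 / A
    if (st$par1) { st$b <- st$b * A; tI[2] <- A }
    if (!is.null(st$beta_PA)) st$beta_PA <- st$beta_PA * A
  }
  if (!st$fix_phi && st$td && !st$WL) {
    G <- exp(mean(log(st$phi)))
    st$phi <- st$phi / G
    st$zeta <- st$zeta * G
    tP[2] <- G; tI[3] <- 1 / G
    if (st$par2) { st$lambda <- st$lambda * G; tI[4] <- G }
    if (!is.null(st$beta_PT)) st$beta_PT <- st$beta_PT * G
  }
  st$mu_P <- st$mu_P * tP
  st$Sigma_P <- st$Sigma_P * tcrossprod(tP)
  st$mu_I <- st$mu_I * tI
  st$Sigma_I <- st$Sigma_I * tcrossprod(tI)

  if (st$ident == 1) {
    if (!st$fix_b) {
      if (st$par1) {
        d <- -mean(st$b)
        st$b <- st$b + d
        st$mu_I[2] <- st$mu_I[2] + d
      } else {
        d <- -sum(st$b) / sum(st$a)
        st$b <- st$b + st$a * d
        st$mu_I[2] <- st$mu_I[2] + mean(st$a) * d
      }
      st$theta <- st$theta + d
      st$mu_P[1] <- st$mu_P[1] + d
    }
    if (!st$fix_lambda) {
      if (st$par2) {
        e <- -mean(st$lambda)
        st$lambda <- st$lambda + e
        st$mu_I[4] <- st$mu_I[4] + e
      } else if (st$WL) {
        e <- -mean(st$lambda)
        st$lambda <- st$lambda + e
        st$mu_I[4] <- st$mu_I[4] + e
      } else {
        e <- -sum(st$lambda) / sum(st$phi)
        st$lambda <- st$lambda + st$phi * e
        st$mu_I[4] <- st$mu_I[4] + mean(st$phi) * e
      }
      st$zeta <- st$zeta + e
      st$mu_P[2] <- st$mu_P[2] + e
    }
  }
  st
}

# Missing-at-random cells are refreshed from their posterior predictive
# distributions; missing-by-design cells are never touched (they are
# excluded from every likelihood term through the WY/WT masks).
impute_missing <- function(st) {
  if (any(st$marY)) {
    E <- ra_mean(st)
    Cm <- matrix(st$cg, st$N, st$K, byrow = TRUE)
    Pm <- Cm + (1 - Cm) * stats::pnorm(E)
    st$Y[st$marY] <- stats::rbinom(sum(st$marY), 1, Pm[st$marY])
  }
  if (any(st$marT)) {
    rp <- rt_mean_parts(st)
    M <- matrix(rp$lamw, st$N, st$K, byrow = TRUE) -
      outer(st$zeta, rp$phieff)
    Sd <- matrix(sqrt(st$sigma2), st$N, st$K, byrow = TRUE)
    st$RT[st$marT] <- M[st$marT] + stats::rnorm(sum(st$marT)) * Sd[st$marT]
  }
  st
}

# ---- chain storage -----------------------------------------------------

alloc_jirt_draws <- function(XG, N, K, st) {
  dr <- list(a = matrix(NA_real_, XG, K), b = matrix(NA_real_, XG, K),
             phi = matrix(NA_real_, XG, K),
             lambda = matrix(NA_real_, XG, K),
             sigma2 = matrix(NA_real_, XG, K),
             theta = matrix(NA_real_, XG, N),
             zeta = matrix(NA_real_, XG, N),
             mu_P = matrix(NA_real_, XG, 2),
             Sigma_P = array(NA_real_, c(XG, 2, 2)),
             mu_I = matrix(NA_real_, XG, 4),
             Sigma_I = array(NA_real_, c(XG, 4, 4)))
  if (st$guess) dr$c <- matrix(NA_real_, XG, K)
  for (nm in c("beta_PA", "beta_PT", "beta_IA", "beta_IT"))
    if (!is.null(st[[nm]]))
      dr[[nm]] <- matrix(NA_real_, XG, length(st[[nm]]))
  dr
}

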