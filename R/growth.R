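# Differential working-speed extension: working speed follows a
# person-specific quadratic trajectory over the solve order of the items.

#' Equidistant time scale from item solve orders
#'
#' Maps the order in which a person solves the items to the equidistant
#' time scale `X_ik = (position - 1) / K`, so the first item solved is at
#' time 0 and the last at `(K - 1) / K`.
#'
#' @param order `N x K` matrix (or length-`K` vector applied to all
#'   persons) giving each item's solve position; every row must be a
#'   permutation of `1:K`.
#' @param K number of items.
#' @return matrix (or vector) of time points in `[0, (K-1)/K]`.
#' @examples
#' build_time_scale(1:4, 4)       # 0.00 0.25 0.50 0.75
#' @export
build_time_scale <- function(order, K) {
  if (is.vector(order)) {
    if (!identical(sort(as.integer(order)), seq_len(K)))
      stop("'order' must be a permutation of 1:K")
    return((order - 1) / K)
  }
  order <- as.matrix(order)
  if (ncol(order) != K) stop("'order' must have K columns")
  ok <- apply(order, 1, function(r) identical(sort(as.integer(r)),
                                              seq_len(K)))
  if (!all(ok))
    stop("row(s) ", paste(which(!ok), collapse = ", "),
         " of 'order' are not permutations of 1:K")
  (order - 1) / K
}

#' Working speed at a time point of the quadratic trajectory
#'
#' `zeta0 + zeta1 * x + zeta2 * x^2`: the random intercept is the initial
#' speed, the linear trend models a steady increase or decrease, and the
#' quadratic component accelerates or decelerates the trend.
#'
#' @param zeta0,zeta1,zeta2 growth components (vectorized).
#' @param x time point(s) in `[0, 1)`.
#' @return working speed value(s).
#' @export
speed_at <- function(zeta0, zeta1 = 0, zeta2 = 0, x = 0) {
  zeta0 + zeta1 * x + zeta2 * x^2
}

#' Fit the joint model with differential working speed
#'
#' Extends [jirt()] by replacing the constant working speed with a latent
#' growth trajectory: the speed of person `i` at item `k` is
#' `zeta0_i + zeta1_i * X_ik + zeta2_i * X_ik^2` over the equidistant
#' time scale `X`, so the log response-time mean is
#' `lambda_k - phi_k * (zeta0_i + zeta1_i X_ik + zeta2_i X_ik^2)`.
#' Ability and the speed components are jointly multivariate normal with
#' speed means fixed at zero; by default the covariance among the speed
#' components is restricted to zero (their dependence is carried by the
#' time discriminations) while the ability-speed covariances are free,
#' which is implemented through the conjugate factorization
#' `p(speed) p(ability | speed)`. With `full_cov = TRUE` (allowed only
#' when all time discriminations are fixed at one, `td = FALSE`) the full
#' covariance matrix gets an inverse-Wishart prior.
#'
#' Identification: product of discriminations and of time discriminations
#' one, difficulties summing to zero (with the compensating ability
#' shift), speed-component means zero; the mean ability is free. Persons
#' whose record is entirely missing are allowed when covered by
#' missing-by-design masks; they receive prior-driven draws and their
#' posterior means shrink to the population averages.
#'
#' @inheritParams jirt
#' @param X time scale: either a length-`K` vector (same solve order for
#'   everyone, e.g. `(1:K - 1)/K`) or an `N x K` matrix from
#'   [build_time_scale()]; default administration order.
#' @param order optional solve-order matrix passed to
#'   [build_time_scale()] instead of `X`.
#' @param trend,quadratic include the linear / quadratic speed
#'   components? With both `FALSE` the model reduces to the
#'   constant-speed joint model.
#' @param full_cov estimate the full covariance of the speed components?
#' @return an object of class `jirtq`.
#' @export
jirtq <- function(Y, RT, X = NULL, order = NULL, XG = 1000, burnin = 10,
                  td = TRUE, trend = TRUE, quadratic = TRUE,
                  full_cov = FALSE, MBDY = NULL, MBDT = NULL,
                  alpha = NULL, beta = NULL, phi = NULL, lambda = NULL,
                  prior = jirt_prior(), seed = NULL, verbose = FALSE,
                  truth = NULL) {
  cl <- match.call()
  if (XG <= 0) stop("'XG' must be a positive integer")
  if (full_cov && td && is.null(phi))
    stop("'full_cov = TRUE' requires time discriminations fixed to one ",
         "(td = FALSE)")
  if (!is.null(seed)) set.seed(seed)
  dat <- prepare_jirt_data_q(Y, RT, MBDY, MBDT)
  N <- dat$N; K <- dat$K
  if (!is.null(order)) X <- build_time_scale(order, K)
  if (is.null(X)) X <- (seq_len(K) - 1) / K
  if (is.vector(X)) {
    if (length(X) != K) stop("'X' must have length K")
    X <- matrix(X, N, K, byrow = TRUE)
  }
  if (!identical(dim(X), c(N, K))) stop("'X' must be N x K")
  if (any(X < 0 | X >= 1)) stop("time scale values must lie in [0, 1)")

  qdim <- 1L + trend + quadratic       # number of speed components
  st <- init_jirtq_state(dat, X, qdim, td = td, full_cov = full_cov,
                         alpha = alpha, beta = beta, phi = phi,
                         lambda = lambda, prior = prior)

  dr <- list(a = matrix(NA_real_, XG, K), b = matrix(NA_real_, XG, K),
             phi = matrix(NA_real_, XG, K),
             lambda = matrix(NA_real_, XG, K),
             sigma2 = matrix(NA_real_, XG, K),
             theta = matrix(NA_real_, XG, N),
             zeta = array(NA_real_, c(XG, N, qdim)),
             mu_theta = numeric(XG),
             Sigma = array(NA_real_, c(XG, 1 + qdim, 1 + qdim)))

  step <- max(1L, floor(XG / 10))
  for (g in seq_len(XG)) {
    st <- q_augment(st)
    st <- q_sample_persons(st)
    st <- q_sample_items(st)
    st <- q_sample_sigma2(st)
    st <- q_sample_hyper(st)
    st <- q_identify(st)
    st <- q_impute(st)
    dr$a[g, ] <- st$a; dr$b[g, ] <- st$b; dr$phi[g, ] <- st$phi
    dr$lambda[g, ] <- st$lambda; dr$sigma2[g, ] <- st$sigma2
    dr$theta[g, ] <- st$theta; dr$zeta[g, , ] <- st$zeta
    dr$mu_theta[g] <- st$mu_theta; dr$Sigma[g, , ] <- st$SigmaQ
    if (verbose && g %% step == 0)
      message(sprintf("iteration %d / %d", g, XG))
  }
  out <- list(call = cl, draws = dr, N = N, K = K, XG = XG,
              burnin = burnin, qdim = qdim, trend = trend,
              quadratic = quadratic, td = td, full_cov = full_cov,
              X = X, Y = dat$Y0, RT = dat$RT0,
              obsY = dat$obsY, obsT = dat$obsT, prior = prior,
              seed = seed, truth = truth)
  class(out) <- "jirtq"
  out
}

# like prepare_jirt_data() but all-missing records are allowed: they
# receive prior-driven draws (population-average posterior means).
prepare_jirt_data_q <- function(Y, RT, MBDY, MBDT) {
  Y <- as.matrix(Y); RT <- as.matrix(RT)
  storage.mode(Y) <- "double"; storage.mode(RT) <- "double"
  if (!identical(dim(Y), dim(RT)))
    stop("'Y' and 'RT' must have identical dimensions")
  if (any(!is.na(Y) & !(Y %in% c(0, 1))))
    stop("'Y' must contain only 0, 1 or NA")
  N <- nrow(Y); K <- ncol(Y)
  WY <- if (is.null(MBDY)) matrix(1, N, K) else (as.matrix(MBDY) != 0) * 1
  WT <- if (is.null(MBDT)) matrix(1, N, K) else (as.matrix(MBDT) != 0) * 1
  Y[WY == 0] <- NA; RT[WT == 0] <- NA
  no_info_col <- colSums(!is.na(Y)) + colSums(!is.na(RT)) == 0
  if (any(no_info_col))
    stop("item(s) ", paste(which(no_info_col), collapse = ", "),
         " have no observed responses")
  list(Y = Y, RT = RT, Y0 = Y, RT0 = RT, WY = WY, WT = WT,
       obsY = !is.na(Y) & WY == 1, obsT = !is.na(RT) & WT == 1,
       N = N, K = K)
}

init_jirtq_state <- function(dat, X, qdim, td, full_cov, alpha, beta,
                             phi, lambda, prior) {
  N <- dat$N; K <- dat$K
  pbar <- pmin(pmax(colMeans(dat$Y, na.rm = TRUE), 0.05), 0.95)
  pbar[is.na(pbar)] <- 0.5
  rtbar <- colMeans(dat$RT, na.rm = TRUE)
  rtbar[is.na(rtbar)] <- mean(dat$RT, na.rm = TRUE)
  st <- list(
    N = N, K = K, Y = dat$Y, RT = dat$RT, WY = dat$WY, WT = dat$WT,
    obsY = dat$obsY, obsT = dat$obsT,
    marY = is.na(dat$Y) & dat$WY == 1, marT = is.na(dat$RT) & dat$WT == 1,
    X = X, qdim = qdim, td = td, full_cov = full_cov, prior = prior,
    theta = stats::rnorm(N, 0, 0.5),
    zeta = matrix(stats::rnorm(N * qdim, 0, 0.2), N, qdim),
    a = alpha %||% exp(stats::rnorm(K, 0, 0.15)),
    b = beta %||% (stats::qnorm(1 - pbar) + stats::rnorm(K, 0, 0.1)),
    phi = phi %||% (if (td) exp(stats::rnorm(K, 0, 0.1)) else rep(1, K)),
    lambda = lambda %||% (rtbar + stats::rnorm(K, 0, 0.1)),
    sigma2 = pmax(apply(dat$RT, 2, stats::var, na.rm = TRUE), 0.05),
    fix_a = !is.null(alpha), fix_b = !is.null(beta),
    fix_phi = !is.null(phi) || !td, fix_lambda = !is.null(lambda),
    mu_theta = 0,
    gammaQ = rep(0, qdim),              # regression of ability on speed
    sig2_e = 0.5,                       # conditional ability variance
    sig2_z = rep(0.1, qdim),            # speed component variances
    SigmaQ = diag(c(1, rep(0.1, qdim))),
    mu_I = prior$mu0, Sigma_I = prior$V_I)
  st$sigma2[is.na(st$sigma2)] <- 0.5
  if (any(st$marY)) {
    Pb <- matrix(pbar, N, K, byrow = TRUE)
    st$Y[st$marY] <- stats::rbinom(sum(st$marY), 1, Pb[st$marY])
  }
  if (any(st$marT)) {
    Mb <- matrix(rtbar, N, K, byrow = TRUE)
    st$RT[st$marT] <- Mb[st$marT] +
      stats::rnorm(sum(st$marT)) * sqrt(0.3)
  }
  st$Y[is.na(st$Y)] <- 0
  st$RT[is.na(st$RT)] <- mean(rtbar)
  st
}

q_speed_matrix <- function(st) {
  S <- matrix(st$zeta[, 1], st$N, st$K)
  if (st$qdim >= 2) S <- S + st$zeta[, 2] * st$X
  if (st$qdim >= 3) S <- S + st$zeta[, 3] * st$X^2
  S
}

q_augment <- function(st) {
  E <- outer(st$theta, st$a) - matrix(st$b, st$N, st$K, byrow = TRUE)
  Z <- E
  up <- st$WY == 1 & st$Y == 1
  dn <- st$WY == 1 & st$Y == 0
  Z[up] <- E[up] + rtnorm_lower(-E[up])
  Z[dn] <- E[dn] - rtnorm_lower(E[dn])
  st$Z <- Z
  st
}

# Person block: (theta, zeta0[, zeta1[, zeta2]]) from the joint normal
# full conditional. The precision entries are polynomial moments of the
# time scale, so they vectorize over persons; the small per-person solves
# are done in a loop.
q_sample_persons <- function(st) {
  N <- st$N; K <- st$K; q <- st$qdim
  wk <- st$phi^2 / st$sigma2
  Mom <- lapply(0:(2 * (q - 1)), function(r)
    drop((st$WT * st$X^r) %*% wk))
  Lw <- matrix(st$lambda, N, K, byrow = TRUE)
  Dm <- st$WT * (Lw - st$RT)
  hv <- lapply(0:(q - 1), function(r)
    drop((Dm * st$X^r) %*% (st$phi / st$sigma2)))
  Itheta <- drop((st$WY) %*% st$a^2)
  Bw <- matrix(st$b, N, K, byrow = TRUE)
  htheta <- drop((st$WY * (st$Z + Bw)) %*% st$a)

  Sinv <- solve(st$SigmaQ)
  m0 <- c(st$mu_theta, rep(0, q))
  pm0 <- drop(Sinv %*% m0)
  out <- matrix(0, N, 1 + q)
  for (i in seq_len(N)) {
    P <- Sinv
    P[1, 1] <- P[1, 1] + Itheta[i]
    for (r in seq_len(q)) for (s in seq_len(q))
      P[1 + r, 1 + s] <- P[1 + r, 1 + s] + Mom[[r + s - 1]][i]
    h <- pm0
    h[1] <- h[1] + htheta[i]
    for (r in seq_len(q)) h[1 + r] <- h[1 + r] + hv[[r]][i]
    out[i, ] <- rmvnorm_prec(h, P)
  }
  st$theta <- out[, 1]
  st$zeta <- out[, -1, drop = FALSE]
  st
}

# Item block under the same 4-variate normal population prior as the
# constant-speed sampler (systematic scan of univariate conditionals,
# positivity-truncated for the discriminations); the speed entering the
# response-time design is the trajectory value at each cell.
q_sample_items <- function(st) {
  K <- st$K
  Sm <- q_speed_matrix(st)
  cond <- lapply(1:4, function(j) {
    oth <- (1:4)[-j]
    w <- solve(st$Sigma_I[oth, oth], st$Sigma_I[oth, j])
    v <- st$Sigma_I[j, j] - sum(st$Sigma_I[j, oth] * w)
    list(w = w, v = max(v, 1e-12), oth = oth)
  })
  mu <- st$mu_I
  for (k in seq_len(K)) {
    iy <- which(st$WY[, k] == 1)
    it <- which(st$WT[, k] == 1)
    zk <- st$Z[iy, k]; thk <- st$theta[iy]
    rtk <- st$RT[it, k]; sk <- Sm[it, k]
    s2 <- st$sigma2[k]
    u <- c(st$a[k], st$b[k], st$phi[k], st$lambda[k])
    cprior <- function(j) {
      cj <- cond[[j]]
      c(mu[j] + sum(cj$w * (u[cj$oth] - mu[cj$oth])), cj$v)
    }
    draw_norm <- function(likprec, likh, pr, positive = FALSE) {
      prec <- likprec + 1 / pr[2]
      m <- (likh + pr[1] / pr[2]) / prec
      s <- 1 / sqrt(prec)
      if (positive) m + s * rtnorm_lower(-m / s) else stats::rnorm(1, m, s)
    }
    if (!st$fix_a)
      u[1] <- draw_norm(sum(thk^2), sum(thk * (zk + u[2])), cprior(1),
                        positive = TRUE)
    if (!st$fix_b)
      u[2] <- draw_norm(length(iy), sum(u[1] * thk - zk), cprior(2))
    if (!st$fix_phi)
      u[3] <- draw_norm(sum(sk^2) / s2, sum(sk * (u[4] - rtk)) / s2,
                        cprior(3), positive = TRUE)
    if (!st$fix_lambda)
      u[4] <- draw_norm(length(it) / s2, sum(rtk + u[3] * sk) / s2,
                        cprior(4))
    st$a[k] <- u[1]; st$b[k] <- u[2]; st$phi[k] <- u[3]; st$lambda[k] <- u[4]
  }
  st
}

q_sample_sigma2 <- function(st) {
  Sm <- q_speed_matrix(st)
  M <- matrix(st$lambda, st$N, st$K, byrow = TRUE) -
    Sm * matrix(st$phi, st$N, st$K, byrow = TRUE)
  ssr <- colSums(st$WT * (st$RT - M)^2)
  n <- colSums(st$WT)
  st$sigma2 <- 1 / stats::rgamma(st$K,
                                 shape = st$prior$sigma2_shape + n / 2,
                                 rate = st$prior$sigma2_rate + ssr / 2)
  st
}

q_sample_hyper <- function(st) {
  N <- st$N; q <- st$qdim
  pr <- st$prior
  hy <- sample_item_hyper(cbind(st$a, st$b, st$phi, st$lambda), pr)
  st$Sigma_I <- hy$Sigma_I
  st$mu_I <- hy$mu_I
  if (st$full_cov) {
    P <- cbind(st$theta, st$zeta)
    # conditional mean ability given speed, for the mu_theta update
    Sc <- st$SigmaQ
    w <- solve(Sc[-1, -1, drop = FALSE], Sc[-1, 1])
    adj <- st$theta - drop(st$zeta %*% w)
    cv <- Sc[1, 1] - sum(Sc[1, -1] * w)
    st$mu_theta <- stats::rnorm(1, mean(adj), sqrt(cv / N))
    R <- P - matrix(c(st$mu_theta, rep(0, q)), N, 1 + q, byrow = TRUE)
    st$SigmaQ <- rinvwishart(q + 3 + N, diag(1 + q) + crossprod(R))
    return(st)
  }
  # factorized structure: independent speed components, ability regressed
  # on the speed components (free ability-speed covariances, zero
  # covariances among the speed components)
  st$sig2_z <- 1 / stats::rgamma(q, shape = 1 + N / 2,
                                 rate = 0.1 + colSums(st$zeta^2) / 2)
  Xr <- cbind(1, st$zeta)
  Prec <- diag(1 / pr$beta_var, 1 + q) + crossprod(Xr) / st$sig2_e
  h <- crossprod(Xr, st$theta) / st$sig2_e
  bdraw <- rmvnorm_prec(drop(h), Prec)
  st$mu_theta <- bdraw[1]
  st$gammaQ <- bdraw[-1]
  res <- st$theta - drop(Xr %*% bdraw)
  st$sig2_e <- 1 / stats::rgamma(1, shape = 1 + N / 2,
                                 rate = 0.1 + sum(res^2) / 2)
  Sz <- diag(st$sig2_z, q)
  ctz <- st$gammaQ * st$sig2_z
  Sq <- matrix(0, 1 + q, 1 + q)
  Sq[1, 1] <- st$sig2_e + sum(st$gammaQ * ctz)
  Sq[1, -1] <- Sq[-1, 1] <- ctz
  Sq[-1, -1] <- Sz
  st$SigmaQ <- Sq
  st
}

q_identify <- function(st) {
  q <- st$qdim
  tI <- rep(1, 4)
  if (!st$fix_a) {
    A <- exp(mean(log(st$a)))
    st$a <- st$a / A
    st$theta <- st$theta * A
    st$mu_theta <- st$mu_theta * A
    st$sig2_e <- st$sig2_e * A^2
    st$gammaQ <- st$gammaQ * A
    st$SigmaQ[1, ] <- st$SigmaQ[1, ] * A
    st$SigmaQ[, 1] <- st$SigmaQ[, 1] * A
    tI[1] <- 1 / A
  }
  if (!st$fix_b) {
    d <- -sum(st$b) / sum(st$a)
    st$b <- st$b + st$a * d
    st$theta <- st$theta + d
    st$mu_theta <- st$mu_theta + d
    st$mu_I[2] <- st$mu_I[2] + mean(st$a) * d
  }
  if (!st$fix_phi) {
    G <- exp(mean(log(st$phi)))
    st$phi <- st$phi / G
    st$zeta <- st$zeta * G
    st$sig2_z <- st$sig2_z * G^2
    st$gammaQ <- st$gammaQ / G
    D <- diag(c(1, rep(G, q)))
    st$SigmaQ <- D %*% st$SigmaQ %*% D
    tI[3] <- 1 / G
  }
  st$mu_I <- st$mu_I * tI
  st$Sigma_I <- st$Sigma_I * tcrossprod(tI)
  st
}

q_impute <- function(st) {
  if (any(st$marY)) {
    E <- outer(st$theta, st$a) - matrix(st$b, st$N, st$K, byrow = TRUE)
    st$Y[st$marY] <- stats::rbinom(sum(st$marY), 1,
                                   stats::pnorm(E)[st$marY])
  }
  if (any(st$marT)) {
    Sm <- q_speed_matrix(st)
    M <- matrix(st$lambda, st$N, st$K, byrow = TRUE) -
      Sm * matrix(st$phi, st$N, st$K, byrow = TRUE)
    Sd <- matrix(sqrt(st$sigma2), st$N, st$K, byrow = TRUE)
    st$RT[st$marT] <- M[st$marT] + stats::rnorm(sum(st$marT)) * Sd[st$marT]
  }
  st
}
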