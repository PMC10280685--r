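test_that("accuracy person-fit statistic matches hand evaluation", {
  # perfect fit: probability-one responses contribute zero
  out <- person_fit_ra(c(1, 1, 1), rep(1 - 1e-13, 3))
  expect_equal(out$statistic, 0, tolerance = 1e-10)
  # two fifty-fifty items, one right one wrong: 2 * ln 2
  out2 <- person_fit_ra(c(1, 0), c(0.5, 0.5))
  expect_equal(out2$statistic, 2 * log(2), tolerance = 1e-12)
  expect_equal(out2$statistic, 1.38629, tolerance = 1e-5)
  # standardization: mean and SD of the conditional distribution
  p <- c(0.3, 0.6, 0.8)
  y <- c(1, 0, 1)
  out3 <- person_fit_ra(y, p)
  m <- sum(-p * log(p) - (1 - p) * log(1 - p))
  v <- sum(p * (1 - p) * log(p / (1 - p))^2)
  expect_equal(out3$standardized, (out3$statistic - m) / sqrt(v))
  # missing responses are dropped; nothing usable warns
  expect_equal(person_fit_ra(c(1, NA), c(0.5, 0.9))$statistic, log(2))
  expect_warning(person_fit_ra(c(NA, NA), c(0.5, 0.5)), "usable")
})

test_that("accuracy person-fit standardization is approximately normal", {
  # null simulation: standardized values behave like standard normals
  set.seed(61)
  K <- 60
  p <- runif(K, 0.2, 0.9)
  ls <- replicate(2000, person_fit_ra(rbinom(K, 1, p), p)$standardized)
  expect_equal(mean(ls), 0, tolerance = 0.08)
  expect_equal(sd(ls), 1, tolerance = 0.08)
  expect_equal(mean(ls > qnorm(0.95)), 0.05,
               tolerance = 3 * sqrt(0.05 * 0.95 / 2000) / 0.05)
})

test_that("response-time person-fit statistic matches the per-cell oracle", {
  set.seed(62)
  K <- 12
  lambda <- rnorm(K, 4, 0.3); phi <- runif(K, 0.7, 1.3)
  sigma2 <- runif(K, 0.1, 0.4); zeta <- 0.4
  rt <- lambda - phi * zeta + rnorm(K, 0, sqrt(sigma2))
  rt[c(3, 7)] <- NA
  out <- person_fit_rt(rt, zeta, lambda, phi, sigma2)
  # brute-force loop oracle, exact equality
  acc <- 0; df <- 0
  for (k in 1:K) if (!is.na(rt[k])) {
    acc <- acc + (rt[k] - (lambda[k] - phi[k] * zeta))^2 / sigma2[k]
    df <- df + 1
  }
  expect_identical(out$statistic, acc)
  expect_equal(out$df, df)
  # zero residuals: statistic 0, tail probability 1
  out0 <- person_fit_rt(lambda - phi * zeta, zeta, lambda, phi, sigma2)
  expect_equal(out0$statistic, 0)
  expect_equal(out0$tail_probability, 1)
  expect_warning(person_fit_rt(rep(NA_real_, 3), 0, 1:3, rep(1, 3),
                               rep(1, 3)), "observed")
})

test_that("response-time person-fit is calibrated against its chi-square", {
  set.seed(63)
  K <- 20
  lambda <- rnorm(K, 4, 0.3); phi <- runif(K, 0.8, 1.2)
  sigma2 <- runif(K, 0.1, 0.4)
  stats <- replicate(3000, {
    rt <- lambda - phi * 0.2 + rnorm(K, 0, sqrt(sigma2))
    person_fit_rt(rt, 0.2, lambda, phi, sigma2)$statistic
  })
  # goodness of fit of the null distribution at the 1% level
  expect_gt(ks.test(stats, pchisq, df = K)$p.value, 0.01)
})

test_that("latent residuals match the truncated-normal oracle", {
  # at a*theta - b = 0 the conditional mean is dnorm(0)/pnorm(0)
  lr <- latent_residual(1, 0, 1, 0)
  expect_equal(lr$expected_residual, dnorm(0) / pnorm(0), tolerance = 1e-12)
  expect_equal(lr$expected_residual, 0.79788, tolerance = 1e-5)
  lr0 <- latent_residual(0, 0, 1, 0)
  expect_equal(lr0$expected_residual, -0.79788, tolerance = 1e-5)
  # probabilities stay in [0, 1] over a wide grid (including large C)
  grid <- expand.grid(t = seq(-4, 4, by = 0.5), C = c(0.5, 2, 3.5),
                      y = 0:1)
  pr <- latent_residual(grid$y, grid$t, 1, 0, C = grid$C)$outlier_probability
  expect_true(all(pr >= 0 & pr <= 1))
  # Monte-Carlo verification of the conditional tail probability
  set.seed(64)
  e <- rnorm(4e5)
  for (tt in c(-1, 0.3, 1.2)) {
    for (C in c(1, 2)) {
      ec <- e[e > tt]                      # correct response: e > b - a*theta
      mc <- mean(abs(ec) > C)
      form <- latent_residual(1, -tt, 1, 0, C = C)$outlier_probability
      expect_equal(form, mc, tolerance = 4 / sqrt(length(ec)) / max(mc, 0.01))
      ei <- e[e < tt]
      mc0 <- mean(abs(ei) > C)
      form0 <- latent_residual(0, -tt, 1, 0, C = C)$outlier_probability
      expect_equal(form0, mc0,
                   tolerance = 4 / sqrt(length(ei)) / max(mc0, 0.01))
    }
  }
})

test_that("response-time residual outlier probability matches normal tails", {
  expect_equal(rt_residual_prob(0, 1, C = 0), 1)
  expect_equal(rt_residual_prob(0, 1, C = 1.96), 2 * pnorm(-1.96),
               tolerance = 1e-12)
  expect_equal(rt_residual_prob(0, 1, C = 1.96), 0.05, tolerance = 1e-3)
  expect_equal(rt_residual_prob(50, 1, C = 2), 1, tolerance = 1e-10)
})

test_that("KS residual check detects misfit and keeps its level", {
  # residuals placed at normal quantiles of a fine grid: D is tiny
  N <- 400
  x <- qnorm((1:N - 0.5) / N)
  out <- ks_resid(x, 1)
  expect_lt(out$D, 1 / (2 * N) + 1e-6)
  # uniform residuals are rejected at this sample size
  set.seed(65)
  bad <- ks_resid(runif(200, -1, 1), 1)
  expect_lt(bad$p_value, 0.05)
  # level under the null across replicates
  rej <- replicate(400, ks_resid(rnorm(80), 1)$p_value <= 0.05)
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  expect_warning(ks_resid(rnorm(5), 1), "fewer")
  expect_warning(out_d <- ks_resid(rep(1, 20), 1), "degenerate")
  expect_true(is.na(out_d$D))
})

test_that("joint flags behave as draw-wise conjunctions", {
  expect_equal(joint_person_flag(rep(0, 50), rep(1, 50)), 0)
  expect_equal(joint_person_flag(rep(1, 50), rep(1, 50)), 1)
  set.seed(66)
  A <- matrix(rbinom(4000, 1, 0.5), 2000, 2)
  B <- matrix(rbinom(4000, 1, 0.5), 2000, 2)
  expect_equal(joint_person_flag(A, B), c(0.25, 0.25), tolerance = 0.15)
})

test_that("aberrant patterns are detected in a fitted model", {
  set.seed(67)
  sim <- jirt_sim(200, 15, seed = 68)
  # contaminate: person 1 answers randomly, person 2 has wild times
  sim$Y[1, ] <- rbinom(15, 1, 0.5)
  sim$RT[2, ] <- sim$RT[2, ] + sample(c(-2, 2), 15, replace = TRUE)
  f <- jirt(sim$Y, sim$RT, XG = 600, XGresid = 200, residual = TRUE,
            seed = 69)
  pf <- person_fit(f)
  # the contaminated time pattern has (much) higher flag probability
  expect_gt(pf$EAPCP1[2], 0.9)
  expect_gt(pf$lZPT[2], quantile(pf$lZPT[-2], 0.99))
  # report shape and probability bounds
  expect_true(all(pf$EAPCP3 <= pmin(pf$EAPCP1, pf$EAPCP2) + 1e-12))
  for (cn in c("PFlp", "lZP", "EAPCP1", "EAPCP2", "EAPCP3"))
    expect_true(all(pf[[cn]] >= 0 & pf[[cn]] <= 1))
  itf <- item_fit(f)
  expect_true(all(itf$EAPKS >= 0 & itf$EAPKS <= 1, na.rm = TRUE))
  expect_equal(nrow(itf), 15)
})
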