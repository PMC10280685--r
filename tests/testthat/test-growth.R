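test_that("the time scale maps solve order to [0, (K-1)/K]", {
  expect_equal(build_time_scale(1:4, 4), c(0, 0.25, 0.5, 0.75))
  # first solved item sits at time zero, last at (K-1)/K
  ord <- rbind(c(2, 1, 3), c(3, 2, 1))
  X <- build_time_scale(ord, 3)
  expect_equal(X[1, 2], 0)
  expect_equal(X[2, 1], 2 / 3)
  # position 21 of 40 sits at 0.5
  expect_equal(build_time_scale(1:40, 40)[21], 0.5)
  # equidistance: row sums are (K-1)/2 exactly
  expect_equal(rowSums(X), rep(3 * (3 - 1) / (2 * 3), 2))
  expect_error(build_time_scale(rbind(c(1, 1, 3)), 3), "permutation")
})

test_that("speed trajectories evaluate the quadratic growth curve", {
  expect_equal(speed_at(0.7), 0.7)
  expect_equal(speed_at(0.2, 1, -1, 0.5), 0.2 + 0.5 - 0.25)
  # constant trajectory when trend and quadratic are zero
  x <- seq(0, 0.9, by = 0.1)
  expect_equal(speed_at(0.3, 0, 0, x), rep(0.3, length(x)))
})

test_that("growth sampler keeps its identification constraints", {
  sim <- jirt_sim_growth(80, 8, seed = 71)
  f <- jirtq(sim$Y, sim$RT, XG = 150, seed = 72)
  expect_true(all(abs(apply(f$draws$a, 1, prod) - 1) < 1e-8))
  expect_true(all(abs(apply(f$draws$phi, 1, prod) - 1) < 1e-8))
  expect_true(all(abs(rowSums(f$draws$b)) < 1e-8))
})

test_that("growth sampler recovers item parameters and trend variance", {
  sim <- jirt_sim_growth(250, 20, seed = 73)
  f <- jirtq(sim$Y, sim$RT, XG = 700, seed = 74)
  cf <- coef(f)
  expect_gt(cor(cf[, "lambda"], sim$items$lambda), 0.95)
  expect_gt(cor(cf[, "sigma2"], sim$items$sigma2), 0.8)
  s <- summary(f)
  # trend variance of the generating process (0.114) within a generous
  # posterior range; with K = 20 the trend is only weakly identified
  expect_gt(s$Sigma["zeta1", "zeta1"], 0.005)
  expect_lt(s$Sigma["zeta1", "zeta1"], 0.6)
  # positive ability / starting-speed covariance is recovered in sign
  expect_gt(s$Sigma["theta", "zeta0"], 0)
})

test_that("all-missing records shrink to the population averages", {
  sim <- jirt_sim_growth(120, 10, seed = 75, mu_theta = -0.3)
  mb <- matrix(1, 120, 10); mb[5, ] <- 0
  f <- jirtq(sim$Y, sim$RT, XG = 500, MBDY = mb, MBDT = mb, seed = 76)
  pe <- person_estimates(f)
  mu_th <- mean(f$draws$mu_theta[51:500])
  expect_lt(abs(pe$theta.EAP[5] - mu_th), 0.25)
  expect_lt(abs(pe$zeta0.EAP[5]), 0.15)
  expect_lt(abs(pe$zeta1.EAP[5]), 0.15)
  expect_lt(abs(pe$zeta2.EAP[5]), 0.15)
  # a person with data is not at the population mean (sanity contrast)
  expect_gt(sd(pe$theta.EAP), 0.2)
})

test_that("full-covariance mode requires fixed time discriminations", {
  sim <- jirt_sim_growth(60, 6, seed = 77)
  expect_error(jirtq(sim$Y, sim$RT, XG = 10, full_cov = TRUE),
               "full_cov")
  f <- jirtq(sim$Y, sim$RT, XG = 120, full_cov = TRUE, td = FALSE,
             seed = 78)
  expect_true(all(f$draws$phi == 1))
  # off-diagonal speed covariances are now estimated (non-zero draws)
  Sg <- f$draws$Sigma[120, , ]
  expect_false(all(Sg[2, 3] == 0))
})
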