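# Internal Gibbs blocks are exercised through small hand-built states and
# through short end-to-end runs.

make_state <- function(Y, theta, a, b, cg = NULL, par1 = FALSE) {
  N <- nrow(Y); K <- ncol(Y)
  list(N = N, K = K, Y = Y, WY = matrix(1, N, K), theta = theta,
       a = a, b = b, cg = cg %||% rep(0, K),
       guess = !is.null(cg), par1 = par1, S = matrix(1, N, K))
}
`%||%` <- function(x, y) if (is.null(x)) y else x
within_list <- function(l, expr) {
  e <- list2env(l)
  eval(substitute(expr), e)
  as.list(e)[names(l)]
}

test_that("augmented propensities follow the truncated-normal conditionals", {
  set.seed(31)
  # E[Z | Y = 1, a*theta - b = 0] = dnorm(0)/pnorm(0) = 0.79788
  st <- make_state(Y = matrix(1, 4000, 1), theta = rep(0, 4000),
                   a = 1, b = 0)
  st <- jirt:::sample_augmented_responses(st)
  expect_equal(mean(st$Z), dnorm(0) / pnorm(0), tolerance = 0.02)
  expect_true(all(st$Z > 0))
  # incorrect responses give strictly negative propensities
  st0 <- make_state(Y = matrix(0, 500, 2), theta = rnorm(500),
                    a = c(1, 1.5), b = c(-0.3, 0.4))
  st0 <- jirt:::sample_augmented_responses(st0)
  expect_true(all(st0$Z < 0))
  # without guessing every response is attributed to the IRT process
  expect_true(all(st0$S == 1))
})

test_that("guessing indicators follow the posterior odds", {
  set.seed(32)
  # P(S=1 | Y=1) = (1-c) Phi / (c + (1-c) Phi)
  st <- make_state(Y = matrix(1, 20000, 1), theta = rep(0.5, 20000),
                   a = 1, b = 0, cg = 0.2)
  st <- jirt:::sample_augmented_responses(st)
  p <- pnorm(0.5)
  expected <- 0.8 * p / (0.2 + 0.8 * p)
  expect_equal(mean(st$S), expected, tolerance = 0.01)
  # c = 0 never attributes a correct response to guessing
  st0 <- make_state(Y = matrix(1, 200, 1), theta = rep(0, 200),
                    a = 1, b = 0, cg = 0)
  st0 <- jirt:::sample_augmented_responses(st0)
  expect_true(all(st0$S == 1))
})

test_that("inverse-Wishart sampler matches the closed-form mean", {
  set.seed(33)
  V <- matrix(c(3, 1, 1, 2), 2, 2)
  nu <- 10
  M <- matrix(0, 2, 2)
  R <- 20000
  for (r in 1:R) M <- M + jirt:::rinvwishart(nu, V)
  expect_equal(M / R, V / (nu - 2 - 1), tolerance = 0.03)
  expect_error(jirt:::rinvwishart(1, V), "degrees of freedom")
})

test_that("item conditionals match the weighted least-squares oracle", {
  # with a flat prior the conditional mean of b_k given Z is the
  # normal-equations solution mean(a*theta - Z); likewise for lambda
  set.seed(34)
  N <- 5
  theta <- c(-1.2, -0.4, 0, 0.6, 1.3); zeta <- c(0.3, -0.1, 0, 0.2, -0.4)
  Z <- matrix(c(0.5, -0.8, 0.2, 1.1, -0.3), N, 1)
  RT <- matrix(c(4.1, 3.8, 4.0, 3.6, 4.4), N, 1)
  a <- 1.1; phi <- 0.9; s2 <- 0.2
  st <- list(N = N, K = 1, WY = matrix(1, N, 1), WT = matrix(1, N, 1),
             S = matrix(1, N, 1), Z = Z, RT = RT, theta = theta,
             zeta = zeta, a = a, b = 0, phi = phi, lambda = 4,
             sigma2 = s2, par1 = FALSE, par2 = FALSE, WL = FALSE,
             td = TRUE, guess = FALSE,
             fix_a = TRUE, fix_b = FALSE, fix_phi = TRUE,
             fix_lambda = FALSE, mu_I = rep(0, 4),
             Sigma_I = diag(4) * 1e6, XIA = NULL, XIT = NULL)
  R <- 4000
  bs <- ls <- numeric(R)
  for (r in 1:R) {
    out <- jirt:::sample_item_parameters(st)
    bs[r] <- out$b; ls[r] <- out$lambda
  }
  b_wls <- mean(a * theta - Z)
  l_wls <- mean(RT + phi * zeta)
  expect_lt(abs(mean(bs) - b_wls), 4 * sd(bs) / sqrt(R) + 1e-3)
  expect_lt(abs(mean(ls) - l_wls), 4 * sd(ls) / sqrt(R) + 1e-3)
})

test_that("persons with no data are drawn from the population prior", {
  set.seed(35)
  sim <- small_sim(N = 60, K = 6, seed = 36)
  mb <- matrix(1, 60, 6); mb[1, ] <- 0      # person 1 fully by design
  f <- jirt(sim$Y, sim$RT, XG = 600, MBDY = mb, MBDT = mb,
            SigmaP = matrix(c(1, 0.2, 0.2, 0.25), 2, 2), seed = 37)
  th1 <- f$draws$theta[101:600, 1]
  ze1 <- f$draws$zeta[101:600, 1]
  # prior N(0, Sigma_P) moments within Monte-Carlo error
  expect_equal(mean(th1), 0, tolerance = 4 / sqrt(500))
  expect_equal(sd(th1), 1, tolerance = 0.15)
  expect_equal(sd(ze1), 0.5, tolerance = 0.12)
})

test_that("a single precise response time pins down the speed", {
  set.seed(38)
  sim <- small_sim(N = 40, K = 3, seed = 39)
  mb <- matrix(1, 40, 3); mb[1, 2:3] <- 0
  RT <- sim$RT; RT[1, 1] <- 3.2
  f <- jirt(sim$Y, RT, XG = 400, MBDT = mb,
            phi = rep(1, 3), lambda = rep(4, 3),
            sigma2 = rep(1e-6, 3), seed = 40)
  # zeta_1 concentrates at lambda - rt = 0.8
  expect_equal(mean(f$draws$zeta[101:400, 1]), 0.8, tolerance = 0.01)
})

test_that("fixed item parameters are never updated", {
  sim <- small_sim(N = 50, K = 5, seed = 41)
  av <- c(0.8, 1, 1.2, 0.9, 1.1)
  f <- jirt(sim$Y, sim$RT, XG = 50, alpha = av, seed = 42)
  expect_true(all(f$draws$a == matrix(av, 50, 5, byrow = TRUE)))
})

test_that("identification transformation is exact and likelihood-invariant", {
  f <- fitted_small()
  pa <- apply(f$draws$a, 1, prod)
  pp <- apply(f$draws$phi, 1, prod)
  expect_true(all(abs(pa - 1) < 1e-8))
  expect_true(all(abs(pp - 1) < 1e-8))
  expect_true(all(f$draws$mu_P == 0))        # ident = 2
  # geometric-mean normalization of a two-item state
  st <- list(a = c(2, 0.5), phi = c(1, 1), theta = rnorm(10),
             zeta = rnorm(10), b = c(0.1, -0.2), lambda = c(4, 4),
             mu_P = c(0, 0), Sigma_P = diag(2), mu_I = rep(1, 4),
             Sigma_I = diag(4), ident = 2, par1 = FALSE, par2 = FALSE,
             td = TRUE, WL = FALSE, fix_a = FALSE, fix_b = FALSE,
             fix_phi = FALSE, fix_lambda = FALSE,
             beta_PA = NULL, beta_PT = NULL)
  p_before <- pnorm(outer(st$theta, st$a) -
                      matrix(st$b, 10, 2, byrow = TRUE))
  out <- jirt:::apply_identification(st)
  expect_equal(prod(out$a), 1, tolerance = 1e-12)
  p_after <- pnorm(outer(out$theta, out$a) -
                     matrix(out$b, 10, 2, byrow = TRUE))
  expect_equal(p_before, p_after, tolerance = 1e-12)
  # idempotence
  out2 <- jirt:::apply_identification(out)
  expect_equal(out2$a, out$a, tolerance = 1e-12)
  expect_equal(out2$theta, out$theta, tolerance = 1e-12)
  expect_error(jirt:::apply_identification(
    within_list(st, a <- c(-1, 2))), "non-positive")
})

test_that("ident = 1 centers difficulties and intensities every draw", {
  sim <- small_sim(N = 80, K = 8, seed = 43)
  f <- jirt(sim$Y, sim$RT, XG = 120, ident = 1, seed = 44)
  expect_true(all(abs(rowSums(f$draws$b)) < 1e-8))
  expect_true(all(abs(rowSums(f$draws$lambda)) < 1e-8))
  expect_true(all(abs(apply(f$draws$a, 1, prod) - 1) < 1e-8))
})

test_that("missing-by-design cells carry no information", {
  sim <- small_sim(N = 60, K = 6, seed = 45)
  mb <- matrix(1, 60, 6); mb[1:10, 1] <- 0
  Y1 <- sim$Y; Y2 <- sim$Y
  Y1[1:10, 1] <- 0; Y2[1:10, 1] <- 1     # masked cells differ
  f1 <- jirt(Y1, sim$RT, XG = 80, MBDY = mb, seed = 46)
  f2 <- jirt(Y2, sim$RT, XG = 80, MBDY = mb, seed = 46)
  expect_identical(f1$draws$b, f2$draws$b)
  expect_identical(f1$draws$theta, f2$draws$theta)
})

test_that("rows with unexplained total missingness are rejected", {
  sim <- small_sim(N = 30, K = 5, seed = 47)
  Y <- sim$Y; RT <- sim$RT
  Y[3, ] <- NA; RT[3, ] <- NA
  expect_error(jirt(Y, RT, XG = 10), "missing-by-design")
  Yb <- sim$Y; Yb[1, 1] <- 2
  expect_error(jirt(Yb, sim$RT, XG = 10), "0, 1 or NA")
})

test_that("configuration contracts are enforced", {
  sim <- small_sim(N = 20, K = 4, seed = 99)
  expect_error(jirt(sim$Y, sim$RT, XG = 0), "positive")
  expect_error(jirt(sim$Y, sim$RT, XG = 10, burnin = 100), "burnin")
  expect_error(jirt(sim$Y, sim$RT, XG = 10, ident = 3), "ident")
  expect_error(jirt(sim$Y, sim$RT, XG = 10, WL = TRUE, par2 = TRUE),
               "mutually exclusive")
  # residual accumulation needs iterations beyond its starting point
  expect_error(jirt(sim$Y, sim$RT, XG = 500, residual = TRUE,
                    XGresid = 1000), "XGresid")
  expect_error(jirt(sim$Y, sim$RT[, 1:3], XG = 10), "identical dimensions")
  expect_error(jirt(sim$Y, sim$RT, XG = 10, alpha = c(1, 1)), "length K")
})

test_that("imputation leaves parameter recovery intact under MAR", {
  sim <- small_sim(N = 150, K = 12, seed = 48)
  simM <- apply_missing_design(sim, mar_rate = 0.10, seed = 49)
  f <- jirt(simM$Y, simM$RT, XG = 500, seed = 50)
  expect_gt(cor(coef(f)[, "lambda"], sim$items$lambda), 0.95)
  expect_gt(cor(coef(f)[, "b"], sim$items$b), 0.8)
})

test_that("adding a constant to one item's log-times shifts its intensity", {
  sim <- small_sim(N = 250, K = 10, seed = 51)
  f0 <- jirt(sim$Y, sim$RT, XG = 500, seed = 52)
  RT2 <- sim$RT; RT2[, 3] <- RT2[, 3] + 0.7
  f1 <- jirt(sim$Y, RT2, XG = 500, seed = 52)
  d_lam <- coef(f1)[, "lambda"] - coef(f0)[, "lambda"]
  expect_equal(unname(d_lam[3]), 0.7, tolerance = 0.05)
  expect_true(all(abs(d_lam[-3]) < 0.05))
  expect_true(all(abs(coef(f1)[, "b"] - coef(f0)[, "b"]) < 0.05))
})

test_that("explanatory variables recover a known group effect", {
  set.seed(53)
  N <- 400; K <- 12
  x <- rep(c(-1, 1), each = N / 2)
  spec <- jirt_popspec()
  persons <- draw_persons(N, spec, seed = 54)
  persons[, 1] <- persons[, 1] + 0.5 * x    # ability shifted by group
  items <- draw_items(K, spec, seed = 55)
  sim <- generate_dataset(persons, items, seed = 56)
  f <- jirt(sim$Y, sim$RT, XG = 600, XPA = cbind(x), seed = 57)
  bhat <- mean(f$draws$beta_PA[151:600, 1])
  expect_equal(bhat, 0.5, tolerance = 0.15)
})
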