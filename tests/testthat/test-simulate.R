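test_that("person draws reproduce the population moments", {
  N <- 10000
  spec <- jirt_popspec(Sigma_P = matrix(c(1, 0.4, 0.4, 1), 2, 2))
  P <- draw_persons(N, spec, seed = 7)
  expect_equal(dim(P), c(N, 2))
  # sample means within 3 sigma / sqrt(N) of zero
  expect_lt(abs(mean(P[, 1])), 3 / sqrt(N))
  expect_lt(abs(mean(P[, 2])), 3 / sqrt(N))
  # Monte-Carlo check against the generating correlation
  expect_equal(cor(P[, 1], P[, 2]), 0.4, tolerance = 0.03 / 0.4)
  # independence under a diagonal covariance
  P0 <- draw_persons(N, jirt_popspec(Sigma_P = diag(2)), seed = 8)
  expect_lt(abs(cor(P0[, 1], P0[, 2])), 3 / sqrt(N))
  # reproducibility
  expect_identical(draw_persons(50, spec, seed = 9),
                   draw_persons(50, spec, seed = 9))
  expect_error(draw_persons(10, jirt_popspec(
    Sigma_P = matrix(c(1, 2, 2, 1), 2, 2))), "definite")
})

test_that("item draws respect constraints and degenerate covariances", {
  spec <- jirt_popspec()
  for (s in 1:5) {
    it <- draw_items(50, spec, seed = s)
    expect_true(min(it$a) > 0)
    expect_true(min(it$phi) > 0)
    expect_true(all(it$sigma2 > 0))
  }
  # degenerate (zero) covariance returns the means exactly
  sp0 <- jirt_popspec(Sigma_I = matrix(0, 4, 4))
  it0 <- draw_items(5, sp0, seed = 1)
  expect_equal(unname(as.matrix(it0[, c("a", "b", "phi", "lambda")])),
               matrix(spec$mu_I, 5, 4, byrow = TRUE))
  # Beta(20, 80) guessing draws center on 1/5
  itg <- draw_items(4000, spec, guess = TRUE, seed = 2)
  expect_equal(mean(itg$c), 0.2, tolerance = 0.01 / 0.2)
})

test_that("generated data match the measurement models", {
  # zero noise: log response times equal their expectation
  items <- data.frame(a = c(1, 1.2), b = c(0, 0.5), phi = c(1, 0.9),
                      lambda = c(4, 3.5), sigma2 = c(1e-18, 1e-18))
  persons <- cbind(theta = c(0, 1), zeta = c(0.3, -0.2))
  sim <- generate_dataset(persons, items, seed = 3)
  M <- outer(persons[, 2], items$phi)
  expect_equal(sim$RT,
               matrix(items$lambda, 2, 2, byrow = TRUE) - M,
               tolerance = 1e-6)
  # saturation: very able person answers (almost) everything correctly
  items2 <- data.frame(a = rep(1, 30), b = rep(0, 30), phi = 1,
                       lambda = 4, sigma2 = 0.25)
  sim2 <- generate_dataset(cbind(rep(10, 50), 0), items2, seed = 4)
  expect_gt(mean(sim2$Y), 0.999)
  # per-item mean log-RT close to lambda when speed is centered
  set.seed(5)
  N <- 2000
  persons3 <- draw_persons(N, jirt_popspec(), seed = 5)
  persons3[, 2] <- persons3[, 2] - mean(persons3[, 2])
  items3 <- draw_items(20, jirt_popspec(), seed = 6)
  sim3 <- generate_dataset(persons3, items3, seed = 7)
  tol <- 3 * sqrt(items3$sigma2) / sqrt(N)
  expect_true(all(abs(colMeans(sim3$RT) - items3$lambda) < tol +
                    3 * items3$phi * sd(persons3[, 2]) / sqrt(N)))
  # reproducibility of the full pipeline
  expect_identical(jirt_sim(40, 6, seed = 11)$RT,
                   jirt_sim(40, 6, seed = 11)$RT)
})

test_that("growth simulator nests the constant-speed model", {
  # first time point is zero for every person under administration order
  sim <- jirt_sim_growth(30, 8, seed = 12)
  expect_true(all(sim$X[, 1] == 0))
  expect_equal(sim$X[1, ], (0:7) / 8)
  # increasing-speed person: expected log-RT net of intensity decreases
  items <- draw_items(10, seed = 13)
  S0 <- diag(c(0.4, 0.05, 1e-12, 1e-12)); S0[1, 2] <- S0[2, 1] <- 0.05
  g <- jirt_sim_growth(5, 10, Sigma = S0, items = items, seed = 14)
  pers <- cbind(theta = 0, zeta0 = 0.2, zeta1 = 0.8, zeta2 = 0)
  x <- (0:9) / 10
  sp <- speed_at(pers[, "zeta0"], pers[, "zeta1"], pers[, "zeta2"], x)
  # with unit time discrimination the expected log-RT net of the
  # intensity, -phi * speed, decreases strictly over the solve order
  expect_true(all(diff(-1 * sp) < 0))
  # zero trend/quadratic variance reduces to the constant-speed generator
  gq <- jirt_sim_growth(3000, 10, Sigma = S0, items = items, seed = 15)
  pc <- draw_persons(3000, jirt_popspec(
    Sigma_P = matrix(c(0.4, 0.05, 0.05, 0.05), 2, 2)), seed = 16)
  sc <- generate_dataset(pc, items, seed = 17)
  expect_equal(colMeans(gq$RT), colMeans(sc$RT), tolerance = 0.05)
  expect_equal(apply(gq$RT, 2, sd), apply(sc$RT, 2, sd), tolerance = 0.05)
  expect_equal(colMeans(gq$Y), colMeans(sc$Y), tolerance = 0.06)
})

test_that("missing-design application distinguishes design from random", {
  sim <- small_sim(N = 90, K = 12, seed = 18)
  # identity when nothing is masked
  s0 <- apply_missing_design(sim, mar_rate = 0)
  expect_identical(s0$Y, sim$Y)
  # booklet design: three groups each see one block of four items
  mb <- matrix(0, 90, 12)
  for (gi in 1:3) mb[(gi - 1) * 30 + 1:30, (gi - 1) * 4 + 1:4] <- 1
  s1 <- apply_missing_design(sim, mbdy = mb, mbdt = mb)
  for (k in 1:12) {
    grp <- (k - 1) %/% 4 + 1
    obs <- which(!is.na(s1$Y[, k]))
    expect_true(all(obs %in% ((grp - 1) * 30 + 1:30)))
  }
  # missing-at-random thinning rate
  simL <- small_sim(N = 400, K = 25, seed = 19)
  s2 <- apply_missing_design(simL, mar_rate = 0.05, seed = 20)
  rate <- mean(is.na(s2$Y))
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / (400 * 25)))
  expect_error(apply_missing_design(sim, mbdy = matrix(1, 2, 2)),
               "dimensions")
})

test_that("simulated datasets round-trip through CSV with a manifest", {
  dir <- tempfile()
  sim <- small_sim(N = 25, K = 5, seed = 21)
  files <- write_jirt_sim(sim, dir)
  expect_true(all(file.exists(files)))
  Y2 <- read_matrix_csv(file.path(dir, "Y.csv"))
  expect_equal(unname(Y2), unname(sim$Y))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$N, 25)
  expect_equal(man$K, 5)
  unlink(dir, recursive = TRUE)
})
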