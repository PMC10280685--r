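#' Generate joint accuracy / response-time data from given parameters
#'
#' Given person and item parameters, draws a binary accuracy matrix from
#' the normal-ogive model and a log response-time matrix from the
#' log-normal model, each cell independently given the parameters.
#'
#' @param persons `N x 2` matrix of (theta, zeta), e.g. from [draw_persons()].
#' @param items data.frame with columns `a`, `b`, `phi`, `lambda`, `sigma2`
#'   and optionally `c`, e.g. from [draw_items()].
#' @param par1 bracketed (ability-scale) convention for the difficulty?
#' @param par2 bracketed (speed-scale) convention for the time intensity?
#' @param wl reciprocal-error-SD time parameterization? When `TRUE` the
#'   residual SD is `1/phi` and `sigma2` is ignored.
#' @param seed optional integer seed.
#' @return an object of class `jirt_sim`: list with `Y` (N x K integer),
#'   `RT` (N x K log-times), `persons`, `items` and the convention flags.
#' @export
generate_dataset <- function(persons, items, par1 = FALSE, par2 = FALSE,
                             wl = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  persons <- as.matrix(persons)
  N <- nrow(persons); K <- nrow(items)
  if (ncol(persons) != 2) stop("'persons' must have two columns (theta, zeta)")
  cc <- if ("c" %in% names(items)) items$c else rep(0, K)
  P <- t(vapply(seq_len(K), function(k)
    success_probability(persons[, 1], items$a[k], items$b[k], cc[k], par1),
    numeric(N)))                              # K x N
  Y <- matrix(stats::rbinom(N * K, 1L, t(P)), N, K)
  M <- t(vapply(seq_len(K), function(k)
    expected_log_rt(persons[, 2], items$phi[k], items$lambda[k], par2, wl),
    numeric(N)))                              # K x N
  sdk <- if (wl) 1 / items$phi else sqrt(items$sigma2)
  RT <- t(M) + matrix(stats::rnorm(N * K), N, K) * rep(sdk, each = N)
  structure(list(Y = Y, RT = RT, persons = persons, items = items,
                 par1 = par1, par2 = par2, wl = wl,
                 MBDY = NULL, MBDT = NULL),
            class = "jirt_sim")
}

#' Simulate a complete joint-model dataset
#'
#' Convenience wrapper: draws persons and items from a population
#' specification and generates accuracy and log response-time matrices.
#' The returned object carries the generating parameters (ground truth)
#' for use in parameter-recovery studies.
#'
#' @param N,K numbers of persons and items.
#' @param spec a [jirt_popspec()].
#' @param guess simulate a guessing mixture (3PL accuracy model)?
#' @param par1,par2,wl measurement-model convention flags, see
#'   [generate_dataset()].
#' @param seed optional integer seed.
#' @return an object of class `jirt_sim`; see [generate_dataset()].
#' @examples
#' sim <- jirt_sim(50, 10, seed = 1)
#' dim(sim$Y); dim(sim$RT)
#' @export
jirt_sim <- function(N, K, spec = jirt_popspec(), guess = FALSE,
                     par1 = FALSE, par2 = FALSE, wl = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  persons <- draw_persons(N, spec)
  items <- draw_items(K, spec, guess = guess)
  sim <- generate_dataset(persons, items, par1 = par1, par2 = par2, wl = wl)
  sim$spec <- spec
  sim
}

#' Simulate data under the differential working-speed model
#'
#' Working speed follows a person-specific quadratic trajectory over the
#' solve order of the items: the speed applied by person `i` at item `k`
#' is `zeta0 + zeta1 * X_ik + zeta2 * X_ik^2`, with `X` the equidistant
#' time scale of [build_time_scale()]. Person effects
#' `(theta, zeta0, zeta1, zeta2)` are drawn from a 4-variate normal whose
#' speed components have mean zero. The default covariance mirrors a
#' chess problem-solving study: modest variance in starting speed (0.06),
#' larger variance in trends (0.11), and a positive ability / starting
#' speed covariance.
#'
#' @param N,K numbers of persons and items.
#' @param Sigma 4x4 covariance of (theta, zeta0, zeta1, zeta2).
#' @param mu_theta population mean ability.
#' @param items optional item data.frame (drawn from `spec` if `NULL`).
#' @param spec a [jirt_popspec()] used for the item draw.
#' @param order optional `N x K` matrix giving the solve order of the
#'   items (each row a permutation of `1:K`); default is administration
#'   (column) order.
#' @param seed optional integer seed.
#' @return an object of class `jirt_sim` with an extra `persons` matrix of
#'   four columns and the time-scale matrix `X`.
#' @export
jirt_sim_growth <- function(N, K, Sigma = default_growth_cov(),
                            mu_theta = 0, items = NULL,
                            spec = jirt_popspec(), order = NULL,
                            seed = NULL) {
  check_spd(Sigma, 4, "Sigma")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(items)) items <- draw_items(K, spec)
  if (is.null(order)) order <- matrix(rep(seq_len(K), each = N), N, K)
  X <- build_time_scale(order, K)
  persons <- rmvnorm_chol(N, c(mu_theta, 0, 0, 0), Sigma)
  colnames(persons) <- c("theta", "zeta0", "zeta1", "zeta2")
  P <- stats::pnorm(outer(persons[, 1], items$a) -
                      matrix(items$b, N, K, byrow = TRUE))
  Y <- matrix(stats::rbinom(N * K, 1L, P), N, K)
  speed <- persons[, 2] + persons[, 3] * X + persons[, 4] * X^2
  M <- matrix(items$lambda, N, K, byrow = TRUE) -
    speed * matrix(items$phi, N, K, byrow = TRUE)
  RT <- M + matrix(stats::rnorm(N * K), N, K) *
    rep(sqrt(items$sigma2), each = N)
  structure(list(Y = Y, RT = RT, persons = persons, items = items, X = X,
                 order = order, Sigma = Sigma, par1 = FALSE, par2 = FALSE,
                 wl = FALSE, MBDY = NULL, MBDT = NULL),
            class = "jirt_sim")
}

# Growth covariance defaults modeled on the chess application: columns are
# (theta, zeta0, zeta1, zeta2); speed components mutually uncorrelated.
default_growth_cov <- function() {
  S <- diag(c(0.423, 0.060, 0.114, 0.063))
  S[1, 2] <- S[2, 1] <- 0.114
  S[1, 3] <- S[3, 1] <- -0.004
  S[1, 4] <- S[4, 1] <- -0.014
  S
}

#' Apply missing-by-design and missing-at-random patterns
#'
#' Cells whose mask entry is 0 are set missing and flagged as missing by
#' design (they are never imputed by the sampler and drop out of every
#' likelihood term). Additionally a fraction `mar_rate` of the remaining
#' cells is set missing completely at random; those cells are imputed
#' during estimation.
#'
#' @param sim a `jirt_sim` object.
#' @param mbdy,mbdt 0/1 indicator matrices of the same size as `Y` / `RT`
#'   (0 = missing by design); `NULL` means no design missingness.
#' @param mar_rate probability that an observed cell is made missing at
#'   random (applied independently to `Y` and `RT`).
#' @param seed optional integer seed.
#' @return the modified `jirt_sim` object with `MBDY`/`MBDT` masks stored.
#' @export
apply_missing_design <- function(sim, mbdy = NULL, mbdt = NULL,
                                 mar_rate = 0, seed = NULL) {
  stopifnot(inherits(sim, "jirt_sim"), mar_rate >= 0, mar_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  dm <- dim(sim$Y)
  for (nm in c("mbdy", "mbdt")) {
    m <- get(nm)
    if (!is.null(m) && !identical(dim(m), dm))
      stop(sprintf("'%s' must match the data dimensions", toupper(nm)))
  }
  if (!is.null(mbdy)) sim$Y[mbdy == 0] <- NA
  if (!is.null(mbdt)) sim$RT[mbdt == 0] <- NA
  if (mar_rate > 0) {
    dropY <- matrix(stats::runif(prod(dm)) < mar_rate, dm[1], dm[2])
    dropT <- matrix(stats::runif(prod(dm)) < mar_rate, dm[1], dm[2])
    if (!is.null(mbdy)) dropY[mbdy == 0] <- FALSE
    if (!is.null(mbdt)) dropT[mbdt == 0] <- FALSE
    sim$Y[dropY] <- NA
    sim$RT[dropT] <- NA
  }
  sim$MBDY <- mbdy
  sim$MBDT <- mbdt
  sim
}

#' Write a simulated dataset to disk
#'
#' Writes the accuracy and log response-time matrices (and any masks and
#' ground-truth parameters) as CSV files plus a JSON manifest of the
#' generating parameters.
#'
#' @param sim a `jirt_sim` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_jirt_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "jirt_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  wr <- function(x, name) {
    f <- file.path(dir, name)
    utils::write.csv(x, f, row.names = FALSE)
    files <<- c(files, f)
  }
  wr(sim$Y, "Y.csv"); wr(sim$RT, "RT.csv")
  wr(as.data.frame(sim$persons), "persons.csv")
  wr(sim$items, "items.csv")
  if (!is.null(sim$MBDY)) wr(sim$MBDY, "MBDY.csv")
  if (!is.null(sim$MBDT)) wr(sim$MBDT, "MBDT.csv")
  manifest <- list(N = nrow(sim$Y), K = ncol(sim$Y),
                   par1 = sim$par1, par2 = sim$par2, wl = sim$wl)
  if (!is.null(sim$spec))
    manifest$population <- list(mu_P = sim$spec$mu_P,
                                Sigma_P = as.vector(sim$spec$Sigma_P),
                                mu_I = sim$spec$mu_I,
                                Sigma_I = as.vector(sim$spec$Sigma_I),
                                sigma2_shape = sim$spec$sigma2_shape,
                                sigma2_scale = sim$spec$sigma2_scale,
                                guess_shape = sim$spec$guess_shape)
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
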