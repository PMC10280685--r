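# S3 methods for fitted joint models.

eap_sd <- function(ch, keep) {
  if (length(dim(ch)) == 3)
    list(eap = apply(ch[keep, , , drop = FALSE], c(2, 3), mean),
         sd = apply(ch[keep, , , drop = FALSE], c(2, 3), stats::sd))
  else
    list(eap = colMeans(ch[keep, , drop = FALSE]),
         sd = apply(ch[keep, , drop = FALSE], 2, stats::sd))
}

#' @export
print.jirt <- function(x, ...) {
  cat("Bayesian joint model for response accuracy and response times\n")
  cat(sprintf("  %d persons, %d items, %d MCMC iterations (burn-in %g%%)\n",
              x$N, x$K, x$XG, x$burnin))
  cat(sprintf("  identification rule %d; guessing %s; conventions: %s%s%s\n",
              x$ident, ifelse(x$guess, "on", "off"),
              ifelse(x$par1, "bracketed-RA ", "plain-RA "),
              ifelse(x$par2, "bracketed-RT", ifelse(x$WL, "WL-RT",
                                                    "plain-RT")),
              ifelse(x$td, "", " (time discrimination fixed at 1)")))
  if (!is.null(x$fit))
    cat(sprintf("  residual analysis over %d draws\n", x$fit$ndraws))
  cat("Use summary() for parameter estimates.\n")
  invisible(x)
}

#' Posterior summary of a fitted joint model
#'
#' Discards the burn-in fraction of the chains and reports posterior
#' means (EAP) and standard deviations for the item parameters, the
#' person parameters, the item and person population means and
#' covariance matrices (with the implied correlation matrices), and any
#' regression coefficients.
#'
#' @param object a `jirt` fit.
#' @param burnin burn-in percentage; defaults to the value used at fit
#'   time.
#' @param ... unused.
#' @return an object of class `summary.jirt`.
#' @export
summary.jirt <- function(object, burnin = object$burnin, ...) {
  keep <- retained_iterations(object$XG, burnin)
  dr <- object$draws
  items <- data.frame(row.names = seq_len(object$K))
  for (p in c("a", "b", "c", "phi", "lambda", "sigma2")) {
    if (is.null(dr[[p]])) next
    es <- eap_sd(dr[[p]], keep)
    items[[paste0(p, ".EAP")]] <- es$eap
    items[[paste0(p, ".SD")]] <- es$sd
  }
  th <- eap_sd(dr$theta, keep); ze <- eap_sd(dr$zeta, keep)
  persons <- data.frame(theta.EAP = th$eap, theta.SD = th$sd,
                        zeta.EAP = ze$eap, zeta.SD = ze$sd)
  mu_I <- eap_sd(dr$mu_I, keep)
  mu_P <- eap_sd(dr$mu_P, keep)
  Sigma_I <- eap_sd(dr$Sigma_I, keep)$eap
  Sigma_P <- eap_sd(dr$Sigma_P, keep)$eap
  dimnames(Sigma_I) <- list(c("a", "b", "phi", "lam"),
                            c("a", "b", "phi", "lam"))
  dimnames(Sigma_P) <- list(c("theta", "zeta"), c("theta", "zeta"))
  betas <- list()
  for (p in c("beta_PA", "beta_PT", "beta_IA", "beta_IT"))
    if (!is.null(dr[[p]])) betas[[p]] <- eap_sd(dr[[p]], keep)
  out <- list(items = items, persons = persons,
              mu_I = stats::setNames(mu_I$eap,
                                     c("mu_a", "mu_b", "mu_phi", "mu_lam")),
              mu_I_sd = mu_I$sd,
              mu_P = stats::setNames(mu_P$eap, c("mu_theta", "mu_zeta")),
              mu_P_sd = mu_P$sd,
              Sigma_I = Sigma_I, Sigma_P = Sigma_P,
              Cor_I = stats::cov2cor(Sigma_I),
              Cor_P = stats::cov2cor(Sigma_P),
              rho = stats::cov2cor(Sigma_P)[1, 2],
              betas = betas, retained = length(keep),
              N = object$N, K = object$K,
              par1 = object$par1, par2 = object$par2, WL = object$WL,
              truth = object$truth)
  class(out) <- "summary.jirt"
  out
}

#' @export
print.summary.jirt <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summary (%d retained draws)\n", x$retained))
  conv <- sprintf("difficulty on the %s scale; time intensity on the %s scale",
                  ifelse(x$par1, "ability (bracketed)", "propensity"),
                  ifelse(x$par2, "speed (bracketed)",
                         ifelse(x$WL, "WL (phi = 1/sigma)", "log-time")))
  cat("  ", conv, "\n\n", sep = "")
  cat("--- Item parameters (EAP / SD) ---\n")
  print(round(utils::head(x$items, 10), digits))
  if (x$K > 10) cat("  ... (", x$K - 10, " more items)\n", sep = "")
  cat("\n--- Population means ---\n")
  print(round(c(x$mu_I, x$mu_P), digits))
  cat("\n--- Covariance matrix Items (EAP) ---\n")
  print(round(x$Sigma_I, digits))
  cat("\n--- Item correlation matrix ---\n")
  print(round(x$Cor_I, digits))
  cat("\n--- Covariance matrix Persons (EAP) ---\n")
  print(round(x$Sigma_P, digits))
  cat(sprintf("\nability-speed correlation: %.3f\n", x$rho))
  for (nm in names(x$betas)) {
    cat("\n--- ", nm, " (EAP / SD) ---\n", sep = "")
    print(round(cbind(EAP = x$betas[[nm]]$eap, SD = x$betas[[nm]]$sd),
                digits))
  }
  invisible(x)
}

#' Item parameter estimates of a fitted joint model
#'
#' @param object a `jirt` fit.
#' @param ... unused.
#' @return matrix of posterior means, one row per item.
#' @export
coef.jirt <- function(object, ...) {
  s <- summary(object)
  m <- as.matrix(s$items[, grep("EAP", names(s$items))])
  colnames(m) <- sub(".EAP", "", colnames(m), fixed = TRUE)
  m
}

#' Person parameter estimates (EAP and posterior SD)
#'
#' @param object a `jirt` or `jirtq` fit.
#' @return data.frame with one row per person.
#' @export
person_estimates <- function(object) {
  if (inherits(object, "jirtq")) {
    keep <- retained_iterations(object$XG, object$burnin)
    th <- eap_sd(object$draws$theta, keep)
    out <- data.frame(theta.EAP = th$eap, theta.SD = th$sd)
    lbl <- c("zeta0", "zeta1", "zeta2")[seq_len(object$qdim)]
    for (j in seq_len(object$qdim)) {
      zj <- object$draws$zeta[keep, , j, drop = FALSE]
      out[[paste0(lbl[j], ".EAP")]] <- apply(zj, 2, mean)
      out[[paste0(lbl[j], ".SD")]] <- apply(zj, 2, stats::sd)
    }
    return(out)
  }
  summary(object)$persons
}

#' Posterior predictive datasets from a fitted joint model
#'
#' Draws replicate accuracy / log response-time datasets. Each replicate
#' uses the parameter values of one retained MCMC draw, so the replicates
#' reflect posterior uncertainty.
#'
#' @param object a `jirt` fit.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `jirt_sim`-like lists with `Y` and `RT`.
#' @export
simulate.jirt <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  keep <- retained_iterations(object$XG, object$burnin)
  gs <- sample(keep, nsim, replace = nsim > length(keep))
  dr <- object$draws
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    g <- gs[r]
    items <- data.frame(a = dr$a[g, ], b = dr$b[g, ], phi = dr$phi[g, ],
                        lambda = dr$lambda[g, ], sigma2 = dr$sigma2[g, ],
                        c = if (!is.null(dr$c)) dr$c[g, ] else 0)
    persons <- cbind(theta = dr$theta[g, ], zeta = dr$zeta[g, ])
    out[[r]] <- generate_dataset(persons, items, par1 = object$par1,
                                 par2 = object$par2, wl = object$WL)
  }
  if (nsim == 1) out[[1]] else out
}

#' Response-time residuals of a fitted joint model
#'
#' Observed log response times minus the fitted mean `lambda - phi * zeta`
#' at the posterior means; cells that were missing are `NA`. For fits run
#' with `residual = TRUE` the Rao-Blackwellized latent accuracy residuals
#' are attached as an attribute `"latent"`.
#'
#' @param object a `jirt` fit.
#' @param ... unused.
#' @return `N x K` matrix of residuals.
#' @export
residuals.jirt <- function(object, ...) {
  s <- summary(object)
  lamw <- if (object$par2) s$items$phi.EAP * s$items$lambda.EAP
          else s$items$lambda.EAP
  phieff <- if (object$WL) rep(1, object$K) else s$items$phi.EAP
  M <- matrix(lamw, object$N, object$K, byrow = TRUE) -
    outer(s$persons$zeta.EAP, phieff)
  R <- object$RT - M
  R[!object$obsT] <- NA
  if (!is.null(object$fit)) attr(R, "latent") <- object$fit$latent_residual
  R
}

#' Fitted success probabilities / expected log response times
#'
#' Evaluates the measurement models at the posterior means, for the
#' fitted persons or for new person parameter values.
#'
#' @param object a `jirt` fit.
#' @param type `"success"` for probabilities of a correct response,
#'   `"logrt"` for expected log response times.
#' @param theta,zeta optional person parameter vectors (default: EAPs of
#'   the fitted persons).
#' @param ... unused.
#' @return matrix persons x items.
#' @export
predict.jirt <- function(object, type = c("success", "logrt"),
                         theta = NULL, zeta = NULL, ...) {
  type <- match.arg(type)
  s <- summary(object)
  if (type == "success") {
    theta <- theta %||% s$persons$theta.EAP
    cc <- if (!is.null(s$items$c.EAP)) s$items$c.EAP else rep(0, object$K)
    out <- vapply(seq_len(object$K), function(k)
      success_probability(theta, s$items$a.EAP[k], s$items$b.EAP[k],
                          cc[k], object$par1), numeric(length(theta)))
  } else {
    zeta <- zeta %||% s$persons$zeta.EAP
    out <- vapply(seq_len(object$K), function(k)
      expected_log_rt(zeta, s$items$phi.EAP[k], s$items$lambda.EAP[k],
                      object$par2, object$WL), numeric(length(zeta)))
  }
  out
}

#' Trace and summary plots for a fitted joint model
#'
#' Base-graphics panel: trace plots of the ability-speed correlation and
#' the population means, and a scatter plot of the person estimates.
#'
#' @param x a `jirt` fit.
#' @param ... passed to `plot`.
#' @export
plot.jirt <- function(x, ...) {
  keep <- retained_iterations(x$XG, x$burnin)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  rho <- apply(x$draws$Sigma_P[keep, , , drop = FALSE], 1,
               function(S) stats::cov2cor(S)[1, 2])
  graphics::plot(keep, rho, type = "l", xlab = "iteration",
                 ylab = "ability-speed correlation", main = "trace", ...)
  graphics::plot(keep, x$draws$mu_I[keep, 4], type = "l",
                 xlab = "iteration", ylab = "mean time intensity",
                 main = "trace", ...)
  s <- summary(x)
  graphics::plot(s$persons$theta.EAP, s$persons$zeta.EAP,
                 xlab = "ability (EAP)", ylab = "speed (EAP)",
                 main = "person estimates", pch = 16, cex = 0.5, ...)
  graphics::plot(s$items$b.EAP, s$items$lambda.EAP,
                 xlab = "difficulty (EAP)", ylab = "time intensity (EAP)",
                 main = "item estimates", pch = 16, ...)
  invisible(x)
}

# ---- jirtq methods -----------------------------------------------------

#' @export
print.jirtq <- function(x, ...) {
  cat("Joint model with differential working speed\n")
  cat(sprintf("  %d persons, %d items, %d MCMC iterations (burn-in %g%%)\n",
              x$N, x$K, x$XG, x$burnin))
  cat(sprintf("  speed components: intercept%s%s\n",
              ifelse(x$trend, " + trend", ""),
              ifelse(x$quadratic, " + quadratic", "")))
  invisible(x)
}

#' Posterior summary of a differential working-speed fit
#'
#' @param object a `jirtq` fit.
#' @param burnin burn-in percentage.
#' @param ... unused.
#' @return an object of class `summary.jirtq`.
#' @export
summary.jirtq <- function(object, burnin = object$burnin, ...) {
  keep <- retained_iterations(object$XG, burnin)
  dr <- object$draws
  items <- data.frame(row.names = seq_len(object$K))
  for (p in c("a", "b", "phi", "lambda", "sigma2")) {
    es <- eap_sd(dr[[p]], keep)
    items[[paste0(p, ".EAP")]] <- es$eap
    items[[paste0(p, ".SD")]] <- es$sd
  }
  Sq <- apply(dr$Sigma[keep, , , drop = FALSE], c(2, 3), mean)
  lbl <- c("theta", c("zeta0", "zeta1", "zeta2")[seq_len(object$qdim)])
  dimnames(Sq) <- list(lbl, lbl)
  out <- list(items = items, persons = person_estimates(object),
              mu_theta = mean(dr$mu_theta[keep]),
              Sigma = Sq, retained = length(keep),
              N = object$N, K = object$K, qdim = object$qdim)
  class(out) <- "summary.jirtq"
  out
}

#' @export
print.summary.jirtq <- function(x, digits = 3, ...) {
  cat(sprintf("Differential working-speed model (%d retained draws)\n\n",
              x$retained))
  cat("--- Item parameters (EAP / SD) ---\n")
  print(round(utils::head(x$items, 10), digits))
  if (x$K > 10) cat("  ... (", x$K - 10, " more items)\n", sep = "")
  cat(sprintf("\nmean ability: %.3f\n", x$mu_theta))
  cat("\n--- Covariance matrix Persons (EAP) ---\n")
  print(round(x$Sigma, digits))
  invisible(x)
}

#' @export
coef.jirtq <- function(object, ...) {
  s <- summary(object)
  m <- as.matrix(s$items[, grep("EAP", names(s$items))])
  colnames(m) <- sub(".EAP", "", colnames(m), fixed = TRUE)
  m
}
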