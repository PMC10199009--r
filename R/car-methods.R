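# S3 methods for fitted Leroux CAR regressions.

#' @export
print.car_leroux <- function(x, ...) {
  cat("Gaussian CAR regression (Leroux prior)\n")
  cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("%d areas, %d retained draws (n_iter %d, burn-in %d, thin %d)\n",
              length(x$y), nrow(x$draws$beta), x$config$n_iter,
              x$config$burn_in, x$config$thin))
  cat("Posterior medians:\n")
  print(round(coef(x), 4))
  cat(sprintf("rho %.3f  tau2 %.3f  nu2 %.3f  (rho acceptance %.2f)\n",
              median(x$draws$rho), median(x$draws$tau2),
              median(x$draws$nu2), x$rho_accept_rate))
  invisible(x)
}

#' @export
coef.car_leroux <- function(object, ...) {
  apply(object$draws$beta, 2L, median)
}

#' @export
fitted.car_leroux <- function(object, ...) {
  eta <- object$X %*% t(object$draws$beta) + t(object$draws$phi)
  setNames(apply(eta, 1L, median), rownames(object$W))
}

#' @export
residuals.car_leroux <- function(object, ...) {
  object$y - fitted(object)
}

#' Predict from a fitted CAR regression
#'
#' Without `newdata`, returns fitted values (posterior median of
#' `X beta + phi`). With `newdata`, returns the posterior median of the
#' linear predictor `X beta` only, since new areas carry no estimated
#' spatial effect.
#' @param object a `car_leroux` fit.
#' @param newdata optional data frame of new covariate values.
#' @param ... unused.
#' @export
predict.car_leroux <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  X <- model.matrix(delete.response(object$terms), newdata)
  apply(X %*% t(object$draws$beta), 1L, median)
}

#' Posterior predictive simulation
#'
#' Draws replicate outcome vectors from the posterior predictive
#' distribution: for each of `nsim` retained draws, `X beta + phi` plus
#' Gaussian noise with that draw's `nu2`.
#' @param object a `car_leroux` fit.
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param ... unused.
#' @return matrix (areas x nsim).
#' @export
simulate.car_leroux <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  keep <- sample.int(nrow(object$draws$beta), nsim, replace = TRUE)
  n <- length(object$y)
  out <- sapply(keep, function(k) {
    drop(object$X %*% object$draws$beta[k, ]) + object$draws$phi[k, ] +
      rnorm(n, 0, sqrt(object$draws$nu2[k]))
  })
  matrix(out, nrow = n, dimnames = list(rownames(object$W), NULL))
}

#' Trace plots of the main chains
#' @param x a `car_leroux` fit.
#' @param ... unused.
#' @export
plot.car_leroux <- function(x, ...) {
  b <- x$draws$beta
  pars <- c(colnames(b), "rho", "tau2", "nu2")
  old <- par(mfrow = c(ceiling(length(pars) / 2), 2),
             mar = c(3, 4, 2, 1))
  on.exit(par(old))
  for (p in colnames(b))
    plot(b[, p], type = "l", ylab = p, xlab = "", main = p)
  for (p in c("rho", "tau2", "nu2"))
    plot(x$draws[[p]], type = "l", ylab = p, xlab = "", main = p)
  invisible(x)
}

#' @export
summary.car_leroux <- function(object, ...) {
  out <- summarise_posterior(object, increment_pct = 1)
  class(out) <- c("summary.car_leroux", class(out))
  out
}

#' @export
print.summary.car_leroux <- function(x, ...) {
  cat("Posterior summary (median and 95% credible interval)\n")
  y <- x
  class(y) <- "data.frame"
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

summarise_chain <- function(ch) {
  q <- unname(quantile(ch, c(0.5, 0.025, 0.975), type = 7))
  c(median = q[1], lower = q[2], upper = q[3])
}

#' Summarise posterior draws
#'
#' Per-coefficient posterior median, 95% credible interval (2.5th and
#' 97.5th percentiles), a significance flag (the interval excludes zero),
#' and the Geweke convergence z statistic. Since the predictors are
#' percentages of area participants, coefficient draws are multiplied by
#' `increment_pct` so each reported effect corresponds to an
#' `increment_pct`-point increment of the metric (default 5). The intercept
#' and the variance/dependence parameters `rho`, `tau2`, `nu2` are reported
#' unscaled.
#'
#' @param draws a `car_leroux` fit, a draws matrix with named columns, or a
#'   numeric vector for a single parameter.
#' @param increment_pct increment (percentage points) the reported
#'   coefficients correspond to.
#' @param ... passed between methods.
#' @return data frame with columns `parameter`, `increment`, `median`,
#'   `lower`, `upper`, `significant`, `geweke_z`.
#' @export
summarise_posterior <- function(draws, increment_pct = 5, ...) {
  UseMethod("summarise_posterior")
}

#' @rdname summarise_posterior
#' @export
summarise_posterior.numeric <- function(draws, increment_pct = 5, ...) {
  summarise_posterior(matrix(draws, ncol = 1,
                             dimnames = list(NULL, "parameter")),
                      increment_pct = increment_pct, ...)
}

#' @rdname summarise_posterior
#' @param unscaled names of columns left on their native scale (the
#'   intercept and the model's variance/dependence parameters by default).
#' @export
summarise_posterior.matrix <- function(draws, increment_pct = 5,
                                       unscaled = c("(Intercept)", "rho",
                                                    "tau2", "nu2"), ...) {
  if (nrow(draws) < 2L)
    stop("at least 2 retained draws are required", call. = FALSE)
  rows <- lapply(colnames(draws), function(p) {
    scale <- if (p %in% unscaled) 1 else increment_pct
    ch <- draws[, p] * scale
    s <- summarise_chain(ch)
    gz <- if (length(ch) >= 20L && var(ch) > 0)
      suppressWarnings(geweke_z(ch)) else NA_real_
    data.frame(parameter = p,
               increment = if (p %in% unscaled) NA_real_ else increment_pct,
               median = s["median"], lower = s["lower"], upper = s["upper"],
               significant = s["lower"] > 0 | s["upper"] < 0,
               geweke_z = gz)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname summarise_posterior
#' @export
summarise_posterior.car_leroux <- function(draws, increment_pct = 5, ...) {
  fit <- draws
  m <- cbind(fit$draws$beta, rho = fit$draws$rho, tau2 = fit$draws$tau2,
             nu2 = fit$draws$nu2)
  summarise_posterior(m, increment_pct = increment_pct, ...)
}
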