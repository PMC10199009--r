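#' MCMC schedule configuration
#'
#' Sampler schedule: total iterations, burn-in discarded from the front, and
#' thinning of the remainder. The number of retained draws is
#' `floor((n_iter - burn_in) / thin)`; the conventional area-health schedule
#' of 100,000 iterations, 10,000 burn-in and thin 100 retains 900 draws.
#'
#' @param n_iter total iterations.
#' @param burn_in iterations discarded (must be < `n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw (>= 1).
#' @param seed optional integer seed applied before sampling.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 100000, burn_in = 10000, thin = 100,
                        seed = NULL) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in < 0 || burn_in >= n_iter)
    stop("burn_in must satisfy 0 <= burn_in < n_iter", call. = FALSE)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed), class = "mcmc_config")
}

#' Number of retained posterior draws under a schedule
#' @param config an [mcmc_config()].
#' @return `floor((n_iter - burn_in) / thin)`.
#' @export
retained_draws <- function(config) {
  stopifnot(inherits(config, "mcmc_config"))
  (config$n_iter - config$burn_in) %/% config$thin
}

#' Prior hyperparameters for the CAR regression
#'
#' Weakly informative defaults in the style of the areal-modelling
#' ecosystem: mean-zero Gaussian priors with large variance on each
#' regression coefficient, inverse-gamma(1, 0.01) on both variance
#' components, and a Uniform(0, 1) prior on the spatial dependence `rho`.
#'
#' @param beta_var prior variance of each coefficient.
#' @param nu2_shape,nu2_scale inverse-gamma hyperparameters for the
#'   observation noise variance.
#' @param tau2_shape,tau2_scale inverse-gamma hyperparameters for the
#'   spatial variance.
#' @return object of class `car_priors`.
#' @export
car_priors <- function(beta_var = 1e5, nu2_shape = 1, nu2_scale = 0.01,
                       tau2_shape = 1, tau2_scale = 0.01) {
  vals <- c(beta_var, nu2_shape, nu2_scale, tau2_shape, tau2_scale)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all prior hyperparameters must be positive", call. = FALSE)
  structure(list(beta_var = beta_var, nu2_shape = nu2_shape,
                 nu2_scale = nu2_scale, tau2_shape = tau2_shape,
                 tau2_scale = tau2_scale), class = "car_priors")
}

#' Fit a Gaussian CAR regression with the Leroux prior by MCMC
#'
#' Fits the spatial linear model `y = X beta + phi + eps` with Gaussian
#' likelihood and identity link, where the spatial random effects `phi`
#' carry the proper Leroux conditional autoregressive prior with precision
#' `(rho (D - W) + (1 - rho) I) / tau2` over the contiguity matrix `W`. The
#' Gibbs sampler uses conjugate Gaussian updates for `beta`, single-site
#' conjugate updates for `phi` (re-centred each sweep for identifiability
#' with the intercept), conjugate inverse-gamma updates for `nu2` and
#' `tau2`, and a reflecting random-walk Metropolis step on \[0, 1\] for
#' `rho`, tuned during burn-in towards 30–50% acceptance. A fixed
#' `config$seed` reproduces the chains bit-exactly.
#'
#' @param formula model formula, e.g. `outcome_rate ~ pct_high_at + irsd`.
#' @param data data frame of area profiles; row order must match `W`.
#' @param W binary symmetric contiguity matrix (see
#'   [adjacency_from_edges()]).
#' @param config an [mcmc_config()].
#' @param priors a [car_priors()].
#' @return object of class `car_leroux` with retained draws for `beta`
#'   (matrix, named columns), `phi`, `nu2`, `tau2`, `rho`, plus the data,
#'   schedule and the Metropolis acceptance rate for `rho`.
#' @seealso [summarise_posterior()], [geweke_z()]
#' @export
fit_car_leroux <- function(formula, data, W, config = mcmc_config(),
                           priors = car_priors()) {
  stopifnot(inherits(config, "mcmc_config"), inherits(priors, "car_priors"))
  validate_adjacency(W)
  mf <- model.frame(formula, data, na.action = NULL)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  if (anyNA(X) || anyNA(y))
    stop("model variables contain missing values; subset the areas (and W) ",
         "first", call. = FALSE)
  if (any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  if (n != nrow(W))
    stop("nrow(W) must equal the number of observations", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)

  islands <- sum(rowSums(W) == 0)
  if (islands > 0)
    warning(islands, " island area(s): their spatial effects follow the ",
            "exchangeable (1 - rho) part of the Leroux prior", call. = FALSE)

  # neighbour structure (0-based flat list) and eigenvalues of D - W
  nb_list <- lapply(seq_len(n), function(i) which(W[i, ] == 1) - 1L)
  nb <- as.integer(unlist(nb_list))
  nb_start <- c(0L, cumsum(lengths(nb_list)))
  lambda <- eigen(diag(rowSums(W)) - W, symmetric = TRUE,
                  only.values = TRUE)$values

  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .car_leroux_mcmc(as.numeric(y), X, nb, nb_start, lambda,
                          config$n_iter, config$burn_in, config$thin,
                          priors$beta_var, priors$nu2_shape,
                          priors$nu2_scale, priors$tau2_shape,
                          priors$tau2_scale, TRUE)
  colnames(res$beta) <- colnames(X)
  colnames(res$phi) <- rownames(W)
  structure(list(draws = list(beta = res$beta, phi = res$phi,
                              nu2 = drop(res$nu2), tau2 = drop(res$tau2),
                              rho = drop(res$rho)),
                 y = as.numeric(y), X = X, W = W,
                 formula = formula, terms = attr(mf, "terms"),
                 config = config, priors = priors,
                 rho_accept_rate = res$rho_accept_rate,
                 call = match.call()),
            class = "car_leroux")
}
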