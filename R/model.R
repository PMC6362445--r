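#' Species-level parameters of the community model
#'
#' Each species `k` has a vector of six logit-scale occupancy coefficients
#' (intercept plus FOREST, FOREST^2, TEMP, TEMP^2, PREC effects) and a
#' logit detection probability `lp_k`; detection is constant across sites
#' and replicates.
#'
#' @param delta 6 x n-species numeric matrix of occupancy coefficients
#'   (rows: intercept, FOREST, FOREST2, TEMP, TEMP2, PREC).
#' @param lp numeric vector of logit detection probabilities, one per
#'   species.
#' @return a `species_params` object.
#' @export
species_params <- function(delta, lp) {
  delta <- as.matrix(delta)
  if (nrow(delta) != 6) stop("delta must have 6 rows (intercept + 5 effects)")
  if (ncol(delta) != length(lp)) stop("delta and lp disagree on species count")
  if (!all(is.finite(delta)) || !all(is.finite(lp))) {
    stop("species parameters must be finite")
  }
  rownames(delta) <- c("delta0", "delta1", "delta2", "delta3", "delta4",
                       "delta5")
  structure(list(delta = delta, lp = as.numeric(lp)),
            class = "species_params")
}

#' Community hyperparameters
#'
#' The species-level coefficients are Normal random effects governed by
#' community means and standard deviations: `delta[m, k] ~ N(mu_delta[m],
#' sigma_delta[m])` and `lp[k] ~ N(mu_lp, sigma_lp)`.  `sigma_lpsi > 0`
#' activates an optional site-by-species logit-normal occupancy
#' overdispersion term.
#'
#' @param mu_delta length-6 community mean coefficients.
#' @param sigma_delta length-6 community sds (> 0).
#' @param mu_lp community mean logit detection.
#' @param sigma_lp community sd of logit detection (> 0).
#' @param sigma_lpsi occupancy overdispersion sd (>= 0; 0 disables).
#' @return a `hyper_params` object.
#' @export
hyper_params <- function(mu_delta, sigma_delta, mu_lp, sigma_lp,
                         sigma_lpsi = 0) {
  stopifnot(length(mu_delta) == 6, length(sigma_delta) == 6,
            all(sigma_delta > 0), sigma_lp > 0, sigma_lpsi >= 0)
  structure(list(mu_delta = as.numeric(mu_delta),
                 sigma_delta = as.numeric(sigma_delta),
                 mu_lp = as.numeric(mu_lp), sigma_lp = as.numeric(sigma_lp),
                 sigma_lpsi = as.numeric(sigma_lpsi)),
            class = "hyper_params")
}

#' Logit-scale occupancy linear predictor
#'
#' `mu = delta0 + delta1*FOREST + delta2*FOREST^2 + delta3*TEMP +
#' delta4*TEMP^2 + delta5*PREC`, all covariates standardized.
#'
#' @param x_row length-5 standardized covariate vector
#'   (FOREST, FOREST2, TEMP, TEMP2, PREC).
#' @param delta_k length-6 coefficient vector (intercept first).
#' @return the logit-scale occupancy predictor (scalar).
#' @export
linear_predictor <- function(x_row, delta_k) {
  stopifnot(length(x_row) == 5, length(delta_k) == 6,
            all(is.finite(x_row)), all(is.finite(delta_k)))
  delta_k[1] + sum(delta_k[-1] * x_row)
}

#' Occupancy probability matrix
#'
#' `psi[i, k] = plogis(mu[i, k] + eps[i, k])` where `mu` is the linear
#' predictor of site `i` under species `k`'s coefficients and `eps` is the
#' optional overdispersion matrix (zero when disabled).
#'
#' @param site_data a `site_data` with standardized design matrix.
#' @param params a `species_params`.
#' @param noise optional n-sites x n-species overdispersion matrix.
#' @return n-sites x n-species matrix of occupancy probabilities in (0,1).
#' @export
psi_matrix <- function(site_data, params, noise = NULL) {
  Xf <- .design_full(site_data)
  mu <- Xf %*% params$delta
  if (!is.null(noise)) {
    stopifnot(all(dim(noise) == dim(mu)))
    mu <- mu + noise
  }
  stats::plogis(mu)
}

#' Marginal likelihood of one site-by-species cell
#'
#' Probability of observing the species on `y` of the `J` replicates of a
#' site, with the latent presence state summed out:
#' `psi * choose(J, y) * p^y * (1-p)^(J-y) + (1-psi) * 1[y == 0]`.
#' Vectorized over all arguments.
#'
#' @param y detections (0..J).
#' @param J replicates at the site (>= y).
#' @param psi occupancy probability.
#' @param p per-replicate detection probability.
#' @return the marginal probability.
#' @export
site_species_marglik <- function(y, J, psi, p) {
  if (any(y < 0) || any(y > J)) stop("y must satisfy 0 <= y <= J")
  if (any(psi < 0 | psi > 1) || any(p < 0 | p > 1)) {
    stop("psi and p must lie in [0, 1]")
  }
  psi * stats::dbinom(y, J, p) + (1 - psi) * as.numeric(y == 0)
}

#' Marginal log-likelihood of the full detection matrix
#'
#' Sum over sites and species of the log marginal likelihood of
#' `Ysum[i, k]` given `J[i]`, `psi[i, k]` and `p_k`.  Returns `-Inf` (with
#' a warning) when any cell has probability zero.
#'
#' @inheritParams psi_matrix
#' @return the total log-likelihood (scalar; `-Inf` if degenerate).
#' @export
total_loglik <- function(site_data, params, noise = NULL) {
  psi <- psi_matrix(site_data, params, noise)
  N <- nrow(psi); K <- ncol(psi)
  P <- matrix(stats::plogis(params$lp), N, K, byrow = TRUE)
  Jm <- matrix(site_data$J, N, K)
  lik <- psi * stats::dbinom(site_data$Ysum, Jm, P) +
    (1 - psi) * (site_data$Ysum == 0)
  if (any(lik == 0)) {
    warning("zero-probability cell(s); log-likelihood is -Inf")
    return(-Inf)
  }
  sum(log(lik))
}

#' Full conditional of the latent presence state
#'
#' `P(z = 1 | y, J, psi, p)`: equals 1 whenever the species was detected
#' (`y > 0`); otherwise `psi (1-p)^J / (psi (1-p)^J + 1 - psi)`.  The
#' degenerate corner `psi = 1, p = 1, y = 0` returns the limit 1.
#' Vectorized.
#'
#' @inheritParams site_species_marglik
#' @return probability that the species is present.
#' @export
z_full_conditional <- function(y, J, psi, p) {
  if (any(y < 0) || any(y > J)) stop("y must satisfy 0 <= y <= J")
  num <- psi * (1 - p)^J
  den <- num + (1 - psi)
  out <- ifelse(den == 0, 1, num / den)
  out[y > 0] <- 1
  out
}

#' Log-density of the hierarchical priors
#'
#' Normal random-effect log-densities of every species coefficient and
#' logit detection given the community hyperparameters, plus the hyperprior
#' log-densities (Normal hypermeans, Uniform hyper-sds).
#'
#' @param params a `species_params`.
#' @param hyper a `hyper_params`.
#' @param priors a [prior_config()].
#' @return the summed log prior density.
#' @export
log_prior <- function(params, hyper, priors = prior_config()) {
  lp <- sum(stats::dnorm(params$delta, hyper$mu_delta, hyper$sigma_delta,
                         log = TRUE)) +
    sum(stats::dnorm(params$lp, hyper$mu_lp, hyper$sigma_lp, log = TRUE))
  lp <- lp +
    sum(stats::dnorm(c(hyper$mu_delta, hyper$mu_lp), 0, priors$mu_sd,
                     log = TRUE)) +
    sum(stats::dunif(c(hyper$sigma_delta, hyper$sigma_lp), 0,
                     priors$sigma_upper, log = TRUE))
  lp
}
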