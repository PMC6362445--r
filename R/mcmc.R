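#' @title Bespoke MCMC for the community occupancy model
#' @description Data-augmented Gibbs sampler: the latent presence matrix z
#'   is drawn from its exact full conditional, species-level coefficient
#'   blocks move by random-walk Metropolis (one block per species, adapted
#'   during burn-in only), and community hyperparameters are conjugate
#'   Gibbs draws (Normal means; truncated inverse-gamma variances matching
#'   the Uniform sd prior).
#' @name commocc-mcmc
NULL

# deterministic per-chain stream seed, kept under 2^31
.derive_seed <- function(seed, chain_id) {
  as.integer((as.double(seed) %% 1000000L) * 2011L + chain_id * 7919L + 1L)
}

# per-chain constants: full design, detection matrix, replicate counts
.preamble <- function(site_data) {
  Xf <- .design_full(site_data)
  N <- nrow(site_data$Ysum); K <- ncol(site_data$Ysum)
  Jm <- matrix(site_data$J, N, K)
  list(Xf = Xf, N = N, K = K, Y = site_data$Ysum, J = site_data$J,
       Jm = Jm, JmY = Jm - site_data$Ysum, obs = site_data$Ysum > 0,
       Y0 = (site_data$Ysum == 0) + 0)
}

# log(1 + exp(x)) without overflow
.log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# occupancy linear predictor including overdispersion, from the cache
.mu_eff <- function(state) {
  if (is.null(state$eps)) state$MU else state$MU + state$eps
}

#' Initialize one chain
#'
#' Latent z starts at 1 wherever the species was detected and Bernoulli(0.5)
#' elsewhere; coefficients start from dispersed random draws so chains are
#' overdispersed relative to the posterior.  Fully reproducible from
#' `(seed, chain_id)`.
#'
#' @param site_data a `site_data` with standardized design matrix.
#' @param config a [run_config()].
#' @param chain_id integer chain index (1-based).
#' @param init optional named list overriding initial values (`delta`,
#'   `lp`, `z`, `mu_delta`, `sigma_delta`, `mu_lp`, `sigma_lp`, `eps`,
#'   `sigma_lpsi`).
#' @return a `chain_state` list.
#' @export
init_state <- function(site_data, config, chain_id, init = NULL) {
  pre <- .preamble(site_data)
  set.seed(.derive_seed(config$seed, chain_id))
  K <- pre$K; N <- pre$N
  mu_delta <- stats::rnorm(6, 0, 1)
  sigma_delta <- stats::runif(6, 0.5, 2)
  mu_lp <- stats::rnorm(1, 0, 1)
  sigma_lp <- stats::runif(1, 0.5, 2)
  delta <- matrix(stats::rnorm(6 * K, mu_delta, sigma_delta), 6, K)
  # centre the intercept and detection starts on naive empirical rates,
  # keeping chain-specific overdispersed jitter around them
  naive_psi <- pmin(pmax(colMeans(pre$obs), 0.05), 0.95)
  det_reps <- pmax(colSums(pre$Jm * pre$obs), 1)
  naive_p <- pmin(pmax(colSums(pre$Y) / det_reps, 0.05), 0.95)
  delta[1, ] <- stats::qlogis(naive_psi) + stats::rnorm(K, 0, 1)
  lp <- stats::qlogis(naive_p) + stats::rnorm(K, 0, 1)
  z <- matrix(as.numeric(pre$obs | (stats::runif(N * K) < 0.5)), N, K)
  eps <- NULL; sigma_lpsi <- 0
  if (config$overdispersion) {
    sigma_lpsi <- stats::runif(1, 0.2, 1)
    eps <- matrix(stats::rnorm(N * K, 0, sigma_lpsi), N, K)
  }
  state <- list(z = z, delta = delta, lp = lp,
                mu_delta = mu_delta, sigma_delta = sigma_delta,
                mu_lp = mu_lp, sigma_lp = sigma_lp,
                eps = eps, sigma_lpsi = sigma_lpsi,
                step_delta = rep(0.1, K), step_lp = rep(0.4, K),
                step_marg = rep(0.3, K), step_eps = 0.5,
                acc_delta = rep(0, K), acc_lp = rep(0, K),
                acc_marg = rep(0, K), n_acc = 0,
                chain_id = chain_id, iteration = 0L)
  if (!is.null(init)) {
    for (nm in names(init)) state[[nm]] <- init[[nm]]
    if (!is.null(init$z)) state$z <- matrix(as.numeric(init$z), N, K)
  }
  state$z[pre$obs] <- 1
  state$MU <- pre$Xf %*% state$delta
  structure(state, class = "chain_state")
}

#' Gibbs update of the latent presence matrix
#'
#' Every `z[i, k]` is redrawn from its exact full conditional
#' `P(z = 1 | y = 0) = psi (1-p)^J / (psi (1-p)^J + 1 - psi)`; cells with
#' at least one detection stay occupied.
#'
#' @param state a `chain_state`.
#' @param site_data the `site_data` the chain is fitted to.
#' @return the updated `chain_state`.
#' @export
update_z <- function(state, site_data) {
  .update_z_pre(.fresh_mu(state, .preamble(site_data)),
                .preamble(site_data))
}

# refresh the cached linear predictor (used by the exported single-step
# wrappers, whose callers may have modified delta directly)
.fresh_mu <- function(state, pre) {
  state$MU <- pre$Xf %*% state$delta
  state
}

.update_z_pre <- function(state, pre) {
  psi <- stats::plogis(.mu_eff(state))
  p <- stats::plogis(state$lp)
  # (1-p)^J as exp(J * log(1-p)), J varying by row and p by column
  q <- exp(outer(pre$J, log1p(-pmin(p, 1 - 1e-15))))
  num <- psi * q
  pz <- num / (num + (1 - psi))
  pz[!is.finite(pz)] <- 1   # psi = 1 and p = 1 corner: limit is 1
  z <- stats::runif(pre$N * pre$K) < pz
  z[pre$obs] <- TRUE
  state$z <- matrix(as.numeric(z), pre$N, pre$K)
  state
}

# per-species Bernoulli(z | psi) log-likelihood for a given predictor
# matrix: sum_i [z mu - log(1 + e^mu)]
.bern_ll <- function(MU, z) colSums(z * MU) - colSums(.log1pexp(MU))

#' Metropolis update of the species-level parameters
#'
#' One random-walk block per species for the six occupancy coefficients and
#' one for the logit detection probability; acceptance uses the exact
#' conditional posterior given z and the hyperparameters (the detection
#' block reduces to the sufficient statistics `sum_i z y` and
#' `sum_i z (J - y)`).  Step sizes adapt (Robbins-Monro toward ~35%
#' acceptance) only while `adapting = TRUE`, i.e. during burn-in.
#'
#' @inheritParams update_z
#' @param adapting adapt step sizes this iteration (burn-in only).
#' @return the updated `chain_state`.
#' @export
update_species_params <- function(state, site_data, adapting = FALSE) {
  pre <- .preamble(site_data)
  .update_species_pre(.fresh_mu(state, pre), pre, adapting)
}

.update_species_pre <- function(state, pre, adapting,
                                do_delta = TRUE, do_lp = TRUE) {
  K <- pre$K
  gain <- if (adapting) min(0.5, 2 / sqrt(max(state$iteration, 1))) else 0

  if (do_delta) {
    prop <- state$delta +
      matrix(stats::rnorm(6 * K), 6, K) * rep(state$step_delta, each = 6)
    MUp <- pre$Xf %*% prop
    cur_eff <- .mu_eff(state)
    prop_eff <- if (is.null(state$eps)) MUp else MUp + state$eps
    ll0 <- .bern_ll(cur_eff, state$z) +
      colSums(stats::dnorm(state$delta, state$mu_delta, state$sigma_delta,
                           log = TRUE))
    ll1 <- .bern_ll(prop_eff, state$z) +
      colSums(stats::dnorm(prop, state$mu_delta, state$sigma_delta,
                           log = TRUE))
    acc <- log(stats::runif(K)) < (ll1 - ll0)
    state$delta[, acc] <- prop[, acc]
    state$MU[, acc] <- MUp[, acc]
    state$acc_delta <- state$acc_delta + acc
    if (adapting) {
      state$step_delta <- state$step_delta *
        exp(gain * (as.numeric(acc) - 0.35))
    }
  }

  if (do_lp) {
    # sufficient statistics of the Binomial detection likelihood over
    # currently occupied sites
    s1 <- colSums(state$z * pre$Y)
    s2 <- colSums(state$z * pre$JmY)
    lp_ll <- function(lp) {
      p <- pmin(pmax(stats::plogis(lp), 1e-15), 1 - 1e-15)
      s1 * log(p) + s2 * log1p(-p) +
        stats::dnorm(lp, state$mu_lp, state$sigma_lp, log = TRUE)
    }
    prop_lp <- state$lp + stats::rnorm(K) * state$step_lp
    acc2 <- log(stats::runif(K)) < (lp_ll(prop_lp) - lp_ll(state$lp))
    state$lp[acc2] <- prop_lp[acc2]
    state$acc_lp <- state$acc_lp + acc2
    if (adapting) {
      state$step_lp <- state$step_lp * exp(gain * (as.numeric(acc2) - 0.35))
    }
  }
  state$n_acc <- state$n_acc + 1
  state
}

# per-species log marginal likelihood (latent z summed out, binomial
# coefficient dropped as it cancels in Metropolis ratios):
# sum_i log[ psi p^y (1-p)^(J-y) + (1-psi) 1{y=0} ]
.marg_ll <- function(MU, lp, pre) {
  psi <- stats::plogis(MU)
  p <- pmin(pmax(stats::plogis(lp), 1e-15), 1 - 1e-15)
  Lp <- matrix(log(p), pre$N, pre$K, byrow = TRUE)
  L1p <- matrix(log1p(-p), pre$N, pre$K, byrow = TRUE)
  lik <- psi * exp(pre$Y * Lp + pre$JmY * L1p) + (1 - psi) * pre$Y0
  colSums(log(lik))
}

# joint (delta_k, lp_k) random-walk move against the z-marginalized
# likelihood; the latent matrix is redrawn from its full conditional
# immediately afterwards in the sweep, making the pair a valid
# partially-collapsed block.  This move crosses the occupancy/detection
# ridge that the conditional blocks traverse slowly.
.update_marginal_pre <- function(state, pre, adapting) {
  K <- pre$K
  gain <- if (adapting) min(0.5, 2 / sqrt(max(state$iteration, 1))) else 0
  e <- matrix(stats::rnorm(7 * K), 7, K) * rep(state$step_marg, each = 7)
  prop_delta <- state$delta + e[1:6, , drop = FALSE]
  prop_lp <- state$lp + e[7, ]
  MUp <- pre$Xf %*% prop_delta
  cur_eff <- .mu_eff(state)
  prop_eff <- if (is.null(state$eps)) MUp else MUp + state$eps
  ll0 <- .marg_ll(cur_eff, state$lp, pre) +
    colSums(stats::dnorm(state$delta, state$mu_delta, state$sigma_delta,
                         log = TRUE)) +
    stats::dnorm(state$lp, state$mu_lp, state$sigma_lp, log = TRUE)
  ll1 <- .marg_ll(prop_eff, prop_lp, pre) +
    colSums(stats::dnorm(prop_delta, state$mu_delta, state$sigma_delta,
                         log = TRUE)) +
    stats::dnorm(prop_lp, state$mu_lp, state$sigma_lp, log = TRUE)
  acc <- log(stats::runif(K)) < (ll1 - ll0)
  state$delta[, acc] <- prop_delta[, acc]
  state$MU[, acc] <- MUp[, acc]
  state$lp[acc] <- prop_lp[acc]
  state$acc_marg <- state$acc_marg + acc
  if (adapting) {
    state$step_marg <- state$step_marg * exp(gain * (as.numeric(acc) - 0.25))
  }
  state
}

# sd draw: Uniform(0, upper) prior on sigma => p(v) ~ v^(-1/2) on the
# variance, conjugate with the Normal likelihood: v | . ~
# InvGamma((K-1)/2, SS/2) truncated to v < upper^2, sampled by inverse CDF
# on the precision.
.draw_sigma <- function(values, mu, upper, current) {
  K <- length(values)
  if (K < 2) return(current)
  SS <- max(sum((values - mu)^2), 1e-300)
  a <- (K - 1) / 2
  b <- SS / 2
  tau_min <- 1 / upper^2
  plo <- stats::pgamma(tau_min, a, rate = b)
  u <- stats::runif(1, plo, 1)
  tau <- stats::qgamma(min(u, 1 - 1e-16), a, rate = b)
  1 / sqrt(max(tau, tau_min))
}

#' Conjugate Gibbs update of the community hyperparameters
#'
#' Given the species-level values, each community mean is a Normal draw
#' (Normal prior) and each community sd a truncated inverse-gamma draw on
#' the variance scale (Uniform sd prior).
#'
#' @inheritParams update_z
#' @param config a [run_config()] (for the prior settings).
#' @return the updated `chain_state`.
#' @export
update_hyper <- function(state, config) {
  pr <- config$priors
  K <- length(state$lp)
  s0sq <- pr$mu_sd^2
  for (m in 1:6) {
    v <- state$delta[m, ]
    sig2 <- state$sigma_delta[m]^2
    pv <- 1 / (K / sig2 + 1 / s0sq)
    state$mu_delta[m] <- stats::rnorm(1, pv * sum(v) / sig2, sqrt(pv))
    state$sigma_delta[m] <- .draw_sigma(v, state$mu_delta[m],
                                        pr$sigma_upper,
                                        state$sigma_delta[m])
  }
  sig2 <- state$sigma_lp^2
  pv <- 1 / (K / sig2 + 1 / s0sq)
  state$mu_lp <- stats::rnorm(1, pv * sum(state$lp) / sig2, sqrt(pv))
  state$sigma_lp <- .draw_sigma(state$lp, state$mu_lp, pr$sigma_upper,
                                state$sigma_lp)
  state
}

# elementwise Metropolis update of the overdispersion matrix, then a
# truncated inverse-gamma draw of its sd
.update_eps <- function(state, pre, config, adapting) {
  cur <- state$eps
  prop <- cur + state$step_eps * matrix(stats::rnorm(pre$N * pre$K),
                                        pre$N, pre$K)
  tgt <- function(e) {
    MU <- state$MU + e
    state$z * MU - .log1pexp(MU) +
      stats::dnorm(e, 0, state$sigma_lpsi, log = TRUE)
  }
  acc <- matrix(log(stats::runif(pre$N * pre$K)), pre$N, pre$K) <
    (tgt(prop) - tgt(cur))
  cur[acc] <- prop[acc]
  state$eps <- cur
  if (adapting) {
    state$step_eps <- state$step_eps * exp(
      min(0.5, 2 / sqrt(max(state$iteration, 1))) * (mean(acc) - 0.35))
  }
  state$sigma_lpsi <- .draw_sigma(as.vector(cur), 0,
                                  config$priors$sigma_upper,
                                  state$sigma_lpsi)
  state
}

.par_names <- function(K, overdispersion) {
  c(sprintf("delta[%d,%d]", rep(0:5, K), rep(seq_len(K), each = 6)),
    sprintf("lp[%d]", seq_len(K)),
    sprintf("mu_delta[%d]", 0:5), sprintf("sigma_delta[%d]", 0:5),
    "mu_lp", "sigma_lp",
    if (overdispersion) "sigma_lpsi")
}

.state_vector <- function(state, overdispersion) {
  c(as.vector(state$delta), state$lp,
    state$mu_delta, state$sigma_delta, state$mu_lp, state$sigma_lp,
    if (overdispersion) state$sigma_lpsi)
}

#' Fit the community occupancy model by MCMC
#'
#' Runs `n_chains` independent chains of the sweep (z update, species
#' blocks, hyperparameters, optional overdispersion), discards burn-in,
#' applies thinning, and retains all scalar parameters plus per-site
#' richness draws `Nsite[i] = sum_k z[i, k]` (when `store_z`).  Bit-wise
#' reproducible from the seed.
#'
#' @param site_data a `site_data` with standardized design matrix.
#' @param config a [run_config()].
#' @param init optional list of initial-value overrides passed to
#'   [init_state()] (applied to every chain).
#' @param verbose print per-chain progress.
#' @return an `occ_draws` object: `draws` is a list (one matrix per chain,
#'   retained iterations x named parameters), `nsite` the per-chain
#'   richness draw matrices (or `NULL`), `meta` the run metadata including
#'   mean Metropolis acceptance rates.
#' @export
run_chains <- function(site_data, config, init = NULL, verbose = FALSE) {
  stopifnot(inherits(site_data, "site_data"), inherits(config, "run_config"))
  pre <- .preamble(site_data)
  keep <- n_retained(config)
  if (keep < 1) stop("no retained draws; check n_iter/n_burnin/thin")
  pnames <- .par_names(pre$K, config$overdispersion)
  upd <- config$update

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))

  draws <- vector("list", config$n_chains)
  nsite <- if (config$store_z) vector("list", config$n_chains) else NULL
  accept <- vector("list", config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    state <- init_state(site_data, config, ch, init = init)
    mat <- matrix(NA_real_, keep, length(pnames),
                  dimnames = list(NULL, pnames))
    nmat <- if (config$store_z) matrix(NA_real_, keep, pre$N) else NULL
    r <- 0L
    for (it in seq_len(config$n_iter)) {
      state$iteration <- it
      adapting <- config$adapt && it <= config$n_burnin
      if (upd$species || upd$lp) {
        state <- .update_species_pre(state, pre, adapting,
                                     do_delta = upd$species,
                                     do_lp = upd$lp)
      }
      # the partially-collapsed joint move must be followed directly by
      # the z redraw so the (parameters, z) pair stays a joint draw
      if (upd$marg && upd$species && upd$lp && upd$z) {
        state <- .update_marginal_pre(state, pre, adapting)
      }
      if (upd$z) state <- .update_z_pre(state, pre)
      if (upd$hyper) state <- update_hyper(state, config)
      if (config$overdispersion && upd$eps) {
        state <- .update_eps(state, pre, config, adapting)
      }
      if (it > config$n_burnin &&
          (it - config$n_burnin) %% config$thin == 0 && r < keep) {
        r <- r + 1L
        mat[r, ] <- .state_vector(state, config$overdispersion)
        if (config$store_z) nmat[r, ] <- rowSums(state$z)
      }
    }
    draws[[ch]] <- mat
    if (config$store_z) nsite[[ch]] <- nmat
    accept[[ch]] <- c(delta = mean(state$acc_delta) / max(state$n_acc, 1),
                      lp = mean(state$acc_lp) / max(state$n_acc, 1),
                      marg = mean(state$acc_marg) / max(state$n_acc, 1))
    if (verbose) {
      message(sprintf(
        "chain %d: %d retained draws, acc(delta)=%.2f acc(lp)=%.2f",
        ch, r, accept[[ch]]["delta"], accept[[ch]]["lp"]))
    }
  }

  structure(list(
    draws = draws, nsite = nsite,
    meta = list(n_chains = config$n_chains, n_iter = config$n_iter,
                n_burnin = config$n_burnin, thin = config$thin,
                seed = config$seed, priors = unclass(config$priors),
                overdispersion = config$overdispersion,
                species_ids = site_data$species_ids,
                n_sites = pre$N,
                cell_size_arcsec = site_data$cell_size_arcsec,
                accept = accept)),
    class = "occ_draws")
}

#' @export
print.occ_draws <- function(x, ...) {
  cat(sprintf(
    "Posterior draws: %d chain(s) x %d retained iterations, %d parameters\n",
    length(x$draws), nrow(x$draws[[1]]), ncol(x$draws[[1]])))
  cat(sprintf("  %d species, %d sites (%g\" cells); richness draws %s\n",
              length(x$meta$species_ids), x$meta$n_sites,
              x$meta$cell_size_arcsec %||% NA,
              if (is.null(x$nsite)) "not stored" else "stored"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (whole-chain) diagnostic: with `W` the mean within-chain sample
#' variance and `B/n` the variance of the chain means,
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)`.  `split = TRUE` first splits
#' every chain in half (the modern variant).  Values near 1 indicate
#' convergence.
#'
#' @param draws an `occ_draws`, or a list of numeric vectors (one per
#'   chain).
#' @param parameter parameter name (when `draws` is an `occ_draws`).
#' @param split use split chains.
#' @return the Rhat value; `NA` (with a warning) when all chains have zero
#'   within-chain variance.
#' @export
rhat <- function(draws, parameter = NULL, split = FALSE) {
  chains <- if (inherits(draws, "occ_draws")) {
    if (is.null(parameter)) stop("give a parameter name")
    lapply(draws$draws, function(m) m[, parameter])
  } else {
    draws
  }
  if (split) {
    chains <- unlist(lapply(chains, function(v) {
      h <- length(v) %/% 2
      list(v[seq_len(h)], v[(h + 1):(2 * h)])
    }), recursive = FALSE)
  }
  m <- length(chains)
  if (m < 2) stop("need at least two chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 4) stop("need at least 4 draws per chain")
  W <- mean(vapply(chains, stats::var, 0))
  B_n <- stats::var(vapply(chains, mean, 0))
  if (W == 0) {
    warning("degenerate chains: zero within-chain variance")
    return(NA_real_)
  }
  sqrt(((n - 1) / n * W + B_n) / W)
}

#' Rhat for many parameters at once
#'
#' @param draws an `occ_draws`.
#' @param parameters parameter names; defaults to all.
#' @param threshold flag parameters with Rhat above this value.
#' @inheritParams rhat
#' @return data.frame with `parameter`, `rhat`, `flagged`.
#' @export
rhat_all <- function(draws, parameters = NULL, split = FALSE,
                     threshold = 1.1) {
  stopifnot(inherits(draws, "occ_draws"))
  if (is.null(parameters)) parameters <- colnames(draws$draws[[1]])
  r <- vapply(parameters, function(p)
    suppressWarnings(rhat(draws, p, split = split)), 0)
  data.frame(parameter = parameters, rhat = r,
             flagged = !is.na(r) & r > threshold, row.names = NULL)
}
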