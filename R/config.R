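#' Prior settings for the community model
#'
#' Weakly-informative defaults for logit-scale community models: Normal
#' hypermeans with sd 2.25 (roughly uniform on the probability scale after
#' the inverse logit) and Uniform(0, `sigma_upper`) hyper-sds.
#'
#' @param mu_sd sd of the Normal(0, mu_sd) prior on every hypermean.
#' @param sigma_upper upper bound of the Uniform(0, upper) prior on every
#'   hyper-sd.
#' @return a `prior_config` list.
#' @export
prior_config <- function(mu_sd = 2.25, sigma_upper = 5) {
  stopifnot(mu_sd > 0, sigma_upper > 0)
  structure(list(mu_sd = mu_sd, sigma_upper = sigma_upper),
            class = "prior_config")
}

#' MCMC / analysis run configuration
#'
#' Defaults mirror a standard community-occupancy fit: 3 chains of 15,000
#' iterations, burn-in 5,000, thinning 2 (5,000 retained draws per chain).
#'
#' @param cell_size_arcsec analysis grid cell size in arc-seconds
#'   (60 = the 2x2, 90 = the 3x3 aggregation scheme).
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations discarded per chain.
#' @param thin thinning interval applied after burn-in.
#' @param seed integer master seed; per-chain streams are derived from
#'   (seed, chain id).
#' @param priors a [prior_config()].
#' @param overdispersion enable the optional site-by-species logit-normal
#'   occupancy overdispersion term (single sd, default off).
#' @param store_z retain per-iteration site richness draws (needed for the
#'   richness summary).
#' @param adapt adapt Metropolis step sizes during burn-in (Robbins-Monro,
#'   target acceptance ~0.35); never adapts after burn-in.
#' @param update named list of logical toggles (`z`, `species`, `lp`,
#'   `marg`, `hyper`, `eps`) enabling individual sampler blocks; all
#'   `TRUE` by default (`marg` is the partially-collapsed joint
#'   occupancy/detection move, active only when `species`, `lp` and `z`
#'   all update).  Fixing a block is mainly useful for validation studies.
#' @return a `run_config` list.
#' @export
run_config <- function(cell_size_arcsec = 60, n_chains = 3,
                       n_iter = 15000, n_burnin = 5000, thin = 2,
                       seed = 1, priors = prior_config(),
                       overdispersion = FALSE, store_z = TRUE,
                       adapt = TRUE, update = list()) {
  stopifnot(cell_size_arcsec > 0, n_chains >= 1, thin >= 1,
            n_burnin >= 0, n_burnin < n_iter)
  upd <- list(z = TRUE, species = TRUE, lp = TRUE, marg = TRUE,
              hyper = TRUE, eps = TRUE)
  upd[names(update)] <- update
  structure(list(cell_size_arcsec = cell_size_arcsec,
                 n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin),
                 seed = as.integer(seed),
                 priors = priors,
                 overdispersion = isTRUE(overdispersion),
                 store_z = isTRUE(store_z),
                 adapt = isTRUE(adapt),
                 update = upd),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return for the reader, a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  pr <- if (!is.null(x$priors)) do.call(prior_config, x$priors)
        else prior_config()
  x$priors <- pr
  do.call(run_config, x)
}

#' @rdname read_run_config
#' @param config a `run_config` to serialize.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$priors <- unclass(x$priors)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Number of retained posterior draws per chain
#'
#' `floor((n_iter - n_burnin) / thin)`: e.g. 15,000 iterations with burn-in
#' 5,000 and thin 2 retain 5,000 draws per chain.
#'
#' @param config a `run_config`.
#' @return integer count of retained draws per chain.
#' @export
n_retained <- function(config) {
  as.integer((config$n_iter - config$n_burnin) %/% config$thin)
}
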