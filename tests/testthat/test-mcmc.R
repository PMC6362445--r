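test_that("chain initialization is reproducible, dispersed and z-consistent", {
  study <- simulate_study(sim_config(seed = 4, n_transects = 50,
                                     n_species = 6))
  cfg <- run_config(seed = 11, n_iter = 10, n_burnin = 2, thin = 1)
  s1 <- init_state(study$site_data, cfg, chain_id = 1)
  s1b <- init_state(study$site_data, cfg, chain_id = 1)
  s2 <- init_state(study$site_data, cfg, chain_id = 2)
  expect_identical(s1$delta, s1b$delta)
  expect_identical(s1$lp, s1b$lp)
  expect_false(isTRUE(all.equal(s1$delta, s2$delta)))
  expect_true(all(s1$z[study$site_data$Ysum > 0] == 1))
})

test_that("retention arithmetic is exact", {
  expect_equal(n_retained(run_config(n_iter = 15000, n_burnin = 5000,
                                     thin = 2)), 5000L)
  expect_equal(n_retained(run_config(n_iter = 3000, n_burnin = 1000,
                                     thin = 1)), 2000L)
  expect_equal(n_retained(run_config(n_iter = 101, n_burnin = 1,
                                     thin = 10)), 10L)
})

test_that("the sampler is bit-wise reproducible from the seed", {
  study <- simulate_study(sim_config(seed = 6, n_transects = 40,
                                     n_species = 5))
  cfg <- run_config(n_chains = 2, n_iter = 80, n_burnin = 30, thin = 2,
                    seed = 123)
  f1 <- run_chains(study$site_data, cfg)
  f2 <- run_chains(study$site_data, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$nsite, f2$nsite)
  expect_equal(nrow(f1$draws[[1]]), 25L)  # floor(50 / 2)
})

test_that("Gibbs z draws match the full conditional frequency", {
  # one empty cell with psi = 0.5, p = 0.5, J = 2: P(z = 1 | y = 0) = 0.2
  sd1 <- toy_site_data(matrix(0L, 1, 1), J = 2)
  cfg <- run_config(n_chains = 1, n_iter = 1e5, n_burnin = 0, thin = 1,
                    seed = 5, adapt = FALSE,
                    update = list(species = FALSE, lp = FALSE,
                                  hyper = FALSE))
  fit <- run_chains(sd1, cfg,
                    init = list(delta = matrix(c(0, 0, 0, 0, 0, 0), 6, 1),
                                lp = 0))
  pz <- mean(fit$nsite[[1]][, 1])
  mc_err <- sqrt(0.2 * 0.8 / 1e5)
  expect_lt(abs(pz - 0.2), 4 * mc_err)

  # certain detection: with p = 1 an undetected species is never present
  fit2 <- run_chains(sd1, cfg,
                     init = list(delta = matrix(c(0, 0, 0, 0, 0, 0), 6, 1),
                                 lp = 40))
  expect_equal(max(fit2$nsite[[1]]), 0)

  # detections pin z at one
  sd2 <- toy_site_data(matrix(1L, 1, 1), J = 2)
  fit3 <- run_chains(sd2, run_config(n_chains = 1, n_iter = 200,
                                     n_burnin = 0, thin = 1, seed = 2),
                     init = NULL)
  expect_equal(min(fit3$nsite[[1]]), 1)
})

test_that("vanishing proposal steps are always accepted", {
  study <- simulate_study(sim_config(seed = 9, n_transects = 40,
                                     n_species = 5))
  cfg <- run_config(n_chains = 1, n_iter = 50, n_burnin = 0, thin = 1,
                    seed = 3, adapt = FALSE)
  st <- init_state(study$site_data, cfg, 1)
  st$step_delta[] <- 1e-12
  st$step_lp[] <- 1e-12
  for (i in 1:50) {
    st$iteration <- i
    st <- update_species_params(st, study$site_data)
  }
  expect_gte(min(st$acc_delta / st$n_acc), 0.98)
  expect_gte(min(st$acc_lp / st$n_acc), 0.98)
})

test_that("a species with no occupied sites samples detection from its prior", {
  # psi forced ~0 so z = 0 everywhere: lp has no likelihood and its draws
  # must match the Normal(mu_lp, sigma_lp) random-effect prior
  sd1 <- toy_site_data(matrix(0L, 8, 2), J = rep(2, 8))
  cfg <- run_config(n_chains = 1, n_iter = 2e4, n_burnin = 0, thin = 1,
                    seed = 7, adapt = FALSE,
                    update = list(species = FALSE, hyper = FALSE))
  fit <- run_chains(sd1, cfg,
                    init = list(delta = matrix(rep(c(-30, 0, 0, 0, 0, 0), 2),
                                               6, 2),
                                lp = c(0, 0), mu_lp = 0.4, sigma_lp = 0.7,
                                step_lp = rep(1.5, 2)))
  lp_draws <- fit$draws[[1]][, "lp[1]"]
  expect_lt(abs(mean(lp_draws) - 0.4), 0.05)
  expect_lt(abs(sd(lp_draws) - 0.7), 0.05)
})

test_that("hypermean updates match the conjugate closed form", {
  # fixed species values and fixed sigma: mu | . ~ Normal(pv * sum/sig2, pv)
  # with pv = 1/(K/sig2 + 1/s0^2) -- the textbook Normal-mean posterior
  sd1 <- toy_site_data(matrix(0L, 2, 30), J = c(1, 1))
  cfg <- run_config(seed = 1, priors = prior_config(mu_sd = 2.25))
  st <- init_state(sd1, cfg, 1)
  vals <- seq(-1, 1, length.out = 30)
  st$delta[1, ] <- vals
  sig <- 0.9
  set.seed(42)
  mus <- numeric(2e4)
  for (r in seq_along(mus)) {
    st$sigma_delta[1] <- sig
    st$delta[1, ] <- vals
    st <- update_hyper(st, cfg)
    mus[r] <- st$mu_delta[1]
  }
  pv <- 1 / (30 / sig^2 + 1 / 2.25^2)
  expect_lt(abs(mean(mus) - pv * sum(vals) / sig^2), 4 * sqrt(pv / 2e4))
  expect_lt(abs(var(mus) - pv) / pv, 0.05)
  # sigma draws always respect the Uniform prior support
  set.seed(43)
  sigs <- numeric(2000)
  for (r in seq_along(sigs)) {
    st <- update_hyper(st, cfg)
    sigs[r] <- st$sigma_delta[1]
  }
  expect_true(all(sigs > 0 & sigs <= cfg$priors$sigma_upper))
})

test_that("a single-species community centres the hypermean on it", {
  sd1 <- toy_site_data(matrix(0L, 2, 1), J = c(1, 1))
  cfg <- run_config(seed = 1)
  st <- init_state(sd1, cfg, 1)
  set.seed(9)
  mus <- numeric(4000)
  for (r in seq_along(mus)) {
    st$delta[1, ] <- 1.7
    st$sigma_delta[1] <- 0.2
    st <- update_hyper(st, cfg)
    mus[r] <- st$mu_delta[1]
  }
  expect_lt(abs(mean(mus) - 1.7), 0.05)
})

test_that("Rhat follows the Brooks-Gelman formula", {
  # identical chains: B = 0, Rhat = sqrt((n-1)/n) < 1
  v <- c(0.3, 1.2, -0.5, 0.9, 0.1)
  expect_equal(rhat(list(v, v, v)), sqrt(4 / 5), tolerance = 1e-12)
  # hand-computed two-chain example: W = 5/3, B/n = 5000
  expect_equal(rhat(list(c(1, 2, 3, 4), c(101, 102, 103, 104))),
               sqrt(((3 / 4) * (5 / 3) + 5000) / (5 / 3)),
               tolerance = 1e-12)
  expect_equal(rhat(list(c(1, 2, 3, 4), c(101, 102, 103, 104))),
               54.78, tolerance = 1e-3)
  # degenerate chains are flagged, not a crash
  expect_warning(r <- rhat(list(rep(1, 5), rep(1, 5))), "degenerate")
  expect_true(is.na(r))
  expect_error(rhat(list(c(1, 2, 3, 4))), "two chains")
})

test_that("long well-mixed chains on a toy posterior converge by Rhat", {
  # well-identified toy: plenty of replicates per site, hyper fixed
  set.seed(61)
  Ysum <- matrix(rbinom(20 * 2, 6, 0.45 * 0.6), 20, 2)
  sd1 <- toy_site_data(Ysum, J = rep(6L, 20))
  cfg <- run_config(n_chains = 3, n_iter = 20000, n_burnin = 5000,
                    thin = 5, seed = 71, update = list(hyper = FALSE))
  fit <- run_chains(sd1, cfg,
                    init = list(mu_delta = rep(0, 6),
                                sigma_delta = rep(1.5, 6),
                                mu_lp = 0, sigma_lp = 1.5))
  rh <- rhat_all(fit, parameters = c("delta[0,1]", "delta[0,2]",
                                     "lp[1]", "lp[2]"))
  expect_true(all(rh$rhat < 1.1))
})

test_that("MCMC matches the exact posterior on an enumerable toy", {
  # 2 sites x 2 species, fixed parameters: P(z = 1 | data) by enumeration
  Ysum <- matrix(c(0L, 0L, 2L, 1L), 2, 2)   # species 2 detected everywhere
  J <- c(2L, 2L)
  sd1 <- toy_site_data(Ysum, J)
  psi_true <- matrix(c(0.45, 0.45, 0.6, 0.6), 2, 2)
  p_true <- c(0.35, 0.5)
  delta <- rbind(qlogis(c(0.45, 0.6)), 0, 0, 0, 0, 0)
  cfg <- run_config(n_chains = 1, n_iter = 4e4, n_burnin = 0, thin = 1,
                    seed = 17, adapt = FALSE,
                    update = list(species = FALSE, lp = FALSE,
                                  hyper = FALSE))
  fit <- run_chains(sd1, cfg, init = list(delta = delta,
                                          lp = qlogis(p_true)))
  # species 2 is fixed at z = 1 by its detections, so Nsite_i - 1 = z_i1
  z1 <- fit$nsite[[1]] - 1
  for (i in 1:2) {
    want <- enum_pz(Ysum, J, psi_true, p_true, i, 1)
    expect_lt(abs(mean(z1[, i]) - want), 0.01)
  }
})
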