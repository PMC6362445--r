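# Fixtures and independent oracles shared across the test files.

# hand-built site_data: detection matrix + replicate counts, standardized
# design defaulting to all-zero covariates (an "average" site everywhere)
toy_site_data <- function(Ysum, J, X = NULL) {
  Ysum <- as.matrix(Ysum)
  storage.mode(Ysum) <- "integer"
  N <- nrow(Ysum)
  K <- ncol(Ysum)
  if (is.null(colnames(Ysum))) colnames(Ysum) <- sprintf("sp%02d", seq_len(K))
  if (is.null(X)) {
    X <- matrix(0, N, 5,
                dimnames = list(NULL,
                                c("FOREST", "FOREST2", "TEMP", "TEMP2",
                                  "PREC")))
  }
  structure(list(cells = data.frame(ix = seq_len(N), iy = 0L),
                 transect_ids = split(sprintf("t%03d", seq_len(sum(J))),
                                      rep(seq_len(N), J)),
                 J = as.integer(J),
                 species_ids = colnames(Ysum),
                 Ysum = Ysum,
                 cell_size_arcsec = 60,
                 covariates = NULL, X = X,
                 std = list(mean = c(FOREST = 0, TEMP = 0, PREC = 0),
                            sd = c(FOREST = 1, TEMP = 1, PREC = 1))),
            class = "site_data")
}

# exhaustive enumeration over all 2^(N*K) latent-presence configurations:
# log joint probability of the detection matrix
enum_loglik <- function(Ysum, J, psi, p) {
  N <- nrow(Ysum)
  K <- ncol(Ysum)
  states <- as.matrix(expand.grid(rep(list(0:1), N * K)))
  tot <- 0
  for (s in seq_len(nrow(states))) {
    z <- matrix(states[s, ], N, K)
    pr <- prod(ifelse(z == 1, psi, 1 - psi))
    for (i in seq_len(N)) {
      for (k in seq_len(K)) {
        pr <- pr * if (z[i, k] == 1) dbinom(Ysum[i, k], J[i], p[k])
                   else as.numeric(Ysum[i, k] == 0)
      }
    }
    tot <- tot + pr
  }
  log(tot)
}

# enumeration posterior P(z[i0, k0] = 1 | data) under fixed parameters
enum_pz <- function(Ysum, J, psi, p, i0, k0) {
  N <- nrow(Ysum)
  K <- ncol(Ysum)
  states <- as.matrix(expand.grid(rep(list(0:1), N * K)))
  num <- 0
  den <- 0
  for (s in seq_len(nrow(states))) {
    z <- matrix(states[s, ], N, K)
    pr <- prod(ifelse(z == 1, psi, 1 - psi))
    for (i in seq_len(N)) {
      for (k in seq_len(K)) {
        pr <- pr * if (z[i, k] == 1) dbinom(Ysum[i, k], J[i], p[k])
                   else as.numeric(Ysum[i, k] == 0)
      }
    }
    den <- den + pr
    if (z[i0, k0] == 1) num <- num + pr
  }
  num / den
}

# fine-grid quadrature CDF of the 1-D posterior of a species' occupancy
# intercept, all other parameters fixed and covariates at zero:
# target(d0) = N(d0; mu0, s0) * prod_i marglik(y_i | plogis(d0), p)
quad_delta0_cdf <- function(y, J, p, mu0, s0,
                            grid = seq(-12, 12, length.out = 20001)) {
  lp <- dnorm(grid, mu0, s0, log = TRUE)
  for (i in seq_along(y)) {
    psi <- plogis(grid)
    lp <- lp + log(psi * dbinom(y[i], J[i], p) +
                     (1 - psi) * as.numeric(y[i] == 0))
  }
  w <- exp(lp - max(lp))
  cdf <- cumsum(w) / sum(w)
  list(grid = grid, cdf = cdf)
}

# Kolmogorov-Smirnov distance between a sample and a tabulated CDF
ks_to_cdf <- function(x, grid, cdf) {
  f <- approxfun(grid, cdf, yleft = 0, yright = 1)
  xs <- sort(x)
  n <- length(xs)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  th <- f(xs)
  max(abs(emp_hi - th), abs(emp_lo - th))
}

# manual occ_draws builder for summary-level tests
manual_draws <- function(mats, species_ids, nsite = NULL, cell = 60,
                         n_sites = if (!is.null(nsite)) ncol(nsite[[1]]) else 1L) {
  structure(list(draws = mats, nsite = nsite,
                 meta = list(n_chains = length(mats),
                             species_ids = species_ids,
                             n_sites = n_sites,
                             cell_size_arcsec = cell)),
            class = "occ_draws")
}

# a constant-parameter draw matrix in the sampler's column layout
constant_draw_matrix <- function(delta, lp, mu_delta, sigma_delta,
                                 mu_lp, sigma_lp, n = 5) {
  K <- length(lp)
  v <- c(as.vector(delta), lp, mu_delta, sigma_delta, mu_lp, sigma_lp)
  nm <- c(sprintf("delta[%d,%d]", rep(0:5, K), rep(seq_len(K), each = 6)),
          sprintf("lp[%d]", seq_len(K)),
          sprintf("mu_delta[%d]", 0:5), sprintf("sigma_delta[%d]", 0:5),
          "mu_lp", "sigma_lp")
  matrix(rep(v, each = n), n, length(v), dimnames = list(NULL, nm))
}
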