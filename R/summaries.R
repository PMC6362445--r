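#' @title Posterior summaries
#' @description Derived quantities of a fitted community occupancy model:
#'   per-species detectability and mean occupancy, per-site richness,
#'   community response curves along environmental gradients, community
#'   means, and cross-scheme comparisons.
#' @name commocc-summaries
NULL

.stack_draws <- function(draws) {
  stopifnot(inherits(draws, "occ_draws"))
  do.call(rbind, draws$draws)
}

.n_species <- function(draws) length(draws$meta$species_ids)

# per-draw species mean occupancy psibar_k = mean_i psi[i,k]
# (rows: stacked retained draws over chains, columns: species)
.psibar_draws <- function(draws, site_data) {
  D <- .stack_draws(draws)
  K <- .n_species(draws)
  Xf <- .design_full(site_data)
  dcols <- sprintf("delta[%d,%d]", rep(0:5, K), rep(seq_len(K), each = 6))
  Dd <- D[, dcols, drop = FALSE]
  out <- matrix(NA_real_, nrow(D), K)
  for (r in seq_len(nrow(D))) {
    delta <- matrix(Dd[r, ], 6, K)
    out[r, ] <- colMeans(stats::plogis(Xf %*% delta))
  }
  colnames(out) <- draws$meta$species_ids
  out
}

#' Per-species posterior estimates
#'
#' For every retained draw computes each species' detection probability
#' `p_k = plogis(lp_k)` and across-site mean occupancy
#' `psibar_k = mean_i psi[i, k]`, then summarizes both by posterior mean
#' and sd.
#'
#' @param draws an `occ_draws` from [run_chains()].
#' @param site_data the `site_data` the model was fitted to.
#' @return a `species_summary` data.frame with columns `species_id`,
#'   `p_mean`, `p_sd`, `psi_mean`, `psi_sd`.
#' @export
species_estimates <- function(draws, site_data) {
  D <- .stack_draws(draws)
  K <- .n_species(draws)
  p_draws <- stats::plogis(D[, sprintf("lp[%d]", seq_len(K)), drop = FALSE])
  psibar <- .psibar_draws(draws, site_data)
  out <- data.frame(species_id = draws$meta$species_ids,
                    p_mean = colMeans(p_draws),
                    p_sd = apply(p_draws, 2, stats::sd),
                    psi_mean = colMeans(psibar),
                    psi_sd = apply(psibar, 2, stats::sd),
                    row.names = NULL)
  structure(out, class = c("species_summary", "data.frame"),
            cell_size_arcsec = draws$meta$cell_size_arcsec)
}

#' Per-site species richness
#'
#' Posterior mean and sd of `Nsite_i = sum_k z[i, k]` from the retained
#' richness draws, plus the community-level average over sites.  Because
#' detection implies presence, every draw satisfies `Nsite_i >= observed
#' richness at site i`.
#'
#' @param draws an `occ_draws` with stored richness draws
#'   (`store_z = TRUE` in the run configuration).
#' @param site_data optional; adds the observed species count per site.
#' @return a `richness_summary`: data.frame `sites` (`site`, `mean`, `sd`,
#'   optionally `observed`) with attributes `community_mean` (mean over
#'   sites of the posterior means) and `community_sd` (mean posterior sd).
#' @export
site_richness <- function(draws, site_data = NULL) {
  if (is.null(draws$nsite)) {
    stop("richness draws were not stored; re-run with store_z = TRUE")
  }
  NS <- do.call(rbind, draws$nsite)
  out <- data.frame(site = seq_len(ncol(NS)),
                    mean = colMeans(NS),
                    sd = apply(NS, 2, stats::sd))
  if (!is.null(site_data)) out$observed <- rowSums(site_data$Ysum > 0)
  structure(out, class = c("richness_summary", "data.frame"),
            community_mean = mean(out$mean),
            community_sd = mean(out$sd))
}

#' @export
print.richness_summary <- function(x, ...) {
  cat(sprintf("Site richness: %d sites; community size %.2f +/- %.2f species\n",
              nrow(x), attr(x, "community_mean"), attr(x, "community_sd")))
  invisible(x)
}

#' Community occupancy response curve
#'
#' Evaluates, for every retained draw, the community mean occupancy along
#' one standardized covariate:
#' `plogis(mu_delta0 + mu_lin * x + mu_quad * x^2)` (the quadratic term
#' exists for FOREST and TEMP only), with the other covariates held at
#' their standardized mean of 0; summarizes by posterior mean and a
#' central credible band.
#'
#' @param draws an `occ_draws`.
#' @param covariate `"FOREST"`, `"TEMP"` or `"PREC"`.
#' @param grid standardized covariate values at which to evaluate; default
#'   100 equally spaced points over the observed standardized range (from
#'   `site_data`) or `[-2, 2]`.
#' @param site_data optional, supplies the observed covariate range.
#' @param level credible level of the band (default 0.95).
#' @return a `response_curve` data.frame with `x`, `mean`, `lower`,
#'   `upper`.
#' @export
community_response_curve <- function(draws, covariate, grid = NULL,
                                     site_data = NULL, level = 0.95) {
  cols <- list(FOREST = c(1, 2), TEMP = c(3, 4), PREC = c(5, NA))
  if (!covariate %in% names(cols)) {
    stop("unknown covariate: ", covariate,
         " (expected FOREST, TEMP or PREC)")
  }
  idx <- cols[[covariate]]
  if (is.null(grid)) {
    rng <- if (!is.null(site_data)) range(site_data$X[, covariate])
           else c(-2, 2)
    grid <- seq(rng[1], rng[2], length.out = 100)
  }
  D <- .stack_draws(draws)
  mu0 <- D[, "mu_delta[0]"]
  mul <- D[, sprintf("mu_delta[%d]", idx[1])]
  eta <- outer(grid, mul) + matrix(mu0, length(grid), nrow(D), byrow = TRUE)
  if (!is.na(idx[2])) {
    muq <- D[, sprintf("mu_delta[%d]", idx[2])]
    eta <- eta + outer(grid^2, muq)
  }
  psi <- stats::plogis(eta)
  alpha <- (1 - level) / 2
  qs <- apply(psi, 1, stats::quantile, probs = c(alpha, 1 - alpha))
  out <- data.frame(x = grid, mean = rowMeans(psi),
                    lower = qs[1, ], upper = qs[2, ])
  structure(out, class = c("response_curve", "data.frame"),
            covariate = covariate, level = level)
}

#' Compare species estimates between aggregation schemes
#'
#' Pearson correlations, across species, of the posterior-mean detection
#' probabilities and posterior-mean occupancies of two fits of the same
#' community at different grid resolutions, plus the paired scatter table.
#'
#' @param summary_a,summary_b `species_summary` objects
#'   (from [species_estimates()]) over the same species set.
#' @return a `scheme_comparison`: list with `r_psi`, `r_p` and the paired
#'   `table`.
#' @export
compare_schemes <- function(summary_a, summary_b) {
  sa <- summary_a$species_id; sb <- summary_b$species_id
  if (!setequal(sa, sb)) {
    stop("species sets differ between schemes; only in A: ",
         paste(setdiff(sa, sb), collapse = ", "), "; only in B: ",
         paste(setdiff(sb, sa), collapse = ", "))
  }
  b <- summary_b[match(sa, sb), ]
  tab <- data.frame(species_id = sa,
                    psi_a = summary_a$psi_mean, psi_b = b$psi_mean,
                    p_a = summary_a$p_mean, p_b = b$p_mean)
  structure(list(r_psi = stats::cor(tab$psi_a, tab$psi_b),
                 r_p = stats::cor(tab$p_a, tab$p_b),
                 table = tab),
            class = "scheme_comparison")
}

#' @export
print.scheme_comparison <- function(x, ...) {
  cat(sprintf("Cross-scheme correlation over %d species: r(psi) = %.3f, r(p) = %.3f\n",
              nrow(x$table), x$r_psi, x$r_p))
  invisible(x)
}

#' Community mean occupancy and detectability
#'
#' Two definitions, both reported: (`hypermean`) the posterior means of
#' `plogis(mu_delta0)` and `plogis(mu_lp)` — the inverse-logit community
#' hypermeans, i.e. the typical species at an average site; (`average`)
#' the posterior means of the across-species (and across-sites, for
#' occupancy) averages of the probabilities themselves.  The two differ
#' under species heterogeneity (Jensen's inequality).
#'
#' @inheritParams species_estimates
#' @return list with numeric `hypermean` and `average`, each
#'   `c(psi = , p = )`.
#' @export
community_means <- function(draws, site_data) {
  D <- .stack_draws(draws)
  K <- .n_species(draws)
  p_draws <- stats::plogis(D[, sprintf("lp[%d]", seq_len(K)), drop = FALSE])
  psibar <- .psibar_draws(draws, site_data)
  list(hypermean = c(psi = mean(stats::plogis(D[, "mu_delta[0]"])),
                     p = mean(stats::plogis(D[, "mu_lp"]))),
       average = c(psi = mean(psibar), p = mean(p_draws)))
}
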