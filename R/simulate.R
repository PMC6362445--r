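#' @title Synthetic community occupancy studies
#' @description Generates complete studies with known truth — smooth
#'   covariate landscapes, clustered transect placement, a community of
#'   species drawn from Normal random effects, latent presence per grid
#'   cell and Bernoulli detections per transect — emulating the structure
#'   of a regional forest-bird census: a few hundred 1-km transects over a
#'   ~1.5 degree region, 50-80 species of heterogeneous occupancy and
#'   detectability, 1-7 transects per occupied cell.
#' @name commocc-simulate
NULL

#' Default true community hyperparameters for simulation
#'
#' Chosen so that at the generator's default landscape the realized
#' community mean occupancy and detection probability are both near 0.4
#' (the scale of regional forest-bird communities), with strong negative
#' climate effects and a weak negative forest-cover effect.  The intercept
#' and detection hypermeans were calibrated once by Monte Carlo over the
#' generator's own site distribution.
#'
#' @return a `hyper_params` truth object.
#' @export
sim_default_hyper <- function() {
  hyper_params(
    mu_delta = c(-0.24, -0.2, -0.15, -0.5, -0.25, -0.4),
    sigma_delta = c(1.25, 0.5, 0.3, 0.5, 0.3, 0.4),
    mu_lp = -0.49, sigma_lp = 1.0)
}

#' Configuration of a synthetic study
#'
#' @param seed master seed; every stage derives its own stream from it, so
#'   regeneration is bit-identical.
#' @param lon,lat region extent, decimal degrees (default a ~1.5 x 1.5
#'   degree window).
#' @param n_transects number of 1-km transects (default 377).
#' @param n_species community size (default 73).
#' @param hyper true community [hyper_params()] (default
#'   [sim_default_hyper()]).
#' @param raster_res_arcsec covariate raster resolution (default 30").
#' @param cell_size_arcsec analysis cell size at which latent presence is
#'   generated (default 60"); closure then holds by construction at that
#'   scale.
#' @param noise_amp named smooth-noise amplitudes per covariate, on the
#'   unit field scale before rescaling (0 gives exactly planar fields).
#' @param gradient named list of `c(gx, gy)` gradient directions per
#'   covariate on the unit square.
#' @param ranges named list of `c(lo, hi)` target ranges: FOREST %, TEMP
#'   degrees C, PREC mm/yr.
#' @param cluster transect clustering: `n_parents` cluster centres,
#'   `sd_arcsec` scatter around a centre, `p_cluster` probability a
#'   transect joins a cluster rather than falling uniformly.  Tuned so
#'   60" cells mostly hold 1-2 transects with a tail to ~5.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       lon = c(-2.0, -0.5), lat = c(37.5, 39.0),
                       n_transects = 377, n_species = 73,
                       hyper = sim_default_hyper(),
                       raster_res_arcsec = 30,
                       cell_size_arcsec = 60,
                       noise_amp = c(FOREST = 0.35, TEMP = 0.15,
                                     PREC = 0.2),
                       gradient = list(FOREST = c(0.8, 0.4),
                                       TEMP = c(-0.4, -1.0),
                                       PREC = c(0.3, 1.0)),
                       ranges = list(FOREST = c(0, 95),
                                     TEMP = c(10.9, 18.3),
                                     PREC = c(275, 580)),
                       cluster = list(n_parents = 80, sd_arcsec = 25,
                                      p_cluster = 0.9)) {
  stopifnot(n_transects >= 1, n_species >= 2,
            lon[2] > lon[1], lat[2] > lat[1],
            raster_res_arcsec > 0, cell_size_arcsec > 0,
            inherits(hyper, "hyper_params"))
  structure(list(seed = as.integer(seed), lon = lon, lat = lat,
                 n_transects = as.integer(n_transects),
                 n_species = as.integer(n_species), hyper = hyper,
                 raster_res_arcsec = raster_res_arcsec,
                 cell_size_arcsec = cell_size_arcsec,
                 noise_amp = noise_amp, gradient = gradient,
                 ranges = ranges, cluster = cluster),
            class = "sim_config")
}

# one covariate field: linear gradient across the unit square plus a few
# random low-frequency cosine waves, rescaled linearly onto the target
# range (so a zero-noise field stays exactly planar)
.sim_field <- function(u, v, g, amp, rng) {
  raw <- g[1] * u + g[2] * v
  for (h in 1:3) {
    # wave parameters are always drawn so the RNG stream does not depend
    # on the amplitude setting
    fr <- stats::runif(2, 0.5, 2.5) * sign(stats::runif(2) - 0.5)
    ph <- stats::runif(1, 0, 2 * pi)
    if (amp > 0) {
      raw <- raw + amp / h * cos(2 * pi * (fr[1] * u + fr[2] * v) + ph)
    }
  }
  lo <- min(raw); hi <- max(raw)
  if (hi == lo) return(rep(mean(rng), length(raw)))
  rng[1] + (raw - lo) / (hi - lo) * (rng[2] - rng[1])
}

#' Simulate the covariate landscape
#'
#' Builds FOREST (%), TEMP (degrees C) and PREC (mm/yr) rasters covering
#' the region at the configured resolution, each a linear spatial gradient
#' plus smooth noise rescaled to a realistic range; FOREST is clipped to
#' [0, 100].
#'
#' @param config a [sim_config()].
#' @return named list of three `covariate_grid`s.
#' @export
simulate_landscape <- function(config) {
  res_deg <- config$raster_res_arcsec / 3600
  xll <- floor(config$lon[1] / res_deg) * res_deg
  yll <- floor(config$lat[1] / res_deg) * res_deg
  nc <- ceiling((config$lon[2] - xll) / res_deg)
  nr <- ceiling((config$lat[2] - yll) / res_deg)
  lonc <- xll + (seq_len(nc) - 0.5) * res_deg
  latc <- yll + (nr - seq_len(nr) + 0.5) * res_deg   # row 1 = north
  u <- matrix(rep((lonc - config$lon[1]) / diff(config$lon), times = nr),
              nr, nc, byrow = TRUE)
  v <- matrix(rep((latc - config$lat[1]) / diff(config$lat), times = nc),
              nr, nc, byrow = FALSE)
  out <- list()
  for (i in seq_along(c("FOREST", "TEMP", "PREC"))) {
    nm <- c("FOREST", "TEMP", "PREC")[i]
    set.seed(.derive_seed(config$seed, 100L + i))
    vals <- .sim_field(as.vector(u), as.vector(v),
                       config$gradient[[nm]], config$noise_amp[[nm]],
                       config$ranges[[nm]])
    m <- matrix(vals, nr, nc)
    if (nm == "FOREST") m <- pmin(pmax(m, 0), 100)
    out[[nm]] <- new_covariate_grid(nm, m, xll, yll, res_deg)
  }
  out
}

#' Simulate transect locations
#'
#' Clustered-uniform placement: cluster centres fall uniformly over the
#' region; each transect joins a random centre with probability
#' `p_cluster` (scattered around it by an isotropic Normal) and otherwise
#' falls uniformly.  With clustering off the points are i.i.d. uniform.
#'
#' @param config a [sim_config()].
#' @return data.frame with `transect_id`, `lon`, `lat`.
#' @export
simulate_transects <- function(config) {
  set.seed(.derive_seed(config$seed, 201L))
  n <- config$n_transects
  cl <- config$cluster
  px <- stats::runif(cl$n_parents, config$lon[1], config$lon[2])
  py <- stats::runif(cl$n_parents, config$lat[1], config$lat[2])
  clustered <- stats::runif(n) < cl$p_cluster
  parent <- sample.int(cl$n_parents, n, replace = TRUE)
  sdd <- cl$sd_arcsec / 3600
  lon <- ifelse(clustered, px[parent] + stats::rnorm(n, 0, sdd),
                stats::runif(n, config$lon[1], config$lon[2]))
  lat <- ifelse(clustered, py[parent] + stats::rnorm(n, 0, sdd),
                stats::runif(n, config$lat[1], config$lat[2]))
  lon <- pmin(pmax(lon, config$lon[1]), config$lon[2] - 1e-9)
  lat <- pmin(pmax(lat, config$lat[1]), config$lat[2] - 1e-9)
  data.frame(transect_id = sprintf("t%03d", seq_len(n)),
             lon = lon, lat = lat, stringsAsFactors = FALSE)
}

#' Simulate the species community
#'
#' Draws every species' occupancy coefficients and logit detectability
#' from the community-level Normal random-effect distributions — exactly
#' the fitted model run forward, so parameter-recovery studies are valid.
#'
#' @param config a [sim_config()].
#' @return list with `params` (`species_params` truth) and `hyper`.
#' @export
simulate_community <- function(config) {
  set.seed(.derive_seed(config$seed, 301L))
  K <- config$n_species
  h <- config$hyper
  delta <- matrix(stats::rnorm(6 * K, h$mu_delta, h$sigma_delta), 6, K)
  lp <- stats::rnorm(K, h$mu_lp, h$sigma_lp)
  list(params = species_params(delta, lp), hyper = h)
}

#' Simulate detections for given transects and community
#'
#' Aggregates the transect coordinates at the analysis cell size, attaches
#' and standardizes the landscape covariates, draws latent presence
#' `z[i, k] ~ Bern(psi[i, k])` per occupied cell, and then per transect in
#' cell `i` a detection `~ Bern(p_k * z[i, k])`.  Re-aggregating the
#' returned table reproduces the generator's `Ysum` bookkeeping exactly.
#'
#' @param community output of [simulate_community()].
#' @param transects data.frame from [simulate_transects()].
#' @param grids landscape from [simulate_landscape()].
#' @param config a [sim_config()].
#' @return list with `transects` (a `transect_table` with detections),
#'   `site_data` (covariates attached and standardized), `z`, `psi`, `p`
#'   and the per-cell `Ysum` bookkeeping.
#' @export
simulate_detections <- function(community, transects, grids, config) {
  K <- config$n_species
  spid <- sprintf("sp%02d", seq_len(K))
  Y0 <- matrix(0L, nrow(transects), K,
               dimnames = list(transects$transect_id, spid))
  tt0 <- new_transect_table(transects, Y0)
  sd0 <- build_site_data(tt0, config$cell_size_arcsec)
  sd0 <- attach_covariates(sd0, grids)
  sd0 <- standardize_design(sd0)

  psi <- psi_matrix(sd0, community$params)
  p <- stats::plogis(community$params$lp)
  N <- nrow(psi)
  set.seed(.derive_seed(config$seed, 401L))
  z <- matrix(as.numeric(stats::runif(N * K) < psi), N, K)

  cells <- assign_cell(transects$lon, transects$lat,
                       config$cell_size_arcsec)
  skey <- paste(sd0$cells$ix, sd0$cells$iy, sep = ":")
  site_of <- match(paste(cells[, "ix"], cells[, "iy"], sep = ":"), skey)
  Pm <- matrix(p, nrow(transects), K, byrow = TRUE)
  det <- matrix(stats::runif(nrow(transects) * K), nrow(transects), K) <
    (Pm * z[site_of, , drop = FALSE])
  Y <- matrix(as.integer(det), nrow(transects), K,
              dimnames = list(transects$transect_id, spid))

  Ysum_truth <- rowsum(Y + 0L, group = site_of, reorder = TRUE)
  tt <- new_transect_table(transects, Y)
  sd1 <- build_site_data(tt, config$cell_size_arcsec)
  sd1$covariates <- sd0$covariates
  sd1$X <- sd0$X
  sd1$std <- sd0$std
  list(transects = tt, site_data = sd1, z = z, psi = psi, p = p,
       Ysum = Ysum_truth, site_key = skey)
}

#' Generate a complete in-memory study
#'
#' Orchestrates landscape, transects, community and detections; the
#' returned truth object carries everything the validation oracles need.
#'
#' @param config a [sim_config()].
#' @return a `sim_study`: list with `transects` (detections included),
#'   `grids`, `site_data` (model-ready) and `truth` (hyperparameters,
#'   species parameters, latent z, psi, p, per-cell bookkeeping).
#' @export
simulate_study <- function(config = sim_config()) {
  grids <- simulate_landscape(config)
  tr <- simulate_transects(config)
  comm <- simulate_community(config)
  det <- simulate_detections(comm, tr, grids, config)
  structure(list(transects = det$transects, grids = grids,
                 site_data = det$site_data,
                 truth = list(hyper = comm$hyper, params = comm$params,
                              z = det$z, psi = det$psi, p = det$p,
                              Ysum = det$Ysum, site_key = det$site_key,
                              config = config)),
            class = "sim_study")
}

#' Write a synthetic study to disk
#'
#' Writes the transect table (wide CSV), the three covariate rasters
#' (ASCII grids) and a YAML truth sidecar (config scalars, true
#' hyperparameters and species parameters) into a directory.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the file `paths` and the in-memory
#'   `study`.
#' @export
make_study <- function(config = sim_config(), dir) {
  study <- simulate_study(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(transects = file.path(dir, "transects.csv"),
                FOREST = file.path(dir, "forest.asc"),
                TEMP = file.path(dir, "temp.asc"),
                PREC = file.path(dir, "prec.asc"),
                truth = file.path(dir, "truth.yaml"))
  write_transect_table(study$transects, paths$transects, dialect = "wide")
  write_covariate_grid(study$grids$FOREST, paths$FOREST)
  write_covariate_grid(study$grids$TEMP, paths$TEMP)
  write_covariate_grid(study$grids$PREC, paths$PREC)
  tr <- study$truth
  yaml::write_yaml(list(
    seed = config$seed, n_transects = config$n_transects,
    n_species = config$n_species,
    cell_size_arcsec = config$cell_size_arcsec,
    hyper = unclass(tr$hyper),
    species = list(delta = apply(tr$params$delta, 2, as.numeric,
                                 simplify = FALSE),
                   lp = as.numeric(tr$params$lp))), paths$truth)
  invisible(list(paths = paths, study = study))
}
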