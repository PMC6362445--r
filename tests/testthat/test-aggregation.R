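test_that("cell assignment follows the half-open arc-second convention", {
  expect_equal(assign_cell(0, 0, 90), cbind(ix = 0L, iy = 0L))
  # -1.0125 * 3600 / 60 = -60.75 -> floor -61; 38.0042 * 3600 / 60 =
  # 2280.252 -> 2280
  expect_equal(assign_cell(-1.0125, 38.0042, 60),
               cbind(ix = -61L, iy = 2280L))
  # a point exactly on an edge belongs to the higher cell
  edge <- 120 / 3600   # lon * 3600 = 120, divisible by 60
  expect_equal(assign_cell(edge, edge, 60)[1, ], c(ix = 2L, iy = 2L))
  expect_equal(assign_cell(-edge, -edge, 60)[1, ], c(ix = -2L, iy = -2L))
})

test_that("shifting by whole cells shifts the index by exactly that much", {
  set.seed(31)
  lon <- runif(50, -10, 10); lat <- runif(50, 30, 45)
  for (cs in c(60, 90)) {
    base <- assign_cell(lon, lat, cs)
    for (k in c(-3L, 1L, 7L)) {
      shifted <- assign_cell(lon + k * cs / 3600, lat, cs)
      expect_equal(shifted[, "ix"], base[, "ix"] + k)
      expect_equal(shifted[, "iy"], base[, "iy"])
    }
  }
})

test_that("site construction counts replicates and detections per cell", {
  tdf <- data.frame(transect_id = c("a", "b", "c"),
                    lon = c(0.001, 0.005, 0.012),  # all inside the 60" cell
                    lat = rep(0.002, 3))
  Y <- matrix(c(1L, 1L, 0L, 0L, 0L, 0L), 3, 2,
              dimnames = list(tdf$transect_id, c("spA", "spB")))
  sd1 <- build_site_data(new_transect_table(tdf, Y), 60)
  expect_equal(nrow(sd1$Ysum), 1L)
  expect_equal(sd1$J, 3L)
  expect_equal(unname(sd1$Ysum[1, "spA"]), 2L)
  expect_equal(unname(sd1$Ysum[1, "spB"]), 0L)
  expect_equal(sd1$transect_ids[[1]], c("a", "b", "c"))
})

test_that("aggregation conserves transects across cell sizes", {
  study <- simulate_study(sim_config(seed = 3))
  for (cs in c(60, 90)) {
    sdc <- build_site_data(study$transects, cs)
    expect_equal(sum(sdc$J), nrow(study$transects$transects))
    expect_true(all(sdc$Ysum >= 0))
    expect_true(all(sdc$Ysum <= matrix(sdc$J, nrow(sdc$Ysum),
                                       ncol(sdc$Ysum))))
  }
})

test_that("aggregated Ysum and J match the generator's own bookkeeping", {
  study <- simulate_study(sim_config(seed = 8))
  sd1 <- build_site_data(study$transects,
                         study$truth$config$cell_size_arcsec)
  skey <- paste(sd1$cells$ix, sd1$cells$iy, sep = ":")
  expect_equal(skey, study$truth$site_key)
  expect_equal(unname(as.matrix(sd1$Ysum)),
               unname(as.matrix(study$truth$Ysum)))
  # detection implies presence in the truth as well
  occ <- study$truth$z[cbind(rep(seq_len(nrow(sd1$Ysum)), ncol(sd1$Ysum)),
                             rep(seq_len(ncol(sd1$Ysum)),
                                 each = nrow(sd1$Ysum)))]
  expect_true(all(occ[as.vector(sd1$Ysum) > 0] == 1))
})

test_that("aggregation summaries reproduce the printed per-scheme totals", {
  as2 <- aggregation_summary(c("1" = 148, "2" = 71, "3" = 22, "4" = 4,
                               "5" = 1))
  expect_equal(as2$total_sites, 246L)
  expect_equal(as2$total_transects, 377L)
  as3 <- aggregation_summary(c("1" = 83, "2" = 50, "3" = 24, "4" = 22,
                               "5" = 3, "6" = 2, "7" = 1))
  expect_equal(as3$total_sites, 185L)
  expect_equal(as3$total_transects, 377L)
  single <- aggregation_summary(c("1" = 1))
  expect_equal(single$total_sites, 1L)
  expect_equal(single$total_transects, 1L)
})

test_that("summary identities hold on random synthetic studies", {
  for (s in 1:4) {
    study <- simulate_study(sim_config(seed = 100 + s, n_transects = 150,
                                       n_species = 10))
    for (cs in c(60, 90)) {
      sdc <- build_site_data(study$transects, cs)
      agg <- aggregation_summary(sdc)
      jv <- as.integer(names(agg$counts_by_J))
      expect_equal(agg$total_sites, sum(agg$counts_by_J))
      expect_equal(agg$total_transects, sum(jv * agg$counts_by_J))
      expect_equal(agg$total_transects, 150L)
    }
  }
})

test_that("covariate attachment averages covering raster cells", {
  tdf <- data.frame(transect_id = "t1", lon = 0.005, lat = 0.005)
  Y <- matrix(0L, 1, 2, dimnames = list("t1", c("a", "b")))
  sd1 <- build_site_data(new_transect_table(tdf, Y), 60)

  # uniform grid: every site inherits the constant
  g5 <- new_covariate_grid("FOREST", matrix(5, 20, 20), -0.05, -0.05,
                           30 / 3600)
  out <- attach_covariates(sd1, list(FOREST = g5))
  expect_equal(out$covariates$FOREST, 5)

  # one 60" cell covering exactly four 30" raster cells valued 1..4
  m <- matrix(0, 4, 4)
  m[2:3, 2:3] <- matrix(c(1, 3, 2, 4), 2, 2)  # centred on the site cell
  g <- new_covariate_grid("TEMP", m, -30 / 3600, -30 / 3600, 30 / 3600)
  out2 <- attach_covariates(sd1, list(TEMP = g))
  expect_equal(out2$covariates$TEMP, 2.5)

  # a grid that misses the site entirely errors with the cell name
  gfar <- new_covariate_grid("PREC", matrix(1, 2, 2), 5, 5, 30 / 3600)
  expect_error(attach_covariates(sd1, list(PREC = gfar)), "0:0")
})

test_that("zero-noise landscapes agree with the analytic plane at sites", {
  cfg <- sim_config(seed = 12, noise_amp = c(FOREST = 0, TEMP = 0,
                                             PREC = 0))
  land <- simulate_landscape(cfg)
  tr <- simulate_transects(cfg)
  tt <- new_transect_table(tr, matrix(0L, nrow(tr), 2,
                                      dimnames = list(tr$transect_id,
                                                      c("a", "b"))))
  sd1 <- attach_covariates(build_site_data(tt, 60), land)

  # reconstruct the plane from the raster itself (linear in lon/lat)
  g <- land$TEMP
  nc <- ncol(g$values); nr <- nrow(g$values)
  lon1 <- g$xll + 0.5 * g$cellsize
  lat1 <- g$yll + (nr - 0.5) * g$cellsize
  ax <- (g$values[1, 2] - g$values[1, 1]) / g$cellsize
  ay <- (g$values[1, 1] - g$values[2, 1]) / g$cellsize
  plane <- function(lon, lat) {
    g$values[1, 1] + ax * (lon - lon1) + ay * (lat - lat1)
  }
  ctr_lon <- (sd1$cells$ix + 0.5) * 60 / 3600
  ctr_lat <- (sd1$cells$iy + 0.5) * 60 / 3600
  expect_equal(sd1$covariates$TEMP, plane(ctr_lon, ctr_lat),
               tolerance = 1e-6)
})

test_that("standardization uses sample sd and squares the scaled columns", {
  tdf <- data.frame(transect_id = c("t1", "t2"),
                    lon = c(0.001, 0.1), lat = c(0.001, 0.1))
  Y <- matrix(0L, 2, 2, dimnames = list(tdf$transect_id, c("a", "b")))
  sd1 <- build_site_data(new_transect_table(tdf, Y), 60)
  sd1$covariates <- data.frame(FOREST = c(30, 60), TEMP = c(10, 20),
                               PREC = c(300, 500))
  out <- standardize_design(sd1)
  # sd with divisor n-1: sd(c(10,20)) = 7.0711 -> (-0.7071, 0.7071)
  expect_equal(unname(out$X[, "TEMP"]), c(-1, 1) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(unname(out$X[, "TEMP2"]), unname(out$X[, "TEMP"])^2)
  expect_equal(unname(out$X[, "FOREST2"]), unname(out$X[, "FOREST"])^2)
  expect_equal(mean(out$X[, "PREC"]), 0, tolerance = 1e-12)
  expect_equal(sd(out$X[, "PREC"]), 1, tolerance = 1e-12)
  expect_equal(unname(out$std$mean["TEMP"]), 15)

  sd1$covariates$FOREST <- c(40, 40)
  expect_error(standardize_design(sd1), "zero-variance")
})

test_that("standardized columns have mean zero and unit sd on real studies", {
  study <- simulate_study(sim_config(seed = 21))
  X <- study$site_data$X
  for (col in c("FOREST", "TEMP", "PREC")) {
    expect_equal(mean(X[, col]), 0, tolerance = 1e-10)
    expect_equal(sd(X[, col]), 1, tolerance = 1e-10)
  }
})
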