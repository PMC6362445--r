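#' Assign a point to an arc-second grid cell
#'
#' Cells are axis-aligned squares of `cell_size` arc-seconds whose edges sit
#' at integer multiples of the cell size from 0 degrees longitude/latitude;
#' intervals are half-open `[edge, edge + cell_size)`, so a point exactly on
#' an edge belongs to the higher-index cell.  Vectorized over coordinates.
#'
#' @param lon,lat decimal degrees (WGS84).
#' @param cell_size cell size in arc-seconds (> 0).
#' @return a two-column integer matrix with columns `ix`, `iy`.
#' @export
assign_cell <- function(lon, lat, cell_size) {
  stopifnot(cell_size > 0)
  idx <- function(deg) {
    q <- deg * 3600 / cell_size
    # snap to the nearest integer when within floating-point noise of an
    # edge, so that decimally-exact edge coordinates land in the upper cell
    r <- round(q)
    q[abs(q - r) < 1e-9] <- r[abs(q - r) < 1e-9]
    as.integer(floor(q))
  }
  cbind(ix = idx(lon), iy = idx(lat))
}

#' Aggregate transects into grid-cell sites
#'
#' Nests transects as spatial replicates within the grid cell each falls in.
#' Only occupied cells (>= 1 transect) become sites.  `Ysum[i, k]` counts
#' the replicates of site `i` on which species `k` was detected; `J[i]` is
#' the number of replicates.
#'
#' @param transects a `transect_table`.
#' @param cell_size cell size in arc-seconds.
#' @return a `site_data` object with elements `cells` (data.frame `ix`,
#'   `iy`), `transect_ids` (list per site), `J`, `species_ids`, `Ysum`,
#'   `cell_size_arcsec`; covariates are unattached (`covariates`, `X`,
#'   `std` are `NULL` until [attach_covariates()] / [standardize_design()]).
#' @export
build_site_data <- function(transects, cell_size) {
  stopifnot(inherits(transects, "transect_table"), cell_size > 0)
  n <- nrow(transects$transects)
  if (n < 1) stop("need at least one transect")
  cells <- assign_cell(transects$transects$lon, transects$transects$lat,
                       cell_size)
  key <- paste(cells[, "ix"], cells[, "iy"], sep = ":")
  # deterministic site order: by ix then iy
  ukey <- unique(key)
  ucell <- do.call(rbind, strsplit(ukey, ":", fixed = TRUE))
  storage.mode(ucell) <- "integer"
  ord <- order(ucell[, 1L], ucell[, 2L])
  ukey <- ukey[ord]
  ucell <- ucell[ord, , drop = FALSE]

  site_of <- match(key, ukey)
  J <- tabulate(site_of, nbins = length(ukey))
  Ysum <- rowsum(transects$Y, group = site_of, reorder = TRUE)
  Ysum <- matrix(as.integer(Ysum), nrow = length(ukey),
                 dimnames = list(ukey, colnames(transects$Y)))
  tid <- split(transects$transects$transect_id, site_of)
  tid <- tid[as.character(seq_along(ukey))]

  structure(list(cells = data.frame(ix = ucell[, 1L], iy = ucell[, 2L]),
                 transect_ids = unname(tid),
                 J = as.integer(J),
                 species_ids = colnames(transects$Y),
                 Ysum = Ysum,
                 cell_size_arcsec = cell_size,
                 covariates = NULL, X = NULL, std = NULL),
            class = "site_data")
}

#' Summarize an aggregation (Table-1 style)
#'
#' Histogram of replicate counts per site plus totals.  The totals obey
#' `total_sites = sum(counts)` and `total_transects = sum(J * counts)`.
#'
#' @param x a `site_data`, or a named numeric vector mapping a replicate
#'   count `J` to the number of sites with exactly that many transects
#'   (e.g. `c("1" = 148, "2" = 71, ...)`).
#' @return an `aggregation_summary` with `counts_by_J`, `total_sites`,
#'   `total_transects`.
#' @export
aggregation_summary <- function(x) UseMethod("aggregation_summary")

#' @export
aggregation_summary.site_data <- function(x) {
  tab <- table(x$J)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  aggregation_summary(counts)
}

#' @export
aggregation_summary.numeric <- function(x) {
  if (is.null(names(x))) stop("counts_by_J vector must be named by J")
  jv <- as.integer(names(x))
  if (anyNA(jv) || any(jv < 1)) stop("names of counts_by_J must be J >= 1")
  structure(list(counts_by_J = stats::setNames(as.integer(x), names(x)),
                 total_sites = as.integer(sum(x)),
                 total_transects = as.integer(sum(jv * x))),
            class = "aggregation_summary")
}

#' @export
print.aggregation_summary <- function(x, ...) {
  cat("N. transects per site:\n")
  print(x$counts_by_J)
  cat("Total sites:", x$total_sites,
      " Total transects:", x$total_transects, "\n")
  invisible(x)
}

#' Attach raster covariates to sites
#'
#' For each site cell, the raw covariate value is by default the mean of
#' the raster-cell values whose centers fall inside the site cell
#' (`method = "mean"`); alternatively the value of the raster cell
#' containing the site-cell center (`method = "center"`).
#'
#' @param site_data a `site_data`.
#' @param grids named list of `covariate_grid`s (names become covariate
#'   names, conventionally FOREST, TEMP, PREC).
#' @param method `"mean"` or `"center"`.
#' @param na_action `"error"` (default) stops when a site cell has no
#'   non-missing covering raster cell; `"drop"` removes such sites with a
#'   warning.
#' @return the `site_data` with a `covariates` data.frame attached.
#' @export
attach_covariates <- function(site_data, grids,
                              method = c("mean", "center"),
                              na_action = c("error", "drop")) {
  method <- match.arg(method)
  na_action <- match.arg(na_action)
  stopifnot(inherits(site_data, "site_data"), length(grids) >= 1)
  if (is.null(names(grids)) || any(!nzchar(names(grids)))) {
    names(grids) <- vapply(grids, function(g) g$name, "")
  }
  cs <- site_data$cell_size_arcsec
  skey <- paste(site_data$cells$ix, site_data$cells$iy, sep = ":")
  vals <- matrix(NA_real_, nrow = length(skey), ncol = length(grids),
                 dimnames = list(NULL, names(grids)))
  for (gname in names(grids)) {
    g <- grids[[gname]]
    stopifnot(inherits(g, "covariate_grid"))
    if (method == "mean") {
      ctr <- .grid_centers(g)
      keep <- !is.na(ctr$value)
      cellm <- assign_cell(ctr$lon[keep], ctr$lat[keep], cs)
      ckey <- paste(cellm[, "ix"], cellm[, "iy"], sep = ":")
      mm <- tapply(ctr$value[keep], ckey, mean)
      vals[, gname] <- as.numeric(mm[skey])
    } else {
      clon <- (site_data$cells$ix + 0.5) * cs / 3600
      clat <- (site_data$cells$iy + 0.5) * cs / 3600
      col <- floor((clon - g$xll) / g$cellsize) + 1
      row <- nrow(g$values) - floor((clat - g$yll) / g$cellsize)
      ok <- col >= 1 & col <= ncol(g$values) & row >= 1 & row <= nrow(g$values)
      v <- rep(NA_real_, length(skey))
      v[ok] <- g$values[cbind(row[ok], col[ok])]
      vals[, gname] <- v
    }
  }
  bad <- which(rowSums(is.na(vals)) > 0)
  if (length(bad)) {
    labs <- skey[bad]
    if (na_action == "error") {
      stop("site cell(s) with no covariate coverage: ",
           paste(labs, collapse = ", "))
    }
    warning(length(bad), " site(s) dropped for missing covariates: ",
            paste(labs, collapse = ", "))
    site_data <- .subset_sites(site_data, setdiff(seq_along(skey), bad))
    vals <- vals[setdiff(seq_along(skey), bad), , drop = FALSE]
  }
  site_data$covariates <- as.data.frame(vals)
  site_data
}

.subset_sites <- function(sd, idx) {
  sd$cells <- sd$cells[idx, , drop = FALSE]
  rownames(sd$cells) <- NULL
  sd$transect_ids <- sd$transect_ids[idx]
  sd$J <- sd$J[idx]
  sd$Ysum <- sd$Ysum[idx, , drop = FALSE]
  if (!is.null(sd$covariates)) sd$covariates <- sd$covariates[idx, , drop = FALSE]
  if (!is.null(sd$X)) sd$X <- sd$X[idx, , drop = FALSE]
  sd
}

#' Build the standardized design matrix
#'
#' Z-scores each raw covariate over sites (sample sd, divisor n-1) and adds
#' quadratic columns for FOREST and TEMP as element-wise squares of the
#' standardized linear columns.  Standardization constants are stored for
#' prediction on new covariate values.
#'
#' @param site_data a `site_data` with covariates attached (FOREST, TEMP,
#'   PREC).
#' @return the `site_data` with `X` (n-sites x 5; columns FOREST, FOREST2,
#'   TEMP, TEMP2, PREC) and `std` (per-covariate mean and sd) filled.
#' @export
standardize_design <- function(site_data) {
  stopifnot(inherits(site_data, "site_data"))
  cov <- site_data$covariates
  if (is.null(cov)) stop("attach covariates before standardizing")
  need <- c("FOREST", "TEMP", "PREC")
  if (!all(need %in% names(cov))) {
    stop("covariates must include ", paste(need, collapse = ", "))
  }
  if (nrow(cov) < 2) stop("need at least two sites to standardize")
  mu <- vapply(cov[need], mean, 0)
  sdv <- vapply(cov[need], stats::sd, 0)
  if (any(sdv == 0)) {
    stop("zero-variance covariate(s): ",
         paste(need[sdv == 0], collapse = ", "))
  }
  z <- sweep(sweep(as.matrix(cov[need]), 2, mu), 2, sdv, "/")
  X <- cbind(FOREST = z[, "FOREST"], FOREST2 = z[, "FOREST"]^2,
             TEMP = z[, "TEMP"], TEMP2 = z[, "TEMP"]^2,
             PREC = z[, "PREC"])
  site_data$X <- X
  site_data$std <- list(mean = mu, sd = sdv)
  site_data
}

#' @export
print.site_data <- function(x, ...) {
  cat(sprintf("Site data: %d sites (%g\" cells), %d species, %d transects\n",
              nrow(x$Ysum), x$cell_size_arcsec, ncol(x$Ysum), sum(x$J)))
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  if (!is.null(x$X)) cat("  design matrix: standardized\n")
  invisible(x)
}

# design matrix with intercept column, for the linear predictor
.design_full <- function(site_data) {
  if (is.null(site_data$X)) stop("design matrix not built; run standardize_design")
  cbind(`(Intercept)` = 1, site_data$X)
}
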