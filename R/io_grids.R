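#' Read a gridded covariate (ESRI ASCII grid)
#'
#' Parses a headered ASCII raster (`ncols`, `nrows`, `xllcorner`/`xllcenter`,
#' `yllcorner`/`yllcenter`, `cellsize`, optional `NODATA_value`, then
#' `nrows` rows of values from north to south).  Cells equal to the
#' missing-value sentinel become `NA`.
#'
#' @param path path to the `.asc` file.
#' @param name covariate name (e.g. `"FOREST"`, `"TEMP"`, `"PREC"`);
#'   defaults to the file name without extension.
#' @return a `covariate_grid`: list with `name`, `values` (numeric matrix,
#'   row 1 = northernmost), `xll`, `yll` (degrees, lower-left corner),
#'   `cellsize` (degrees) and `resolution_arcsec`.
#' @export
read_covariate_grid <- function(path, name = NULL) {
  if (!file.exists(path)) stop("covariate grid not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("not a valid ASCII grid (too short): ", path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2) stop("malformed header line: ", lines[i])
    hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need]))) {
    stop("ASCII grid header must define ncols, nrows, cellsize: ", path)
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if (cs <= 0) stop("cellsize must be positive")
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2
         else stop("grid is not georeferenced (no xllcorner/xllcenter)")
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2
         else stop("grid is not georeferenced (no yllcorner/yllcenter)")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA_real_

  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(vals) != nc * nr) {
    stop("ASCII grid body has ", length(vals), " values, expected ",
         nc * nr, ": ", path)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.na(nodata)) m[m == nodata] <- NA_real_
  if (is.null(name)) name <- toupper(sub("\\.[^.]*$", "", basename(path)))
  new_covariate_grid(name, m, xll, yll, cs)
}

#' Construct a covariate grid
#'
#' @param name covariate name.
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xll,yll lower-left corner, decimal degrees.
#' @param cellsize cell size in decimal degrees.
#' @return a `covariate_grid` object.
#' @export
new_covariate_grid <- function(name, values, xll, yll, cellsize) {
  stopifnot(is.matrix(values), is.numeric(values), cellsize > 0)
  structure(list(name = name, values = values, xll = xll, yll = yll,
                 cellsize = cellsize,
                 resolution_arcsec = cellsize * 3600),
            class = "covariate_grid")
}

#' Write a covariate grid as an ESRI ASCII raster
#'
#' @param grid a `covariate_grid`.
#' @param path output path.
#' @param nodata sentinel written for `NA` cells.
#' @export
write_covariate_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "covariate_grid"))
  m <- grid$values
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10f", grid$xll),
           sprintf("yllcorner %.10f", grid$yll),
           sprintf("cellsize %.12f", grid$cellsize),
           sprintf("NODATA_value %g", nodata))
  body <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# lon/lat coordinates of every raster cell center, in file (row-major) order
.grid_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  lon <- grid$xll + (seq_len(nc) - 0.5) * grid$cellsize
  lat <- grid$yll + (nr - seq_len(nr) + 0.5) * grid$cellsize
  list(lon = rep(lon, times = nr), lat = rep(lat, each = nc),
       value = as.vector(t(grid$values)))
}

#' @export
print.covariate_grid <- function(x, ...) {
  cat(sprintf("Covariate grid %s: %d x %d cells @ %g\" (%d missing)\n",
              x$name, nrow(x$values), ncol(x$values),
              x$resolution_arcsec, sum(is.na(x$values))))
  invisible(x)
}
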