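#' Read a transect survey table
#'
#' Reads a table of 1-km census transects with coordinates and per-species
#' detection records.  Two dialects are supported: `"long"` with columns
#' `transect_id, lon, lat, species_id, count`, and `"wide"` with columns
#' `transect_id, lon, lat` followed by one column per species.  Counts
#' greater than zero collapse to a detection indicator of 1 (the model is
#' occupancy, not abundance).  Transects with no detections are kept: they
#' still contribute a spatial replicate to their grid cell.
#'
#' @param path path to a CSV or TSV file (UTF-8, header required).
#' @param dialect `"long"` or `"wide"`.
#' @param sep field separator; by default inferred from the file extension
#'   (`.tsv`/`.txt` use tab, anything else comma).
#' @return a `transect_table`: list with `transects` (data.frame of
#'   `transect_id`, `lon`, `lat`) and `Y`, an n-transects x n-species 0/1
#'   detection matrix with transect ids as row names and species ids as
#'   column names.
#' @export
read_transect_table <- function(path, dialect = c("long", "wide"), sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("transect table not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  if (dialect == "long") {
    .transects_from_long(raw)
  } else {
    .transects_from_wide(raw)
  }
}

.coerce_coord <- function(x, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | !is.finite(v))
  if (length(bad)) {
    stop("non-numeric ", what, " at row(s): ", paste(bad, collapse = ", "))
  }
  v
}

.check_coord_range <- function(lon, lat) {
  if (any(lon < -180 | lon >= 180)) stop("longitude outside [-180, 180)")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
}

.transects_from_long <- function(raw) {
  need <- c("transect_id", "lon", "lat", "species_id", "count")
  if (!all(need %in% names(raw))) {
    stop("long dialect requires columns: ", paste(need, collapse = ", "))
  }
  lon <- .coerce_coord(raw$lon, "lon")
  lat <- .coerce_coord(raw$lat, "lat")
  cnt <- suppressWarnings(as.numeric(raw$count))
  if (anyNA(cnt)) {
    stop("non-numeric count at row(s): ",
         paste(which(is.na(cnt)), collapse = ", "))
  }
  det <- as.integer(cnt > 0)

  ids <- unique(raw$transect_id)
  # one coordinate per transect; conflicting coordinates are an error
  first <- match(ids, raw$transect_id)
  tdf <- data.frame(transect_id = ids, lon = lon[first], lat = lat[first],
                    stringsAsFactors = FALSE)
  mism <- tapply(seq_len(nrow(raw)), raw$transect_id, function(ii) {
    length(unique(lon[ii])) > 1L || length(unique(lat[ii])) > 1L
  })
  if (any(mism)) {
    stop("conflicting coordinates for transect(s): ",
         paste(names(mism)[mism], collapse = ", "))
  }
  .check_coord_range(tdf$lon, tdf$lat)

  sp <- unique(raw$species_id)
  Y <- matrix(0L, nrow = length(ids), ncol = length(sp),
              dimnames = list(ids, sp))
  key <- paste(raw$transect_id, raw$species_id, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    conf <- tapply(det[dup], key[dup], function(v) length(unique(v)) > 1L)
    if (any(conf)) {
      stop("conflicting duplicate (transect_id, species_id) records: ",
           paste(gsub("\r", "/", names(conf)[conf]), collapse = ", "))
    }
  }
  Y[cbind(match(raw$transect_id, ids), match(raw$species_id, sp))] <- det
  new_transect_table(tdf, Y)
}

.transects_from_wide <- function(raw) {
  need <- c("transect_id", "lon", "lat")
  if (!all(need %in% names(raw))) {
    stop("wide dialect requires columns transect_id, lon, lat first")
  }
  if (anyDuplicated(raw$transect_id)) {
    stop("duplicate transect_id in wide table: ",
         paste(unique(raw$transect_id[duplicated(raw$transect_id)]),
               collapse = ", "))
  }
  lon <- .coerce_coord(raw$lon, "lon")
  lat <- .coerce_coord(raw$lat, "lat")
  .check_coord_range(lon, lat)
  spcols <- setdiff(names(raw), need)
  if (!length(spcols)) stop("wide table has no species columns")
  Y <- sapply(spcols, function(s) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    if (anyNA(v)) {
      stop("non-numeric count for species ", s, " at row(s): ",
           paste(which(is.na(v)), collapse = ", "))
    }
    as.integer(v > 0)
  })
  Y <- matrix(Y, nrow = nrow(raw), dimnames = list(raw$transect_id, spcols))
  tdf <- data.frame(transect_id = raw$transect_id, lon = lon, lat = lat,
                    stringsAsFactors = FALSE)
  new_transect_table(tdf, Y)
}

#' Construct a transect table from components
#'
#' @param transects data.frame with `transect_id`, `lon`, `lat`.
#' @param Y 0/1 detection matrix, transects x species, with dimnames.
#' @return a `transect_table` object.
#' @export
new_transect_table <- function(transects, Y) {
  stopifnot(is.data.frame(transects),
            all(c("transect_id", "lon", "lat") %in% names(transects)),
            is.matrix(Y), nrow(Y) == nrow(transects))
  if (anyDuplicated(transects$transect_id)) {
    stop("transect_id must be unique within a table")
  }
  .check_coord_range(transects$lon, transects$lat)
  storage.mode(Y) <- "integer"
  if (any(Y < 0L | Y > 1L)) stop("detections must be 0/1")
  rownames(transects) <- NULL
  structure(list(transects = transects, Y = Y), class = "transect_table")
}

#' Write a transect table
#'
#' @param tt a `transect_table`.
#' @param path output file (CSV).
#' @param dialect `"wide"` (default) or `"long"`.
#' @export
write_transect_table <- function(tt, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(tt, "transect_table"))
  if (dialect == "wide") {
    out <- cbind(tt$transects, as.data.frame(tt$Y, check.names = FALSE))
  } else {
    n <- nrow(tt$Y); k <- ncol(tt$Y)
    out <- data.frame(
      transect_id = rep(tt$transects$transect_id, times = k),
      lon = rep(tt$transects$lon, times = k),
      lat = rep(tt$transects$lat, times = k),
      species_id = rep(colnames(tt$Y), each = n),
      count = as.vector(tt$Y),
      stringsAsFactors = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.transect_table <- function(x, ...) {
  cat("Transect table:", nrow(x$Y), "transects,", ncol(x$Y), "species;",
      sum(x$Y), "detections\n")
  invisible(x)
}
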