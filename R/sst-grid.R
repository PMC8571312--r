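#' Construct a gridded sea-surface-temperature field
#'
#' A regular latitude-longitude grid of cell-centre SST values with an
#' ocean mask.  Axes must be strictly monotone increasing cell centres;
#' longitudes use the [-180, 180) convention.  Values must be finite on
#' every ocean cell.
#'
#' @param lat,lon numeric vectors of cell-centre coordinates (degrees).
#' @param values numeric matrix, \code{length(lat)} rows by
#'   \code{length(lon)} columns, degrees C.
#' @param mask logical matrix congruent with \code{values}; \code{TRUE}
#'   marks ocean.  Default: all ocean.
#' @param epoch free-text label (e.g. "baseline").
#' @return object of class \code{sst_grid}.
#' @export
sst_grid <- function(lat, lon, values, mask = NULL, epoch = "") {
  if (is.null(mask)) mask <- matrix(TRUE, length(lat), length(lon))
  stopifnot(is.matrix(values), nrow(values) == length(lat),
            ncol(values) == length(lon),
            identical(dim(mask), dim(values)))
  if (any(diff(lat) <= 0) || any(diff(lon) <= 0)) {
    stop("grid axes must be strictly increasing")
  }
  if (any(!is.finite(values[mask]))) {
    stop("SST values must be finite on every ocean cell")
  }
  structure(list(lat = lat, lon = lon, values = values,
                 mask = mask, epoch = epoch),
            class = "sst_grid")
}

#' @export
print.sst_grid <- function(x, ...) {
  cat(sprintf("SST grid [%s]: %d x %d cells, %.0f%% ocean, %.1f to %.1f degC\n",
              x$epoch, length(x$lat), length(x$lon),
              100 * mean(x$mask),
              min(x$values[x$mask]), max(x$values[x$mask])))
  invisible(x)
}

#' Write / read an SST grid as delimited text
#'
#' Long-format CSV round-trip (lat, lon, sst, ocean) for archiving grids
#' as plain text.
#'
#' @param grid an \code{sst_grid}.
#' @param path file path.
#' @param epoch epoch label applied on read.
#' @return \code{path} invisibly / an \code{sst_grid}.
#' @export
write_sst_grid <- function(grid, path) {
  df <- data.frame(lat = rep(grid$lat, times = length(grid$lon)),
                   lon = rep(grid$lon, each = length(grid$lat)),
                   sst = as.vector(grid$values),
                   ocean = as.vector(grid$mask))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sst_grid
#' @export
read_sst_grid <- function(path, epoch = "") {
  df <- utils::read.csv(path)
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  ii <- match(df$lat, lat)
  jj <- match(df$lon, lon)
  values <- matrix(NA_real_, length(lat), length(lon))
  mask <- matrix(FALSE, length(lat), length(lon))
  values[cbind(ii, jj)] <- df$sst
  mask[cbind(ii, jj)] <- as.logical(df$ocean)
  values[!mask] <- NA_real_
  sst_grid(lat, lon, values, mask, epoch)
}

#' @keywords internal
check_congruent <- function(g1, g2) {
  if (!isTRUE(all.equal(g1$lat, g2$lat)) ||
      !isTRUE(all.equal(g1$lon, g2$lon)) ||
      !identical(g1$mask, g2$mask)) {
    stop("grids are not congruent (axes or ocean mask differ)")
  }
  invisible(TRUE)
}

# great-circle distance (km) between points, haversine
haversine_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  h <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(h)))
}

#' Baseline habitat temperature at isolation sites
#'
#' Returns the SST of the grid cell containing each point.  When that cell
#' is land (masked), the nearest ocean cell within a square search window
#' of \code{radius} cells (longitude wrapping across the dateline) is
#' substituted; nearest is judged by great-circle distance to the cell
#' centre.  Substitutions are recorded in the \code{"substituted"}
#' attribute of the result.
#'
#' @param lat,lon isolation coordinates (degrees), vectorised.
#' @param baseline an \code{sst_grid} for the baseline epoch.
#' @param radius search radius in cells (default 3).
#' @param strain_id optional labels used in error messages.
#' @return numeric vector of habitat temperatures with attribute
#'   \code{substituted} (logical).
#' @export
habitat_temperature <- function(lat, lon, baseline, radius = 3,
                                strain_id = NULL) {
  stopifnot(inherits(baseline, "sst_grid"), length(lat) == length(lon))
  if (is.null(strain_id)) strain_id <- as.character(seq_along(lat))
  nlat <- length(baseline$lat); nlon <- length(baseline$lon)
  out <- numeric(length(lat))
  subst <- logical(length(lat))
  for (k in seq_along(lat)) {
    if (!is.finite(lat[k]) || !is.finite(lon[k])) {
      stop(sprintf("strain %s: isolation coordinates are missing",
                   strain_id[k]))
    }
    i <- which.min(abs(baseline$lat - lat[k]))
    dlon <- abs(baseline$lon - lon[k])
    j <- which.min(pmin(dlon, 360 - dlon))
    if (baseline$mask[i, j]) {
      out[k] <- baseline$values[i, j]
      next
    }
    ii <- i + (-radius:radius)
    ii <- ii[ii >= 1 & ii <= nlat]
    jj <- ((j - 1 + (-radius:radius)) %% nlon) + 1
    cells <- expand.grid(i = ii, j = jj)
    ocean <- baseline$mask[cbind(cells$i, cells$j)]
    if (!any(ocean)) {
      stop(sprintf(
        "strain %s: no ocean cell within %d cells of (%.2f, %.2f)",
        strain_id[k], radius, lat[k], lon[k]))
    }
    cells <- cells[ocean, ]
    d <- haversine_km(lat[k], lon[k],
                      baseline$lat[cells$i], baseline$lon[cells$j])
    pick <- cells[which.min(d), ]
    out[k] <- baseline$values[pick$i, pick$j]
    subst[k] <- TRUE
  }
  attr(out, "substituted") <- subst
  out
}

#' Zonal warming profile between two epochs
#'
#' Per-cell warming \code{future - baseline} summarised at each latitude by
#' the mean and sample standard deviation across unmasked longitudes.
#' Latitudes without ocean cells are omitted.
#'
#' @param baseline,future congruent \code{sst_grid} objects.
#' @return data frame with \code{lat}, \code{mean_dT}, \code{sd_dT},
#'   \code{n_cells}.
#' @export
zonal_warming_profile <- function(baseline, future) {
  check_congruent(baseline, future)
  dT <- future$values - baseline$values
  rows <- lapply(seq_along(baseline$lat), function(i) {
    v <- dT[i, baseline$mask[i, ]]
    if (!length(v)) return(NULL)
    data.frame(lat = baseline$lat[i], mean_dT = mean(v),
               sd_dT = if (length(v) > 1) stats::sd(v) else 0,
               n_cells = length(v))
  })
  do.call(rbind, rows)
}
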