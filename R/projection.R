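#' Strain growth field on an SST grid
#'
#' Evaluates a strain's reaction norm at every ocean cell.  Temperatures
#' outside the thermal niche yield zero growth (the curve's negative tails
#' are clamped, as growth below zero has no viability meaning here); land
#' cells are NA.
#'
#' @param params reaction-norm parameters (or a \code{norberg_fit}).
#' @param grid an \code{sst_grid}.
#' @return numeric matrix congruent with the grid.
#' @export
strain_growth_field <- function(params, grid) {
  if (inherits(params, "norberg_fit")) params <- params$params
  p <- as_norberg_params(params)
  stopifnot(inherits(grid, "sst_grid"))
  mu <- norberg_growth(grid$values, p)
  tmin <- p[["z"]] - p[["w"]] / 2
  tmax <- p[["z"]] + p[["w"]] / 2
  mu[grid$values <= tmin | grid$values >= tmax] <- 0
  mu[!grid$mask] <- NA_real_
  mu
}

#' Thermal viability mask
#'
#' A cell is viable when growth is at least \code{fraction} of the
#' strain's maximum growth rate (inclusive: "at least 20 percent").
#'
#' @param growth_field matrix from [strain_growth_field()].
#' @param mu_max the strain's maximum growth rate (per day, > 0).
#' @param fraction viability threshold as a fraction of \code{mu_max}.
#' @return logical matrix (FALSE on land).
#' @export
viability_mask <- function(growth_field, mu_max, fraction = 0.2) {
  stopifnot(is.finite(mu_max), mu_max > 0, fraction > 0, fraction < 1)
  out <- !is.na(growth_field) & growth_field >= fraction * mu_max
  out
}

#' Proportional growth change between epochs
#'
#' \code{(mu_future - mu_past) / mu_past}, defined only where the strain
#' is viable in BOTH epochs; all other cells are NA.  Viability guarantees
#' the denominator is at least \code{fraction * mu_max > 0}.
#'
#' @param past,future growth-field matrices.
#' @param mask_past,mask_future viability masks for the two epochs.
#' @return numeric matrix of proportional changes (NA where undefined).
#' @export
proportional_change_field <- function(past, future, mask_past,
                                      mask_future) {
  stopifnot(identical(dim(past), dim(future)),
            identical(dim(mask_past), dim(past)),
            identical(dim(mask_future), dim(past)))
  out <- matrix(NA_real_, nrow(past), ncol(past))
  both <- mask_past & mask_future
  out[both] <- (future[both] - past[both]) / past[both]
  out
}

#' Median proportional-change map for a functional type
#'
#' Cellwise median over the strains that have a defined change at each
#' cell (standard midpoint median for even counts); cells where no strain
#' contributes stay NA.  Also returns the per-cell count of contributing
#' strains.
#'
#' @param change_fields list of change matrices (one per strain).
#' @return list with \code{median} and \code{n_strains} matrices.
#' @export
pft_median_map <- function(change_fields) {
  if (!length(change_fields)) stop("no strain fields supplied")
  arr <- simplify2array(change_fields)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  med <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else stats::median(v)
  })
  n <- apply(arr, c(1, 2), function(v) sum(!is.na(v)))
  list(median = med, n_strains = n)
}

#' Zonal summary of a change map
#'
#' Mean and sample standard deviation of the map across defined
#' longitudes at each latitude; latitudes with no defined cells are
#' omitted.
#'
#' @param change_map numeric matrix (lat rows).
#' @param lat latitude cell centres.
#' @return data frame with \code{lat}, \code{mean_change},
#'   \code{sd_change}, \code{n_cells}.
#' @export
zonal_change_summary <- function(change_map, lat) {
  stopifnot(nrow(change_map) == length(lat))
  rows <- lapply(seq_along(lat), function(i) {
    v <- change_map[i, ]
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    data.frame(lat = lat[i], mean_change = mean(v),
               sd_change = if (length(v) > 1) stats::sd(v) else 0,
               n_cells = length(v))
  })
  do.call(rbind, rows)
}

#' Spherical cell areas of a regular grid
#'
#' \eqn{A(\phi) = R^2 \Delta\lambda \Delta\phi \cos\phi} with
#' \eqn{R = 6371} km and the grid's (regular) spacings in radians.
#'
#' @param grid an \code{sst_grid}.
#' @return numeric matrix of cell areas in km^2.
#' @export
cell_areas <- function(grid) {
  stopifnot(inherits(grid, "sst_grid"))
  R <- 6371
  dphi <- diff(grid$lat)[1] * pi / 180
  dlam <- diff(grid$lon)[1] * pi / 180
  a_lat <- R^2 * dlam * dphi * cos(grid$lat * pi / 180)
  matrix(a_lat, length(grid$lat), length(grid$lon))
}

#' Range expansion (and loss) under future conditions
#'
#' For each strain, the newly habitable area is the total area of cells
#' viable in the future but not the past; the expansion percent is that
#' area relative to the strain's own past viable area.  Strains with an
#' empty past range have an undefined percent and are excluded from the
#' percent mean (their ids are reported).  Range loss (viable in the past
#' only) is computed symmetrically.
#'
#' @param past_masks,future_masks named lists of per-strain viability
#'   masks.
#' @param grid the \code{sst_grid} the masks live on.
#' @return list: \code{per_strain} data frame (new/lost/past areas in
#'   km^2, expansion percent), \code{mean_new_area_km2},
#'   \code{mean_expansion_percent}, \code{percent_undefined} (strain ids).
#' @export
range_expansion <- function(past_masks, future_masks, grid) {
  stopifnot(length(past_masks) == length(future_masks))
  areas <- cell_areas(grid)
  ids <- names(past_masks) %||% as.character(seq_along(past_masks))
  per <- do.call(rbind, lapply(seq_along(past_masks), function(k) {
    pm <- past_masks[[k]]; fm <- future_masks[[k]]
    stopifnot(identical(dim(pm), dim(areas)),
              identical(dim(fm), dim(areas)))
    new_a <- sum(areas[fm & !pm])
    lost_a <- sum(areas[pm & !fm])
    past_a <- sum(areas[pm])
    data.frame(strain_id = ids[k], past_area_km2 = past_a,
               new_area_km2 = new_a, lost_area_km2 = lost_a,
               expansion_percent = if (past_a > 0) 100 * new_a / past_a
                                   else NA_real_)
  }))
  rownames(per) <- NULL
  undef <- per$strain_id[is.na(per$expansion_percent)]
  list(per_strain = per,
       mean_new_area_km2 = mean(per$new_area_km2),
       mean_expansion_percent = mean(per$expansion_percent, na.rm = TRUE),
       percent_undefined = undef)
}

#' Project strain growth between two SST epochs
#'
#' End-to-end projection for a compilation: evaluates every strain's
#' reaction norm on both grids, applies the viability rule, forms
#' per-strain proportional-change fields, and aggregates per functional
#' type into median change maps, zonal summaries and range-expansion
#' statistics.
#'
#' @param traits data frame with columns \code{strain_id}, \code{pft},
#'   \code{a}, \code{b}, \code{z}, \code{w} (e.g. from [strain_traits()]
#'   or a simulation truth table); rows with non-finite parameters are
#'   dropped.
#' @param baseline,future congruent \code{sst_grid} objects.
#' @param fraction viability threshold (default 0.2).
#' @return object of class \code{projection_result}: per-PFT list with
#'   \code{median_map}, \code{n_strains_map}, \code{zonal},
#'   \code{expansion} and strain counts, plus the grid axes.
#' @export
project_strains <- function(traits, baseline, future, fraction = 0.2) {
  check_congruent(baseline, future)
  ok <- is.finite(traits$a) & is.finite(traits$b) &
    is.finite(traits$z) & is.finite(traits$w)
  traits <- traits[ok, ]
  if (!nrow(traits)) stop("no strains with usable parameters")
  per_pft <- list()
  for (g in unique(traits$pft)) {
    tg <- traits[traits$pft == g, ]
    ch <- list(); pm <- list(); fm <- list()
    for (k in seq_len(nrow(tg))) {
      p <- c(a = tg$a[k], b = tg$b[k], z = tg$z[k], w = tg$w[k])
      mu_max <- derive_traits(p)$mu_max
      gp <- strain_growth_field(p, baseline)
      gf <- strain_growth_field(p, future)
      mp <- viability_mask(gp, mu_max, fraction)
      mf <- viability_mask(gf, mu_max, fraction)
      ch[[tg$strain_id[k]]] <- proportional_change_field(gp, gf, mp, mf)
      pm[[tg$strain_id[k]]] <- mp
      fm[[tg$strain_id[k]]] <- mf
    }
    med <- pft_median_map(ch)
    per_pft[[g]] <- list(
      median_map = med$median,
      n_strains_map = med$n_strains,
      zonal = zonal_change_summary(med$median, baseline$lat),
      expansion = range_expansion(pm, fm, baseline),
      n_strains = nrow(tg))
  }
  structure(list(per_pft = per_pft, lat = baseline$lat,
                 lon = baseline$lon, fraction = fraction),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("Growth projection (viability threshold %.0f%% of mu_max)\n",
              100 * x$fraction))
  for (g in names(x$per_pft)) {
    e <- x$per_pft[[g]]$expansion
    cat(sprintf(
      "  %-16s %3d strains; mean new range %.3g km^2 (%.1f%% of past range)\n",
      g, x$per_pft[[g]]$n_strains, e$mean_new_area_km2,
      e$mean_expansion_percent))
  }
  invisible(x)
}

#' Band-mean zonal change
#'
#' Mean of a zonal summary's per-latitude means inside a latitude band --
#' a compact way to read the sign structure of a projection (e.g. tropics
#' versus poleward of 40 degrees).
#'
#' @param zonal data frame from [zonal_change_summary()].
#' @param lat_range length-2 numeric, inclusive band limits; use absolute
#'   latitudes with \code{absolute = TRUE}.
#' @param absolute treat the band as a band of |latitude| (default FALSE).
#' @return mean change over the band's latitudes (NA if none defined).
#' @export
band_mean_change <- function(zonal, lat_range, absolute = FALSE) {
  l <- if (absolute) abs(zonal$lat) else zonal$lat
  sel <- l >= lat_range[1] & l <= lat_range[2]
  if (!any(sel)) return(NA_real_)
  mean(zonal$mean_change[sel])
}
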