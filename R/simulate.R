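#' Simulation configuration for a strain compilation
#'
#' Describes, per functional type, the distributions that strain-level
#' Norberg parameters are drawn from, the assay temperature design, the
#' observation-noise model and the isolation-latitude distribution.  The
#' defaults emulate the published group contrasts qualitatively --
#' cyanobacteria with a steep envelope slope, low intercept and a warm,
#' narrow niche; diatoms numerous, fast-growing and wide-niched;
#' dinoflagellates flat-curved with low maximum rates -- with strain
#' counts matching the compiled group sizes (30/32/135/46).  They are
#' illustrative ensembles, not fits to any deposited dataset.
#'
#' Each group entry holds \code{n_strains} and \code{(mean, sd)} pairs for
#' \code{a} (per day), \code{b} (per degree C), \code{z} and \code{w}
#' (degrees C) and \code{lat} (degrees).  Draws are clipped to the
#' reaction-norm bounds \code{a > 0.01}, \code{b} in (-0.2, 0.4), \code{w}
#' in (2, 80), \code{lat} in [-75, 75].
#'
#' @param groups named list of group configurations; defaults as above.
#' @param n_temps assay temperatures per strain (default 10), evenly
#'   spaced from just above the cold niche limit to slightly beyond the
#'   warm limit so both limbs are observed.
#' @param noise_sd_frac Gaussian observation noise sd as a fraction of the
#'   strain's true maximum growth rate (default 0.1).
#' @return list of class \code{pft_sim_config}.
#' @export
pft_sim_config <- function(groups = NULL, n_temps = 10,
                           noise_sd_frac = 0.1) {
  if (is.null(groups)) {
    groups <- list(
      coccolithophore = list(n_strains = 30, a = c(0.45, 0.15),
                             b = c(0.035, 0.010), z = c(16, 5),
                             w = c(24, 5), lat = c(35, 15)),
      cyanobacterium = list(n_strains = 32, a = c(0.18, 0.05),
                            b = c(0.076, 0.012), z = c(23.5, 2.5),
                            w = c(17, 3), lat = c(15, 12)),
      diatom = list(n_strains = 135, a = c(0.65, 0.20),
                    b = c(0.045, 0.012), z = c(13, 8),
                    w = c(30, 6), lat = c(45, 18)),
      dinoflagellate = list(n_strains = 46, a = c(0.28, 0.10),
                            b = c(0.050, 0.012), z = c(17, 6),
                            w = c(28, 5), lat = c(30, 18)))
  }
  for (g in names(groups)) {
    cfg <- groups[[g]]
    for (par in c("a", "b", "z", "w", "lat")) {
      if (length(cfg[[par]]) != 2 || cfg[[par]][2] < 0) {
        stop(sprintf("config error: group %s parameter %s needs (mean, sd >= 0)",
                     g, par))
      }
    }
    if (cfg$n_strains < 1) stop("config error: n_strains must be >= 1")
  }
  stopifnot(n_temps >= 4, noise_sd_frac >= 0)
  structure(list(groups = groups, n_temps = n_temps,
                 noise_sd_frac = noise_sd_frac),
            class = "pft_sim_config")
}

#' Simulate a strain growth-rate compilation
#'
#' Draws per-strain Norberg parameters from the group distributions,
#' evaluates the true curve at each strain's temperature design, adds
#' Gaussian observation noise and floors observed rates at zero (real
#' growth tables do not report negative specific rates; the floor mildly
#' truncates noise near the niche edges).  Returns the ground-truth
#' parameter table alongside the observed dataset; both are pure
#' functions of (config, seed).
#'
#' @param cfg a [pft_sim_config()].
#' @param seed integer RNG seed.
#' @return list with \code{truth} (strain_id, pft, a, b, z, w, T_opt,
#'   mu_max, isolation_lat, isolation_lon) and \code{dataset} (a
#'   \code{growth_dataset}).
#' @export
simulate_strain_dataset <- function(cfg = pft_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "pft_sim_config"))
  set.seed(seed)
  abbrev <- c(coccolithophore = "CO", cyanobacterium = "CY",
              diatom = "DT", dinoflagellate = "DF")
  truth <- list(); meas <- list()
  for (g in names(cfg$groups)) {
    gc <- cfg$groups[[g]]
    for (k in seq_len(gc$n_strains)) {
      sid <- sprintf("%s_%03d", abbrev[[g]] %||% toupper(substr(g, 1, 2)), k)
      a <- max(stats::rnorm(1, gc$a[1], gc$a[2]), 0.01)
      b <- min(max(stats::rnorm(1, gc$b[1], gc$b[2]), -0.19), 0.39)
      z <- stats::rnorm(1, gc$z[1], gc$z[2])
      w <- min(max(stats::rnorm(1, gc$w[1], gc$w[2]), 2.5), 79)
      lat <- min(max(stats::rnorm(1, gc$lat[1], gc$lat[2]), -75), 75)
      lon <- stats::runif(1, -180, 180 - 1e-9)
      p <- c(a = a, b = b, z = z, w = w)
      tr <- derive_traits(p)
      temps <- seq(z - w / 2 + 1, z + w / 2 + 2,
                   length.out = cfg$n_temps)
      temps <- pmin(pmax(temps, -5), 60)
      mu_true <- norberg_growth(temps, p)
      mu_obs <- pmax(mu_true + stats::rnorm(length(temps), 0,
                                            cfg$noise_sd_frac * tr$mu_max),
                     0)
      truth[[sid]] <- data.frame(
        strain_id = sid, pft = g, a = a, b = b, z = z, w = w,
        T_opt = tr$T_opt, mu_max = tr$mu_max,
        isolation_lat = lat, isolation_lon = lon)
      meas[[sid]] <- data.frame(
        strain_id = sid, pft = g, temperature = temps,
        growth_rate = mu_obs, light = 100, day_length = 12,
        is_diazotroph = FALSE, fluctuating_nutrients = FALSE,
        isolation_lat = lat, isolation_lon = lon, source = "simulated")
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(truth = truth,
       dataset = growth_dataset(do.call(rbind, meas)))
}

#' Simulation configuration for SST epoch fields
#'
#' Baseline SST follows the canonical zonal structure
#' \eqn{T(\phi) = T_{eq} - \Delta T_{pole} \sin^2\phi} plus independent
#' cellwise Gaussian noise; the future epoch adds a deterministic warming
#' profile \eqn{\Delta(\phi) = \Delta_{eq} + (\Delta_{pole} - \Delta_{eq})
#' \sin^2\phi} (uniform warming when the two coefficients are equal,
#' polar-amplified when \eqn{\Delta_{pole} > \Delta_{eq}}).  Defaults give
#' a 28 degC equator, -2 degC poles, and a 2.5 to 5 degC polar-amplified
#' warming of the scale separating a mid-20th-century baseline from an
#' end-of-century high-emission epoch.
#'
#' @param resolution cell size in degrees; must divide 180 evenly
#'   (default 2.5).
#' @param t_eq equatorial baseline SST (degC).
#' @param contrast pole-minus-equator baseline contrast (degC, > 0).
#' @param noise_sd cellwise longitudinal noise sd (degC).
#' @param warming_eq,warming_pole warming at the equator and poles (degC).
#' @param land_fraction fraction of cells masked as land (default 0).
#' @return list of class \code{sst_sim_config}.
#' @export
sst_sim_config <- function(resolution = 2.5, t_eq = 28, contrast = 30,
                           noise_sd = 0.5, warming_eq = 2.5,
                           warming_pole = 5, land_fraction = 0) {
  if (abs(180 / resolution - round(180 / resolution)) > 1e-9) {
    stop("config error: resolution must divide 180 evenly")
  }
  stopifnot(contrast > 0, noise_sd >= 0,
            land_fraction >= 0, land_fraction < 1)
  structure(list(resolution = resolution, t_eq = t_eq,
                 contrast = contrast, noise_sd = noise_sd,
                 warming_eq = warming_eq, warming_pole = warming_pole,
                 land_fraction = land_fraction),
            class = "sst_sim_config")
}

#' Simulate congruent baseline and future SST grids
#'
#' @param cfg an [sst_sim_config()].
#' @param seed integer RNG seed (noise and land mask).
#' @return list with \code{baseline} and \code{future} \code{sst_grid}
#'   objects sharing axes and mask.
#' @export
simulate_sst_fields <- function(cfg = sst_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sst_sim_config"))
  set.seed(seed)
  res <- cfg$resolution
  lat <- seq(-90 + res / 2, 90 - res / 2, by = res)
  lon <- seq(-180 + res / 2, 180 - res / 2, by = res)
  nlat <- length(lat); nlon <- length(lon)
  s2 <- sin(lat * pi / 180)^2
  base <- matrix(cfg$t_eq - cfg$contrast * s2, nlat, nlon) +
    matrix(stats::rnorm(nlat * nlon, 0, cfg$noise_sd), nlat, nlon)
  warm <- matrix(cfg$warming_eq + (cfg$warming_pole - cfg$warming_eq) * s2,
                 nlat, nlon)
  mask <- matrix(TRUE, nlat, nlon)
  if (cfg$land_fraction > 0) {
    land <- sample.int(nlat * nlon, round(cfg$land_fraction * nlat * nlon))
    mask[land] <- FALSE
  }
  b <- base; b[!mask] <- NA_real_
  f <- base + warm; f[!mask] <- NA_real_
  list(baseline = sst_grid(lat, lon, b, mask, epoch = "baseline"),
       future = sst_grid(lat, lon, f, mask, epoch = "future"))
}
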