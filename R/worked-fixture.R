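#' Worked end-to-end fixture with frozen oracle results
#'
#' A small deterministic bundle used by the integration tests and the
#' examples: eight strains (two per functional type) with exact (noise
#' free) growth measurements at nine temperatures each, and a congruent
#' 10 x 16 pair of SST epoch grids (zonal baseline, polar-amplified
#' warming, all ocean).  The \code{expected} element holds reference
#' results computed once by brute-force oracles -- dense-grid argmax for
#' the thermal optima, exhaustive two-point line search for the pooled
#' 99th-quantile fit, fine-scan root finding for the growth-equivalence
#' distances, and direct cell-loop aggregation for the projection
#' summaries -- and frozen here, so the pipeline can be checked end to end
#' against values that never passed through the package's own solvers.
#'
#' @return list with \code{strains} (true parameter table),
#'   \code{dataset} (a \code{growth_dataset}), \code{baseline} and
#'   \code{future} (\code{sst_grid}s) and \code{expected} (frozen
#'   reference values).
#' @export
worked_fixture <- function() {
  strains <- data.frame(
    strain_id = c("CO_1", "CO_2", "CY_1", "CY_2",
                  "DT_1", "DT_2", "DF_1", "DF_2"),
    pft = rep(c("coccolithophore", "cyanobacterium",
                "diatom", "dinoflagellate"), each = 2),
    a = c(0.45, 0.50, 0.18, 0.20, 0.60, 0.70, 0.28, 0.30),
    b = c(0.030, 0.040, 0.080, 0.070, 0.045, 0.050, 0.050, 0.055),
    z = c(16, 14, 24, 22, 12, 10, 18, 16),
    w = c(24, 22, 16, 18, 30, 28, 28, 26),
    isolation_lat = c(35, 45, 10, 5, 50, 55, 30, 25),
    isolation_lon = c(-40, -20, -150, 60, -30, 10, 140, -70))

  meas <- do.call(rbind, lapply(seq_len(nrow(strains)), function(k) {
    s <- strains[k, ]
    temps <- seq(s$z - s$w / 2 + 1, s$z + s$w / 2 + 2, length.out = 9)
    data.frame(strain_id = s$strain_id, pft = s$pft,
               temperature = temps,
               growth_rate = norberg_growth(
                 temps, c(a = s$a, b = s$b, z = s$z, w = s$w)),
               isolation_lat = s$isolation_lat,
               isolation_lon = s$isolation_lon)
  }))

  lat <- seq(-81, 81, by = 18)
  lon <- seq(-168.75, 168.75, by = 22.5)
  s2 <- sin(lat * pi / 180)^2
  base <- matrix(28 - 30 * s2, length(lat), length(lon))
  fut <- base + matrix(2.5 + 2.5 * s2, length(lat), length(lon))

  expected <- list(
    pooled = list(intercept_a = 1.229418016056,
                  slope_b = 0.003249865268,
                  Q10 = 1.033032501314,
                  loss = 0.654839845839, n_used = 64L),
    T_opt = c(18.0942, 16.3130, 26.3408, 24.5986,
              16.5887, 14.4131, 22.4131, 20.1694),
    mu_max = c(0.7508035948, 0.9177327347, 1.3538633735, 1.0257417922,
               1.1472985571, 1.2960554051, 0.7733949852, 0.8161126948),
    capacity = data.frame(
      strain_id = strains$strain_id,
      T_hab = c(21.816778784, 13, 27.265847744, 27.265847744,
                13, 4.183221216, 21.816778784, 21.816778784),
      TSM = c(-3.7225787844, 3.3130000000, -0.9250477444,
              -2.6672477444, 3.5887000000, 10.2298787844,
              0.5963212156, -1.6473787844),
      DGE = c(0, 6.247248900, 0, 0, 6.701944000, 17.085490484,
              1.176409316, 0),
      WT = c(6.183221216, 12, 4.734152256, 3.734152256, 14,
             19.816778784, 10.183221216, 7.183221216)),
    expansion_km2 = c(coccolithophore = 72748109.484733,
                      cyanobacterium = 56653918.490219,
                      diatom = 25067290.166779,
                      dinoflagellate = 72748109.484733),
    band_means = list(
      cyanobacterium_tropics = -0.432640005677,
      dinoflagellate_tropics = -0.420860844274,
      coccolithophore_poleward40 = 0.143655352774,
      diatom_poleward40 = 0.283980693478,
      dinoflagellate_poleward40 = 0.332716012355))

  list(strains = strains,
       dataset = growth_dataset(meas),
       baseline = sst_grid(lat, lon, base, epoch = "baseline"),
       future = sst_grid(lat, lon, fut, epoch = "future"),
       expected = expected)
}
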