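make_grid <- function(nlat = 10, nlon = 16, t_eq = 28, contrast = 30) {
  lat <- seq(-90 + 180 / nlat / 2, 90 - 180 / nlat / 2, length.out = nlat)
  lon <- seq(-180 + 360 / nlon / 2, 180 - 360 / nlon / 2, length.out = nlon)
  vals <- matrix(t_eq - contrast * sin(lat * pi / 180)^2, nlat, nlon)
  sst_grid(lat, lon, vals, epoch = "baseline")
}

test_that("habitat temperature reads the containing cell and falls back to nearby ocean", {
  g <- make_grid()
  i <- which.min(abs(g$lat - 40))
  expect_equal(as.numeric(habitat_temperature(40, 0, g)), g$values[i, 8])

  # land at the query cell: nearest ocean neighbour is substituted and logged
  mask <- g$mask
  j <- which.min(abs(g$lon - 0))
  mask[i, j] <- FALSE
  vals <- g$values; vals[!mask] <- NA
  g2 <- sst_grid(g$lat, g$lon, vals, mask, epoch = "baseline")
  th <- habitat_temperature(40, 0, g2)
  expect_true(attr(th, "substituted"))
  expect_true(is.finite(th))

  # fully masked neighbourhood errors with the strain name
  mask3 <- matrix(FALSE, length(g$lat), length(g$lon))
  mask3[1, 1] <- TRUE  # keep one far-away ocean cell so the grid is valid
  vals3 <- g$values; vals3[!mask3] <- NA
  g3 <- sst_grid(g$lat, g$lon, vals3, mask3)
  expect_error(habitat_temperature(40, 0, g3, radius = 2,
                                   strain_id = "CCMP1335"),
               "CCMP1335")
})

test_that("capacity metrics honour their defining identities", {
  # symmetric curve: the equivalence point mirrors the habitat around z
  m <- capacity_metrics(c(a = 1, b = 0, z = 20, w = 20), T_hab = 15)
  expect_equal(m$TSM, 5)
  expect_equal(m$DGE, 10, tolerance = 1e-7)
  expect_equal(m$WT, 15)
  expect_equal(m$DGE, 2 * m$TSM, tolerance = 1e-7)

  # at or above the optimum the growth-equivalence distance is zero
  p <- c(a = 1, b = 0.1, z = 20, w = 20)
  topt <- derive_traits(p)$T_opt
  expect_equal(capacity_metrics(p, topt)$DGE, 0)
  expect_equal(capacity_metrics(p, topt + 2)$DGE, 0)
  expect_equal(capacity_metrics(p, topt)$TSM, 0)

  # skewed curve: the root equation holds to tolerance
  m2 <- capacity_metrics(p, 20)
  expect_equal(m2$TSM, topt - 20, tolerance = 1e-9)
  expect_lt(abs(norberg_growth(20 + m2$DGE, p) - norberg_growth(20, p)),
            1e-6)

  # habitat at/below the cold limit: equivalence collapses onto T_max
  cold <- capacity_metrics(p, derive_traits(p)$T_min - 1)
  expect_equal(cold$DGE, cold$WT)
  expect_equal(cold$T_equiv, derive_traits(p)$T_max)
})

test_that("capacity ordering and continuity hold across random strains", {
  set.seed(33)
  for (k in 1:400) {
    p <- c(a = runif(1, 0.1, 2), b = runif(1, -0.1, 0.3),
           z = runif(1, 5, 30), w = runif(1, 6, 50))
    tr <- derive_traits(p)
    th <- runif(1, tr$T_min - 3, tr$T_max + 3)
    m <- capacity_metrics(p, th)
    expect_equal(m$WT, tr$T_max - th, tolerance = 1e-9)
    expect_gte(m$DGE, 0)
    if (th >= tr$T_opt) expect_identical(m$DGE, 0)
    if (th > tr$T_min && th < tr$T_opt) {
      expect_lte(m$TSM, m$DGE + 1e-7)
      expect_lte(m$DGE, m$WT + 1e-7)
    }
  }
  # DGE -> 0 continuously as the habitat approaches the optimum
  p <- c(a = 1, b = 0.05, z = 18, w = 24)
  topt <- derive_traits(p)$T_opt
  dges <- vapply(c(1, 0.3, 0.1, 0.01), function(d) {
    capacity_metrics(p, topt - d)$DGE
  }, numeric(1))
  expect_true(all(diff(dges) < 0))
  expect_lt(dges[4], 0.05)
})

test_that("the capacity table keeps only QC-passing strains of known origin", {
  fx <- worked_fixture()
  traits <- strain_traits(fx$dataset)
  traits$isolation_lat[traits$strain_id == "DT_1"] <- NA
  cap <- capacity_table(traits, fx$baseline)
  expect_false("DT_1" %in% cap$strain_id)
  expect_true(all(c("T_hab", "TSM", "DGE", "WT") %in% names(cap)))
  expect_true("DT_1" %in% attr(cap, "excluded"))
  expect_true(all(cap$DGE >= 0))
})

test_that("zonal warming profiles compute per-latitude moments over ocean cells", {
  g1 <- make_grid()
  vals <- g1$values + 3
  g2 <- sst_grid(g1$lat, g1$lon, vals, g1$mask, epoch = "future")
  zp <- zonal_warming_profile(g1, g2)
  expect_equal(zp$mean_dT, rep(3, length(g1$lat)))
  expect_equal(zp$sd_dT, rep(0, length(g1$lat)))

  same <- zonal_warming_profile(g1, g1)
  expect_true(all(same$mean_dT == 0))

  # one of four ocean cells warmed by 2: mean 0.5, sample sd 1
  b <- sst_grid(0, c(-135, -45, 45, 135), matrix(10, 1, 4))
  f <- sst_grid(0, c(-135, -45, 45, 135), matrix(c(12, 10, 10, 10), 1, 4))
  zp2 <- zonal_warming_profile(b, f)
  expect_equal(zp2$mean_dT, 0.5)
  expect_equal(zp2$sd_dT, 1)

  g3 <- make_grid(nlat = 8)
  expect_error(zonal_warming_profile(g1, g3), "congruent")
})

test_that("group comparisons reproduce hand-ranked statistics and are label-invariant", {
  v <- c(1, 2, 3, 7, 8, 9)
  g <- rep(c("a", "b"), each = 3)
  out <- compare_groups(v, g, n_boot = 200)
  expect_equal(out$H, 3.857143, tolerance = 1e-6)      # direct rank-sum arithmetic
  expect_equal(out$epsilon_sq, out$H / (length(v) - 1))
  expect_equal(nrow(out$dunn), 1)

  ident <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                          n_boot = 100)
  expect_equal(ident$H, 0)
  expect_equal(ident$epsilon_sq, 0)

  # epsilon-squared arithmetic: H = 5, n = 11 gives 0.5
  expect_equal(5 / (11 - 1), 0.5)

  # invariance to group input order and relabelling
  perm <- sample(length(v))
  out2 <- compare_groups(v[perm], g[perm], n_boot = 200)
  expect_equal(out2$H, out$H)
  out3 <- compare_groups(v, c(a = "zz", b = "aa")[g], n_boot = 200)
  expect_equal(out3$H, out$H)
  expect_equal(sort(abs(out3$dunn$z)), sort(abs(out$dunn$z)))

  expect_error(compare_groups(c(1, 2), c("a", "b")), "at least two")

  # Dunn separates well-separated groups, adjustment is monotone
  set.seed(8)
  v4 <- c(rnorm(15, 0), rnorm(15, 0), rnorm(15, 6))
  g4 <- rep(c("x", "y", "zz"), each = 15)
  d_none <- compare_groups(v4, g4, n_boot = 100)$dunn
  d_bonf <- compare_groups(v4, g4, adjust = "bonferroni", n_boot = 100)$dunn
  expect_true(all(d_bonf$p_adjusted >= d_none$p_adjusted - 1e-12))
  expect_true(d_none$significant[d_none$group1 == "x" & d_none$group2 == "zz"])
})

test_that("trait correlations match the base test", {
  set.seed(10)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  tc <- trait_correlation(x, y)
  ref <- cor.test(x, y)
  expect_equal(tc$r, unname(ref$estimate))
  expect_equal(tc$df, 28)
  expect_equal(tc$p_value, ref$p.value)
})
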