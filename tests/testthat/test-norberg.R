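test_that("the curve evaluates to its closed forms at the vertex and niche edges", {
  sym <- c(a = 1, b = 0, z = 20, w = 20)
  expect_equal(norberg_growth(20, sym), 1)
  expect_equal(norberg_growth(c(10, 30), sym), c(0, 0))
  expect_equal(norberg_growth(20, c(a = 1, b = 0.1, z = 20, w = 20)),
               exp(2))
  # strictly positive inside the niche, negative outside
  tt <- seq(10.01, 29.99, by = 0.5)
  expect_true(all(norberg_growth(tt, sym) > 0))
  expect_true(all(norberg_growth(c(5, 35), sym) < 0))
  expect_error(norberg_growth(20, c(a = 1, b = 0, z = 20, w = -3)), "width")
})

test_that("closed-form thermal traits match the dense-grid argmax oracle", {
  tr <- derive_traits(c(a = 1, b = 0, z = 20, w = 20))
  expect_equal(tr$T_opt, 20)
  expect_equal(tr$mu_max, 1)
  expect_equal(tr$T_min, 10)
  expect_equal(tr$T_max, 30)

  skew <- c(a = 1, b = 0.1, z = 20, w = 20)
  expect_equal(derive_traits(skew)$T_opt, 24.142, tolerance = 1e-4)
  expect_equal(derive_traits(skew)$T_opt, grid_topt(skew),
               tolerance = 1e-3)

  set.seed(42)
  for (k in 1:50) {
    p <- c(a = runif(1, 0.1, 2), b = runif(1, -0.15, 0.35),
           z = runif(1, 0, 35), w = runif(1, 5, 60))
    tr <- derive_traits(p)
    expect_lt(abs(tr$T_opt - grid_topt(p)), 1e-3)
    if (p[["b"]] > 0) expect_gt(tr$T_opt, p[["z"]])
  }
})

test_that("performance breadth solves the defining equation and mirrors curve skew", {
  sym <- c(a = 1, b = 0, z = 20, w = 20)
  br <- performance_breadth(sym, 0.2)
  expect_equal(br$T_lo, 20 - sqrt(0.8) * 10, tolerance = 1e-7)
  expect_equal(br$T_hi, 20 + sqrt(0.8) * 10, tolerance = 1e-7)
  expect_equal(br$slope_up, 0.8 / (sqrt(0.8) * 10), tolerance = 1e-7)
  expect_equal(br$slope_up, br$slope_down, tolerance = 1e-9)
  expect_error(performance_breadth(sym, 1.2), "fraction")

  # any warming-skewed curve (b > 0) descends faster than it ascends
  set.seed(7)
  for (k in 1:40) {
    p <- c(a = runif(1, 0.1, 2), b = runif(1, 0.01, 0.3),
           z = runif(1, 5, 30), w = runif(1, 8, 50))
    br <- performance_breadth(p, 0.2)
    mm <- derive_traits(p)$mu_max
    expect_gt(br$slope_down, br$slope_up)
    expect_lt(br$T_hi - br$T_lo, p[["w"]])
    expect_equal(norberg_growth(br$T_lo, p), 0.2 * mm, tolerance = 1e-6)
    expect_equal(norberg_growth(br$T_hi, p), 0.2 * mm, tolerance = 1e-6)
  }
})

test_that("noiseless fits recover the generating parameters", {
  p <- c(a = 1, b = 0.05, z = 18, w = 24)
  tt <- seq(7, 29, length.out = 8)
  fit <- fit_reaction_norm(tt, norberg_growth(tt, p))
  expect_true(fit$converged)
  expect_lt(max(abs(coef(fit) - p)), 1e-3)
  expect_lt(fit$sigma, 1e-4)

  # richer designs and other parameter corners
  for (p2 in list(c(a = 0.2, b = 0.08, z = 25, w = 16),
                  c(a = 0.7, b = 0, z = 12, w = 30))) {
    tt2 <- seq(p2[["z"]] - p2[["w"]] / 2 + 0.5,
               p2[["z"]] + p2[["w"]] / 2 - 0.5, length.out = 12)
    f2 <- fit_reaction_norm(tt2, norberg_growth(tt2, p2))
    expect_lt(max(abs(coef(f2) - p2)), 1e-3)
  }

  expect_error(fit_reaction_norm(c(5, 10, 15), c(0.1, 0.3, 0.2)),
               "insufficient")
  expect_error(fit_reaction_norm(seq(5, 30, 5), rep(-0.1, 6)),
               "degenerate")
})

test_that("the optimum is recovered under observation noise", {
  p <- c(a = 0.5, b = 0.1, z = 22, w = 9)
  topt <- derive_traits(p)$T_opt
  mm <- derive_traits(p)$mu_max
  temps <- seq(18, 27.5, length.out = 10)
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    mu <- norberg_growth(temps, p) + rnorm(10, 0, 0.1 * mm)
    f <- tryCatch(fit_reaction_norm(temps, mu), error = function(e) NULL)
    !is.null(f) && abs(derive_traits(f)$T_opt - topt) <= 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("T_opt bias shrinks as the design grows", {
  p <- c(a = 0.5, b = 0.08, z = 22, w = 16)
  topt <- derive_traits(p)$T_opt
  mm <- derive_traits(p)$mu_max
  bias_at <- function(n_temps) {
    errs <- vapply(1:120, function(s) {
      set.seed(s)
      temps <- seq(15, 30, length.out = n_temps)
      mu <- norberg_growth(temps, p) + rnorm(n_temps, 0, 0.1 * mm)
      f <- tryCatch(fit_reaction_norm(temps, mu), error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      derive_traits(f)$T_opt - topt
    }, numeric(1))
    abs(mean(errs, na.rm = TRUE))
  }
  b6 <- bias_at(6); b24 <- bias_at(24)
  expect_lt(b24, b6)
  expect_lt(b24, 0.15)
})

test_that("upper-limit QC requires descending-limb data and bounded extrapolation", {
  p <- c(a = 1, b = 0.05, z = 18, w = 24)
  both_limbs <- seq(7, 29, length.out = 8)     # T_max = 30, 1 degC beyond
  fit <- fit_reaction_norm(both_limbs, norberg_growth(both_limbs, p))
  expect_true(qc_tmax(fit))

  # all data below the optimum fails criterion (i)
  topt <- derive_traits(fit)$T_opt
  expect_false(qc_tmax(fit, temperature = both_limbs[both_limbs < topt]))

  # extrapolating T_max 10 degC past the warmest assay fails criterion (ii)
  expect_false(qc_tmax(fit, temperature = c(both_limbs[both_limbs < topt],
                                            topt + 0.5, 20)))
  expect_true(qc_tmax(fit, temperature = c(both_limbs[both_limbs < topt],
                                           topt + 0.5, 20), margin = 12))
})

test_that("model-object methods are coherent", {
  p <- c(a = 1, b = 0.05, z = 18, w = 24)
  tt <- seq(7, 29, length.out = 8)
  set.seed(1)
  mu <- norberg_growth(tt, p) + rnorm(8, 0, 0.05)
  fit <- fit_reaction_norm(tt, mu)
  expect_named(coef(fit), c("a", "b", "z", "w"))
  expect_equal(predict(fit, tt), norberg_growth(tt, coef(fit)))
  expect_equal(residuals(fit), mu - predict(fit))
  expect_equal(as.numeric(logLik(fit)), -fit$nll)
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(8L, 3L))
  expect_true(all(sims >= 0))
  expect_output(print(fit), "T_opt")
  s <- summary(fit)
  expect_true(is.logical(s$tmax_qc_pass))
})

test_that("per-strain trait tables flag unfittable strains instead of failing", {
  df <- tiny_growth_df()
  # third strain with too few distinct temperatures
  extra <- data.frame(strain_id = "s3", pft = "diatom",
                      temperature = c(10, 10, 15), growth_rate = c(0.2, 0.25, 0.3),
                      light = 100, day_length = 12, is_diazotroph = FALSE,
                      fluctuating_nutrients = FALSE, isolation_lat = 5,
                      isolation_lon = 5, source = "unit test")
  ds <- growth_dataset(rbind(df, extra))
  tab <- strain_traits(ds)
  expect_equal(nrow(tab), 3)
  expect_false(tab$converged[tab$strain_id == "s3"])
  expect_true(all(is.na(tab$T_opt[tab$strain_id == "s3"])))
  fitted_rows <- tab[tab$converged, ]
  expect_true(all(fitted_rows$T_min < fitted_rows$T_opt &
                    fitted_rows$T_opt < fitted_rows$T_max))
  expect_true(all(fitted_rows$T_lo > fitted_rows$T_min &
                    fitted_rows$T_hi < fitted_rows$T_max))
})
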