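test_that("the quantile fit is pinball-loss optimal against exhaustive line search", {
  set.seed(1)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    tau <- sample(c(0.1, 0.5, 0.9, 0.99), 1)
    x <- runif(n, 0, 30)
    y <- 0.05 * x + rnorm(n)
    fit <- phytotherm:::rq_line(x, y, tau)
    oracle <- brute_rq(x, y, tau)
    expect_lte(fit$loss, oracle$loss + 1e-9)
  }
})

test_that("an exact exponential envelope is interpolated (Eppley construction)", {
  a0 <- 0.59
  b0 <- log(1.88) / 10
  set.seed(2)
  tt <- rep(seq(0, 30, by = 2.5), each = 12)
  env <- a0 * exp(b0 * tt)
  mu <- env * runif(length(tt), 0.15, 0.995)
  mu[seq(1, length(tt), by = 13)] <- env[seq(1, length(tt), by = 13)]
  d <- fit_quantile_exponential(tt, mu, tau = 0.99)
  expect_equal(d$intercept_a, a0, tolerance = 1e-9)
  expect_equal(d$slope_b, b0, tolerance = 1e-9)
  expect_equal(d$Q10, 1.88, tolerance = 1e-8)

  # quantile property: few points lie strictly above the fitted line
  r <- d$data$log_growth -
    (log(d$intercept_a) + d$slope_b * d$data$temperature)
  expect_lte(mean(r > 1e-12), 1 - 0.99 + 2 / d$n_used)

  # with fewer than 1/(1 - tau) points, a far outlier pulls the
  # 99th-quantile envelope to itself (the pinball balance tips at n = 100)
  keep <- seq_len(80)
  mu2 <- mu[keep]; mu2[40] <- 10 * env[keep][40]
  d2 <- fit_quantile_exponential(tt[keep], mu2, tau = 0.99)
  r2 <- log(mu2[40]) - (log(d2$intercept_a) + d2$slope_b * tt[keep][40])
  expect_lte(r2, 1e-8)
  # and the returned fit is loss-optimal against exhaustive line search
  oracle <- brute_rq(tt[keep], log(mu2), 0.99)
  expect_lte(d2$loss, oracle$loss + 1e-9)
})

test_that("preconditions and degeneracies error informatively", {
  expect_error(fit_quantile_exponential(1:8, rep(0.5, 8)), "insufficient")
  expect_error(fit_quantile_exponential(rep(20, 12), runif(12, 0.1, 1)),
               "rank")
  dat <- envelope_data(60, 0.6, 0.05, 0.9, 1)
  d <- fit_quantile_exponential(dat$temperature, dat$growth_rate, tau = 0.9)
  expect_error(bootstrap_dependency_ci(d, n_iter = 50), "at least 100")
  expect_error(bootstrap_dependency_ci(d, method = "jackknife"),
               "'arg' should be")
})

test_that("scaling growth rates rescales the intercept and leaves the slope fixed", {
  dat <- envelope_data(120, 0.6, 0.05, 0.99, 3)
  d1 <- fit_quantile_exponential(dat$temperature, dat$growth_rate)
  d2 <- fit_quantile_exponential(dat$temperature, 3 * dat$growth_rate)
  expect_equal(d2$slope_b, d1$slope_b, tolerance = 1e-9)
  expect_equal(d2$intercept_a, 3 * d1$intercept_a, tolerance = 1e-9)
})

test_that("Q10 and activation energy follow the printed coefficient pairs", {
  qe <- q10_and_activation_energy(log(1.88) / 10)
  expect_equal(qe$Q10, 1.88)
  expect_equal(round(qe$Ea, 2), 0.41)
  expect_equal(round(q10_and_activation_energy(log(2.13) / 10)$Ea, 2), 0.49)
  expect_equal(round(q10_and_activation_energy(log(1.67) / 10)$Ea, 2), 0.33)
  zero <- q10_and_activation_energy(0)
  expect_equal(zero$Q10, 1)
  expect_equal(zero$Ea, 0)
})

test_that("dependencies evaluate growth maxima consistently with their Q10", {
  eppley <- exponential_dependency(0.59, Q10 = 1.88)
  expect_equal(round(evaluate_mu_max(eppley, 20), 2), 2.09)
  expect_equal(evaluate_mu_max(eppley, 0), 0.59)
  cyano <- exponential_dependency(0.19, Q10 = 2.13)
  expect_equal(round(evaluate_mu_max(cyano, 20), 2), 0.86)
  # Q10 identity at arbitrary temperatures
  for (tt in c(-2, 0, 7.3, 19)) {
    expect_equal(evaluate_mu_max(cyano, tt + 10) / evaluate_mu_max(cyano, tt),
                 cyano$Q10, tolerance = 1e-12)
  }
  expect_error(exponential_dependency(0.5), "exactly one")
  expect_error(exponential_dependency(0.5, slope_b = 0.05, Q10 = 1.6),
               "exactly one")
})

test_that("bootstrap intervals are reproducible and collapse on a rigid envelope", {
  dat <- envelope_data(150, 0.6, 0.05, 0.9, 4)
  d <- fit_quantile_exponential(dat$temperature, dat$growth_rate, tau = 0.9)
  b1 <- bootstrap_dependency_ci(d, n_iter = 300, method = "mcmb", seed = 11)
  b2 <- bootstrap_dependency_ci(d, n_iter = 300, method = "mcmb", seed = 11)
  expect_identical(b1$ci, b2$ci)
  expect_lt(b1$ci$b[1], d$slope_b + 1e-9)
  expect_gt(b1$ci$b[2], d$slope_b - 1e-9)
  expect_lte(b1$ci$a[1], b1$ci$a[2])
  expect_lte(b1$ci$b[1], b1$ci$b[2])

  # curve band is centred at the bootstrap median and ordered
  expect_true(all(b1$ci$curve$lo <= b1$ci$curve$median + 1e-12))
  expect_true(all(b1$ci$curve$median <= b1$ci$curve$hi + 1e-12))

  # exact envelope with every point on the line: resampling cannot move it
  tt <- rep(seq(0, 30, 2.5), 4)
  d0 <- fit_quantile_exponential(tt, 0.6 * exp(0.05 * tt), tau = 0.99)
  b0 <- bootstrap_dependency_ci(d0, n_iter = 200, method = "pair", seed = 5)
  expect_lt(diff(b0$ci$b), 1e-6)

  # the pair bootstrap agrees with mcmb on the slope to first order
  bp <- bootstrap_dependency_ci(d, n_iter = 300, method = "pair", seed = 11)
  expect_lt(abs(mean(bp$boot[, "slope"]) - mean(b1$boot[, "slope"])), 0.01)
})

test_that("the group interaction improves pooled fits only when slopes differ", {
  mk <- function(b, pft, seed, n = 120) {
    dat <- envelope_data(n, 0.5, b, 0.9, seed)
    data.frame(strain_id = paste0(pft, "_", rep(1:12, length.out = n)),
               pft = pft, temperature = dat$temperature,
               growth_rate = dat$growth_rate)
  }
  ds_diff <- growth_dataset(rbind(mk(0.02, "diatom", 1),
                                  mk(0.08, "cyanobacterium", 2)))
  cmp <- compare_pft_interaction(ds_diff, tau = 0.9)
  expect_lt(cmp$table$AICc[2], cmp$table$AICc[1])

  # identical generating envelopes: interaction rarely earns its parameters
  verdicts <- vapply(1:60, function(s) {
    ds_same <- growth_dataset(rbind(mk(0.05, "diatom", 2 * s),
                                    mk(0.05, "cyanobacterium", 2 * s + 1)))
    tab <- compare_pft_interaction(ds_same, tau = 0.9)$table
    tab$AICc[1] <= tab$AICc[2] || abs(diff(tab$AICc)) < 4
  }, logical(1))
  expect_gte(mean(verdicts), 0.8)

  one <- growth_dataset(mk(0.05, "diatom", 99))
  expect_error(compare_pft_interaction(one), "at least two")
})

test_that("coefficient contrasts separate distinct envelopes and not identical ones", {
  mkd <- function(b, seed, n = 200) {
    dat <- envelope_data(n, 0.5, b, 0.9, seed)
    bootstrap_dependency_ci(
      fit_quantile_exponential(dat$temperature, dat$growth_rate, tau = 0.9),
      n_iter = 400, method = "mcmb", seed = seed)
  }
  same <- contrast_coefficients(list(g1 = mkd(0.05, 21), g2 = mkd(0.05, 22)))
  expect_false(same$slope_significant)
  expect_true(same$slope_lo <= 0 && same$slope_hi >= 0)

  diff_ <- contrast_coefficients(list(lo = mkd(0.040, 23), hi = mkd(0.075, 24)))
  expect_true(diff_$slope_significant)
  expect_lt(diff_$slope_hi, 0)

  d <- mkd(0.05, 25)
  self <- contrast_coefficients(list(a = d, b = d))
  expect_equal(self$slope_diff, 0)

  pdat <- envelope_data(60, 0.5, 0.05, 0.9, 26)
  plain <- fit_quantile_exponential(pdat$temperature, pdat$growth_rate,
                                    tau = 0.9)
  expect_error(contrast_coefficients(list(plain, plain)), "replicates")
})
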