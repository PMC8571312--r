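# Independent oracles used across tests: exhaustive two-point line search
# for quantile regression, dense-grid argmax for the thermal optimum, and
# small fixture builders.

# best tau-quantile line among all two-point interpolants (exact for the
# LP vertex solution at small n)
brute_rq <- function(x, y, tau) {
  best <- list(loss = Inf)
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (x[i] == x[j]) next
    b <- (y[j] - y[i]) / (x[j] - x[i])
    a <- y[i] - b * x[i]
    r <- y - a - b * x
    l <- sum(r * (tau - (r < 0)))
    if (l < best$loss) best <- list(intercept = a, slope = b, loss = l)
  }
  best
}

# argmax of the reaction norm on a dense temperature grid (coarse pass
# plus 1e-4 degC refinement around the coarse winner)
grid_topt <- function(p) {
  tmin <- p[["z"]] - p[["w"]] / 2
  tmax <- p[["z"]] + p[["w"]] / 2
  tt <- seq(tmin, tmax, by = 0.01)
  i <- which.max(norberg_growth(tt, p))
  tt2 <- seq(max(tmin, tt[i] - 0.02), min(tmax, tt[i] + 0.02), by = 1e-4)
  tt2[which.max(norberg_growth(tt2, p))]
}

# minimal valid growth table
tiny_growth_df <- function() {
  data.frame(
    strain_id = rep(c("s1", "s2"), each = 5),
    pft = rep(c("diatom", "dinoflagellate"), each = 5),
    temperature = rep(seq(10, 26, by = 4), 2),
    growth_rate = c(0.2, 0.5, 0.8, 0.6, 0.1, 0.1, 0.3, 0.5, 0.4, 0.1),
    light = 100, day_length = 12, is_diazotroph = FALSE,
    fluctuating_nutrients = FALSE,
    isolation_lat = rep(c(42, -10), each = 5),
    isolation_lon = rep(c(-30, 120), each = 5),
    source = "unit test")
}

# envelope dataset: log-growth has exact tau-quantile line a + b T
envelope_data <- function(n, a, b, tau, seed, noise = 0.3) {
  set.seed(seed)
  x <- stats::runif(n, 0, 30)
  y <- log(a) + b * x + noise * (stats::rnorm(n) - stats::qnorm(tau))
  data.frame(temperature = x, growth_rate = exp(y))
}
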