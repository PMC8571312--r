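#' Physical and procedural constants
#'
#' Boltzmann's constant in electron-volts, the reference temperature used
#' to convert exponential slopes to activation energies, and the default
#' quantile level, bootstrap size and significance level used by the
#' dependency fits.
#'
#' @return named list: \code{k_B} (8.617e-5 eV/K), \code{T_ref} (273.15 K),
#'   \code{tau_default} (0.99), \code{boot_iters_default} (10000),
#'   \code{alpha} (0.05).
#' @export
thermal_constants <- function() {
  list(k_B = 8.617e-5, T_ref = 273.15, tau_default = 0.99,
       boot_iters_default = 10000L, alpha = 0.05)
}

#' Temperature coefficient and activation energy from an exponential slope
#'
#' For the exponential maximum-growth dependency
#' \eqn{\mu_{max}(T) = a e^{bT}} the temperature coefficient is
#' \eqn{Q_{10} = e^{10 b}} and the Arrhenius-equivalent activation energy
#' is \eqn{E_a = b \, k_B \, T_{ref}^2} in eV, with \eqn{k_B} Boltzmann's
#' constant in eV/K and \eqn{T_{ref} = 273.15} K.
#'
#' @param slope_b exponential shape (per degree C); vectorised.
#' @return list with numeric \code{Q10} and \code{Ea} (eV).
#' @examples
#' q10_and_activation_energy(log(1.88) / 10)  # Q10 = 1.88, Ea ~ 0.41 eV
#' @export
q10_and_activation_energy <- function(slope_b) {
  stopifnot(all(is.finite(slope_b)))
  const <- thermal_constants()
  list(Q10 = exp(10 * slope_b),
       Ea = slope_b * const$k_B * const$T_ref^2)
}

#' Construct an exponential maximum-growth dependency
#'
#' Builds an \code{exp_dependency} object directly from coefficients, e.g.
#' from published compilations, so that maximum growth rates can be
#' evaluated and compared without refitting.  Exactly one of
#' \code{slope_b} or \code{Q10} must be given.
#'
#' @param intercept_a maximum growth rate at 0 degrees C (per day), > 0.
#' @param slope_b exponential shape (per degree C).
#' @param Q10 temperature coefficient; converted via
#'   \code{slope_b = log(Q10) / 10}.
#' @param tau nominal quantile level associated with the coefficients.
#' @param group label (functional type or "All").
#' @return object of class \code{exp_dependency}.
#' @examples
#' eppley <- exponential_dependency(0.59, Q10 = 1.88)
#' evaluate_mu_max(eppley, 20)
#' @export
exponential_dependency <- function(intercept_a, slope_b = NULL, Q10 = NULL,
                                   tau = 0.99, group = "All") {
  if (is.null(slope_b) == is.null(Q10)) {
    stop("supply exactly one of slope_b or Q10")
  }
  if (is.null(slope_b)) slope_b <- log(Q10) / 10
  stopifnot(is.finite(intercept_a), intercept_a > 0, is.finite(slope_b))
  qe <- q10_and_activation_energy(slope_b)
  structure(list(group = group, tau = tau,
                 intercept_a = intercept_a, slope_b = slope_b,
                 Q10 = qe$Q10, Ea = qe$Ea,
                 n_used = NA_integer_, n_dropped = NA_integer_,
                 loss = NA_real_, data = NULL, ci = NULL, boot = NULL,
                 method_meta = NULL),
            class = "exp_dependency")
}

#' Fit the exponential maximum-growth dependency by quantile regression
#'
#' Characterises how a group's maximum growth rate scales with temperature
#' by fitting the \eqn{\tau}-th (default 99th) regression quantile of
#' log-transformed growth rates against temperature:
#' \eqn{Q_\tau(\ln\mu \mid T) = \alpha + \beta T}, reported as
#' \eqn{\mu_{max}(T) = a e^{bT}} with \eqn{a = e^\alpha}, \eqn{b = \beta}.
#' Fitting an extreme upper quantile uses every measurement while tracking
#' the growth envelope, rather than the mean response.  The minimiser is
#' exact (a vertex of the pinball-loss linear program), found by convex
#' profile search with a two-point polish.  Nonpositive growth rates
#' cannot be log-transformed and are dropped first; the count is kept.
#'
#' @param temperature assay temperatures (degrees C), or a
#'   \code{growth_dataset} (in which case \code{growth_rate} is ignored).
#' @param growth_rate specific growth rates (per day).
#' @param tau quantile level in (0, 1); default 0.99.
#' @param group label stored on the result.
#' @param min_positive minimum number of positive rates required
#'   (default 10).
#' @return object of class \code{exp_dependency} with elements
#'   \code{intercept_a}, \code{slope_b}, \code{Q10}, \code{Ea},
#'   \code{n_used}, \code{n_dropped}, \code{loss}, and the fitting data.
#' @seealso [bootstrap_dependency_ci()], [evaluate_mu_max()],
#'   [compare_pft_interaction()]
#' @export
fit_quantile_exponential <- function(temperature, growth_rate = NULL,
                                     tau = 0.99, group = "All",
                                     min_positive = 10) {
  if (inherits(temperature, "growth_dataset")) {
    growth_rate <- temperature$growth_rate
    temperature <- temperature$temperature
  }
  stopifnot(length(temperature) == length(growth_rate),
            tau > 0, tau < 1)
  pos <- is.finite(growth_rate) & growth_rate > 0 & is.finite(temperature)
  n_dropped <- sum(!pos)
  x <- temperature[pos]
  y <- log(growth_rate[pos])
  if (length(x) < min_positive) {
    stop(sprintf(
      "insufficient data: %d positive growth rates, need at least %d",
      length(x), min_positive))
  }
  if (length(unique(x)) < 2) {
    stop("rank error: all measurements share one temperature")
  }
  f <- rq_line(x, y, tau)
  qe <- q10_and_activation_energy(f$slope)
  structure(list(group = group, tau = tau,
                 intercept_a = exp(f$intercept), slope_b = f$slope,
                 Q10 = qe$Q10, Ea = qe$Ea,
                 n_used = length(x), n_dropped = n_dropped,
                 loss = f$loss,
                 data = data.frame(temperature = x, log_growth = y),
                 ci = NULL, boot = NULL, method_meta = NULL),
            class = "exp_dependency")
}

#' Evaluate a dependency's maximum growth rate at a temperature
#'
#' @param dep an \code{exp_dependency}.
#' @param temperature degrees C (vectorised).
#' @return per-day rate \code{intercept_a * exp(slope_b * temperature)},
#'   equivalently \code{intercept_a * Q10^(temperature / 10)}.
#' @export
evaluate_mu_max <- function(dep, temperature) {
  stopifnot(inherits(dep, "exp_dependency"))
  dep$intercept_a * exp(dep$slope_b * temperature)
}

#' @export
coef.exp_dependency <- function(object, ...) {
  c(intercept_a = object$intercept_a, slope_b = object$slope_b)
}

#' @export
predict.exp_dependency <- function(object, temperature, ...) {
  evaluate_mu_max(object, temperature)
}

#' @export
print.exp_dependency <- function(x, ...) {
  cat(sprintf("Exponential maximum-growth dependency [%s], tau = %g\n",
              x$group, x$tau))
  cat(sprintf("  mu_max(T) = %.4g * exp(%.4g T)   Q10 = %.3f   Ea = %.3f eV\n",
              x$intercept_a, x$slope_b, x$Q10, x$Ea))
  if (!is.na(x$n_used)) {
    cat(sprintf("  n = %d measurements used (%d nonpositive dropped)\n",
                x$n_used, x$n_dropped))
  }
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI  a: [%.4g, %.4g]   b: [%.4g, %.4g]  (%s, %d iters)\n",
                x$ci$a[1], x$ci$a[2], x$ci$b[1], x$ci$b[2],
                x$method_meta$method, x$method_meta$n_iter))
  }
  invisible(x)
}

#' @export
plot.exp_dependency <- function(x, ...) {
  if (is.null(x$data)) stop("dependency carries no fitting data")
  graphics::plot(x$data$temperature, exp(x$data$log_growth),
                 xlab = "Temperature (degC)", ylab = "Growth rate (/d)",
                 log = "y", ...)
  tt <- seq(min(x$data$temperature), max(x$data$temperature),
            length.out = 100)
  graphics::lines(tt, evaluate_mu_max(x, tt))
  if (!is.null(x$ci$curve)) {
    graphics::lines(x$ci$curve$temperature, x$ci$curve$lo, lty = 2)
    graphics::lines(x$ci$curve$temperature, x$ci$curve$hi, lty = 2)
  }
  invisible(x)
}

#' Bootstrap confidence intervals for an exponential dependency
#'
#' Attaches percentile 95 percent intervals for the intercept and slope and
#' a pointwise curve band centred at the bootstrap median.  Two resampling
#' schemes are provided: \code{"mcmb"}, the Markov chain marginal bootstrap
#' (coordinate-wise one-dimensional updates of the quantile estimating
#' equations, cheap enough for large compilations and many iterations),
#' and \code{"pair"}, a plain case-resampling bootstrap refitting the
#' exact quantile line each draw.  Results are reproducible given
#' \code{seed}.
#'
#' @param dep a fitted \code{exp_dependency} (must carry fitting data).
#' @param n_iter bootstrap iterations (>= 100; default 10000).
#' @param method \code{"mcmb"} (default) or \code{"pair"}.
#' @param seed integer RNG seed.
#' @param level confidence level (default 0.95).
#' @param t_step spacing (degrees C) of the curve-band grid over the data's
#'   temperature range.
#' @return \code{dep} with \code{boot} (draw matrix), \code{ci} (elements
#'   \code{a}, \code{b}, \code{curve}) and \code{method_meta} filled in.
#' @export
bootstrap_dependency_ci <- function(dep, n_iter = 10000,
                                    method = c("mcmb", "pair"),
                                    seed = 1, level = 0.95, t_step = 0.5) {
  stopifnot(inherits(dep, "exp_dependency"))
  if (is.null(dep$data)) stop("dependency carries no fitting data")
  if (n_iter < 100) stop("n_iter must be at least 100")
  method <- match.arg(method)
  x <- dep$data$temperature
  y <- dep$data$log_growth
  fit <- list(intercept = log(dep$intercept_a), slope = dep$slope_b)
  set.seed(seed)
  draws <- switch(method,
    mcmb = mcmb_chain(x, y, dep$tau, fit, n_iter),
    pair = pair_boot(x, y, dep$tau, n_iter))
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  tt <- seq(min(x), max(x), by = t_step)
  curves <- exp(outer(draws[, "intercept"], rep(1, length(tt))) +
                  outer(draws[, "slope"], tt))
  band <- apply(curves, 2, stats::quantile, probs = c(pr[1], 0.5, pr[2]))
  dep$boot <- draws
  dep$ci <- list(
    a = unname(stats::quantile(exp(draws[, "intercept"]), pr)),
    b = unname(stats::quantile(draws[, "slope"], pr)),
    curve = data.frame(temperature = tt, lo = band[1, ],
                       median = band[2, ], hi = band[3, ]))
  dep$method_meta <- list(method = method, n_iter = n_iter, seed = seed,
                          level = level)
  dep
}

# Maximised asymmetric-Laplace log-likelihood for a quantile fit with total
# pinball loss V on n points: scale sigma_hat = V/n.
al_loglik <- function(V, n, tau) {
  n * log(tau * (1 - tau)) - n * log(V / n) - n
}

#' Compare pooled dependency models with and without a group interaction
#'
#' Fits the quantile exponential to pooled measurements twice: M0, one
#' common intercept and slope for all functional types, and M1,
#' group-specific intercepts and slopes (independent per-group fits at the
#' same quantile).  Models are compared by AICc computed from the maximised
#' asymmetric-Laplace quasi-likelihood at level \code{tau}, counting one
#' scale parameter plus the regression coefficients.  A lower AICc for M1
#' indicates the temperature-by-group interaction improves the pooled
#' description.  Groups with fewer than \code{min_positive} positive rates
#' are excluded and listed.
#'
#' @param ds a \code{growth_dataset} with at least two functional types.
#' @param tau quantile level (default 0.99).
#' @param min_positive per-group minimum positive rates (default 10).
#' @return list with \code{table} (model, k, loglik, AICc, delta_AICc),
#'   \code{excluded_groups} and the per-group fits.
#' @export
compare_pft_interaction <- function(ds, tau = 0.99, min_positive = 10) {
  stopifnot(inherits(ds, "growth_dataset"))
  pos <- ds$growth_rate > 0
  counts <- table(ds$pft[pos])
  ok <- names(counts)[counts >= min_positive]
  excluded <- setdiff(unique(ds$pft), ok)
  if (length(ok) < 2) {
    stop("need at least two functional types with enough positive rates")
  }
  sub <- ds[ds$pft %in% ok & pos, ]
  n <- nrow(sub)
  m0 <- rq_line(sub$temperature, log(sub$growth_rate), tau)
  fits <- lapply(ok, function(g) {
    gi <- sub$pft == g
    rq_line(sub$temperature[gi], log(sub$growth_rate[gi]), tau)
  })
  names(fits) <- ok
  v1 <- sum(vapply(fits, `[[`, numeric(1), "loss"))
  k0 <- 2 + 1
  k1 <- 2 * length(ok) + 1
  ll0 <- al_loglik(m0$loss, n, tau)
  ll1 <- al_loglik(v1, n, tau)
  aicc <- function(k, ll) 2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1)
  tab <- data.frame(
    model = c("M0: common slope and intercept",
              "M1: group-specific slopes and intercepts"),
    k = c(k0, k1), loglik = c(ll0, ll1),
    AICc = c(aicc(k0, ll0), aicc(k1, ll1)))
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  list(table = tab, excluded_groups = excluded, group_fits = fits,
       pooled_fit = m0, n = n, tau = tau)
}

#' Pairwise coefficient contrasts between bootstrapped dependencies
#'
#' For every pair of dependencies carrying bootstrap replicates, computes
#' the difference of slopes and of intercepts (first minus second) with
#' percentile confidence intervals formed from the paired bootstrap draws;
#' a difference is flagged significant when its interval excludes zero.
#'
#' @param deps named list of \code{exp_dependency} objects, each with
#'   bootstrap replicates (see [bootstrap_dependency_ci()]).
#' @param alpha significance level (default 0.05).
#' @return data frame with one row per ordered pair: groups, slope and
#'   intercept differences, CI bounds, significance flags.
#' @export
contrast_coefficients <- function(deps, alpha = 0.05) {
  if (is.null(names(deps))) names(deps) <- seq_along(deps)
  for (d in deps) {
    if (!inherits(d, "exp_dependency") || is.null(d$boot)) {
      stop("every dependency must carry bootstrap replicates")
    }
  }
  pr <- c(alpha / 2, 1 - alpha / 2)
  out <- list()
  nm <- names(deps)
  for (i in seq_along(deps)) for (j in seq_along(deps)) {
    if (j <= i) next
    d1 <- deps[[i]]; d2 <- deps[[j]]
    m <- min(nrow(d1$boot), nrow(d2$boot))
    db <- d1$boot[seq_len(m), "slope"] - d2$boot[seq_len(m), "slope"]
    da <- exp(d1$boot[seq_len(m), "intercept"]) -
      exp(d2$boot[seq_len(m), "intercept"])
    cb <- unname(stats::quantile(db, pr))
    ca <- unname(stats::quantile(da, pr))
    out[[length(out) + 1L]] <- data.frame(
      group1 = nm[i], group2 = nm[j],
      slope_diff = d1$slope_b - d2$slope_b,
      slope_lo = cb[1], slope_hi = cb[2],
      slope_significant = cb[1] > 0 | cb[2] < 0,
      intercept_diff = d1$intercept_a - d2$intercept_a,
      intercept_lo = ca[1], intercept_hi = ca[2],
      intercept_significant = ca[1] > 0 | ca[2] < 0)
  }
  do.call(rbind, out)
}
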