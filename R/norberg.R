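#' Norberg thermal reaction norm
#'
#' Evaluates the unimodal thermal performance curve
#' \deqn{\mu(T) = a\,e^{bT}\left[1 - \left(\frac{T - z}{w/2}\right)^2\right]}
#' used to describe a strain's specific growth rate as a function of
#' temperature.  The curve is the product of an exponential envelope
#' (scale \code{a}, shape \code{b}) and a downward parabola that is zero at
#' the niche limits \code{z - w/2} and \code{z + w/2}.
#'
#' Values are returned as computed: the curve is negative outside the niche
#' \code{(z - w/2, z + w/2)}.  Callers that need a viability semantics (for
#' example the projection functions) clamp negative growth to zero
#' themselves.
#'
#' @param temperature numeric vector of temperatures (degrees C).
#' @param params reaction-norm parameters: a named vector or list with
#'   elements \code{a} (per-day scale), \code{b} (per degree C exponential
#'   shape), \code{z} (niche midpoint, degrees C) and \code{w} (niche width,
#'   degrees C, strictly positive).
#' @return numeric vector of growth rates (per day), same length as
#'   \code{temperature}.
#' @examples
#' norberg_growth(20, c(a = 1, b = 0, z = 20, w = 20))   # 1 at the vertex
#' norberg_growth(c(10, 30), c(a = 1, b = 0, z = 20, w = 20))  # niche edges
#' @export
norberg_growth <- function(temperature, params) {
  p <- as_norberg_params(params)
  u <- (temperature - p[["z"]]) / (p[["w"]] / 2)
  p[["a"]] * exp(p[["b"]] * temperature) * (1 - u^2)
}

#' Validate and normalise reaction-norm parameters
#'
#' @param params named vector or list with elements a, b, z, w.
#' @return named numeric vector \code{c(a, b, z, w)}.
#' @keywords internal
as_norberg_params <- function(params) {
  p <- unlist(params)[c("a", "b", "z", "w")]
  if (anyNA(p)) {
    stop("reaction-norm parameters must supply named elements a, b, z, w")
  }
  if (!all(is.finite(p))) {
    stop("reaction-norm parameters must all be finite")
  }
  if (p[["w"]] <= 0) {
    stop("thermal niche width w must be strictly positive")
  }
  p
}

#' Control settings for reaction-norm fitting
#'
#' @param min_distinct_temps minimum number of distinct assay temperatures
#'   required before a fit is attempted.
#' @param z_grid,w_grid,b_grid multi-start grids for the niche midpoint,
#'   width and exponential shape (degrees C, degrees C, per degree C).  The
#'   scale start is taken from the largest observed growth rate.
#' @param b_bounds,w_bounds,z_bounds box constraints used by the optimiser;
#'   width and scale are optimised on the log scale so positivity is
#'   structural.
#' @param tmax_qc_margin allowed extrapolation (degrees C) of the fitted
#'   upper thermal limit beyond the warmest assayed temperature before the
#'   fit fails quality control (see [qc_tmax()]).
#' @return a list of class \code{norberg_control}.
#' @export
norberg_control <- function(min_distinct_temps = 4,
                            z_grid = seq(5, 35, by = 5),
                            w_grid = c(10, 20, 30, 40),
                            b_grid = c(0, 0.05, 0.1),
                            b_bounds = c(-0.2, 0.4),
                            w_bounds = c(2, 80),
                            z_bounds = c(-20, 60),
                            tmax_qc_margin = 5) {
  stopifnot(min_distinct_temps >= 3, w_bounds[1] > 0,
            diff(b_bounds) > 0, diff(w_bounds) > 0, diff(z_bounds) > 0)
  structure(list(min_distinct_temps = min_distinct_temps,
                 z_grid = z_grid, w_grid = w_grid, b_grid = b_grid,
                 b_bounds = b_bounds, w_bounds = w_bounds,
                 z_bounds = z_bounds, tmax_qc_margin = tmax_qc_margin),
            class = "norberg_control")
}

#' Fit a thermal reaction norm to one strain's growth measurements
#'
#' Maximum-likelihood fit of the Norberg curve under Gaussian observation
#' noise with a constant (estimated) standard deviation.  With constant
#' noise the likelihood is maximised by minimising the residual sum of
#' squares; the profile noise scale is \code{sigma = sqrt(SSE / n)}.  A
#' deterministic multi-start over a coarse grid of niche midpoints, widths
#' and shapes guards against the local optima this curve family is known
#' for; the best (lowest negative log-likelihood) start wins, with ties
#' broken towards the narrower niche and then the flatter exponential.
#'
#' @param temperature numeric vector of assay temperatures (degrees C).
#' @param growth_rate numeric vector of specific growth rates (per day),
#'   same length.
#' @param control a [norberg_control()] list.
#' @return an object of class \code{norberg_fit}: a list with elements
#'   \code{params} (named vector a, b, z, w), \code{sigma}, \code{nll},
#'   \code{n_points}, \code{n_distinct_temps}, \code{converged},
#'   \code{data} (the fitting frame) and \code{control}.
#' @seealso [derive_traits()], [performance_breadth()], [qc_tmax()]
#' @examples
#' p <- c(a = 1, b = 0.05, z = 18, w = 24)
#' tt <- seq(8, 29, by = 3)
#' fit <- fit_reaction_norm(tt, norberg_growth(tt, p))
#' coef(fit)
#' @export
fit_reaction_norm <- function(temperature, growth_rate,
                              control = norberg_control()) {
  stopifnot(length(temperature) == length(growth_rate))
  keep <- is.finite(temperature) & is.finite(growth_rate)
  temperature <- temperature[keep]
  growth_rate <- growth_rate[keep]
  n_distinct <- length(unique(temperature))
  if (n_distinct < control$min_distinct_temps) {
    stop(sprintf(
      "insufficient data: %d distinct temperatures, need at least %d",
      n_distinct, control$min_distinct_temps))
  }
  if (!any(growth_rate > 0)) {
    stop("degenerate data: no positive growth rates to anchor the curve")
  }
  n <- length(growth_rate)
  mu_top <- max(growth_rate)

  sse_fun <- function(theta) {
    a <- exp(theta[1]); b <- theta[2]; z <- theta[3]; w <- exp(theta[4])
    u <- (temperature - z) / (w / 2)
    r <- growth_rate - a * exp(b * temperature) * (1 - u^2)
    sum(r * r)
  }
  sse_grad <- function(theta) {
    a <- exp(theta[1]); b <- theta[2]; z <- theta[3]; w <- exp(theta[4])
    u <- (temperature - z) / (w / 2)
    e <- a * exp(b * temperature)
    mu <- e * (1 - u^2)
    r <- growth_rate - mu
    c(-2 * sum(r * mu),                    # d/d log a
      -2 * sum(r * mu * temperature),      # d/d b
      -2 * sum(r * e * 4 * u / w),         # d/d z
      -2 * sum(r * e * 2 * u^2))           # d/d log w
  }
  lower <- c(-20, control$b_bounds[1], control$z_bounds[1],
             log(control$w_bounds[1]))
  upper <- c(20, control$b_bounds[2], control$z_bounds[2],
             log(control$w_bounds[2]))

  best <- NULL
  for (z0 in control$z_grid) for (w0 in control$w_grid)
    for (b0 in control$b_grid) {
      a0 <- mu_top * exp(-b0 * z0)
      theta0 <- pmin(pmax(c(log(max(a0, 1e-8)), b0, z0, log(w0)),
                          lower + 1e-6), upper - 1e-6)
      opt <- tryCatch(
        stats::optim(theta0, sse_fun, sse_grad, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 1000, factr = 1e3)),
        error = function(e) NULL)
      if (is.null(opt) || !is.finite(opt$value)) next
      cand <- list(theta = opt$par, sse = opt$value,
                   converged = opt$convergence == 0)
      if (is.null(best) || cand$sse < best$sse - 1e-10 ||
          (abs(cand$sse - best$sse) <= 1e-10 &&
           (exp(cand$theta[4]) < exp(best$theta[4]) - 1e-9 ||
            (abs(exp(cand$theta[4]) - exp(best$theta[4])) <= 1e-9 &&
             abs(cand$theta[2]) < abs(best$theta[2]))))) {
        best <- cand
      }
    }
  if (is.null(best)) {
    stop("reaction-norm optimisation failed from every start")
  }
  sigma <- sqrt(best$sse / n)
  nll <- if (sigma > 0) {
    n / 2 * (log(2 * pi * sigma^2) + 1)
  } else {
    -Inf  # perfect interpolation; likelihood unbounded, flagged not used
  }
  structure(list(
    params = c(a = exp(best$theta[1]), b = best$theta[2],
               z = best$theta[3], w = exp(best$theta[4])),
    sigma = sigma, nll = nll, n_points = n,
    n_distinct_temps = n_distinct, converged = best$converged,
    data = data.frame(temperature = temperature, growth_rate = growth_rate),
    control = control), class = "norberg_fit")
}

#' @export
coef.norberg_fit <- function(object, ...) object$params

#' @export
print.norberg_fit <- function(x, ...) {
  p <- x$params
  cat("Thermal reaction norm (Norberg) fit\n")
  cat(sprintf("  a = %.4g /d   b = %.4g /degC   z = %.2f degC   w = %.2f degC\n",
              p[["a"]], p[["b"]], p[["z"]], p[["w"]]))
  tr <- derive_traits(x)
  cat(sprintf("  T_opt = %.2f degC   mu_max = %.3f /d   niche = (%.2f, %.2f) degC\n",
              tr$T_opt, tr$mu_max, tr$T_min, tr$T_max))
  cat(sprintf("  n = %d points (%d temperatures), sigma = %.4g, converged: %s\n",
              x$n_points, x$n_distinct_temps, x$sigma, x$converged))
  invisible(x)
}

#' @export
predict.norberg_fit <- function(object, temperature = NULL, ...) {
  if (is.null(temperature)) temperature <- object$data$temperature
  norberg_growth(temperature, object$params)
}

#' @export
residuals.norberg_fit <- function(object, ...) {
  object$data$growth_rate - predict(object)
}

#' @export
fitted.norberg_fit <- function(object, ...) predict(object)

#' @export
logLik.norberg_fit <- function(object, ...) {
  structure(-object$nll, df = 5L, nobs = object$n_points, class = "logLik")
}

#' @export
simulate.norberg_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  out <- as.data.frame(replicate(
    nsim, pmax(mu + stats::rnorm(length(mu), 0, object$sigma), 0)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.norberg_fit <- function(x, ...) {
  tr <- derive_traits(x)
  tt <- seq(tr$T_min, tr$T_max, length.out = 200)
  graphics::plot(x$data$temperature, x$data$growth_rate,
                 xlab = "Temperature (degC)",
                 ylab = "Growth rate (/d)", ...)
  graphics::lines(tt, norberg_growth(tt, x$params))
  graphics::abline(v = tr$T_opt, lty = 3)
  invisible(x)
}

#' @export
summary.norberg_fit <- function(object, ...) {
  out <- c(as.list(object$params),
           derive_traits(object),
           performance_breadth(object),
           list(sigma = object$sigma, nll = object$nll,
                n_points = object$n_points,
                n_distinct_temps = object$n_distinct_temps,
                converged = object$converged,
                tmax_qc_pass = qc_tmax(object)))
  class(out) <- "summary.norberg_fit"
  out
}

#' @export
print.summary.norberg_fit <- function(x, ...) {
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Thermal traits of a reaction norm
#'
#' Derives the classical thermal traits from Norberg parameters.  The niche
#' limits are \code{T_min = z - w/2} and \code{T_max = z + w/2}.  The
#' optimum has the closed form \code{T_opt = z + (w/2) u*} with
#' \code{u* = (-2 + sqrt(4 + b^2 w^2)) / (b w)} when \code{b != 0} (the
#' root of the first-order condition inside the niche) and \code{u* = 0}
#' for a symmetric curve.
#'
#' @param params reaction-norm parameters (named vector/list), or a
#'   \code{norberg_fit}.
#' @return list with \code{T_opt}, \code{mu_max}, \code{T_min},
#'   \code{T_max}, \code{niche_width} (all degrees C except \code{mu_max},
#'   per day).
#' @examples
#' derive_traits(c(a = 1, b = 0, z = 20, w = 20))
#' @export
derive_traits <- function(params) {
  if (inherits(params, "norberg_fit")) params <- params$params
  p <- as_norberg_params(params)
  a <- p[["a"]]; b <- p[["b"]]; z <- p[["z"]]; w <- p[["w"]]
  u_star <- if (b == 0) 0 else (-2 + sqrt(4 + b^2 * w^2)) / (b * w)
  t_opt <- z + (w / 2) * u_star
  list(T_opt = t_opt,
       mu_max = norberg_growth(t_opt, p),
       T_min = z - w / 2,
       T_max = z + w / 2,
       niche_width = w)
}

#' Thermal performance breadth and limb slopes
#'
#' Finds the two temperatures at which growth equals a fraction (default
#' 20 percent) of the maximum, one on each limb of the curve, by bisection
#' to 1e-8 degrees C, and the average rates of performance change along
#' each limb: \code{slope_up = (1 - fraction) mu_max / (T_opt - T_lo)} and
#' \code{slope_down = (1 - fraction) mu_max / (T_hi - T_opt)}, both
#' reported as magnitudes.  A steeper descending than ascending slope marks
#' a negatively skewed curve.
#'
#' @inheritParams derive_traits
#' @param fraction performance threshold as a fraction of \code{mu_max},
#'   in (0, 1).
#' @return list with \code{T_lo}, \code{T_hi} (degrees C), \code{slope_up},
#'   \code{slope_down} (per day per degree C).
#' @examples
#' performance_breadth(c(a = 1, b = 0, z = 20, w = 20))
#' @export
performance_breadth <- function(params, fraction = 0.2) {
  if (inherits(params, "norberg_fit")) params <- params$params
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1")
  }
  p <- as_norberg_params(params)
  tr <- derive_traits(p)
  target <- fraction * tr$mu_max
  f <- function(tt) norberg_growth(tt, p) - target
  t_lo <- stats::uniroot(f, lower = tr$T_min, upper = tr$T_opt,
                         tol = 1e-8)$root
  t_hi <- stats::uniroot(f, lower = tr$T_opt, upper = tr$T_max,
                         tol = 1e-8)$root
  list(T_lo = t_lo, T_hi = t_hi,
       slope_up = (tr$mu_max - target) / (tr$T_opt - t_lo),
       slope_down = (tr$mu_max - target) / (t_hi - tr$T_opt))
}

#' Quality control of the fitted upper thermal limit
#'
#' A fitted upper thermal limit is only trusted when the data constrain it:
#' the fit passes when (i) at least one measurement lies above the fitted
#' optimum, so the descending limb was observed, and (ii) the fitted
#' \code{T_max} does not extrapolate more than \code{margin} degrees C
#' beyond the warmest assayed temperature.  Strains failing QC are excluded
#' from thermal-capacity analyses but still contribute measurements to the
#' group-level quantile fits.
#'
#' @param fit a \code{norberg_fit}.
#' @param temperature assay temperatures; defaults to those stored in the
#'   fit.
#' @param margin allowed extrapolation in degrees C (default from the fit's
#'   control, itself defaulting to 5).
#' @return logical flag.
#' @export
qc_tmax <- function(fit, temperature = fit$data$temperature,
                    margin = fit$control$tmax_qc_margin) {
  stopifnot(inherits(fit, "norberg_fit"))
  if (!isTRUE(fit$converged)) return(FALSE)
  tr <- derive_traits(fit)
  any(temperature > tr$T_opt) && tr$T_max <= max(temperature) + margin
}
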