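# Exact linear quantile regression in one covariate.
#
# The tau-th regression quantile minimises the pinball (asymmetric absolute)
# loss sum_i rho_tau(y_i - alpha - beta x_i).  Profiling out the intercept
# -- for fixed slope the optimal alpha is the tau-th sample quantile of
# y - beta x -- leaves a convex piecewise-linear function of the slope,
# which golden-section search minimises to numerical precision; a final
# polish over lines through pairs of near-active points recovers the exact
# vertex solution of the underlying linear program.

#' Pinball (quantile) loss
#' @param r residual vector.
#' @param tau quantile level in (0, 1).
#' @return total loss.
#' @keywords internal
pinball_loss <- function(r, tau) sum(r * (tau - (r < 0)))

# Exact minimiser of sum rho_tau(u - a): the type-1 tau-th sample quantile.
quantile_intercept <- function(u, tau) {
  su <- sort(u)
  su[min(length(u), max(1L, ceiling(length(u) * tau)))]
}

# Exact tau-th quantile line fit.  Returns intercept/slope/loss.
rq_line <- function(x, y, tau, bracket = c(-2, 2)) {
  n <- length(x)
  stopifnot(length(y) == n, tau > 0, tau < 1)
  if (n < 2 || length(unique(x)) < 2) {
    stop("rank error: need at least two distinct covariate values")
  }
  profile <- function(b) {
    a <- quantile_intercept(y - b * x, tau)
    pinball_loss(y - a - b * x, tau)
  }
  lo <- bracket[1]; hi <- bracket[2]
  for (round in 1:6) {
    opt <- stats::optimize(profile, c(lo, hi), tol = 1e-12)
    span <- hi - lo
    if (opt$minimum > lo + 1e-6 * span && opt$minimum < hi - 1e-6 * span) break
    lo <- lo - span; hi <- hi + span  # optimum pinned at bracket edge: widen
  }
  b <- opt$minimum
  a <- quantile_intercept(y - b * x, tau)
  best <- list(intercept = a, slope = b,
               loss = pinball_loss(y - a - b * x, tau))
  # vertex polish: the exact optimum interpolates two data points
  res <- abs(y - a - b * x)
  cand <- order(res)[seq_len(min(n, 8L))]
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (j <= i) next
    p <- cand[i]; q <- cand[j]
    if (x[p] == x[q]) next
    bb <- (y[q] - y[p]) / (x[q] - x[p])
    aa <- y[p] - bb * x[p]
    loss <- pinball_loss(y - aa - bb * x, tau)
    if (loss < best$loss - 1e-12) {
      best <- list(intercept = aa, slope = bb, loss = loss)
    }
  }
  best$n <- n
  best$tau <- tau
  best
}

# Solve sum_i v_i * psi_tau(y_i - offset_i - v_i * xi) = target in xi,
# where the left side is a non-increasing step function of xi.  Used by the
# marginal bootstrap one-dimensional updates.
solve_marginal <- function(v, resid0, tau, target) {
  nz <- v != 0
  if (!any(nz)) stop("marginal solve: all covariate entries zero")
  v <- v[nz]
  bp <- resid0[nz] / v                 # breakpoints in xi
  s_start <- tau * sum(v[v > 0]) + (tau - 1) * sum(v[v < 0])
  ord <- order(bp)
  cum <- s_start - cumsum(abs(v)[ord])
  idx <- which(cum <= target)
  if (!length(idx)) return(bp[ord][length(bp)])
  bp[ord][idx[1]]
}

# Markov chain marginal bootstrap (coordinate-wise one-dimensional updates)
# for the two-parameter quantile line.  Returns an n_iter x 2 matrix of
# (intercept, slope) draws.
mcmb_chain <- function(x, y, tau, fit, n_iter) {
  n <- length(x)
  X <- cbind(1, x)
  beta <- c(fit$intercept, fit$slope)
  e_hat <- y - X %*% beta
  psi_hat <- tau - (e_hat < 0)
  z <- X * as.vector(psi_hat)          # n x 2 score contributions
  draws <- matrix(NA_real_, n_iter, 2)
  for (k in seq_len(n_iter)) {
    for (j in 1:2) {
      target <- sum(z[sample.int(n, n, replace = TRUE), j])
      partial <- y - X[, -j, drop = FALSE] %*% beta[-j]
      beta[j] <- solve_marginal(X[, j], as.vector(partial), tau, target)
    }
    draws[k, ] <- beta
  }
  colnames(draws) <- c("intercept", "slope")
  draws
}

# (x, y)-pair bootstrap for the quantile line.
pair_boot <- function(x, y, tau, n_iter) {
  n <- length(x)
  draws <- matrix(NA_real_, n_iter, 2)
  k <- 1L
  while (k <= n_iter) {
    idx <- sample.int(n, n, replace = TRUE)
    f <- tryCatch(rq_line(x[idx], y[idx], tau), error = function(e) NULL)
    if (is.null(f)) next                # resample drew a degenerate design
    draws[k, ] <- c(f$intercept, f$slope)
    k <- k + 1L
  }
  colnames(draws) <- c("intercept", "slope")
  draws
}
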