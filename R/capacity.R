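#' Static thermal-capacity metrics for one strain
#'
#' Given a strain's reaction norm and its baseline habitat temperature
#' \code{T_hab}, computes three warming-tolerance metrics (all in degrees
#' C of warming relative to \code{T_hab}):
#' \describe{
#'   \item{TSM}{thermal safety margin, \code{T_opt - T_hab}; negative when
#'     the strain already lives above its optimum.}
#'   \item{DGE}{distance to growth equivalence: warming sustainable before
#'     growth falls below its habitat-temperature value.  Defined through
#'     \code{T_equiv}, the temperature above the optimum at which growth
#'     equals growth at \code{T_hab}; \code{DGE = T_equiv - T_hab}.  Zero
#'     when \code{T_hab >= T_opt}; equal to WT when the habitat sits at or
#'     below the cold niche limit (zero growth at home, so any temperature
#'     up to \code{T_max} is no worse).}
#'   \item{WT}{warming tolerance, \code{T_max - T_hab}: warming until the
#'     upper lethal limit.}
#' }
#' On the ascending limb (\code{T_min < T_hab < T_opt}) the ordering
#' \code{TSM <= DGE <= WT} always holds.  \code{T_equiv} is found by
#' bisection on \code{(T_opt, T_max]} to 1e-8 degrees C.
#'
#' @param params reaction-norm parameters (or a \code{norberg_fit}).
#' @param T_hab baseline habitat temperature (degrees C).
#' @return list with \code{T_hab}, \code{TSM}, \code{DGE}, \code{WT} and
#'   \code{T_equiv} (NA when the DGE is zero by definition).
#' @examples
#' capacity_metrics(c(a = 1, b = 0, z = 20, w = 20), T_hab = 15)
#' @export
capacity_metrics <- function(params, T_hab) {
  if (inherits(params, "norberg_fit")) params <- params$params
  p <- as_norberg_params(params)
  stopifnot(is.finite(T_hab))
  tr <- derive_traits(p)
  tsm <- tr$T_opt - T_hab
  wt <- tr$T_max - T_hab
  if (T_hab >= tr$T_opt) {
    dge <- 0
    t_equiv <- NA_real_
  } else if (T_hab <= tr$T_min) {
    t_equiv <- tr$T_max
    dge <- wt
  } else {
    mu_hab <- norberg_growth(T_hab, p)
    f <- function(tt) norberg_growth(tt, p) - mu_hab
    t_equiv <- stats::uniroot(f, lower = tr$T_opt, upper = tr$T_max,
                              tol = 1e-8)$root
    dge <- t_equiv - T_hab
  }
  list(T_hab = T_hab, TSM = tsm, DGE = dge, WT = wt, T_equiv = t_equiv)
}

#' Thermal-capacity table for a strain compilation
#'
#' Extracts habitat temperatures at isolation sites from the baseline SST
#' grid and computes [capacity_metrics()] per strain.  Only strains of
#' known origin whose upper thermal limit passed quality control
#' (\code{tmax_qc_pass}) are used; the others are dropped with a note in
#' the \code{excluded} attribute.
#'
#' @param traits a traits table from [strain_traits()] (needs columns
#'   \code{strain_id}, \code{pft}, \code{a}, \code{b}, \code{z}, \code{w},
#'   \code{isolation_lat}, \code{isolation_lon}, \code{tmax_qc_pass}).
#' @param baseline an \code{sst_grid}.
#' @param radius land-cell search radius for [habitat_temperature()].
#' @return data frame, one row per eligible strain: ids, traits,
#'   \code{T_hab}, \code{TSM}, \code{DGE}, \code{WT}, \code{T_equiv}.
#' @export
capacity_table <- function(traits, baseline, radius = 3) {
  ok <- traits$tmax_qc_pass & is.finite(traits$isolation_lat) &
    is.finite(traits$isolation_lon)
  excluded <- traits$strain_id[!ok]
  tr <- traits[ok, ]
  if (!nrow(tr)) stop("no strains eligible for capacity analysis")
  t_hab <- habitat_temperature(tr$isolation_lat, tr$isolation_lon,
                               baseline, radius, tr$strain_id)
  rows <- lapply(seq_len(nrow(tr)), function(k) {
    m <- capacity_metrics(c(a = tr$a[k], b = tr$b[k],
                            z = tr$z[k], w = tr$w[k]), t_hab[k])
    data.frame(strain_id = tr$strain_id[k], pft = tr$pft[k],
               isolation_lat = tr$isolation_lat[k],
               isolation_lon = tr$isolation_lon[k],
               T_opt = tr$T_opt[k], T_max = tr$T_max[k],
               T_hab = m$T_hab, TSM = m$TSM, DGE = m$DGE, WT = m$WT,
               T_equiv = m$T_equiv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "substituted") <- attr(t_hab, "substituted")
  out
}

#' Nonparametric comparison of a metric across functional types
#'
#' Kruskal-Wallis test (tie-corrected) with the epsilon-squared effect
#' size \eqn{\epsilon^2 = H / (n - 1)} and a stratified bootstrap
#' percentile interval for it, followed by Dunn's pairwise z tests on mean
#' ranks with the tie-corrected variance.  Dunn p values are two-sided and
#' reported unadjusted by default; set \code{adjust} to any
#' [stats::p.adjust()] method to correct for multiplicity.
#'
#' @param values numeric vector of the metric.
#' @param group group labels, same length; at least two groups with at
#'   least two values each.
#' @param alpha significance level used for the Dunn flags.
#' @param adjust p-adjustment method for the Dunn table (default "none").
#' @param n_boot bootstrap resamples for the epsilon-squared interval.
#' @param seed RNG seed for the bootstrap.
#' @return list: \code{H}, \code{df}, \code{p_value},
#'   \code{epsilon_sq}, \code{epsilon_ci}, \code{dunn} (data frame),
#'   \code{n}.
#' @export
compare_groups <- function(values, group, alpha = 0.05, adjust = "none",
                           n_boot = 1000, seed = 1) {
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]
  group <- as.character(group[keep])
  counts <- table(group)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need at least two groups with at least two values each")
  }
  kw <- stats::kruskal.test(values, factor(group))
  n <- length(values)
  h <- unname(kw$statistic)
  eps2 <- h / (n - 1)

  idx_by_group <- split(seq_along(values), group)
  set.seed(seed)
  eps_draws <- vapply(seq_len(n_boot), function(b) {
    idx <- unlist(lapply(idx_by_group, function(ix) {
      ix[sample.int(length(ix), length(ix), replace = TRUE)]
    }), use.names = FALSE)
    kb <- stats::kruskal.test(values[idx], factor(group[idx]))
    unname(kb$statistic) / (n - 1)
  }, numeric(1))

  # Dunn: z on mean ranks, pooled tie-corrected variance
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  gnames <- names(counts)
  mean_rank <- tapply(r, group, mean)
  pairs <- utils::combn(gnames, 2)
  dunn <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    se <- sqrt(v0 * (1 / counts[[g1]] + 1 / counts[[g2]]))
    z <- (mean_rank[[g1]] - mean_rank[[g2]]) / se
    data.frame(group1 = g1, group2 = g2, z = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  }))
  dunn$p_adjusted <- stats::p.adjust(dunn$p_value, method = adjust)
  dunn$significant <- dunn$p_adjusted < alpha
  rownames(dunn) <- NULL

  list(H = h, df = unname(kw$parameter), p_value = kw$p.value,
       epsilon_sq = eps2,
       epsilon_ci = unname(stats::quantile(eps_draws, c(0.025, 0.975))),
       dunn = dunn, n = n)
}

#' Pearson correlation of a trait against a covariate
#'
#' Thin wrapper over [stats::cor.test()] reporting the pieces used when
#' screening trait-covariate relationships (e.g. niche width against group
#' sample size or absolute isolation latitude).
#'
#' @param x,y numeric vectors.
#' @return list with \code{r}, \code{df}, \code{p_value}.
#' @export
trait_correlation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p_value = ct$p.value)
}
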