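#' Resampled species-accumulation runs
#'
#' Each run is one uniform random permutation of all sites (resampling
#' without replacement); along it we accumulate the number of distinct
#' species and the total habitat area. The run ensemble is the Monte-Carlo
#' object behind both the site-count and the area rarefaction envelopes.
#'
#' Implementation: for a given ordering, a species first appears at the
#' minimum rank of its occupied sites, so each run costs one pass over the
#' incidence lists rather than a cumulative matrix sweep.
#'
#' @param occ an `occurrence_matrix`.
#' @param areas per-site areas (ha) aligned with `rownames(occ)`, or `NULL`
#'   for unit areas (site-count analyses only).
#' @param n_runs number of random orderings (default 2000).
#' @param seed integer seed.
#' @return an `accumulation_runs` object: list with matrices `richness` and
#'   `area` (`n_runs` x `n_sites`, row `r` = cumulative values along run
#'   `r`), the `orderings` matrix, `gamma`, and `site_ids`.
#' @export
accumulation_runs <- function(occ, areas = NULL, n_runs = 2000, seed = 1) {
  n <- nrow(occ)
  if (is.null(areas)) areas <- rep(1, n)
  if (length(areas) != n || anyNA(areas)) stop("missing area for some site")
  if (any(areas <= 0)) stop("areas must be positive")
  occ_sites <- lapply(seq_len(ncol(occ)), function(j) which(occ[, j] == 1L))
  rich <- matrix(0L, n_runs, n)
  area <- matrix(0, n_runs, n)
  ords <- matrix(0L, n_runs, n)
  set.seed(seed)
  pos <- integer(n)
  for (r in seq_len(n_runs)) {
    ord <- sample.int(n)
    pos[ord] <- seq_len(n)
    firsts <- vapply(occ_sites, function(s) min(pos[s]), numeric(1))
    rich[r, ] <- cumsum(tabulate(firsts, nbins = n))
    area[r, ] <- cumsum(areas[ord])
    ords[r, ] <- ord
  }
  structure(list(richness = rich, area = area, orderings = ords,
                 gamma = ncol(occ), site_ids = rownames(occ),
                 n_runs = n_runs, seed = seed),
            class = "accumulation_runs")
}

#' Exact sample-based rarefaction (hypergeometric expectation)
#'
#' Expected number of distinct species in a uniform random subset of `m`
#' sites: `sum_i [1 - C(n - n_i, m) / C(n, m)]`, where `n_i` is the number
#' of sites species `i` occupies. Evaluated with log-gamma arithmetic
#' (`lchoose`) for stability. This closed form is the exact mean of the
#' permutation-resampling curve and serves as its oracle.
#'
#' @param occ an `occurrence_matrix` with `n` sites.
#' @param m number of sites, `1 <= m <= n` (vectorised).
#' @return expected richness at each `m`.
#' @export
analytic_sample_rarefaction <- function(occ, m) {
  n <- nrow(occ)
  if (any(m < 1 | m > n)) stop("m must be in 1..", n)
  ni <- colSums(occ)
  vapply(m, function(mm) {
    # lchoose(n - ni, mm) is -Inf-safe: choose(a, b) = 0 when b > a
    sum(1 - exp(lchoose(n - ni, mm) - lchoose(n, mm)))
  }, numeric(1))
}

#' Site-count rarefaction envelope
#'
#' At each site count `k` the central curve is the mean cumulative richness
#' over runs, and the bounds are the empirical 2.5th and 97.5th percentiles
#' (type-7 interpolation). With `x` discrete, per-`k` empirical quantiles
#' are exact and need no regression.
#'
#' @param runs an [accumulation_runs()] object.
#' @return an `envelope` with `axis = "sites"`, `grid = 1:n`, `central`,
#'   `lo`, `hi`, `n_runs`.
#' @export
sample_envelope <- function(runs) {
  stopifnot(inherits(runs, "accumulation_runs"))
  if (runs$n_runs < 2) stop("need at least 2 runs")
  r <- runs$richness
  qs <- apply(r, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE,
              type = 7)
  env <- list(axis = "sites", grid = seq_len(ncol(r)),
              central = colMeans(r), lo = qs[1, ], hi = qs[2, ],
              n_runs = runs$n_runs)
  class(env) <- "envelope"
  fix_crossing(env)
}

#' Quantile regression on a B-spline basis
#'
#' Minimises the pinball (check) loss `sum(rho_tau(y - B(x) beta))` by
#' iteratively reweighted least squares with an epsilon floor on the
#' residual weights — the classic smooth approximation to the
#' nondifferentiable quantile objective.
#'
#' @param x,y data.
#' @param tau quantile level in (0, 1).
#' @param df B-spline basis dimension (including intercept).
#' @param eps residual floor in the IRLS weights.
#' @param maxit maximum IRLS iterations.
#' @return list with `coef`, the basis descriptor `basis` (knots, boundary
#'   knots, degree) and `tau`; evaluate with [predict_quantile_spline()].
#' @export
fit_quantile_spline <- function(x, y, tau, df = 5, eps = 1e-6, maxit = 200) {
  if (length(unique(x)) < 2) stop("degenerate x-range for quantile spline")
  B <- splines::bs(x, df = df, intercept = TRUE)
  basis <- list(knots = attr(B, "knots"), boundary = attr(B, "Boundary.knots"),
                degree = attr(B, "degree"), df = df)
  beta <- stats::lm.fit(B, y)$coefficients
  beta[is.na(beta)] <- 0
  for (it in seq_len(maxit)) {
    r <- y - drop(B %*% beta)
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), eps)
    fit <- stats::lm.wfit(B, y, w)
    new_beta <- fit$coefficients
    new_beta[is.na(new_beta)] <- 0
    if (max(abs(new_beta - beta)) < 1e-9 * (1 + max(abs(beta)))) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  list(coef = beta, basis = basis, tau = tau)
}

#' Evaluate a fitted quantile spline
#' @param fit result of [fit_quantile_spline()].
#' @param x new x values (must lie within the fitted boundary knots).
#' @return fitted quantile curve at `x`.
#' @export
predict_quantile_spline <- function(fit, x) {
  b <- fit$basis
  if (any(x < b$boundary[1] - 1e-9) || any(x > b$boundary[2] + 1e-9)) {
    stop("x outside the fitted range [", signif(b$boundary[1], 6), ", ",
         signif(b$boundary[2], 6), "]; no extrapolation")
  }
  B <- splines::bs(pmin(pmax(x, b$boundary[1]), b$boundary[2]),
                   knots = b$knots, Boundary.knots = b$boundary,
                   degree = b$degree, intercept = TRUE)
  drop(B %*% fit$coef)
}

#' Area-axis rarefaction envelope
#'
#' Pools the (cumulative area, cumulative richness) points of all runs and
#' fits three quantile-regression splines (tau = 0.025, 0.5, 0.975). The
#' central curve is the median fit; the bounds are the 2.5th/97.5th
#' percentile fits. Curves are evaluated on a 200-point grid spanning the
#' observed cumulative-area range, then de-crossed pointwise.
#'
#' @param runs an [accumulation_runs()] object built with real areas.
#' @param qr_df spline basis dimension (default 5).
#' @param n_grid grid resolution.
#' @return an `envelope` with `axis = "area"`; also carries the three
#'   quantile-spline fits in `$fits` for exact evaluation off the grid.
#' @export
area_envelope <- function(runs, qr_df = 5, n_grid = 200) {
  stopifnot(inherits(runs, "accumulation_runs"))
  x <- as.vector(runs$area)
  y <- as.vector(runs$richness)
  if (diff(range(x)) <= 0) stop("degenerate area range")
  fits <- lapply(c(0.025, 0.5, 0.975), function(tau) {
    fit_quantile_spline(x, y, tau, df = qr_df)
  })
  grid <- seq(min(x), max(x), length.out = n_grid)
  curves <- vapply(fits, predict_quantile_spline, numeric(n_grid), x = grid)
  env <- list(axis = "area", grid = grid,
              central = curves[, 2], lo = curves[, 1], hi = curves[, 3],
              n_runs = runs$n_runs,
              fits = list(lo = fits[[1]], central = fits[[2]], hi = fits[[3]]))
  class(env) <- "envelope"
  fix_crossing(env)
}

# Pointwise isotonic clean-up of quantile crossing: sort (lo, central, hi)
# at every grid point so lo <= central <= hi holds by construction.
fix_crossing <- function(env) {
  m <- apply(rbind(env$lo, env$central, env$hi), 2, sort)
  env$lo <- m[1, ]
  env$central <- m[2, ]
  env$hi <- m[3, ]
  env
}

#' Expected species loss under the sampling-only null (site count)
#'
#' How many species would be lost if the reference community were simply
#' reduced to `m_target` sites at random, with no ecological change? The
#' point estimate is `gamma - mean accumulation at m_target`; the interval
#' maps the envelope bounds through the same subtraction. The Monte-Carlo
#' mean is reported alongside the closed-form hypergeometric value.
#'
#' @param occ_ref reference `occurrence_matrix` (the richer epoch).
#' @param m_target site count to rarefy down to.
#' @param n_runs,seed resampling controls.
#' @return list with `expected_loss`, `rounded`, `ci` (2-vector),
#'   `analytic_loss`, `gamma`, and the site-axis `envelope`.
#' @export
expected_loss_sites <- function(occ_ref, m_target, n_runs = 2000, seed = 1) {
  n <- nrow(occ_ref)
  if (m_target < 1 || m_target > n) stop("m_target must be in 1..", n)
  runs <- accumulation_runs(occ_ref, areas = NULL, n_runs = n_runs, seed = seed)
  env <- sample_envelope(runs)
  gamma <- ncol(occ_ref)
  loss <- gamma - env$central[m_target]
  analytic <- gamma - analytic_sample_rarefaction(occ_ref, m_target)
  list(expected_loss = loss, rounded = round(loss),
       ci = c(gamma - env$hi[m_target], gamma - env$lo[m_target]),
       analytic_loss = analytic, gamma = gamma, envelope = env)
}

#' Expected species loss under the sampling-only null (total area)
#'
#' As [expected_loss_sites()], but rarefying down to a target total habitat
#' area: the expected richness at `a_target` is the median quantile-spline
#' fit evaluated there, and the interval comes from the 2.5th/97.5th
#' percentile fits. No extrapolation: `a_target` must lie inside the
#' observed cumulative-area range.
#'
#' @param occ_ref reference `occurrence_matrix`.
#' @param areas per-site areas (ha) aligned with `occ_ref`.
#' @param a_target total area (ha) to rarefy down to.
#' @param n_runs,seed resampling controls.
#' @param qr_df quantile-spline basis dimension.
#' @return list with `expected_loss`, `rounded`, `ci`, `gamma`, `envelope`.
#' @export
expected_loss_area <- function(occ_ref, areas, a_target, n_runs = 2000,
                               qr_df = 5, seed = 1) {
  runs <- accumulation_runs(occ_ref, areas = areas, n_runs = n_runs, seed = seed)
  env <- area_envelope(runs, qr_df = qr_df)
  gamma <- ncol(occ_ref)
  at <- vapply(env$fits, predict_quantile_spline, numeric(1), x = a_target)
  at <- sort(at)  # same de-crossing as the grid curves
  loss <- gamma - at[2]
  list(expected_loss = loss, rounded = round(loss),
       ci = c(gamma - at[3], gamma - at[1]),
       gamma = gamma, envelope = env)
}
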