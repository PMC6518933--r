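# Cubic B-spline basis with k functions on equally spaced knots over
# range(x) (the P-spline construction: Eilers & Marx bases + difference
# penalty).
pspline_basis <- function(x, k) {
  xl <- min(x); xr <- max(x)
  if (xr <= xl) stop("degenerate x-range")
  dx <- (xr - xl) / (k - 3)
  knots <- seq(xl - 3 * dx, xr + 3 * dx, by = dx)
  B <- splines::splineDesign(knots, x, ord = 4, outer.ok = TRUE)
  attr(B, "knots") <- knots
  B
}

second_diff_penalty <- function(k) {
  D <- diff(diag(k), differences = 2)
  crossprod(D)
}

default_lambda_grid <- function() 10^seq(-4, 7, length.out = 23)

# Solve the penalized normal equations for a fixed total penalty matrix
# and return RSS and effective degrees of freedom. XtX and Xty may be
# precomputed once per lambda grid.
penalized_solve <- function(X, y, P, lambda_total,
                            XtX = crossprod(X), Xty = crossprod(X, y)) {
  A <- XtX + lambda_total
  ridge <- 1e-10 * mean(diag(A))
  R <- NULL
  for (i in 1:6) {
    R <- tryCatch(chol(A + diag(ridge * (i > 1), ncol(A))), error = function(e) NULL)
    if (!is.null(R)) break
    ridge <- ridge * 100
  }
  if (is.null(R)) stop("penalized normal equations are numerically singular")
  beta <- backsolve(R, forwardsolve(t(R), Xty))
  fitted <- drop(X %*% beta)
  # edf = tr[(X'X + S)^{-1} X'X]
  edf <- sum(diag(backsolve(R, forwardsolve(t(R), XtX))))
  list(beta = beta, fitted = fitted, rss = sum((y - fitted)^2), edf = edf)
}

gcv_score <- function(n, rss, edf) n * rss / (n - edf)^2

#' Penalized cubic regression spline with GCV-chosen smoothness
#'
#' Fits `y ~ f(x)` where `f` is a cubic B-spline expansion with a
#' second-difference penalty on the coefficients, minimising
#' `||y - B theta||^2 + lambda * theta' P theta`. When `lambda = "auto"`
#' the smoothing parameter is chosen by generalised cross-validation over
#' a log-spaced grid. The penalty null space is the linear trend, so the
#' fit tends to a straight line as `lambda` grows.
#'
#' @param x,y data vectors (at least 4 points).
#' @param k basis dimension (default 10); reduced to `#distinct(x) - 1`
#'   (minimum 3 + 1 for the cubic order) when `x` has few distinct values.
#' @param lambda `"auto"` (GCV) or a fixed non-negative value.
#' @return a `smooth_fit`: list with `coef`, `lambda`, `fitted`, `edf`,
#'   `dev_expl`, `rss`, `k`, `gcv`.
#' @export
fit_penalized_spline <- function(x, y, k = 10, lambda = "auto") {
  if (length(x) < 4) stop("need at least 4 points")
  nd <- length(unique(x))
  k <- max(min(k, nd - 1), 4)
  B <- pspline_basis(x, k)
  P <- second_diff_penalty(k)
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  BtB <- crossprod(B)
  Bty <- crossprod(B, y)
  pick <- function(lam) {
    s <- penalized_solve(B, y, P, lam * P, XtX = BtB, Xty = Bty)
    s$lambda <- lam
    s$gcv <- gcv_score(n, s$rss, s$edf)
    s
  }
  if (identical(lambda, "auto")) {
    cands <- lapply(default_lambda_grid(), pick)
    best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "gcv"))]]
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0)
    best <- pick(lambda)
  }
  dev_expl <- if (tss > 0) max(0, min(1, 1 - best$rss / tss)) else 0
  structure(list(coef = best$beta, lambda = best$lambda, fitted = best$fitted,
                 edf = best$edf, dev_expl = dev_expl, rss = best$rss,
                 k = k, gcv = best$gcv, knots = attr(B, "knots")),
            class = "smooth_fit")
}

# Additive two-smooth Gaussian model: y ~ 1 + f1(x1) + f2(x2), each smooth
# a centred P-spline term with its own lambda, jointly chosen by GCV over
# a 2D log grid.
fit_additive_two <- function(x1, x2, y, k = 10,
                             grid = 10^seq(-3, 7, length.out = 9)) {
  n <- length(y)
  k1 <- max(min(k, length(unique(x1)) - 1), 4)
  k2 <- max(min(k, length(unique(x2)) - 1), 4)
  B1 <- pspline_basis(x1, k1); B1 <- sweep(B1, 2, colMeans(B1))
  B2 <- pspline_basis(x2, k2); B2 <- sweep(B2, 2, colMeans(B2))
  X <- cbind(1, B1, B2)
  P1 <- second_diff_penalty(k1)
  P2 <- second_diff_penalty(k2)
  tss <- sum((y - mean(y))^2)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  best <- NULL
  for (l1 in grid) for (l2 in grid) {
    S <- matrix(0, ncol(X), ncol(X))
    S[1 + seq_len(k1), 1 + seq_len(k1)] <- l1 * P1
    S[1 + k1 + seq_len(k2), 1 + k1 + seq_len(k2)] <- l2 * P2
    s <- penalized_solve(X, y, NULL, S, XtX = XtX, Xty = Xty)
    s$gcv <- gcv_score(n, s$rss, s$edf)
    s$lambda <- c(l1, l2)
    if (is.null(best) || s$gcv < best$gcv) best <- s
  }
  best$dev_expl <- if (tss > 0) max(0, min(1, 1 - best$rss / tss)) else 0
  best
}

#' Compare habitat number vs. habitat area as richness predictors in a run
#'
#' Fits the full additive model `richness ~ s(sites) + s(area)` and the two
#' single-term models, each with its own GCV-chosen smoothness, and scores
#' each predictor by its drop-one loss of explained deviance:
#' `importance_j = dev_expl(full) - dev_expl(model without term j)`. The
#' predictor with the larger importance wins; the comparison is a tie when
#' the importances differ by less than `1e-10` (within one run, site count
#' and cumulative area can be exactly affinely related, in which case
#' neither predictor carries separate information).
#'
#' @param richness cumulative richness along one accumulation run.
#' @param area cumulative area along the same run.
#' @param k spline basis dimension per term.
#' @return a `run_comparison`: list with `importance_sites`,
#'   `importance_area`, their unclipped `raw` values, `dev_expl` of the
#'   three fits, and `winner` in `{"sites", "area", "tie"}`.
#' @export
compare_predictors <- function(richness, area, k = 10) {
  n <- length(richness)
  if (n < 8) stop("run length must be at least 8")
  sites <- seq_len(n)
  full <- fit_additive_two(sites, area, richness, k = k)
  sub_area <- fit_penalized_spline(area, richness, k = k)   # drop s(sites)
  sub_sites <- fit_penalized_spline(sites, richness, k = k) # drop s(area)
  raw_sites <- full$dev_expl - sub_area$dev_expl
  raw_area <- full$dev_expl - sub_sites$dev_expl
  imp_sites <- max(raw_sites, 0)
  imp_area <- max(raw_area, 0)
  winner <- if (abs(imp_sites - imp_area) < 1e-10) "tie"
            else if (imp_sites > imp_area) "sites" else "area"
  structure(list(importance_sites = imp_sites, importance_area = imp_area,
                 raw = c(sites = raw_sites, area = raw_area),
                 dev_expl = c(full = full$dev_expl,
                              drop_sites = sub_area$dev_expl,
                              drop_area = sub_sites$dev_expl),
                 winner = winner),
            class = "run_comparison")
}

#' Percentage of runs in which habitat number beats habitat area
#'
#' Applies [compare_predictors()] to every accumulation run and reports
#' `100 * #(winner = sites) / #(decided runs)`; ties are excluded from the
#' denominator and counted separately.
#'
#' @param runs an [accumulation_runs()] object (built with real areas).
#' @param k spline basis dimension.
#' @param max_runs optionally cap the number of runs compared (the fits
#'   dominate the cost; the proportion stabilises quickly).
#' @return list with `pct_sites`, `n_sites`, `n_area`, `n_tie`, `n_compared`.
#' @export
proportion_sites_better <- function(runs, k = 10, max_runs = NULL) {
  stopifnot(inherits(runs, "accumulation_runs"))
  n_use <- if (is.null(max_runs)) runs$n_runs else min(max_runs, runs$n_runs)
  winners <- vapply(seq_len(n_use), function(r) {
    compare_predictors(runs$richness[r, ], runs$area[r, ], k = k)$winner
  }, character(1))
  n_sites <- sum(winners == "sites")
  n_area <- sum(winners == "area")
  n_tie <- sum(winners == "tie")
  decided <- n_sites + n_area
  list(pct_sites = if (decided > 0) 100 * n_sites / decided else NA_real_,
       n_sites = n_sites, n_area = n_area, n_tie = n_tie, n_compared = n_use)
}
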