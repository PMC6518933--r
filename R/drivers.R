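#' Binomial multiple regression (logit link)
#'
#' Thin, validated wrapper over iteratively reweighted least squares
#' (`stats::glm`) with tight convergence control, plus guards the bare
#' fitter does not give: constant response, near-collinear design, and a
#' complete-separation heuristic (any standardised slope beyond 15 on the
#' logit scale flags the fit as not converged).
#'
#' @param y 0/1 response vector.
#' @param X data frame or matrix of predictors (one column per predictor),
#'   or `NULL` for the intercept-only model (whose fitted intercept is the
#'   logit of the empirical mean).
#' @return a `glm_fit`: list with `coefficients`, `se`, `p_values` (Wald),
#'   `null_deviance`, `deviance`, `n`, `p`, `converged`, `family`, and the
#'   underlying `glm` object in `$model`.
#' @export
fit_binomial_glm <- function(y, X = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  if (length(unique(y)) < 2) stop("constant response: cannot fit binomial model")
  intercept_only <- is.null(X) || NCOL(X) == 0
  if (intercept_only) {
    X <- data.frame()[seq_len(n), , drop = FALSE]
    p <- 0
  } else {
    X <- as.data.frame(X)
    p <- ncol(X)
    if (n <= p + 1) stop("need n > p + 1 observations")
    if (!all(vapply(X, function(c) all(is.finite(c)), logical(1)))) {
      stop("non-finite predictor values")
    }
    Xs <- scale(as.matrix(X))
    if (any(attr(Xs, "scaled:scale") == 0)) stop("constant predictor column")
    if (kappa(cbind(1, Xs), exact = TRUE) > 1e10) {
      stop("predictors are (near-)collinear")
    }
  }
  dat <- data.frame(.y = y, X)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  sm <- summary(fit)
  converged <- fit$converged
  if (!intercept_only) {
    slopes_std <- stats::coef(fit)[-1] * attr(Xs, "scaled:scale")
    if (any(abs(slopes_std) > 15)) {
      converged <- FALSE
      warning("possible complete separation: standardised slope exceeds 15")
    }
  }
  structure(list(coefficients = stats::coef(fit),
                 se = sm$coefficients[, "Std. Error"],
                 p_values = sm$coefficients[, "Pr(>|z|)"],
                 null_deviance = fit$null.deviance,
                 deviance = fit$deviance,
                 n = n, p = p, converged = converged,
                 family = "binomial", model = fit),
            class = "glm_fit")
}

#' Species-trait model of regional extinction probability
#'
#' Regresses regional extinction (absence from the epoch-2 species list) on
#' three epoch-1 traits: regional rarity (square root of the proportion of
#' sampled habitats occupied), body size (log-transformed, mm) and habitat
#' preference (mean conductivity of occupied habitats, mS/cm), via a
#' binomial multiple regression.
#'
#' @param traits a `trait_table` from [derive_species_traits()].
#' @return a `glm_fit` with predictors `rarity`, `body_size`, `preference`.
#' @export
extinction_model <- function(traits) {
  X <- data.frame(rarity = sqrt(traits$occupancy_1957),
                  body_size = log(traits$body_size),
                  preference = traits$preference)
  fit_binomial_glm(as.numeric(traits$extinct_2010), X)
}

#' Adjusted (pseudo-)R-squared of a fitted model
#'
#' Deviance-based: `R2 = 1 - deviance / null_deviance` (for a Gaussian
#' model this is the ordinary R-squared), with the Ezekiel small-sample
#' adjustment `1 - (1 - R2) * (n - 1) / (n - p - 1)`.
#'
#' @param fit a `glm_fit`, or any list with `deviance`, `null_deviance`,
#'   `n`, `p`.
#' @return adjusted R-squared (may be negative).
#' @export
adjusted_pseudo_r2 <- function(fit) {
  if (fit$n <= fit$p + 1) stop("n too small for the adjustment")
  r2 <- 1 - fit$deviance / fit$null_deviance
  1 - (1 - r2) * (fit$n - 1) / (fit$n - fit$p - 1)
}

# Adjusted (pseudo-)R2 of y ~ X[, subset] for one predictor subset.
subset_adj_r2 <- function(y, X, subset, family) {
  Xi <- X[, subset, drop = FALSE]
  n <- length(y)
  p <- length(subset)
  if (family == "gaussian") {
    fit <- stats::lm.fit(cbind(1, as.matrix(Xi)), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
  } else {
    dat <- data.frame(.y = y, Xi)
    fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-10, maxit = 100))
    r2 <- 1 - fit$deviance / fit$null.deviance
  }
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Commonality partition of explained variance among three predictors
#'
#' Fits the seven models on the non-empty subsets of the three predictors
#' and decomposes the full model's adjusted (pseudo-)R-squared into the
#' fraction unique to each predictor and the fractions shared by each
#' subset, by the standard three-set commonality algebra. With `R(S)` the
#' adjusted R-squared of the model on subset `S`:
#' `pure_A = R(ABC) - R(BC)`, `shared_AB = R(AC) + R(BC) - R(C) - R(ABC)`,
#' `shared_ABC = R(ABC) - R(AB) - R(AC) - R(BC) + R(A) + R(B) + R(C)`, etc.
#' The seven fractions sum to `R(ABC)` identically; individual fractions
#' may be negative under the adjusted-R-squared convention.
#'
#' @param y response (0/1 for `family = "binomial"`).
#' @param X data frame with exactly three named predictor columns.
#' @param family `"gaussian"` or `"binomial"`.
#' @return a `partition3`: list with `labels`, `pure` (named 3-vector),
#'   `shared` (named 4-vector: AB, AC, BC, ABC), `residual`,
#'   `total_adj_r2`, and the subset R-squared table `r2`.
#' @export
commonality_partition <- function(y, X, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  X <- as.data.frame(X)
  if (ncol(X) != 3) stop("exactly three predictors required")
  labels <- names(X)
  subsets <- list(A = 1, B = 2, C = 3, AB = c(1, 2), AC = c(1, 3),
                  BC = c(2, 3), ABC = 1:3)
  r2 <- vapply(names(subsets), function(s) {
    tryCatch(subset_adj_r2(y, X, subsets[[s]], family),
             error = function(e) stop("subset model {", s, "} failed: ",
                                      conditionMessage(e)))
  }, numeric(1))
  pure <- c(r2["ABC"] - r2["BC"], r2["ABC"] - r2["AC"], r2["ABC"] - r2["AB"])
  shared <- c(AB = unname(r2["AC"] + r2["BC"] - r2["C"] - r2["ABC"]),
              AC = unname(r2["AB"] + r2["BC"] - r2["B"] - r2["ABC"]),
              BC = unname(r2["AB"] + r2["AC"] - r2["A"] - r2["ABC"]),
              ABC = unname(r2["ABC"] - r2["AB"] - r2["AC"] - r2["BC"] +
                             r2["A"] + r2["B"] + r2["C"]))
  names(pure) <- labels
  total <- unname(r2["ABC"])
  if (abs(sum(pure) + sum(shared) - total) > 1e-10) {
    stop("commonality identity violated beyond 1e-10")
  }
  structure(list(labels = labels, pure = pure, shared = shared,
                 residual = 1 - total, total_adj_r2 = total, r2 = r2,
                 family = family),
            class = "partition3")
}

#' Drivers of local richness change at resurveyed ponds
#'
#' For ponds sampled in both epochs, partitions the variance of the change
#' in local richness among the change in closeness centrality (km), the
#' change in conductivity (mS/cm) and the change in (log) habitat area,
#' via the Gaussian commonality partition; significance of the three
#' effects comes from one multiple linear regression (t-test p-values).
#'
#' @param records data frame with columns `pond_id`, `d_richness`,
#'   `d_closeness`, `d_conductivity`, `d_log_area`.
#' @return list with `partition` (a `partition3`), `fit` (the `lm`),
#'   `coefficients` and `p_values`.
#' @export
local_drivers_analysis <- function(records) {
  needed <- c("pond_id", "d_richness", "d_closeness", "d_conductivity",
              "d_log_area")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("records missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) < 8) stop("need at least 8 resurveyed ponds")
  X <- records[, c("d_closeness", "d_conductivity", "d_log_area")]
  part <- commonality_partition(records$d_richness, X, family = "gaussian")
  fit <- stats::lm(d_richness ~ d_closeness + d_conductivity + d_log_area,
                   data = records)
  sm <- summary(fit)
  list(partition = part, fit = fit,
       coefficients = stats::coef(fit),
       p_values = sm$coefficients[, "Pr(>|t|)"])
}
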