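test_that("logistic fits agree with direct likelihood maximisation", {
  set.seed(2)
  for (i in 1:10) {
    n <- 40
    p <- sample(1:3, 1)
    X <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(X) <- paste0("x", seq_len(p))
    eta <- -0.3 + rowSums(X) * 0.8
    y <- rbinom(n, 1, plogis(eta))
    if (length(unique(y)) < 2) next
    fit <- fit_binomial_glm(y, X)
    oracle <- brute_force_logit(y, X)
    expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-4)
  }

  # intercept-only model: closed form logit of the empirical mean
  y <- rep(c(1, 0, 0, 0), 10)
  fit0 <- fit_binomial_glm(y)
  expect_equal(unname(fit0$coefficients), qlogis(0.25), tolerance = 1e-10)
  expect_equal(adjusted_pseudo_r2(fit0), 0)
})

test_that("the logistic wrapper guards against degenerate inputs", {
  set.seed(5)
  X <- data.frame(x = rnorm(30))
  expect_error(fit_binomial_glm(rep(1, 30), X), "constant response")
  expect_error(fit_binomial_glm(rbinom(30, 1, 0.5),
                                data.frame(a = X$x, b = X$x)),
               "collinear")
  expect_error(fit_binomial_glm(c(0, 1, 2), data.frame(x = 1:3)), "0/1")

  # deterministic threshold -> complete separation flagged
  xs <- seq(-2, 2, length.out = 30)
  w <- capture_warnings(
    fit_sep <- fit_binomial_glm(as.numeric(xs > 0), data.frame(x = xs)))
  expect_true(any(grepl("separation", w)))
  expect_false(fit_sep$converged)
})

test_that("adjusted pseudo-R2 matches a hand-derived small example", {
  # deviances recomputed from the likelihood directly, not via the wrapper
  y <- c(0, 0, 1, 0, 1, 1, 0, 1)
  x <- c(-1.5, -1.0, -0.5, -0.2, 0.3, 0.8, 0.1, 1.4)
  fit <- fit_binomial_glm(y, data.frame(x = x))
  beta <- brute_force_logit(y, data.frame(x = x))
  ll <- function(eta) sum(y * eta - log1p(exp(eta)))
  dev_res <- -2 * ll(beta[1] + beta[2] * x)
  dev_null <- -2 * ll(rep(qlogis(mean(y)), 8))
  r2 <- 1 - dev_res / dev_null
  expect_equal(adjusted_pseudo_r2(fit), 1 - (1 - r2) * 7 / 6, tolerance = 1e-6)
})

test_that("commonality fractions obey the sum identity in both families", {
  set.seed(9)
  for (i in 1:10) {
    n <- 60
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y_g <- X$a - 0.5 * X$b + rnorm(n)
    part <- commonality_partition(y_g, X, "gaussian")
    expect_equal(sum(part$pure) + sum(part$shared), part$total_adj_r2,
                 tolerance = 1e-10)
    expect_equal(part$residual, 1 - part$total_adj_r2, tolerance = 1e-12)

    y_b <- rbinom(n, 1, plogis(X$a))
    if (length(unique(y_b)) < 2) next
    part_b <- commonality_partition(y_b, X, "binomial")
    expect_equal(sum(part_b$pure) + sum(part_b$shared), part_b$total_adj_r2,
                 tolerance = 1e-10)
  }
})

test_that("orthogonal predictors yield no shared fractions", {
  set.seed(11)
  Q <- qr.Q(qr(matrix(rnorm(300 * 3), 300, 3)))
  X <- as.data.frame(Q * 10); names(X) <- c("a", "b", "c")
  y <- 2 * X$a + 1 * X$b + rnorm(300, 0, 0.5)
  part <- commonality_partition(y, X, "gaussian")
  expect_true(all(abs(part$shared) < 0.02))
  r2_single <- part$r2[c("A", "B", "C")]
  expect_equal(unname(part$pure), unname(r2_single), tolerance = 0.02)

  # y driven by one predictor only: its pure fraction carries everything
  y_a <- 3 * X$a + rnorm(300, 0, 0.3)
  part_a <- commonality_partition(y_a, X, "gaussian")
  expect_gt(part_a$pure["a"], 0.9 * part_a$total_adj_r2)
  expect_lt(max(abs(part_a$pure[c("b", "c")])), 0.02)
})

test_that("the partition is symmetric under predictor relabelling", {
  set.seed(13)
  X <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  y <- X$a + 2 * X$c + rnorm(50)
  p1 <- commonality_partition(y, X, "gaussian")
  p2 <- commonality_partition(y, X[, c("c", "a", "b")], "gaussian")
  expect_equal(p2$pure[c("a", "b", "c")], p1$pure[c("a", "b", "c")],
               tolerance = 1e-12)
  expect_equal(p2$total_adj_r2, p1$total_adj_r2, tolerance = 1e-12)
  expect_equal(sort(unname(p2$shared)), sort(unname(p1$shared)), tolerance = 1e-10)
})

test_that("the Gaussian partition reproduces vegan's variance partitioning", {
  skip_if_not_installed("vegan")
  set.seed(17)
  n <- 40
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- X$a - X$b + 0.5 * X$c + rnorm(n)
  ours <- commonality_partition(y, X, "gaussian")
  vp <- vegan::varpart(y, ~a, ~b, ~c, data = X)
  ref <- vp$part$indfract$Adj.R.square  # [a] [b] [c] pure fractions first
  expect_equal(unname(ours$pure), ref[1:3], tolerance = 1e-8)
  expect_equal(ours$total_adj_r2, sum(vp$part$indfract$Adj.R.square[1:7]),
               tolerance = 1e-8)
})

test_that("local driver analysis recovers a planted connectivity signal", {
  set.seed(19)
  n <- 24
  rec <- data.frame(
    pond_id = sprintf("p%02d", 1:n),
    d_closeness = rnorm(n, 2, 1.5),
    d_conductivity = rnorm(n, 0.8, 2),
    d_log_area = rnorm(n, -0.2, 0.4)
  )
  rec$d_richness <- -2 * rec$d_closeness + rnorm(n, 0, 1e-4)
  out <- local_drivers_analysis(rec)
  expect_gt(out$partition$pure["d_closeness"], 0.95)
  expect_lt(out$p_values["d_closeness"], 1e-10)
  expect_lt(out$coefficients["d_closeness"] + 2, 1e-3)

  # pure white noise: nothing explained
  rec$d_richness <- rnorm(n)
  out0 <- local_drivers_analysis(rec)
  expect_lt(out0$partition$total_adj_r2, 0.35)
  expect_error(local_drivers_analysis(rec[1:5, ]), "at least 8")
  expect_error(local_drivers_analysis(rec[, -3]), "missing columns")
})

test_that("the extinction model flags rarity-driven loss and separation", {
  cs <- generate_case_study(seed = 21)
  traits <- derive_species_traits(cs$occ_1957, cs$ponds, cs$body_sizes,
                                  colnames(cs$occ_2010))
  fit <- suppressWarnings(extinction_model(traits))
  expect_equal(names(fit$coefficients),
               c("(Intercept)", "rarity", "body_size", "preference"))
  # rarer species are the ones lost: negative slope on sqrt-occupancy
  expect_lt(fit$coefficients["rarity"], 0)

  # deterministic occupancy threshold -> separation warning
  tr2 <- traits
  tr2$extinct_2010 <- traits$occupancy_1957 < stats::median(traits$occupancy_1957)
  w <- capture_warnings(fit2 <- extinction_model(tr2))
  expect_true(any(grepl("separation", w)))
  expect_false(fit2$converged)
})
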