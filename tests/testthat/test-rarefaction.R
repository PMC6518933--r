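test_that("the closed-form rarefaction matches enumeration exactly", {
  toy <- toy3_occ()
  # full enumeration over site subsets gives 7/3 distinct species at m = 2
  expect_equal(enumerate_mean_richness(toy, 2), 7 / 3, tolerance = 1e-12)
  expect_equal(analytic_sample_rarefaction(toy, 2), 7 / 3, tolerance = 1e-12)
  # m = n -> gamma; m = 1 -> mean alpha
  expect_equal(analytic_sample_rarefaction(toy, 3), 3)
  expect_equal(analytic_sample_rarefaction(toy, 1), mean(rowSums(toy)))

  for (seed in 1:5) {
    occ <- random_occ(7, 12, seed = seed)
    for (m in 1:7) {
      expect_equal(analytic_sample_rarefaction(occ, m),
                   enumerate_mean_richness(occ, m), tolerance = 1e-10)
    }
  }
})

test_that("the closed form agrees with vegan's exact accumulation curve", {
  skip_if_not_installed("vegan")
  occ <- random_occ(10, 25, seed = 21)
  ours <- analytic_sample_rarefaction(occ, 1:10)
  ref <- vegan::specaccum(unclass(occ), method = "exact")$richness
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("accumulation runs satisfy their path invariants", {
  occ <- random_occ(12, 18, seed = 2)
  areas <- rlnorm(12, 2, 1)
  runs <- accumulation_runs(occ, areas, n_runs = 100, seed = 5)
  expect_true(all(runs$richness[, 12] == ncol(occ)))        # terminal = gamma
  expect_true(all(apply(runs$richness, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(apply(runs$area, 1, function(a) all(diff(a) > 0))))
  expect_equal(unname(runs$area[, 12]), rep(sum(areas), 100))
  expect_error(accumulation_runs(occ, areas[-1]), "missing area")

  one <- occurrence_matrix(matrix(c(1, 1), 1, 2,
                                  dimnames = list("s", c("a", "b"))), "x")
  r1 <- accumulation_runs(one, 2.5, n_runs = 5, seed = 1)
  expect_equal(unname(r1$richness[, 1]), rep(2, 5))
  expect_equal(unname(r1$area[, 1]), rep(2.5, 5))
})

test_that("resampled means track the analytic expectation within Monte-Carlo error", {
  occ <- random_occ(10, 20, seed = 3)
  runs <- accumulation_runs(occ, NULL, n_runs = 2000, seed = 7)
  env <- sample_envelope(runs)
  for (k in 1:10) {
    se <- sd(runs$richness[, k]) / sqrt(2000)
    expect_lt(abs(env$central[k] - analytic_sample_rarefaction(occ, k)),
              3 * se + 1e-12)
  }
})

test_that("the site envelope collapses for identical runs and covers fresh draws", {
  # all sites identical -> every permutation yields the same curve
  m <- matrix(rep(c(1, 1, 0, 1), each = 5), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("sp", 1:4)))
  m[, 3] <- 1
  occ <- occurrence_matrix(m, "x")
  runs <- accumulation_runs(occ, NULL, n_runs = 50, seed = 1)
  env <- sample_envelope(runs)
  expect_equal(env$lo, env$central)
  expect_equal(env$hi, env$central)

  # ~95% of fresh runs fall inside the band at a middle site count
  occ2 <- random_occ(12, 25, seed = 9)
  env2 <- sample_envelope(accumulation_runs(occ2, NULL, n_runs = 1000, seed = 2))
  fresh <- accumulation_runs(occ2, NULL, n_runs = 400, seed = 3)
  inside <- mean(fresh$richness[, 6] >= env2$lo[6] &
                   fresh$richness[, 6] <= env2$hi[6])
  expect_gt(inside, 0.88)
})

test_that("quantile splines honour their defining property", {
  set.seed(4)
  x <- runif(600, 0, 10)
  y <- sin(x / 2) * 5 + rnorm(600)
  for (tau in c(0.1, 0.5, 0.9)) {
    fit <- fit_quantile_spline(x, y, tau, df = 6)
    frac_below <- mean(y < predict_quantile_spline(fit, x))
    expect_lt(abs(frac_below - tau), 0.05)
  }
  # symmetric noise: median fit tracks the true mean curve
  fit50 <- fit_quantile_spline(x, y, 0.5, df = 6)
  grid <- seq(0.5, 9.5, length.out = 50)
  expect_lt(max(abs(predict_quantile_spline(fit50, grid) - sin(grid / 2) * 5)), 1)
  expect_error(predict_quantile_spline(fit50, 11), "no extrapolation")
})

test_that("the area envelope is flat for constant richness and never crosses", {
  # every site holds every species -> richness constant at gamma along runs
  m <- matrix(1L, 6, 5, dimnames = list(paste0("s", 1:6), paste0("sp", 1:5)))
  occ <- occurrence_matrix(m, "x")
  runs <- accumulation_runs(occ, rlnorm(6, 1, 0.8), n_runs = 30, seed = 2)
  env <- area_envelope(runs, qr_df = 5)
  expect_equal(unname(env$central), rep(5, length(env$grid)), tolerance = 1e-6)
  expect_equal(unname(env$lo), rep(5, length(env$grid)), tolerance = 1e-6)

  occ2 <- random_occ(12, 20, seed = 6)
  runs2 <- accumulation_runs(occ2, rlnorm(12, 2, 1.2), n_runs = 100, seed = 3)
  env2 <- area_envelope(runs2, qr_df = 5)
  expect_true(all(env2$hi >= env2$lo))
  expect_true(all(env2$hi >= env2$central & env2$central >= env2$lo))
})

test_that("expected loss by site count is anchored to the analytic oracle", {
  occ <- random_occ(10, 22, seed = 12)
  full <- expected_loss_sites(occ, 10, n_runs = 200, seed = 1)
  expect_identical(full$expected_loss, 0)  # m = n: loss exactly zero
  expect_equal(full$analytic_loss, 0)

  res <- expected_loss_sites(occ, 4, n_runs = 2000, seed = 5)
  runs <- accumulation_runs(occ, NULL, n_runs = 2000, seed = 5)
  se <- sd(runs$richness[, 4]) / sqrt(2000)
  expect_lt(abs(res$expected_loss - res$analytic_loss), 3 * se)
  expect_true(res$ci[1] <= res$expected_loss & res$expected_loss <= res$ci[2])
  expect_equal(res$rounded, round(res$expected_loss))
  expect_error(expected_loss_sites(occ, 11), "m_target")
})

test_that("area rarefaction agrees with site rarefaction when areas are equal", {
  occ <- random_occ(12, 25, seed = 14)
  areas <- rep(2, 12)
  by_area <- expected_loss_area(occ, areas, a_target = 2 * 6, n_runs = 400,
                                seed = 8)
  by_sites <- expected_loss_sites(occ, 6, n_runs = 400, seed = 8)
  expect_lt(abs(by_area$expected_loss - by_sites$expected_loss), 1)

  # endpoint: rarefying to the full area loses ~nothing
  full <- expected_loss_area(occ, areas, a_target = 24, n_runs = 400, seed = 9)
  expect_lt(abs(full$expected_loss), 1)
  expect_error(expected_loss_area(occ, areas, a_target = 25, n_runs = 50),
               "no extrapolation")
})
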