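test_that("landscape generation is deterministic and matches its distribution", {
  p <- landscape_params(n_ponds = 20)
  a <- generate_landscape(p, seed = 11)
  b <- generate_landscape(p, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_landscape(p, seed = 12)))

  # degenerate spread: every pond gets exp(logmean)
  deg <- generate_landscape(landscape_params(n_ponds = 2, area_logsd = 0,
                                             cond_logsd = 0), seed = 1)
  expect_equal(deg$area_1957, rep(exp(2.0), 2))

  # lognormal moment check at large n: mean ~ exp(mu + sigma^2/2)
  big <- generate_landscape(landscape_params(n_ponds = 1e5), seed = 3)
  mu <- 2.0; sg <- 1.1
  expected <- exp(mu + sg^2 / 2)
  se <- sqrt((exp(sg^2) - 1) * exp(2 * mu + sg^2) / 1e5)
  expect_lt(abs(mean(big$area_1957) - expected), 3 * se)
})

test_that("occurrence simulation follows the niche model", {
  ponds <- generate_landscape(landscape_params(n_ponds = 400), seed = 2)
  pool <- pool_params(n_species = 40)

  # one draw: total incidences within 3 SE of the Poisson-binomial mean
  p <- occurrence_probabilities(ponds, pool, "1957", seed = 9)
  occ <- simulate_occurrence(ponds, pool, "1957", seed = 9)
  total_expected <- sum(p)
  total_se <- sqrt(sum(p * (1 - p)))
  expect_lt(abs(sum(occ) - total_expected), 3 * total_se)

  # flat-niche limit: occupancy probability -> prevalence everywhere
  flat <- pool_params(n_species = 15, niche_sd_log = 1e9)
  pf <- occurrence_probabilities(ponds, flat, "1957", seed = 5)
  set.seed(5)
  prev <- rbeta(15, flat$prevalence_shape1, flat$prevalence_shape2)
  expect_equal(unname(pf), matrix(prev, nrow(pf), 15, byrow = TRUE),
               tolerance = 1e-9)

  # probability formula at a single pond: prev * gaussian niche factor
  one <- ponds; one$cond_1957 <- exp(1.3)
  p1 <- occurrence_probabilities(one, pool, "1957", seed = 9)
  set.seed(9)
  prev2 <- rbeta(40, pool$prevalence_shape1, pool$prevalence_shape2)
  mu2 <- runif(40, pool$niche_optima_range[1], pool$niche_optima_range[2])
  expect_equal(unname(p1[1, ]),
               prev2 * exp(-(1.3 - mu2)^2 / (2 * pool$niche_sd_log^2)),
               tolerance = 1e-12)
})

test_that("habitat loss keeps exactly the requested ponds", {
  ponds <- generate_landscape(landscape_params(n_ponds = 116), seed = 4)
  lost <- apply_habitat_loss(ponds, keep = 30, mode = "random", seed = 1)
  expect_equal(sum(lost$extant_2010), 30)
  clus <- apply_habitat_loss(ponds, keep = 30, mode = "clustered", seed = 1)
  expect_equal(sum(clus$extant_2010), 30)
  all_kept <- apply_habitat_loss(ponds, keep = 116, mode = "random", seed = 1)
  expect_identical(all_kept$extant_2010, all_kept$extant_1957)
  expect_error(apply_habitat_loss(ponds, keep = 117), "keep must be in")

  # uniform-subset symmetry: every pond survives with frequency ~ keep/n
  small <- generate_landscape(landscape_params(n_ponds = 12), seed = 6)
  freq <- rowMeans(vapply(seq_len(2000), function(i) {
    apply_habitat_loss(small, keep = 4, mode = "random", seed = i)$extant_2010
  }, logical(12)))
  se <- sqrt((4 / 12) * (8 / 12) / 2000)
  expect_true(all(abs(freq - 4 / 12) < 3.5 * se))
})

test_that("relaxation removes incidences by the logistic model and never adds", {
  occ <- random_occ(20, 15, seed = 8)
  delta <- data.frame(pond_id = rownames(occ)[1:10], d_closeness = 0,
                      d_log_area = 0, d_conductivity = 0)
  # no-extinction flag: output is the survivor-restricted input
  kept <- simulate_relaxation(occ, delta, relaxation_params(), seed = 1,
                              no_extinction = TRUE)
  expect_identical(unclass(kept)[, ], unclass(occ)[1:10, colSums(occ[1:10, ]) > 0])

  # fair-coin baseline: b0 = 0, all slopes 0 -> each incidence survives w.p. 1/2
  p0 <- relaxation_params(b0 = 0, b_conn = 0, b_area = 0, b_cond = 0)
  n_before <- sum(unclass(occ)[1:10, ])
  kept_tot <- vapply(1:200, function(s) {
    sum(simulate_relaxation(occ, delta, p0, seed = s))
  }, numeric(1))
  se <- sqrt(200 * n_before * 0.25) / 200
  expect_lt(abs(mean(kept_tot) - n_before / 2), 3 * se)

  # richness never increases through relaxation
  out <- simulate_relaxation(occ, delta, relaxation_params(), seed = 3)
  expect_lte(ncol(out), ncol(occ))
  expect_true(all(colnames(out) %in% colnames(occ)))
  expect_error(simulate_relaxation(occ, transform(delta, pond_id = paste0(pond_id, "zz")),
                                   relaxation_params()),
               "absent from the occurrence matrix")
})

test_that("connectivity-dependent extinction hits isolated sites hardest", {
  occ <- random_occ(30, 40, seed = 10, p = 0.5)
  set.seed(10)
  dclose <- sort(runif(30, -1, 5))
  delta <- data.frame(pond_id = rownames(occ), d_closeness = dclose,
                      d_log_area = 0, d_conductivity = 0)
  pr <- relaxation_params(b0 = -1, b_conn = 0.8, b_area = 0, b_cond = 0)
  drop_by_site <- rowMeans(vapply(1:100, function(s) {
    out <- simulate_relaxation(occ, delta, pr, seed = s)
    rowSums(occ[, colnames(out)]) - rowSums(out)
  }, numeric(30)))
  rel_drop <- drop_by_site / rowSums(occ)
  terciles <- cut(dclose, quantile(dclose, c(0, 1/3, 2/3, 1)), include.lowest = TRUE)
  by_terc <- tapply(rel_drop, terciles, mean)
  expect_gt(by_terc[3], by_terc[1])
})

test_that("the case study reproduces the survey dimensions deterministically", {
  cs <- generate_case_study(seed = 17)
  expect_equal(nrow(cs$occ_1957), 53)
  expect_equal(nrow(cs$occ_2010), 30)
  expect_equal(length(intersect(rownames(cs$occ_1957), rownames(cs$occ_2010))), 24)
  expect_equal(sum(cs$ponds$extant_2010), 30)
  expect_equal(sum(cs$ponds$sampled_1957), 53)

  cs2 <- generate_case_study(seed = 17)
  expect_identical(cs, cs2)
  expect_false(identical(unclass(cs$occ_1957),
                         unclass(generate_case_study(seed = 18)$occ_1957)))

  # relaxation only removes: epoch-2 regional list within the epoch-1 pool
  expect_true(all(colnames(cs$occ_2010) %in% colnames(cs$occ_full_1957)))
  expect_lte(ncol(cs$occ_2010), ncol(cs$occ_full_1957))
})

test_that("seed splitting is deterministic, in-range and collision-free", {
  s <- split_seed(123, 1:1000)
  expect_identical(s, split_seed(123, 1:1000))
  expect_true(all(s >= 1 & s <= 2^31 - 1))
  expect_equal(anyDuplicated(s), 0)
  expect_false(any(split_seed(124, 1:1000) == s))
})
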