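#' Alpha, gamma and Whittaker beta diversity of an occurrence matrix
#'
#' `alpha` is per-site richness (row sums), `gamma` the regional richness
#' (number of species present anywhere), and `beta = gamma / mean(alpha)`,
#' Whittaker's multiplicative beta: the effective number of distinct
#' communities among the sites. `beta = 1` iff every site holds the whole
#' regional pool.
#'
#' @param occ an `occurrence_matrix`.
#' @return a `diversity_summary`: list with `epoch`, `alpha`, `gamma`,
#'   `beta`, `mean_alpha`, `n_sites`.
#' @export
diversity_summary <- function(occ) {
  if (nrow(occ) == 0 || ncol(occ) == 0) stop("empty occurrence matrix")
  alpha <- rowSums(occ)
  gamma <- sum(colSums(occ) > 0)
  if (mean(alpha) == 0) stop("mean alpha is zero; beta undefined")
  structure(list(epoch = occ_epoch(occ), alpha = alpha, gamma = gamma,
                 mean_alpha = mean(alpha), beta = gamma / mean(alpha),
                 n_sites = nrow(occ)),
            class = "diversity_summary")
}

# Align two occurrence matrices on the union of their species columns and
# stack the site rows, remembering group membership.
pool_sites <- function(occ_a, occ_b) {
  species <- union(colnames(occ_a), colnames(occ_b))
  pad <- function(occ) {
    m <- matrix(0L, nrow(occ), length(species),
                dimnames = list(rownames(occ), species))
    m[, colnames(occ)] <- unclass(occ)
    m
  }
  list(m = rbind(pad(occ_a), pad(occ_b)),
       n_a = nrow(occ_a), n_b = nrow(occ_b))
}

#' Permutation effect size for mean local (alpha) richness
#'
#' The effect size `D_bar` is the absolute difference between the two
#' epochs' mean per-site richness. Its null distribution comes from
#' pooling all site rows and randomly reassigning them to two groups of
#' the original (unequal) sizes; the p-value uses the add-one correction
#' `p = (1 + #(D_perm >= D_obs)) / (n_perm + 1)` and is two-sided by
#' construction (absolute statistic).
#'
#' Site richness does not depend on the species alignment, so the
#' permutation operates on the pooled per-site richness vector directly.
#'
#' @param occ_a,occ_b the two epochs' `occurrence_matrix` objects.
#' @param n_perm number of permutations (default 200).
#' @param seed integer seed.
#' @return an `effect_size`: list with `statistic`, `D_bar`, `p_value`,
#'   `n_perm`, `seed`, group means.
#' @export
effect_size_alpha <- function(occ_a, occ_b, n_perm = 200, seed = 1) {
  if (nrow(occ_a) == 0 || nrow(occ_b) == 0) stop("empty group")
  alpha <- c(rowSums(occ_a), rowSums(occ_b))
  n_a <- nrow(occ_a)
  n <- length(alpha)
  d_obs <- abs(mean(alpha[seq_len(n_a)]) - mean(alpha[-seq_len(n_a)]))
  set.seed(seed)
  d_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, n_a)
    abs(mean(alpha[idx]) - mean(alpha[-idx]))
  }, numeric(1))
  structure(list(statistic = "alpha_mean", D_bar = d_obs,
                 p_value = (1 + sum(d_perm >= d_obs)) / (n_perm + 1),
                 n_perm = n_perm, seed = seed,
                 mean_a = mean(alpha[seq_len(n_a)]),
                 mean_b = mean(alpha[-seq_len(n_a)])),
            class = "effect_size")
}

#' Permutation effect size for Whittaker beta diversity
#'
#' As [effect_size_alpha()], with the group statistic
#' `beta = gamma / mean(alpha)` computed per group (each group yields one
#' beta). Permutations that land all-empty site rows in one group (beta
#' undefined) are dropped from the null sample.
#'
#' @inheritParams effect_size_alpha
#' @return an `effect_size` with `statistic = "beta"`.
#' @export
effect_size_beta <- function(occ_a, occ_b, n_perm = 200, seed = 1) {
  if (nrow(occ_a) == 0 || nrow(occ_b) == 0) stop("empty group")
  pooled <- pool_sites(occ_a, occ_b)
  grp_beta <- function(m) {
    alpha <- rowSums(m)
    if (mean(alpha) == 0) return(NA_real_)
    sum(colSums(m) > 0) / mean(alpha)
  }
  idx_a <- seq_len(pooled$n_a)
  beta_a <- grp_beta(pooled$m[idx_a, , drop = FALSE])
  beta_b <- grp_beta(pooled$m[-idx_a, , drop = FALSE])
  if (is.na(beta_a) || is.na(beta_b)) stop("beta undefined (mean alpha zero)")
  d_obs <- abs(beta_a - beta_b)
  set.seed(seed)
  d_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nrow(pooled$m), pooled$n_a)
    abs(grp_beta(pooled$m[idx, , drop = FALSE]) -
          grp_beta(pooled$m[-idx, , drop = FALSE]))
  }, numeric(1))
  d_perm <- d_perm[!is.na(d_perm)]
  structure(list(statistic = "beta", D_bar = d_obs,
                 p_value = (1 + sum(d_perm >= d_obs)) / (length(d_perm) + 1),
                 n_perm = n_perm, seed = seed,
                 beta_a = beta_a, beta_b = beta_b),
            class = "effect_size")
}
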