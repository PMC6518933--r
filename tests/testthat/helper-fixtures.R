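# Shared fixtures and independent oracles, all built in code.

# Three-site worked example: sites A {s1}, B {s1, s2}, C {s3}.
toy3_occ <- function() {
  m <- rbind(A = c(1, 0, 0), B = c(1, 1, 0), C = c(0, 0, 1))
  colnames(m) <- c("s1", "s2", "s3")
  occurrence_matrix(m, "toy")
}

# Random incidence matrix with no empty species columns.
random_occ <- function(n_sites, n_species, seed, p = 0.35) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_sites * n_species, 1, p), n_sites, n_species,
                dimnames = list(sprintf("site%02d", seq_len(n_sites)),
                                sprintf("sp%02d", seq_len(n_species))))
    if (all(colSums(m) > 0)) return(occurrence_matrix(m, "rand"))
  }
}

# Brute-force oracle: mean richness over ALL m-site subsets (exact
# expectation of sample-based rarefaction by enumeration).
enumerate_mean_richness <- function(occ, m) {
  subsets <- utils::combn(nrow(occ), m)
  mean(apply(subsets, 2, function(idx) {
    sum(colSums(occ[idx, , drop = FALSE]) > 0)
  }))
}

# Derivative-free logistic-regression oracle: direct maximisation of the
# Bernoulli log-likelihood, independent of any IRLS path.
brute_force_logit <- function(y, X) {
  X1 <- cbind(1, as.matrix(X))
  negll <- function(b) {
    eta <- drop(X1 %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  fit <- optim(rep(0, ncol(X1)), negll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 50000))
  fit$par
}

# Small Euclidean pond table on random coordinates.
random_ponds <- function(n, seed, extent = 20000) {
  set.seed(seed)
  as_pond_table(data.frame(
    pond_id = sprintf("q%02d", seq_len(n)),
    x = runif(n, 0, extent), y = runif(n, 0, extent),
    area_1957 = rlnorm(n, 2, 1), area_2010 = NA_real_,
    cond_1957 = rlnorm(n, 1, 0.5), cond_2010 = NA_real_,
    extant_1957 = TRUE, extant_2010 = FALSE,
    sampled_1957 = TRUE, sampled_2010 = FALSE
  ))
}

# Pond table from explicit coordinates (all extant both epochs unless told
# otherwise) for network hand-calculations. Coordinates in metres.
ponds_from_xy <- function(x, y, extant_2010 = TRUE) {
  n <- length(x)
  as_pond_table(data.frame(
    pond_id = sprintf("n%02d", seq_len(n)),
    x = x, y = y,
    area_1957 = 1, area_2010 = 1,
    cond_1957 = 1, cond_2010 = 1,
    extant_1957 = TRUE, extant_2010 = rep_len(extant_2010, n),
    sampled_1957 = TRUE, sampled_2010 = rep_len(extant_2010, n)
  ))
}
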