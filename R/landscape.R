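#' Parameters of a synthetic pond landscape
#'
#' Defaults emulate a saline-pond district: 116 ponds scattered over a
#' 27 x 10 km rectangle (~270 km2), right-skewed (lognormal) surface areas
#' with a mean around 13 ha, and lognormal annual-mean conductivities with a
#' mean around 3 mS/cm.
#'
#' @param n_ponds number of ponds (>= 2).
#' @param extent_x,extent_y region dimensions in metres.
#' @param area_logmean,area_logsd lognormal parameters of pond area (ha).
#' @param cond_logmean,cond_logsd lognormal parameters of conductivity (mS/cm).
#' @return a `landscape_params` list.
#' @export
landscape_params <- function(n_ponds = 116,
                             extent_x = 27000, extent_y = 10000,
                             area_logmean = 2.0, area_logsd = 1.1,
                             cond_logmean = 0.9, cond_logsd = 0.6) {
  stopifnot(n_ponds >= 2, extent_x > 0, extent_y > 0,
            area_logsd >= 0, cond_logsd >= 0)
  structure(list(n_ponds = n_ponds, extent_x = extent_x, extent_y = extent_y,
                 area_logmean = area_logmean, area_logsd = area_logsd,
                 cond_logmean = cond_logmean, cond_logsd = cond_logsd),
            class = "landscape_params")
}

#' Parameters of a synthetic species pool
#'
#' Species prevalences (maximum occupancy probabilities) are drawn from a
#' right-skewed Beta distribution, giving the many-rare / few-common
#' occupancy structure typical of metacommunity surveys. Each species has a
#' Gaussian niche on log-conductivity: its occupancy probability at a pond
#' falls off with the squared distance between the pond's log-conductivity
#' and the species' optimum.
#'
#' @param n_species pool size.
#' @param prevalence_shape1,prevalence_shape2 Beta parameters of prevalence.
#' @param niche_sd_log niche width on the log-conductivity axis; `Inf` gives
#'   flat (salinity-indifferent) species.
#' @param niche_optima_range range (log mS/cm) over which species optima are
#'   drawn uniformly.
#' @return a `pool_params` list.
#' @export
pool_params <- function(n_species = 60,
                        prevalence_shape1 = 0.35, prevalence_shape2 = 1.6,
                        niche_sd_log = 0.8,
                        niche_optima_range = c(log(0.5), log(10))) {
  stopifnot(n_species >= 1, prevalence_shape1 > 0, prevalence_shape2 > 0,
            niche_sd_log > 0, length(niche_optima_range) == 2)
  structure(list(n_species = n_species,
                 prevalence_shape1 = prevalence_shape1,
                 prevalence_shape2 = prevalence_shape2,
                 niche_sd_log = niche_sd_log,
                 niche_optima_range = niche_optima_range),
            class = "pool_params")
}

#' Parameters of the post-loss relaxation (delayed extinction) model
#'
#' After habitat loss, each remaining incidence (species x surviving pond)
#' is lost independently with probability
#' `plogis(b0 + b_conn * d_closeness + b_area * d_log_area + b_cond * |d_cond|)`.
#' Positive `b_conn` makes extinction more likely at ponds that became more
#' peripheral (closeness increased); negative `b_area` makes shrinking ponds
#' lose more. There is no recolonisation: the model captures relaxation
#' towards a poorer equilibrium, not recovery.
#'
#' @param b0 baseline logit of per-incidence extinction.
#' @param b_conn coefficient on the change in closeness (per km).
#' @param b_area coefficient on the change in log-area.
#' @param b_cond coefficient on the absolute conductivity change (per mS/cm).
#' @param cond_drift_mean,cond_drift_sd additive Gaussian drift of epoch-2
#'   conductivity (mS/cm); the default mean `+0.77` reproduces the observed
#'   regional salinisation trend.
#' @return a `relaxation_params` list.
#' @export
relaxation_params <- function(b0 = 2.0, b_conn = 0.6, b_area = -0.3,
                              b_cond = 0.1,
                              cond_drift_mean = 0.77, cond_drift_sd = 2.0) {
  vals <- c(b0, b_conn, b_area, b_cond, cond_drift_mean, cond_drift_sd)
  stopifnot(all(is.finite(vals)), cond_drift_sd >= 0)
  structure(list(b0 = b0, b_conn = b_conn, b_area = b_area, b_cond = b_cond,
                 cond_drift_mean = cond_drift_mean, cond_drift_sd = cond_drift_sd),
            class = "relaxation_params")
}

#' Generate a synthetic pond landscape
#'
#' Pond coordinates are uniform on the extent rectangle; areas and
#' conductivities are i.i.d. lognormal. All ponds start extant and sampled
#' in epoch 1; habitat loss and survey subsampling are applied separately.
#'
#' @param params a [landscape_params()] list.
#' @param seed integer seed; the generator is a pure function of
#'   `(params, seed)`.
#' @return a `pond_table`.
#' @export
generate_landscape <- function(params = landscape_params(), seed = 1) {
  stopifnot(inherits(params, "landscape_params"))
  set.seed(seed)
  n <- params$n_ponds
  df <- data.frame(
    pond_id = sprintf("p%03d", seq_len(n)),
    x = stats::runif(n, 0, params$extent_x),
    y = stats::runif(n, 0, params$extent_y),
    area_1957 = stats::rlnorm(n, params$area_logmean, params$area_logsd),
    area_2010 = NA_real_,
    cond_1957 = stats::rlnorm(n, params$cond_logmean, params$cond_logsd),
    cond_2010 = NA_real_,
    extant_1957 = TRUE,
    extant_2010 = FALSE,
    sampled_1957 = TRUE,
    sampled_2010 = FALSE
  )
  as_pond_table(df)
}

#' Simulate species occurrences over a landscape
#'
#' Species `i` occupies pond `j` independently with probability
#' `prev_i * exp(-(log(cond_j) - mu_i)^2 / (2 * niche_sd_log^2))`: the
#' prevalence scales overall commonness, the Gaussian factor encodes the
#' salinity niche. Species that end up occupying no pond are dropped.
#'
#' @param ponds `pond_table`; all ponds extant in `epoch` are used.
#' @param pool a [pool_params()] list.
#' @param epoch `"1957"` or `"2010"`; selects extant flags and conductivity.
#' @param seed integer seed.
#' @return an `occurrence_matrix` over the extant ponds of the epoch.
#' @export
simulate_occurrence <- function(ponds, pool = pool_params(), epoch = "1957",
                                seed = 1) {
  stopifnot(inherits(pool, "pool_params"))
  extant <- ponds[[paste0("extant_", epoch)]]
  cond <- ponds[[paste0("cond_", epoch)]][extant]
  ids <- ponds$pond_id[extant]
  if (anyNA(cond)) stop("conductivity absent for extant ponds in epoch ", epoch)
  set.seed(seed)
  prev <- stats::rbeta(pool$n_species, pool$prevalence_shape1, pool$prevalence_shape2)
  mu <- stats::runif(pool$n_species, pool$niche_optima_range[1],
                     pool$niche_optima_range[2])
  # p[j, i]: outer over sites x species
  niche <- exp(-outer(log(cond), mu, "-")^2 / (2 * pool$niche_sd_log^2))
  p <- sweep(niche, 2, prev, "*")
  m <- matrix(stats::rbinom(length(p), 1L, p), nrow = length(ids),
              dimnames = list(ids, sprintf("sp%03d", seq_len(pool$n_species))))
  m <- m[, colSums(m) > 0, drop = FALSE]
  occurrence_matrix(m, epoch)
}

#' Occupancy probability grid of the occurrence model
#'
#' Deterministic companion to [simulate_occurrence()]: the site x species
#' probability matrix for a fixed draw of prevalences and optima (same seed
#' stream), used for expectation checks.
#' @inheritParams simulate_occurrence
#' @return numeric matrix of occupancy probabilities (sites x species).
#' @export
occurrence_probabilities <- function(ponds, pool = pool_params(),
                                     epoch = "1957", seed = 1) {
  extant <- ponds[[paste0("extant_", epoch)]]
  cond <- ponds[[paste0("cond_", epoch)]][extant]
  set.seed(seed)
  prev <- stats::rbeta(pool$n_species, pool$prevalence_shape1, pool$prevalence_shape2)
  mu <- stats::runif(pool$n_species, pool$niche_optima_range[1],
                     pool$niche_optima_range[2])
  niche <- exp(-outer(log(cond), mu, "-")^2 / (2 * pool$niche_sd_log^2))
  p <- sweep(niche, 2, prev, "*")
  dimnames(p) <- list(ponds$pond_id[extant], sprintf("sp%03d", seq_len(pool$n_species)))
  p
}

#' Apply habitat loss to a landscape
#'
#' Marks exactly `keep` ponds as extant in epoch 2. `random` mode draws a
#' uniform subset; `clustered` mode ranks ponds by a noisy logistic decay of
#' survival with distance from a random focal point, so survivors clump.
#'
#' @param ponds `pond_table` with epoch-1 extant ponds.
#' @param keep number (or fraction in (0,1)) of ponds surviving to epoch 2.
#' @param mode `"random"` or `"clustered"`.
#' @param seed integer seed.
#' @param decay_km e-folding distance (km) of the clustered survival decay.
#' @return the `pond_table` with updated `extant_2010`.
#' @export
apply_habitat_loss <- function(ponds, keep, mode = c("random", "clustered"),
                               seed = 1, decay_km = 5) {
  mode <- match.arg(mode)
  n <- sum(ponds$extant_1957)
  if (keep > 0 && keep < 1) keep <- round(keep * n)
  keep <- as.integer(keep)
  if (keep < 1 || keep > n) stop("keep must be in 1..", n)
  idx <- which(ponds$extant_1957)
  set.seed(seed)
  if (mode == "random") {
    survivors <- sample(idx, keep)
  } else {
    focal <- c(stats::runif(1, min(ponds$x), max(ponds$x)),
               stats::runif(1, min(ponds$y), max(ponds$y)))
    d_km <- sqrt((ponds$x[idx] - focal[1])^2 + (ponds$y[idx] - focal[2])^2) / 1000
    score <- stats::plogis(-d_km / decay_km) * stats::runif(length(idx))
    survivors <- idx[order(score, decreasing = TRUE)[seq_len(keep)]]
  }
  ponds$extant_2010 <- FALSE
  ponds$extant_2010[survivors] <- TRUE
  ponds
}

#' Relax a metacommunity after habitat loss
#'
#' Restricts the matrix to surviving sites, then flips each remaining
#' incidence to absence independently with the logistic extinction
#' probability of [relaxation_params()]. No colonisation occurs, so
#' regional richness can only decrease.
#'
#' @param occ `occurrence_matrix` (epoch-1 incidences).
#' @param delta data frame with columns `pond_id`, `d_closeness` (km),
#'   `d_log_area`, `d_conductivity` (mS/cm), one row per surviving site.
#' @param params a [relaxation_params()] list.
#' @param seed integer seed.
#' @param no_extinction if `TRUE`, skip the flips entirely (the output is
#'   the input restricted to survivors).
#' @return an `occurrence_matrix` labelled `"2010"` on the surviving sites;
#'   species left with no occurrences are dropped.
#' @export
simulate_relaxation <- function(occ, delta, params = relaxation_params(),
                                seed = 1, no_extinction = FALSE) {
  stopifnot(inherits(params, "relaxation_params"))
  unknown <- setdiff(delta$pond_id, rownames(occ))
  if (length(unknown) > 0) {
    stop("delta rows for sites absent from the occurrence matrix: ",
         paste(unknown, collapse = ", "))
  }
  # the delta table defines the surviving sites; all other rows are dropped
  keep_sites <- rownames(occ)[rownames(occ) %in% delta$pond_id]
  m <- unclass(occ)[keep_sites, , drop = FALSE]
  d <- delta[match(keep_sites, delta$pond_id), ]
  if (anyNA(d$d_closeness) || anyNA(d$d_log_area) || anyNA(d$d_conductivity)) {
    stop("delta table has missing values")
  }
  if (!no_extinction) {
    q <- stats::plogis(params$b0 + params$b_conn * d$d_closeness +
                         params$b_area * d$d_log_area +
                         params$b_cond * abs(d$d_conductivity))
    set.seed(seed)
    flips <- matrix(stats::runif(length(m)) < q, nrow = nrow(m))  # q recycles by row
    m[m == 1L & flips] <- 0L
  }
  m <- m[, colSums(m) > 0, drop = FALSE]
  occurrence_matrix(m, "2010")
}

#' Generate a complete two-epoch synthetic case study
#'
#' End-to-end fixture mirroring the dimensions of a six-decade pond-loss
#' survey: 116 ponds, of which `n_sampled_1` (53) are sampled in epoch 1;
#' `keep` (30) ponds survive to epoch 2 and all are sampled then, with
#' `n_overlap` (24) of them among the epoch-1 sampled set. Epoch-2
#' conductivity drifts upward (salinisation), areas shrink mildly, the
#' habitat network contracts, and delayed extinctions follow the
#' connectivity-, area- and salinity-dependent relaxation model.
#'
#' @param seed master seed; all stages draw from seeds derived from it.
#' @param landscape,pool,relax parameter lists.
#' @param n_sampled_1 epoch-1 sampled pond count.
#' @param keep epoch-2 surviving pond count.
#' @param n_overlap surviving ponds that were also sampled in epoch 1.
#' @param loss_mode habitat-loss mode, see [apply_habitat_loss()].
#' @param area_shrink_logmean,area_shrink_logsd lognormal shrink factor of
#'   surviving-pond areas.
#' @param no_extinction passed to [simulate_relaxation()].
#' @return a list with `ponds` (pond_table), `occ_1957` (53 x S matrix over
#'   sampled ponds), `occ_2010` (30 x S'), `body_sizes`, `delta` (per-site
#'   changes for survivors) and the parameter lists.
#' @export
generate_case_study <- function(seed = 1,
                                landscape = landscape_params(),
                                pool = pool_params(),
                                relax = relaxation_params(),
                                n_sampled_1 = 53, keep = 30, n_overlap = 24,
                                loss_mode = "clustered",
                                area_shrink_logmean = -0.2,
                                area_shrink_logsd = 0.3,
                                no_extinction = FALSE) {
  stopifnot(n_overlap <= keep, n_sampled_1 <= landscape$n_ponds,
            n_overlap <= n_sampled_1)
  s <- split_seed(seed, 1:7)
  ponds <- generate_landscape(landscape, seed = s[1])
  occ_full <- simulate_occurrence(ponds, pool, epoch = "1957", seed = s[2])
  ponds <- apply_habitat_loss(ponds, keep = keep, mode = loss_mode, seed = s[3])

  # epoch-2 habitat state of survivors: drifted conductivity, shrunken area
  set.seed(s[4])
  surv <- which(ponds$extant_2010)
  ponds$cond_2010[surv] <- pmax(
    ponds$cond_1957[surv] +
      stats::rnorm(length(surv), relax$cond_drift_mean, relax$cond_drift_sd),
    0.1)
  ponds$area_2010[surv] <- ponds$area_1957[surv] *
    stats::rlnorm(length(surv), area_shrink_logmean, area_shrink_logsd)

  # survey design: all survivors sampled in 2010; epoch-1 sample contains
  # n_overlap future survivors plus enough future losses to reach n_sampled_1
  set.seed(s[5])
  surv_ids <- ponds$pond_id[surv]
  lost_ids <- ponds$pond_id[ponds$extant_1957 & !ponds$extant_2010]
  sampled_1 <- c(sample(surv_ids, n_overlap),
                 sample(lost_ids, n_sampled_1 - n_overlap))
  ponds$sampled_1957 <- ponds$pond_id %in% sampled_1
  ponds$sampled_2010 <- ponds$extant_2010

  # network contraction and per-site changes drive the relaxation
  net_1 <- build_network(ponds, "1957")
  net_2 <- build_network(ponds, "2010")
  dclose <- delta_closeness(net_1, net_2, surv_ids)
  delta <- data.frame(
    pond_id = surv_ids,
    d_closeness = dclose[surv_ids],
    d_log_area = log(ponds$area_2010[surv]) - log(ponds$area_1957[surv]),
    d_conductivity = ponds$cond_2010[surv] - ponds$cond_1957[surv]
  )
  occ_2010 <- simulate_relaxation(occ_full, delta, relax, seed = s[6],
                                  no_extinction = no_extinction)

  set.seed(s[7])
  body_sizes <- data.frame(
    species_id = colnames(occ_full),
    body_size_mm = stats::rlnorm(ncol(occ_full), -0.7, 0.8)
  )

  occ_1957 <- unclass(occ_full)[sampled_1, , drop = FALSE]
  occ_1957 <- occ_1957[, colSums(occ_1957) > 0, drop = FALSE]
  list(ponds = ponds,
       occ_1957 = occurrence_matrix(occ_1957, "1957"),
       occ_2010 = occ_2010,
       occ_full_1957 = occ_full,
       body_sizes = body_sizes,
       delta = delta,
       params = list(landscape = landscape, pool = pool, relax = relax,
                     n_sampled_1 = n_sampled_1, keep = keep,
                     n_overlap = n_overlap, seed = seed))
}

#' Materialise a synthetic case study as CSV files
#'
#' Writes `ponds.csv`, `occ_1957.csv`, `occ_2010.csv` and `body_sizes.csv`
#' in the formats read by [read_pond_table()] and
#' [read_occurrence_matrix()].
#'
#' @param seed master seed passed to [generate_case_study()].
#' @param out_dir output directory (created if needed).
#' @param ... further arguments to [generate_case_study()].
#' @return invisibly, the named vector of file paths.
#' @export
make_fixture <- function(seed, out_dir, ...) {
  cs <- generate_case_study(seed = seed, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ponds = file.path(out_dir, "ponds.csv"),
    occ_1957 = file.path(out_dir, "occ_1957.csv"),
    occ_2010 = file.path(out_dir, "occ_2010.csv"),
    body_sizes = file.path(out_dir, "body_sizes.csv")
  )
  write_pond_table(cs$ponds, paths["ponds"])
  write_occurrence_matrix(cs$occ_1957, paths["occ_1957"])
  write_occurrence_matrix(cs$occ_2010, paths["occ_2010"])
  utils::write.csv(cs$body_sizes, paths["body_sizes"], row.names = FALSE)
  invisible(paths)
}

#' Derive per-stage seeds from a master seed
#'
#' Deterministic counter scheme: stage `k` gets
#' `(master * 48271 + k * 16807) mod (2^31 - 1)` (Lehmer-style multipliers;
#' all intermediates stay exactly representable as doubles), so stages can
#' be re-run independently yet reproducibly.
#'
#' @param master master seed (integer).
#' @param stages integer vector of stage counters.
#' @return integer vector of derived seeds, each in `[1, 2^31 - 1]`.
#' @export
split_seed <- function(master, stages) {
  m <- 2147483647
  base <- (as.numeric(master) %% m) * 48271 %% m
  vapply(stages, function(k) {
    as.integer((base %% m + k * 16807) %% m + 1)
  }, integer(1))
}
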