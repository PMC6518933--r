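#' Configuration for a full pipeline run
#'
#' All defaults are explicit and echoed into the report. A single master
#' seed is split deterministically into per-stage streams
#' ([split_seed()]), so any stage can be re-run on its own and reproduce.
#'
#' @param input either `NULL` (generate a synthetic case study from
#'   `seed`) or a named list of CSV paths `ponds`, `occ_1957`, `occ_2010`,
#'   `body_sizes`.
#' @param seed master seed.
#' @param n_runs accumulation resampling runs (default 2000).
#' @param n_perm permutations for effect sizes (default 200).
#' @param n_compare accumulation runs scored in the predictor competition
#'   (the spline fits dominate the cost; the proportion stabilises well
#'   before the full run count).
#' @param qr_df quantile-spline basis dimension for the area envelope.
#' @param spline_k basis dimension of the comparison smooths.
#' @param out_dir optional output directory for `results.json` and
#'   per-stage CSVs.
#' @param no_colonisation flag recorded in the config echo: the relaxation
#'   model never adds incidences (documented assumption, not a switch that
#'   anything currently flips).
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, seed = 1, n_runs = 2000, n_perm = 200,
                       n_compare = 200, qr_df = 5, spline_k = 10,
                       out_dir = NULL, no_colonisation = TRUE) {
  structure(list(input = input, seed = seed, n_runs = n_runs, n_perm = n_perm,
                 n_compare = n_compare, qr_df = qr_df, spline_k = spline_k,
                 out_dir = out_dir, no_colonisation = no_colonisation),
            class = "run_config")
}

load_case_data <- function(config) {
  if (is.null(config$input)) {
    cs <- generate_case_study(seed = split_seed(config$seed, 100))
    list(ponds = cs$ponds, occ_1957 = cs$occ_1957, occ_2010 = cs$occ_2010,
         body_sizes = cs$body_sizes, synthetic = TRUE)
  } else {
    paths <- config$input
    ponds <- read_pond_table(paths$ponds)
    list(ponds = ponds,
         occ_1957 = read_occurrence_matrix(paths$occ_1957, "1957", ponds),
         occ_2010 = read_occurrence_matrix(paths$occ_2010, "2010", ponds),
         body_sizes = utils::read.csv(paths$body_sizes, stringsAsFactors = FALSE),
         synthetic = FALSE)
  }
}

#' Per-pond changes between epochs for resurveyed ponds
#'
#' Builds the site-change table for ponds sampled in both epochs: change
#' in local richness, in closeness centrality (from the full epoch
#' networks), in conductivity, and in log area.
#'
#' @param data list with `ponds`, `occ_1957`, `occ_2010` as produced by the
#'   pipeline loader.
#' @return data frame with one row per resurveyed pond.
#' @export
site_change_records <- function(data) {
  both <- intersect(rownames(data$occ_1957), rownames(data$occ_2010))
  if (length(both) == 0) stop("no ponds sampled in both epochs")
  net_1 <- build_network(data$ponds, "1957")
  net_2 <- build_network(data$ponds, "2010")
  dclose <- delta_closeness(net_1, net_2, both)
  p <- data$ponds[match(both, data$ponds$pond_id), ]
  data.frame(
    pond_id = both,
    d_richness = rowSums(data$occ_2010[both, , drop = FALSE]) -
      rowSums(data$occ_1957[both, , drop = FALSE]),
    d_closeness = unname(dclose[both]),
    d_conductivity = p$cond_2010 - p$cond_1957,
    d_log_area = log(p$area_2010) - log(p$area_1957),
    row.names = NULL
  )
}

#' Run the full two-epoch habitat-loss analysis
#'
#' Executes, in order: data loading (or synthetic generation), diversity
#' summaries, rarefaction to the epoch-2 habitat number and total habitat
#' area (expected losses under the sampling-only null), the habitat-number
#' vs habitat-area predictor competition, network closeness change,
#' permutation effect sizes for alpha and beta diversity, the species-trait
#' extinction model with commonality partition, and the local-drivers
#' partition at resurveyed ponds. Writes `results.json` (and per-stage
#' CSVs) when `config$out_dir` is set.
#'
#' @param config a [run_config()].
#' @return the report bundle (named list), invisibly also written to disk
#'   when requested.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- split_seed(config$seed, 1:6)
  data <- load_case_data(config)
  occ_1957 <- data$occ_1957
  occ_2010 <- data$occ_2010
  ponds <- data$ponds

  div_1957 <- diversity_summary(occ_1957)
  div_2010 <- diversity_summary(occ_2010)
  gained <- setdiff(colnames(occ_2010), colnames(occ_1957))
  lost <- setdiff(colnames(occ_1957), colnames(occ_2010))

  # rarefaction of the epoch-1 community down to the epoch-2 footprint
  m_target <- nrow(occ_2010)
  loss_sites <- expected_loss_sites(occ_1957, m_target,
                                    n_runs = config$n_runs, seed = seeds[1])
  areas_1957 <- ponds$area_1957[match(rownames(occ_1957), ponds$pond_id)]
  ids_2010 <- rownames(occ_2010)
  a_target <- sum(ponds$area_2010[match(ids_2010, ponds$pond_id)])
  runs_area <- accumulation_runs(occ_1957, areas = areas_1957,
                                 n_runs = config$n_runs, seed = seeds[2])
  loss_area <- expected_loss_area(occ_1957, areas_1957, a_target,
                                  n_runs = config$n_runs, qr_df = config$qr_df,
                                  seed = seeds[2])

  # habitat number vs habitat area as predictors, per accumulation run
  areas_2010 <- ponds$area_2010[match(ids_2010, ponds$pond_id)]
  runs_area_2010 <- accumulation_runs(occ_2010, areas = areas_2010,
                                      n_runs = config$n_compare, seed = seeds[3])
  cmp_1957 <- proportion_sites_better(runs_area, k = config$spline_k,
                                      max_runs = config$n_compare)
  cmp_2010 <- proportion_sites_better(runs_area_2010, k = config$spline_k)

  # network contraction
  net_1 <- build_network(ponds, "1957")
  net_2 <- build_network(ponds, "2010")
  shared_extant <- intersect(net_1$ids, net_2$ids)
  dclose <- delta_closeness(net_1, net_2, shared_extant)

  es_alpha <- effect_size_alpha(occ_1957, occ_2010, n_perm = config$n_perm,
                                seed = seeds[4])
  es_beta <- effect_size_beta(occ_1957, occ_2010, n_perm = config$n_perm,
                              seed = seeds[5])

  traits <- derive_species_traits(occ_1957, ponds, data$body_sizes,
                                  regional_2010 = colnames(occ_2010))
  ext_fit <- extinction_model(traits)
  trait_part <- commonality_partition(
    as.numeric(traits$extinct_2010),
    data.frame(rarity = sqrt(traits$occupancy_1957),
               body_size = log(traits$body_size),
               preference = traits$preference),
    family = "binomial")

  records <- site_change_records(data)
  local <- local_drivers_analysis(records)

  report <- list(
    synthetic = data$synthetic,
    n_sites = list(epoch1 = nrow(occ_1957), epoch2 = nrow(occ_2010),
                   resurveyed = nrow(records)),
    gamma = list(epoch1 = div_1957$gamma, epoch2 = div_2010$gamma),
    species_lost = length(lost), species_gained = length(gained),
    net_loss = div_1957$gamma - div_2010$gamma,
    mean_alpha = list(epoch1 = div_1957$mean_alpha, epoch2 = div_2010$mean_alpha),
    beta = list(epoch1 = div_1957$beta, epoch2 = div_2010$beta),
    expected_loss_sites = loss_sites[c("expected_loss", "rounded", "ci",
                                       "analytic_loss")],
    expected_loss_area = loss_area[c("expected_loss", "rounded", "ci")],
    a_target = a_target, m_target = m_target,
    predictor_competition = list(epoch1 = cmp_1957, epoch2 = cmp_2010),
    mean_delta_closeness_km = mean(dclose),
    effect_alpha = unclass(es_alpha)[c("D_bar", "p_value", "n_perm")],
    effect_beta = unclass(es_beta)[c("D_bar", "p_value", "n_perm")],
    extinction_model = list(coefficients = ext_fit$coefficients,
                            p_values = ext_fit$p_values,
                            converged = ext_fit$converged),
    trait_partition = trait_part[c("pure", "shared", "total_adj_r2")],
    mean_d_conductivity = mean(records$d_conductivity),
    local_drivers = list(pure = local$partition$pure,
                         total_adj_r2 = local$partition$total_adj_r2,
                         coefficients = local$coefficients,
                         p_values = local$p_values)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(report, file.path(config$out_dir, "results.json"),
                  seed = config$seed, config = unclass(config)[
                    c("n_runs", "n_perm", "n_compare", "qr_df", "spline_k",
                      "no_colonisation")])
    env <- loss_sites$envelope
    utils::write.csv(data.frame(grid = env$grid, central = env$central,
                                lo = env$lo, hi = env$hi),
                     file.path(config$out_dir, "envelope_sites.csv"),
                     row.names = FALSE)
    enva <- loss_area$envelope
    utils::write.csv(data.frame(grid = enva$grid, central = enva$central,
                                lo = enva$lo, hi = enva$hi),
                     file.path(config$out_dir, "envelope_area.csv"),
                     row.names = FALSE)
    utils::write.csv(records, file.path(config$out_dir, "site_changes.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(traits),
                     file.path(config$out_dir, "traits.csv"), row.names = FALSE)
  }
  report
}
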