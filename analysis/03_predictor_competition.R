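#!/usr/bin/env Rscript
# Stage 3: does habitat NUMBER or habitat AREA better predict regional
# richness? For each resampled accumulation run, fit the additive model
# richness ~ s(sites) + s(area) and score each predictor by drop-one
# explained deviance.

library(pondscape)

dir <- "results/case_study"
ponds <- read_pond_table(file.path(dir, "ponds.csv"))
n_compare <- 200

res <- lapply(c("1957", "2010"), function(ep) {
  occ <- read_occurrence_matrix(file.path(dir, paste0("occ_", ep, ".csv")),
                                ep, ponds)
  areas <- ponds[[paste0("area_", ep)]][match(rownames(occ), ponds$pond_id)]
  runs <- accumulation_runs(occ, areas, n_runs = n_compare,
                            seed = 20 + as.integer(ep == "2010"))
  pr <- proportion_sites_better(runs, k = 10)
  cat("Epoch ", ep, ": habitat number wins ", round(pr$pct_sites, 1),
      "% of ", pr$n_compared, " runs (", pr$n_tie, " ties)\n", sep = "")
  data.frame(epoch = ep, pct_sites = pr$pct_sites, n_sites = pr$n_sites,
             n_area = pr$n_area, n_tie = pr$n_tie, n_runs = pr$n_compared)
})

write.csv(do.call(rbind, res), "results/predictor_competition.csv",
          row.names = FALSE)
cat("Written to results/predictor_competition.csv\n")
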