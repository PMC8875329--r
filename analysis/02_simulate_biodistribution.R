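#!/usr/bin/env Rscript
# Simulate stavudine biodistribution for both formulations with the
# reference rat parameter table, export tidy trajectories, audit mass
# balance, and verify the AUC-ratio partition identities of the free-drug
# model on a long horizon.

suppressPackageStartupMessages(library(stavupbpk))
dir.create("results", showWarnings = FALSE)

groups <- list(
  solution = list(params = default_rat_parameters("solution", BW = 0.252),
                  dose = dose_spec(11.9, BW = 0.252)),
  nanoparticle = list(params = default_rat_parameters("nanoparticle",
                                                      BW = 0.252),
                      dose = dose_spec(15.6, BW = 0.252)))

for (g in names(groups)) {
  tr <- simulate_pbpk(groups[[g]]$params, groups[[g]]$dose, t_end = 24)
  df <- as.data.frame(tr)
  out <- sprintf("results/trajectory_%s.csv", g)
  write.csv(df, out, row.names = FALSE)
  ma <- mass_audit(tr)
  cat(sprintf("%-12s Cp(0) = %.0f ng/mL; mass-balance drift %.2e (%s)\n",
              g, trajectory_state(tr, "Cp")[1] +
                (if (g == "nanoparticle")
                   trajectory_state(tr, "Cp_np")[1] else 0),
              attr(ma, "max_drift"),
              if (attr(ma, "ok")) "closed" else "NOT closed"))
  cat("  wrote", out, "\n")
}

# long-horizon AUC ratios: the free-drug model returns the configured
# partition coefficients
tr200 <- simulate_pbpk(groups$solution$params, groups$solution$dose,
                       output_times = output_grid(200))
aucp <- trajectory_auc(tr200, "Cp")
ratios <- vapply(c("brain", "liver", "spleen", "thymus"), function(nm) {
  trajectory_auc(tr200, paste0(nm, "_ev")) / aucp
}, numeric(1))
ref <- vapply(groups$solution$params$tissues, `[[`, numeric(1), "P")
tab <- data.frame(tissue = names(ratios), auc_ratio = unname(ratios),
                  configured_P = unname(ref[names(ratios)]))
write.csv(tab, "results/auc_ratio_partition.csv", row.names = FALSE)
cat("extravascular/plasma AUC ratios at 200 h:\n")
print(tab, row.names = FALSE, digits = 4)
cat("wrote results/auc_ratio_partition.csv\n")
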