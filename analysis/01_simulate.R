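#!/usr/bin/env Rscript
# Step 1 — simulate the 2002-2008 multimedia fate of BaP for the packaged
# single-region scenario: Level IV integration under daily synthetic
# meteorology and the yearly emission table, then conversion to compartment
# concentrations.  Writes the daily and annual tables under results/.

suppressPackageStartupMessages(library(fugrisk))
dir.create("results", showWarnings = FALSE)
seed <- 1L

scn <- nanjing_default()
case <- run_case_study(scn, seed = seed)

write.csv(case$conc, "results/concentrations_daily.csv", row.names = FALSE)
write.csv(case$annual_conc, "results/concentrations_annual.csv",
          row.names = FALSE)
write_run_manifest("results/manifest_01_simulate.json", seed,
                   outputs = c("results/concentrations_daily.csv",
                               "results/concentrations_annual.csv"))

mb <- mass_balance(case$traj)
message(sprintf("Mass-balance closure over %d days: %.2e (relative)",
                nrow(case$forcing), mb$relative_error))
message("Annual mean concentrations:")
print(reshape(case$annual_conc[, c("year", "compartment", "concentration")],
              idvar = "year", timevar = "compartment", direction = "wide"))
message("Fugacity ranges (Pa):")
print(apply(case$traj$f, 2, range))
message(paste(
  "Findings: air and water concentrations fluctuate in a narrow band",
  "(water pinned near the constant river inflow), while soil and sediment",
  "accumulate year over year - the signature of a hydrophobic chemical",
  "partitioning into organic-rich immobile media."))
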