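#!/usr/bin/env Rscript
# Step 5 — linked 13-district run for 2006 under the prevailing east wind:
# the industrial source sits in the northern Liuhe district; air advection
# follows the wind across shared boundaries, water advection follows the
# river.  Risks are the increment induced by the local source (background
# inflows set to zero), mapped per district.

suppressPackageStartupMessages(library(fugrisk))
dir.create("results", showWarnings = FALSE)
seed <- 2L

regions <- nanjing_districts()
graph <- build_region_graph(regions, wind_direction = "E", wind_speed = 3)
cfg <- scenario_config(years = 2006, c_a = 0, c_w = 0)
forcing <- build_forcing(cfg, seed = seed)

trajs <- run_spatial(bap_default(), graph, forcing, f0 = c(0, 0, 0, 0))
rmap <- map_risk(trajs, exposure_default(), dose_response_default())
write.csv(rmap, "results/spatial_risk.csv", row.names = FALSE)
write_risk_geojson(regions, "results/spatial_risk.geojson", risk = rmap)
write_run_manifest("results/manifest_05_spatial.json", seed,
                   outputs = c("results/spatial_risk.csv",
                               "results/spatial_risk.geojson"))

message("Source-attributable district risks (2006, east wind):")
print(rmap[order(-rmap$R_t), c("district", "R_t", "exceeds")], digits = 3)
message(sprintf("Districts above the 1e-6 threshold: %d of %d",
                sum(rmap$exceeds), nrow(rmap)))
message(paste(
  "Under an east wind the Liuhe emission is exported to its western",
  "neighbour and the river; the urban core receives essentially nothing",
  "by air - the source location shields the city under the prevailing",
  "direction, though other wind directions would not."))
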