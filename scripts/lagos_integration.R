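#!/usr/bin/env Rscript
# Optional full-scale integration run against the LAGOS-NE data (not part
# of the test suite; requires a local download and several hours of compute).
#
# Expected inputs, prepared by the user from the LAGOS-NE distribution
# (GEO v1.03 geospatial module, LIMNO v1.054.1 lake module) and the
# Watershed Boundary Dataset HU-12 polygons:
#
#   <data_dir>/hu12_features.csv   one row per HU-12, 52 natural geographic
#                                  variables (terrestrial / climate /
#                                  freshwater themes), spatially isolated
#                                  units (islands, peninsulas) removed
#   <data_dir>/hu12_themes.csv     variable,theme map for the 52 variables
#   <data_dir>/hu12_edges.csv      HU-12 contiguity edge list (or derive one
#                                  from polygon GeoJSON via
#                                  adjacency_from_polygons())
#   <data_dir>/lakes.csv           point_id,unit_id,tp,secchi - summer-mean
#                                  (2002-2011) total phosphorus (ug/L) and
#                                  Secchi depth (m) per lake
#
# At full scale (~18,856 HU-12s) the published analysis corresponds to:
#   - PCA to 85% cumulative variance (24 axes on the published data)
#   - k = 100 regions; delta in {1, 4, 8, 16}; 1,000 k-means restarts
#   - k sweep 5..1000 (step 5/10/50) against 200 random clusterings,
#     window halfwidth 10 (window size 21); published optimum 80-110
#   - ~40% of lake TP / water-clarity variance among regions at moderate
#     contiguity (delta = 4, 8)

suppressPackageStartupMessages(library(ecoregions))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: lagos_integration.R <data_dir> [out_dir]")
data_dir <- args[1]
out_dir <- if (length(args) > 1) args[2] else "lagos_results"

tab <- read_unit_table(file.path(data_dir, "hu12_features.csv"),
                       theme_map = file.path(data_dir, "hu12_themes.csv"))
graph <- read_adjacency(file.path(data_dir, "hu12_edges.csv"), tab)
lakes <- read_responses(file.path(data_dir, "lakes.csv"))

clean <- preprocess_features(tab, graph)
emb <- pca_reduce(clean)  # 85% variance threshold
message(sprintf("retained %d axes (%.1f%% variance)",
                ncol(emb$scores), 100 * emb$cumulative_fraction))

curve <- ssw_vs_k_curves(emb, graph, delta = 4, n_random = 200,
                         restarts_per_k = 100, seed = 1,
                         space = clean$values)
curve <- select_optimal_k(curve, window_halfwidth = 10)
message(sprintf("selected k = %d (window %d-%d)", curve$chosen_k,
                curve$chosen_window[1], curve$chosen_window[2]))

ex <- run_experiment(tab, graph, k = 100, delta_levels = c(1, 4, 8, 16),
                     restarts = 1000, seed = 1, importance = TRUE,
                     responses = lakes, out_dir = out_dir)
print(ex$grid)
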