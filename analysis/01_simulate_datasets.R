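#!/usr/bin/env Rscript
# Generate the synthetic datasets used throughout the analysis: reference
# blink-count populations (monomeric and dimeric), receptor fields in the
# resting and ligand-stimulated state, a two-channel field with a labeled
# ligand, and three-state track sets. Everything is seeded; ground truth
# is written next to each dataset.

suppressPackageStartupMessages(library(qpalmspt))
out <- "results/sim"

# Counting populations. The photophysics follows the calibration of the
# mEos4b tag: bleaching probability p = 0.27 (monomeric reference),
# per-protomer detection efficiency d = 0.79, labeling efficiency L = 0.81.
# Fields cover 1600 um^2 (a pooled multi-cell acquisition) so the mixture
# fits downstream see ~1000 clusters.
resting <- sim_config(seed = 101, fov_nm = c(40000, 40000),
                      composition = c(monomer = 0.95, dimer = 0.05))
stimulated <- sim_config(seed = 102, fov_nm = c(40000, 40000),
                         composition = c(monomer = 0.29, dimer = 0.71))

run_simulate(resting, file.path(out, "field_resting"))
run_simulate(stimulated, file.path(out, "field_stimulated"))

# Two-channel field: half the clusters carry a bound, dye-labeled ligand.
two_col <- sim_config(seed = 103,
                      ligand = list(bound_fraction = 0.5, channel_sigma = 20,
                                    locs_per_site = 5))
field <- run_simulate(two_col, file.path(out, "field_twocolor"))
lig <- sim_ligand_channel(field$truth, two_col)
write_localizations(lig$table, file.path(out, "field_twocolor", "ligand.csv"))
utils::write.csv(lig$truth, file.path(out, "field_twocolor", "ground_truth.csv"),
                 row.names = FALSE)

# Track sets: a resting-like mobility mix and a strongly immobilized
# (ligand-saturated) mix.
trk_rest <- sim_config(seed = 104, diffusion = list(
  fractions = c(immobile = 0.15, confined = 0.25, free = 0.60),
  D_free = 0.1, D_conf = 0.03, r_c = 100, track_mean_length = 20))
trk_stim <- sim_config(seed = 105, diffusion = list(
  fractions = c(immobile = 0.72, confined = 0.14, free = 0.14),
  D_free = 0.1, D_conf = 0.03, r_c = 100, track_mean_length = 20))
run_simulate(trk_rest, file.path(out, "tracks_resting"), what = "tracks", n = 2000)
run_simulate(trk_stim, file.path(out, "tracks_stimulated"), what = "tracks", n = 2000)

cat("simulated datasets written under", out, "\n")
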