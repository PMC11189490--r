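#!/usr/bin/env Rscript
# Stage 3 — embedding transition probabilities and the fate-shift readout.
#
# For each condition, builds per-population neighbourhoods on the shared
# embedding (floor of 300 cells), correlates each cell's velocity with the
# signed-sqrt-transformed displacement to each neighbour, converts the
# correlations to row-stochastic transition probabilities (sigma = 0.05),
# and sums each cell's mass per target population.  Control and TBI mass
# distributions are then compared pair by pair with two-sided Wilcoxon
# rank-sum tests.

suppressPackageStartupMessages(library(velofate))

ds <- read_dataset("results/data")
dir.create("results/transitions", recursive = TRUE, showWarnings = FALSE)

trans <- do.call(rbind, lapply(sort(unique(ds$cell_meta$condition)),
                               function(cond) {
  keep <- ds$cell_meta$condition == cond
  current <- as.matrix(Matrix::readMM(
    sprintf("results/velocity/current_%s.mtx", cond)))
  deltaE <- as.matrix(Matrix::readMM(
    sprintf("results/velocity/deltaE_%s.mtx", cond)))
  population_transitions(ds$embedding[keep, ], current, deltaE,
                         ds$cell_meta$population[keep], condition = cond,
                         sigma = 0.05, minimum = 300,
                         cell_ids = ds$cell_meta$cell_id[keep])
}))
cmp <- compare_conditions(trans)  # x = Control, y = TBI

write.table(trans, "results/transitions/transition_mass.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cmp, "results/transitions/comparisons.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message("headline fate transitions (mean mass, Control vs TBI):")
key <- cmp$source == "RG-like" &
  cmp$target %in% c("N-stage 1", "A-stage 1", "RG-like")
print(cmp[key, c("source", "target", "mean_x", "mean_y", "p_value")],
      digits = 3, row.names = FALSE)
message("wrote results/transitions")
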