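#!/usr/bin/env Rscript
# Stage 5 — spatial zone assignment and location-shift statistics.
#
# Assigns each cell to a dentate-gyrus stratum from its signed offset
# (Hilus / SGZ / GL1 / GL2 / ML, half-open bands in nucleus widths),
# tabulates per-animal zone percentages per population, and compares
# Control vs TBI per (population, zone) with two-tailed unpaired t-tests
# (GL = GL1 + GL2 aggregate included).

suppressPackageStartupMessages(library(velofate))

sp <- read_spatial("results/data/spatial.tsv")
zones <- assign_zone(sp)
comp <- zone_composition(zones)
tests <- compare_locations(comp)  # x = Control, y = TBI

dir.create("results/spatial", recursive = TRUE, showWarnings = FALSE)
write.table(zones, "results/spatial/zones.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(comp, "results/spatial/composition.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(tests, "results/spatial/location_tests.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message("location shifts (per-animal mean %, Control vs TBI):")
key <- (tests$population == "N-stage 3" & tests$zone %in% c("SGZ", "GL")) |
  (tests$population == "A-stage 1" & tests$zone %in% c("SGZ", "Hilus"))
print(tests[key, c("population", "zone", "mean_x", "sem_x", "mean_y",
                   "sem_y", "p_value")], digits = 3, row.names = FALSE)
message("wrote results/spatial")
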