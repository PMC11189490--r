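#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic study.
#
# Generates the seeded branching-lineage dataset the downstream stages
# analyse: an NSC -> RG-like trunk feeding neuronal (N-stage) and
# astrocytic (A-stage) branches, 500 cells per condition, neuronal fate
# bias 0.5 in Control vs 0.75 after injury (TBI), Poisson counts at ~3000
# per cell with log-normal capture efficiency, plus a layered
# dentate-gyrus-like spatial cell set (4 Control / 5 TBI animals) in which
# injury displaces N-stage 3 cells toward the granule cell layer and
# A-stage 1 cells toward the hilus.

suppressPackageStartupMessages(library(velofate))

seed <- 1L
out <- "results/data"

ds <- simulate_dataset(seed = seed)
write_dataset(ds, out)
sp <- simulate_spatial(seed = seed + 2L)
write_spatial(sp, file.path(out, "spatial.tsv"))

message("wrote ", out)
message("cells per condition x population:")
print(table(ds$cell_meta$condition, ds$cell_meta$population))
message("spatial cells per condition: ")
print(table(sp$condition))
stopifnot(validate_inputs(out)$ok)
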