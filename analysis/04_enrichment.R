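#!/usr/bin/env Rscript
# Stage 4 — cluster-composition enrichment.
#
# Tests, per population, whether the share of TBI cells deviates from the
# TBI share of all analysed cells (exact two-sided binomial test).  With
# the neuronal fate bias raised after injury, neuronal populations should
# read out as enriched and astrocytic ones as depleted.

suppressPackageStartupMessages(library(velofate))

ds <- read_dataset("results/data")
enr <- binomial_enrichment(composition_table(ds$cell_meta))
write.table(enr, "results/enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("expected TBI fraction p0 = %.2f%%", 100 * enr$p0[1]))
print(enr[, c("cluster", "n", "k", "observed_fraction", "p_value",
              "direction")], digits = 3, row.names = FALSE)
message("wrote results/enrichment.tsv")
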