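# velofate

Steady-state RNA velocity and fate-transition statistics for a branching
neural-stem-cell lineage, with a seeded synthetic-data generator so every
stage is testable without downloads.

## The problem

Adult hippocampal neural stem cells (NSCs) in the dentate gyrus generate
both neurons and astrocytes. A central question after traumatic brain
injury is whether the bipotent progenitor's *fate decision* shifts —
more neurogenesis at the cost of astrogliogenesis — and whether specific
NSC-derived populations are displaced within the layered tissue.
`velofate` packages the computational machinery needed to ask that
question of paired spliced/unspliced count matrices and of spatial cell
sets, and a simulator that generates branching-lineage data with a known
injury effect so the whole chain can be validated end to end.

## The methods at its core

**Splicing kinetics.** Per gene, du/dt = α − βu, ds/dt = βu − γs, with
analytic solution `solve_kinetics()`. At steady state u*/s* = γ/β.

**Steady-state velocity** (`run_velocity()`): pool each cell over its
`kCells = 20` nearest expression neighbours; keep genes with mean pooled
spliced expression ≥ 0.5 (Malat1 excluded); fit γ per gene as the
through-origin slope Σus/Σs² on the extreme 2% expression quantiles
(`fit.quantile = 0.02`); velocity = u − γ̂s, with extrapolated expression
max(s + Δt·velocity, 0).

**Transition probabilities** (`population_transitions()`): per condition,
correlate each cell's velocity with the signed-√ displacement to each of
its n embedding neighbours (n = max(300, population size), capped), push
the correlations through a row-stochastic exponential kernel
(σ = 0.05), and sum each cell's mass per target population. Control vs
TBI mass distributions are compared per (source, target) pair with
two-sided Wilcoxon rank-sum tests (`compare_conditions()`).

**Composition enrichment** (`binomial_enrichment()`): exact two-sided
binomial test of each cluster's TBI share against the expected fraction
p0 (minimum-likelihood two-sided definition, identical to base-R
`binom.test` to machine precision).

**Spatial zones** (`assign_zone()`): signed offset d (nucleus widths)
from the granule-cell-layer/hilus boundary maps to Hilus (d < −2), SGZ
(−2 ≤ d < 0), GL1 (0 ≤ d < T−3), GL2 (T−3 ≤ d < T), ML (d ≥ T); zone
percentages are tabulated per animal and compared between conditions
with two-tailed unpaired t-tests (`compare_locations()`).

## Worked example

The numbered drivers under `analysis/` run the whole synthetic study
(500 cells/condition, neuronal fate bias 0.5 Control vs 0.75 TBI,
seed 1) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_velocity.R
Rscript analysis/03_transitions.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_spatial.R
```

`analysis/03_transitions.R` prints the headline fate readout:

```
headline fate transitions (mean mass, Control vs TBI):
  source    target mean_x mean_y  p_value
 RG-like A-stage 1  0.322  0.168 4.54e-05
 RG-like N-stage 1  0.106  0.341 3.62e-20
 RG-like   RG-like  0.541  0.459 2.73e-02
```

Read: the mean transition mass of RG-like cells toward the first
neuronal population roughly triples under the injured condition while
mass toward the first astrocytic population halves — the simulated fate
shift, recovered from counts alone. `04_enrichment.R` shows the same
effect as composition (N-stage populations enriched, A-stage depleted,
vs p0 = 50%), and `05_spatial.R` detects the built-in displacement of
N-stage 3 cells out of the SGZ into the granule cell layer (p ≈ 2.6e-5)
and of A-stage 1 cells into the hilus (p ≈ 1.2e-5).

A minimal in-R session:

```r
library(velofate)
ds <- simulate_dataset(seed = 1)           # 100 genes x 1000 cells
vr <- run_velocity(subset_cells(ds, ds$cell_meta$condition == "Control"))
head(vr$gamma_hat)                          # fitted degradation ratios
```

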