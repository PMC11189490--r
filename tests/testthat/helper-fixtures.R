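# Shared fixture builders; everything is generated in code under fixed seeds.

small_lineage <- function(cells = c(Control = 150, TBI = 150),
                          bias = c(Control = 0.5, TBI = 0.75)) {
  lineage_spec(fate_bias = bias, cells_per_condition = cells)
}

small_dataset <- function(seed = 7, n_genes = 40, lineage = small_lineage(),
                          noise = count_noise()) {
  programs <- {
    set.seed(seed)
    default_gene_programs(lineage, n_genes)
  }
  simulate_dataset(lineage, programs, noise, seed = seed)
}

# one condition's transition summary via the standard stages
condition_transitions <- function(dataset, cond, minimum = 60,
                                  sigma = 0.05,
                                  config = velocity_config()) {
  sub <- subset_cells(dataset, dataset$cell_meta$condition == cond)
  vr <- run_velocity(sub, config)
  population_transitions(sub$embedding, vr$current, vr$deltaE,
                         sub$cell_meta$population, condition = cond,
                         sigma = sigma, minimum = minimum,
                         cell_ids = sub$cell_meta$cell_id)
}

# a single gene traversing one full induction (alpha on) then repression
# (alpha off) cycle, sampled uniformly in time; noiseless kinetic means
induction_repression_gene <- function(gamma, beta = 1, alpha = 2,
                                      n_cells = 2000) {
  t_on <- 6 / min(gamma, beta)
  t <- seq(0, 2 * t_on, length.out = n_cells)
  peak <- solve_kinetics(u0 = 0, s0 = 0, alpha = alpha, tau = t_on,
                         beta = beta, gamma = gamma)
  on <- t <= t_on
  us <- solve_kinetics(u0 = 0, s0 = 0, alpha = alpha, tau = t[on],
                       beta = beta, gamma = gamma)
  ds <- solve_kinetics(u0 = peak$u, s0 = peak$s, alpha = 0,
                       tau = t[!on] - t_on, beta = beta, gamma = gamma)
  list(u = c(us$u, ds$u), s = c(us$s, ds$s))
}
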