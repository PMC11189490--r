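test_that("signed square root is the elementwise definition", {
  expect_identical(signed_sqrt(0), 0)
  expect_identical(signed_sqrt(4), 2)
  expect_identical(signed_sqrt(-4), -2)
  expect_equal(signed_sqrt(matrix(c(-9, 1, 0.25), 1)),
               matrix(c(-3, 1, 0.5), 1))
})

test_that("velocity correlations match a direct Pearson oracle", {
  set.seed(8)
  G <- 5; n <- 12
  current <- matrix(rnorm(G * n), G, n)
  deltaE <- matrix(rnorm(G * n), G, n)
  emb <- matrix(rnorm(2 * n), n, 2)
  nb <- embedding_neighbors(emb, 4)
  cc <- velocity_correlation(current, deltaE, nb, scale = "none")
  for (i in seq_len(n)) for (j in seq_len(4)) {
    expect_equal(cc[i, j],
                 cor(current[, nb[i, j]] - current[, i], deltaE[, i]),
                 tolerance = 1e-12)
  }
  expect_true(all(cc >= -1 & cc <= 1))

  # perfect alignment / anti-alignment with a neighbour's displacement
  disp <- current[, nb[1, 1]] - current[, 1]
  deltaE[, 1] <- 2 * disp
  cc <- velocity_correlation(current, deltaE, nb, scale = "none")
  expect_equal(cc[1, 1], 1, tolerance = 1e-12)
  deltaE[, 1] <- -disp
  cc <- velocity_correlation(current, deltaE, nb, scale = "none")
  expect_equal(cc[1, 1], -1, tolerance = 1e-12)

  # zero-variance displacement is a 0, not NA
  current[, nb[2, 1]] <- current[, 2]
  cc <- velocity_correlation(current, deltaE, nb, scale = "none")
  expect_identical(cc[2, 1], 0)
})

test_that("transition probabilities are a stable softmax over neighbours", {
  cc <- matrix(c(0.5, -0.5, 0.2, 0.2), 2, 2, byrow = TRUE)
  tp <- transition_probabilities(cc, sigma = 0.05)
  direct <- exp(cc[1, ] / 0.05) / sum(exp(cc[1, ] / 0.05))
  expect_equal(tp[1, ], direct, tolerance = 1e-12)
  expect_equal(tp[2, ], c(0.5, 0.5))  # equal cc -> uniform
  expect_equal(rowSums(tp), c(1, 1), tolerance = 1e-12)
  # max-shift keeps extreme correlations finite
  tp2 <- transition_probabilities(matrix(c(1, -1), 1), sigma = 1e-3)
  expect_true(all(is.finite(tp2)) && abs(sum(tp2) - 1) < 1e-12)
  expect_error(transition_probabilities(cc, sigma = 0), "positive")
})

test_that("population masses partition each row of tp", {
  # handcrafted 4-cell, 2-population toy
  nb <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  tp <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.6, 0.3),
              c(0.25, 0.25, 0.5), c(1, 0, 0))
  labels <- c("A", "A", "B", "B")
  m <- population_mass(tp, nb, labels)
  expect_equal(m[, "A"], c(0.5, 0.1, 0.5, 1))    # by hand
  expect_equal(m[, "B"], c(0.5, 0.9, 0.5, 0))
  expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-12)
  # all cells one population -> closed system
  m1 <- population_mass(tp, nb, rep("A", 4))
  expect_equal(unname(m1[, 1]), rep(1, 4), tolerance = 1e-12)
  # "mean" mode divides by the neighbour count per population
  mm <- population_mass(tp, nb, labels, mode = "mean")
  expect_equal(unname(mm[1, "A"]), 0.5)          # one A neighbour
  expect_equal(unname(mm[1, "B"]), 0.5 / 2)      # two B neighbours
  expect_error(population_mass(tp, nb, c("A", NA, "B", "B")), "labelled")
})

test_that("neighbourhood size follows the max(minimum, size) rule with a cap", {
  labels <- c(rep("small", 120), rep("big", 950))
  expect_equal(choose_neighborhood(labels, "small", 300), 300)
  expect_equal(choose_neighborhood(labels, "big", 300), 950)
  expect_equal(choose_neighborhood(rep("x", 200), "x", 300), 199)
  expect_error(choose_neighborhood("x", "x"), "at least two")
})

test_that("rank-sum test: exact enumeration, symmetry, and oracle agreement", {
  # identical multisets -> p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 2, 3), c(1, 2, 2, 3),
                                 mode = "exact")$p.value, 1)
  # fully separated groups: 2 of the 70 assignments are as extreme
  w <- wilcoxon_rank_sum(1:4, 5:8, mode = "exact")
  expect_equal(w$p.value, 2 / 70)
  # exact mode equals the base-R exact test on untied samples, n <= 8/group
  set.seed(15)
  for (i in 1:25) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(wilcoxon_rank_sum(x, y, mode = "exact")$p.value, ref,
                 tolerance = 1e-12)
  }
  # normal approximation agrees with the base-R tie-corrected version
  set.seed(16)
  for (i in 1:25) {
    x <- rpois(30, 4); y <- rpois(35, 4)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(wilcoxon_rank_sum(x, y, mode = "normal")$p.value, ref,
                 tolerance = 1e-10)
  }
  # exact and normal modes agree closely at moderate n
  set.seed(17)
  x <- runif(10); y <- runif(10)
  expect_lt(abs(wilcoxon_rank_sum(x, y, mode = "exact")$p.value -
                wilcoxon_rank_sum(x, y, mode = "normal")$p.value), 0.01)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("condition comparison handles identical and degenerate inputs", {
  masses <- data.frame(
    cell_id = rep(sprintf("c%02d", 1:20), 2),
    condition = rep(c("Control", "TBI"), each = 20),
    source = "P", target = "Q",
    mass = rep(seq(0, 1, length.out = 20), 2))
  cmp <- compare_conditions(masses)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$median_x, cmp$median_y)
  # a pair with a single source cell in one condition is not comparable
  one <- rbind(masses,
               data.frame(cell_id = c("d1", "d2"),
                          condition = c("Control", "TBI"),
                          source = "R", target = "Q", mass = c(0.5, 0.6)))
  cmp2 <- compare_conditions(one, min_cells = 3)
  expect_false(cmp2$comparable[cmp2$source == "R"])
  expect_true(is.na(cmp2$p_value[cmp2$source == "R"]))
})

test_that("per-pair means are invariant to permuting cell order", {
  ds <- small_dataset(seed = 31, n_genes = 30,
                      lineage = small_lineage(cells = c(Control = 80,
                                                        TBI = 80)))
  sub <- subset_cells(ds, ds$cell_meta$condition == "Control")
  vr <- run_velocity(sub)
  tr <- population_transitions(sub$embedding, vr$current, vr$deltaE,
                               sub$cell_meta$population, condition = "Control",
                               minimum = 30, cell_ids = sub$cell_meta$cell_id)
  set.seed(1)
  perm <- sample(ncol(sub$spliced))
  tr2 <- population_transitions(sub$embedding[perm, ],
                                vr$current[, perm], vr$deltaE[, perm],
                                sub$cell_meta$population[perm],
                                condition = "Control", minimum = 30,
                                cell_ids = sub$cell_meta$cell_id[perm])
  m1 <- aggregate(mass ~ source + target, tr, mean)
  m2 <- aggregate(mass ~ source + target, tr2, mean)
  m2 <- m2[match(paste(m1$source, m1$target),
                 paste(m2$source, m2$target)), ]
  expect_equal(m1$mass, m2$mass, tolerance = 1e-9)
  # masses partition each source cell's row
  tot <- aggregate(mass ~ cell_id, tr, sum)
  expect_equal(tot$mass, rep(1, nrow(tot)), tolerance = 1e-9)
})

test_that("increasing the neuronal fate bias increases RG-like to N-stage mass", {
  means <- vapply(c(0.3, 0.5, 0.8), function(b) {
    lin <- lineage_spec(fate_bias = c(Control = b, TBI = b),
                        cells_per_condition = c(Control = 150, TBI = 20))
    ds <- small_dataset(seed = 40, n_genes = 30, lineage = lin)
    tr <- condition_transitions(ds, "Control", minimum = 60)
    mean(tr$mass[tr$source == "RG-like" & tr$target == "N-stage 1"])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("rank-sum p-values are calibrated for exchangeable cells in a joint model", {
  # one transition model over both groups; under the null the group labels
  # are exchangeable, so per-pair p-values must be near-uniform
  lin <- lineage_spec(fate_bias = c(Control = 0.5, TBI = 0.5),
                      cells_per_condition = c(Control = 100, TBI = 100))
  ps <- c()
  for (s in 1:12) {
    ds <- small_dataset(seed = 100 + s, n_genes = 30, lineage = lin)
    vr <- run_velocity(ds)
    tr <- population_transitions(ds$embedding, vr$current, vr$deltaE,
                                 ds$cell_meta$population,
                                 minimum = 50,
                                 cell_ids = ds$cell_meta$cell_id)
    tr$condition <- ds$cell_meta$condition[
      match(tr$cell_id, ds$cell_meta$cell_id)]
    cmp <- compare_conditions(tr)
    ps <- c(ps, cmp$p_value[cmp$comparable])
  }
  expect_gt(length(ps), 200)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps < 0.5), 0.3)
})
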