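test_that("simulation is deterministic and conserves requested cell counts", {
  d1 <- small_dataset(seed = 11)
  d2 <- small_dataset(seed = 11)
  expect_identical(d1$spliced, d2$spliced)
  expect_identical(d1$unspliced, d2$unspliced)
  expect_identical(d1$cell_meta, d2$cell_meta)
  expect_identical(d1$embedding, d2$embedding)

  counts <- table(d1$cell_meta$condition)
  expect_equal(as.integer(counts[c("Control", "TBI")]), c(150, 150))
  expect_equal(ncol(d1$spliced), 300)
  expect_true(all(d1$spliced >= 0), all(d1$spliced == round(d1$spliced)))
  # every cell has exactly one condition and one population label
  expect_false(anyNA(d1$cell_meta$condition))
  expect_false(anyNA(d1$cell_meta$population))
  # animals assigned round-robin: 5 Control, 6 TBI animals by default
  expect_equal(length(unique(d1$cell_meta$animal[
    d1$cell_meta$condition == "Control"])), 5)
  expect_equal(length(unique(d1$cell_meta$animal[
    d1$cell_meta$condition == "TBI"])), 6)
})

test_that("branch assignment follows the condition's fate bias", {
  lin <- lineage_spec(fate_bias = c(Control = 0.5, TBI = 0.5),
                      cells_per_condition = c(Control = 1200, TBI = 50))
  ds <- small_dataset(seed = 1, lineage = lin)
  meta <- ds$cell_meta[ds$cell_meta$condition == "Control", ]
  post <- meta$population %in% c(lin$neuronal, lin$astro)
  k <- sum(meta$branch[post] == "neuronal")
  n <- sum(post)
  expect_gte(n, 400)
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("with noise off, steady-state genes satisfy u = (gamma/beta) s", {
  lin <- small_lineage(cells = c(Control = 60, TBI = 60))
  segs <- c(lin$trunk, lin$neuronal, lin$astro)
  # constant alpha across segments: the gene starts at and stays on its
  # steady state along every path
  set.seed(3)
  programs <- lapply(1:20, function(g)
    kinetic_gene_program(sprintf("g%02d", g),
                         setNames(rep(runif(1, 0.5, 3), length(segs)), segs),
                         beta = 1, gamma = runif(1, 0.2, 1.5)))
  ds <- simulate_dataset(lin, programs, count_noise("none"), seed = 5)
  g <- ds$gene_meta$gamma / ds$gene_meta$beta
  resid <- ds$unspliced - g * ds$spliced
  expect_lt(max(abs(resid)), 1e-9)
  # the unspliced/spliced ratio equals gamma/beta across cells
  expect_equal(unname(ds$unspliced[1, ] / ds$spliced[1, ]),
               rep(g[1], ncol(ds$spliced)), tolerance = 1e-12)
})

test_that("spatial simulator bookkeeping and determinism", {
  sp1 <- simulate_spatial(seed = 2)
  sp2 <- simulate_spatial(seed = 2)
  expect_identical(sp1, sp2)
  expect_equal(length(unique(sp1$animal[sp1$condition == "Control"])), 4)
  expect_equal(length(unique(sp1$animal[sp1$condition == "TBI"])), 5)
  expect_true(all(is.finite(sp1$signed_offset)))
  expect_true(all(sp1$gcl_thickness >= 4))

  # a population placed entirely below the layer boundary lands in the SGZ
  layout <- data.frame(population = "P", condition = c("Control", "TBI"),
                       mean_offset = -1, sd_offset = 0)
  sp <- simulate_spatial(layout, cells_per_animal = 5, seed = 1)
  z <- assign_zone(sp)
  expect_true(all(z$zone == "SGZ"))

  expect_error(simulate_spatial(layout, animals_per_condition = c(Control = 0),
                                seed = 1), ">= 1")
  expect_error(simulate_spatial(layout[0, ], seed = 1), "empty")
  expect_error(simulate_spatial(layout, gcl_thickness = 3, seed = 1), ">= 4")
})

test_that("dataset round-trips through the on-disk layout", {
  ds <- small_dataset(seed = 13, n_genes = 25,
                      lineage = small_lineage(cells = c(Control = 40,
                                                        TBI = 40)))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$spliced, ds$spliced)
  expect_equal(back$unspliced, ds$unspliced)
  expect_equal(back$cell_meta$population, ds$cell_meta$population)
  expect_equal(unname(back$embedding), unname(ds$embedding),
               tolerance = 1e-12)
  expect_true(validate_inputs(dir)$ok)
})
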