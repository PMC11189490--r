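#' Branching-lineage specification
#'
#' Describes the simulated differentiation tree: a linear trunk of
#' stem/progenitor populations that splits at its last segment into a
#' neuronal and an astrocytic branch.  Each condition has its own neuronal
#' fate bias (probability that a post-branch cell commits to the neuronal
#' branch) and its own number of cells and animals.
#'
#' Defaults emulate the dentate-gyrus niche under study: an
#' NSC -> RG-like trunk feeding N-stage and A-stage branches, a Control
#' condition with a balanced fate bias of 0.5 and an injured (TBI)
#' condition with a neuronal bias of 0.75, 500 cells and 5 (Control) / 6
#' (TBI) pooled animals per condition.
#'
#' @param trunk Ordered population labels of the shared trunk; the last one
#'   is the branch point.
#' @param neuronal,astro Ordered population labels of the two branches.
#' @param fate_bias Named probability per condition of taking the neuronal
#'   branch, in `[0, 1]`.
#' @param cells_per_condition Named integer cell counts per condition.
#' @param animals_per_condition Named integer animal counts per condition
#'   (cells are assigned round-robin).
#' @param segment_duration Kinetic time a cell spends traversing one
#'   segment, in units of 1/beta.
#' @return An object of class `lineage_spec`.
#' @export
lineage_spec <- function(trunk = c("NSC-stage 1", "NSC-stage 2", "RG-like"),
                         neuronal = c("N-stage 1", "N-stage 2"),
                         astro = c("A-stage 1", "A-stage 2"),
                         fate_bias = c(Control = 0.5, TBI = 0.75),
                         cells_per_condition = c(Control = 500, TBI = 500),
                         animals_per_condition = c(Control = 5, TBI = 6),
                         segment_duration = 3) {
  segs <- c(trunk, neuronal, astro)
  if (anyDuplicated(segs)) stop("segment labels must be unique")
  if (length(trunk) < 1L || length(neuronal) < 1L || length(astro) < 1L)
    stop("trunk and both branches must be non-empty")
  if (length(trunk) + length(neuronal) < 2L || length(trunk) + length(astro) < 2L)
    stop("each branch path needs at least two populations")
  conds <- names(cells_per_condition)
  if (is.null(conds) || anyDuplicated(conds))
    stop("'cells_per_condition' must be uniquely named by condition")
  if (any(cells_per_condition < 1)) stop("'cells_per_condition' must be >= 1")
  if (!all(conds %in% names(fate_bias)))
    stop("'fate_bias' must name every condition")
  if (any(fate_bias < 0 | fate_bias > 1)) stop("fate biases must lie in [0, 1]")
  if (!all(conds %in% names(animals_per_condition)) ||
      any(animals_per_condition < 1))
    stop("'animals_per_condition' must name every condition with counts >= 1")
  if (segment_duration <= 0) stop("'segment_duration' must be positive")
  structure(
    list(trunk = trunk, neuronal = neuronal, astro = astro,
         branch_point = trunk[length(trunk)],
         fate_bias = fate_bias[conds],
         cells_per_condition = cells_per_condition,
         animals_per_condition = animals_per_condition[conds],
         segment_duration = segment_duration),
    class = "lineage_spec"
  )
}

#' Count-noise configuration for the simulator
#'
#' Poisson sampling on kinetic means scaled by a per-cell capture
#' efficiency drawn from LogNormal(0, `capture_sd`^2); the simplest model
#' reproducing cross-cell overdispersion without extra parameters.
#' `model = "none"` returns the noiseless kinetic means themselves (useful
#' for exact steady-state checks).
#'
#' @param model `"poisson"` or `"none"`.
#' @param capture_sd Log-scale s.d. of the per-cell capture efficiency.
#' @param target_counts Expected total spliced counts per cell before
#'   capture-efficiency scaling.
#' @export
count_noise <- function(model = c("poisson", "none"), capture_sd = 0.3,
                        target_counts = 3000) {
  model <- match.arg(model)
  stopifnot(capture_sd >= 0, target_counts > 0)
  list(model = model, capture_sd = capture_sd, target_counts = target_counts)
}

#' Default gene programmes for a lineage
#'
#' Draws `n_genes` kinetic programmes covering the marker classes the
#' downstream analysis needs: trunk markers, branch-specific markers
#' (neuronal or astrocytic), genes ramping up or down along differentiation,
#' and flat housekeeping genes.  Transcription rates switch at segment
#' boundaries (multiplicative profiles with mild jitter), producing the
#' induction/repression phases the extreme-quantile gamma fit relies on.
#' `beta` is normalised to 1 so the fitted ratio is directly `gamma`;
#' `gamma` is drawn log-uniformly from `[0.1, 2]`.
#'
#' Consumes the current RNG stream; call under a seed for reproducibility.
#'
#' @param lineage A [lineage_spec()].
#' @param n_genes Number of genes (>= 20).
#' @return List of [kinetic_gene_program()] objects.
#' @export
default_gene_programs <- function(lineage, n_genes = 100) {
  stopifnot(inherits(lineage, "lineage_spec"))
  if (n_genes < 20) stop("need at least 20 genes")
  trunk <- lineage$trunk; neu <- lineage$neuronal; ast <- lineage$astro
  segs <- c(trunk, neu, ast)
  nt <- length(trunk); nn <- length(neu); na <- length(ast)
  ramp <- function(n, lo, hi) if (n == 1L) hi else seq(lo, hi, length.out = n)

  profile <- function(class) {
    m <- switch(class,
      trunk = c(ramp(nt, 3, 2), ramp(nn, 0.5, 0.15), ramp(na, 0.5, 0.15)),
      neuronal = c(ramp(nt, 0.2, 0.8), ramp(nn, 2.5, 4), rep(0.1, na)),
      astro = c(ramp(nt, 0.2, 0.8), rep(0.1, nn), ramp(na, 2.5, 4)),
      ramp_up = c(ramp(nt, 0.3, 1.2), ramp(nn, 1.8, 3), ramp(na, 1.8, 3)),
      ramp_down = c(ramp(nt, 3, 1.2), ramp(nn, 0.8, 0.25), ramp(na, 0.8, 0.25)),
      flat = rep(1, nt + nn + na))
    stats::setNames(m, segs)
  }
  classes <- sample(c("trunk", "neuronal", "astro", "ramp_up", "ramp_down", "flat"),
                    n_genes, replace = TRUE,
                    prob = c(0.15, 0.2, 0.2, 0.15, 0.15, 0.15))
  width <- max(3L, floor(log10(n_genes)) + 1L)
  lapply(seq_len(n_genes), function(g) {
    a0 <- stats::runif(1, 0.8, 3)
    jitter <- exp(stats::rnorm(length(segs), 0, 0.15))
    kinetic_gene_program(
      gene_id = sprintf(paste0("gene%0", width, "d"), g),
      alpha_by_segment = a0 * profile(classes[g]) * jitter,
      beta = 1,
      gamma = exp(stats::runif(1, log(0.1), log(2)))
    )
  })
}

# (u, s) state at the start of each segment of a path, carrying the state
# continuously across alpha switches; initial state is the steady state of
# the first segment's alpha.
.segment_starts <- function(program, path, duration) {
  a <- program$alpha_by_segment[path]
  if (anyNA(a)) stop("programme lacks alpha for some path segments")
  L <- length(path)
  u0 <- numeric(L); s0 <- numeric(L)
  u <- a[1] / program$beta
  s <- a[1] / program$gamma
  for (k in seq_len(L)) {
    u0[k] <- u; s0[k] <- s
    st <- solve_kinetics(program, u0 = u, s0 = s, alpha = a[k], tau = duration)
    u <- st$u; s <- st$s
  }
  list(u0 = u0, s0 = s0, alpha = unname(a))
}

#' Simulate a paired spliced/unspliced dataset
#'
#' Draws cells along latent time in `[0, 1]` over the lineage tree, assigns
#' post-branch cells a branch by a Bernoulli draw with the condition's fate
#' bias, evaluates each gene's kinetic means piecewise with
#' [solve_kinetics()] (continuous `(u, s)` across segment boundaries),
#' scales means to the target library size, applies the count-noise model,
#' and embeds cells with the first two principal components of
#' log1p-transformed spliced counts.  Ground-truth labels, branch, animal
#' and latent time are stored in `cell_meta`.
#'
#' @param lineage A [lineage_spec()].
#' @param programs Optional list of [kinetic_gene_program()]; defaults to
#'   [default_gene_programs()] with 100 genes.
#' @param noise A [count_noise()] configuration.
#' @param seed Integer seed; required, the simulation is fully seeded.
#' @return An object of class `su_dataset`: list with `spliced`,
#'   `unspliced` (genes x cells matrices), `cell_meta` (data.frame with
#'   `cell_id`, `condition`, `population`, `animal`, `branch`,
#'   `latent_time`), `embedding` (cells x 2), `gene_meta` (with true
#'   `beta`, `gamma`).
#' @export
simulate_dataset <- function(lineage = lineage_spec(), programs = NULL,
                             noise = count_noise(), seed) {
  stopifnot(inherits(lineage, "lineage_spec"))
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  if (is.null(programs)) programs <- default_gene_programs(lineage)
  if (length(programs) < 20) stop("need at least 20 gene programmes")

  conds <- names(lineage$cells_per_condition)
  paths <- list(neuronal = c(lineage$trunk, lineage$neuronal),
                astro = c(lineage$trunk, lineage$astro))

  meta <- do.call(rbind, lapply(conds, function(cd) {
    n <- lineage$cells_per_condition[[cd]]
    branch <- ifelse(stats::rbinom(n, 1, lineage$fate_bias[[cd]]) == 1,
                     "neuronal", "astro")
    t <- stats::runif(n)
    data.frame(condition = cd, branch = branch, latent_time = t,
               animal = paste0(cd, "-", rep_len(seq_len(
                 lineage$animals_per_condition[[cd]]), n)),
               stringsAsFactors = FALSE)
  }))
  n_cells <- nrow(meta)
  meta$cell_id <- sprintf("cell%05d", seq_len(n_cells))

  # segment index and within-segment time from latent time
  L_by_branch <- vapply(paths, length, integer(1))
  L <- L_by_branch[meta$branch]
  seg <- pmin(floor(meta$latent_time * L) + 1L, L)
  frac <- meta$latent_time * L - (seg - 1L)
  meta$population <- vapply(seq_len(n_cells),
                            function(i) paths[[meta$branch[i]]][seg[i]],
                            character(1))

  D <- lineage$segment_duration
  G <- length(programs)
  U <- matrix(0, G, n_cells)
  S <- matrix(0, G, n_cells)
  groups <- split(seq_len(n_cells), list(meta$branch, seg), drop = TRUE)
  for (g in seq_len(G)) {
    pr <- programs[[g]]
    starts <- lapply(paths, .segment_starts, program = pr, duration = D)
    for (key in names(groups)) {
      idx <- groups[[key]]
      br <- meta$branch[idx[1]]
      k <- seg[idx[1]]
      st <- starts[[br]]
      out <- solve_kinetics(pr, u0 = st$u0[k], s0 = st$s0[k],
                            alpha = st$alpha[k], tau = frac[idx] * D)
      U[g, idx] <- out$u
      S[g, idx] <- out$s
    }
  }

  # scale kinetic means to the target library size
  sf <- noise$target_counts / mean(colSums(S))
  U <- U * sf
  S <- S * sf

  if (noise$model == "poisson") {
    capture <- exp(stats::rnorm(n_cells, 0, noise$capture_sd))
    S <- matrix(stats::rpois(length(S), sweep(S, 2, capture, `*`)), G, n_cells)
    U <- matrix(stats::rpois(length(U), sweep(U, 2, capture, `*`)), G, n_cells)
  }
  gene_ids <- vapply(programs, `[[`, character(1), "gene_id")
  dimnames(U) <- dimnames(S) <- list(gene_ids, meta$cell_id)

  emb <- stats::prcomp(t(log1p(S)), center = TRUE, rank. = 2)$x
  colnames(emb) <- c("dim1", "dim2")
  rownames(emb) <- meta$cell_id

  structure(
    list(spliced = S, unspliced = U,
         cell_meta = meta[, c("cell_id", "condition", "population",
                              "animal", "branch", "latent_time")],
         embedding = emb,
         gene_meta = data.frame(
           gene_id = gene_ids,
           beta = vapply(programs, `[[`, numeric(1), "beta"),
           gamma = vapply(programs, `[[`, numeric(1), "gamma"),
           stringsAsFactors = FALSE),
         lineage = lineage, noise = noise, seed = seed),
    class = "su_dataset"
  )
}

#' @export
print.su_dataset <- function(x, ...) {
  cat(sprintf("<su_dataset> %d genes x %d cells; conditions: %s\n",
              nrow(x$spliced), ncol(x$spliced),
              paste(unique(x$cell_meta$condition), collapse = ", ")))
  invisible(x)
}

#' Subset a dataset to selected cells
#'
#' @param dataset An `su_dataset`.
#' @param cells Logical or integer index over cells.
#' @return An `su_dataset` restricted to those cells (embedding included).
#' @export
subset_cells <- function(dataset, cells) {
  stopifnot(inherits(dataset, "su_dataset"))
  dataset$spliced <- dataset$spliced[, cells, drop = FALSE]
  dataset$unspliced <- dataset$unspliced[, cells, drop = FALSE]
  dataset$cell_meta <- dataset$cell_meta[cells, , drop = FALSE]
  dataset$embedding <- dataset$embedding[cells, , drop = FALSE]
  dataset
}

#' Default dentate-gyrus spatial layout
#'
#' Per-population, per-condition placement distributions over the signed
#' offset from the granule-cell-layer/hilus boundary, in nucleus-width
#' units (positive toward the molecular layer).  Under the injured (TBI)
#' condition the immature neuronal population (N-stage 3) is displaced from
#' the subgranular zone into the granule cell layer and the immature
#' astrocytic population (A-stage 1) into the hilus; stem populations stay
#' put, and A-stage 4 sits in the molecular layer in both conditions.
#'
#' @param gcl_thickness Local granule-cell-layer thickness in nucleus
#'   widths (the tissue is 4-8 nuclei thick).
#' @return data.frame with columns `population`, `condition`,
#'   `mean_offset`, `sd_offset`.
#' @export
default_spatial_layout <- function(gcl_thickness = 6) {
  rows <- rbind(
    data.frame(population = "RG-like",    condition = c("Control", "TBI"),
               mean_offset = c(-1.0, -1.0), sd_offset = 0.6),
    data.frame(population = "NSC-stage 1", condition = c("Control", "TBI"),
               mean_offset = c(-1.0, -1.0), sd_offset = 0.6),
    data.frame(population = "N-stage 3",  condition = c("Control", "TBI"),
               mean_offset = c(-0.8, 1.2), sd_offset = c(0.9, 1.4)),
    data.frame(population = "A-stage 1",  condition = c("Control", "TBI"),
               mean_offset = c(-1.0, -2.4), sd_offset = c(0.8, 1.0)),
    data.frame(population = "A-stage 4",  condition = c("Control", "TBI"),
               mean_offset = gcl_thickness + 0.8, sd_offset = 0.6)
  )
  rows
}

#' Simulate a spatial cell set for a layered tissue
#'
#' Samples per-cell signed offsets from the per-population placement
#' distributions (normal over the offset), assigns animal identifiers
#' round-robin within each condition, and echoes the local layer thickness
#' so zones are derivable downstream with [assign_zone()].
#'
#' @param layout data.frame as from [default_spatial_layout()].
#' @param animals_per_condition Named integer counts; the spatial arm of
#'   the study used 4 Control and 5 TBI animals.
#' @param cells_per_animal Cells sampled per (population, animal).
#' @param gcl_thickness Layer thickness in nucleus widths (>= 4).
#' @param seed Integer seed.
#' @return data.frame of class `spatial_cellset` with columns `cell_id`,
#'   `population`, `condition`, `animal`, `signed_offset`, `gcl_thickness`.
#' @export
simulate_spatial <- function(layout = default_spatial_layout(),
                             animals_per_condition = c(Control = 4, TBI = 5),
                             cells_per_animal = 30,
                             gcl_thickness = 6, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (is.null(names(animals_per_condition)) || any(animals_per_condition < 1))
    stop("'animals_per_condition' must be named counts >= 1")
  if (nrow(layout) == 0) stop("empty layout")
  if (gcl_thickness < 4)
    stop("'gcl_thickness' must be >= 4 nucleus widths")
  layout <- layout[layout$condition %in% names(animals_per_condition), ,
                   drop = FALSE]
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrow(layout)), function(r) {
    row <- layout[r, ]
    n_animals <- animals_per_condition[[row$condition]]
    n <- cells_per_animal * n_animals
    data.frame(population = row$population, condition = row$condition,
               animal = paste0(row$condition, "-",
                               rep_len(seq_len(n_animals), n)),
               signed_offset = stats::rnorm(n, row$mean_offset, row$sd_offset),
               gcl_thickness = gcl_thickness,
               stringsAsFactors = FALSE)
  }))
  out$cell_id <- sprintf("sp%06d", seq_len(nrow(out)))
  out <- out[, c("cell_id", "population", "condition", "animal",
                 "signed_offset", "gcl_thickness")]
  class(out) <- c("spatial_cellset", "data.frame")
  out
}
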