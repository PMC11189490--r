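#' Pipeline run configuration
#'
#' Collects every stage toggle and module parameter in one validated list.
#' Velocity and transition models are fitted for each condition
#' separately, with gene filters computed independently per condition.
#'
#' @param seed Integer seed (required when the simulate stage is enabled).
#' @param stages Character subset of
#'   `c("simulate", "velocity", "transitions", "enrich", "spatial")`.
#' @param lineage A [lineage_spec()] for the simulate stage.
#' @param n_genes Genes simulated by the default programmes.
#' @param noise A [count_noise()].
#' @param velocity A [velocity_config()].
#' @param sigma Transition-kernel bandwidth.
#' @param min_neighborhood Neighbourhood floor for transition models.
#' @param scale Correlation transform (`"sqrt"` or `"none"`).
#' @param exclude_populations Populations removed before transition
#'   modelling (terminal clusters not derived from the lineage).
#' @param min_cells Minimum source cells per condition for a transition
#'   comparison.
#' @param p0 `"auto"` (computed from the analysed cells) or a numeric
#'   expected fraction for enrichment.
#' @param keywords Keyword panel for term filtering.
#' @param spatial_layout Layout data.frame for [simulate_spatial()].
#' @param spatial_animals Named animal counts per condition.
#' @param cells_per_animal Spatial cells per (population, animal).
#' @param gcl_thickness Layer thickness in nucleus widths.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       stages = c("simulate", "velocity", "transitions",
                                  "enrich", "spatial"),
                       lineage = lineage_spec(),
                       n_genes = 100,
                       noise = count_noise(),
                       velocity = velocity_config(),
                       sigma = 0.05,
                       min_neighborhood = 300,
                       scale = "sqrt",
                       exclude_populations = character(),
                       min_cells = 3,
                       p0 = "auto",
                       keywords = default_keywords(),
                       spatial_layout = default_spatial_layout(),
                       spatial_animals = c(Control = 4, TBI = 5),
                       cells_per_animal = 30,
                       gcl_thickness = 6) {
  stages <- match.arg(stages, several.ok = TRUE)
  if ("simulate" %in% stages && (missing(seed) || is.null(seed)))
    stop("'seed' must be set whenever simulation is enabled")
  if (is.numeric(p0) && (p0 <= 0 || p0 >= 1))
    stop("numeric 'p0' must lie strictly inside (0, 1)")
  stopifnot(sigma > 0, min_neighborhood >= 1)
  structure(list(seed = as.integer(seed), stages = stages, lineage = lineage,
                 n_genes = n_genes, noise = noise, velocity = velocity,
                 sigma = sigma, min_neighborhood = min_neighborhood,
                 scale = scale, exclude_populations = exclude_populations,
                 min_cells = min_cells, p0 = p0, keywords = keywords,
                 spatial_layout = spatial_layout,
                 spatial_animals = spatial_animals,
                 cells_per_animal = cells_per_animal,
                 gcl_thickness = gcl_thickness),
            class = "run_config")
}

.cfg_echo <- function(config) {
  list(seed = config$seed, stages = config$stages,
       n_genes = config$n_genes,
       fate_bias = as.list(config$lineage$fate_bias),
       cells_per_condition = as.list(config$lineage$cells_per_condition),
       noise = config$noise,
       velocity = config$velocity[c("k_cells", "fit_quantile",
                                    "spliced_average_min", "delta_t",
                                    "n_pcs")],
       excluded_genes = config$velocity$excluded_genes,
       sigma = config$sigma, min_neighborhood = config$min_neighborhood,
       scale = config$scale,
       exclude_populations = config$exclude_populations,
       min_cells = config$min_cells, p0 = config$p0,
       gcl_thickness = config$gcl_thickness)
}

# velocity + transition summary for one condition's cells
.condition_transitions <- function(dataset, cond, config) {
  idx <- dataset$cell_meta$condition == cond
  sub <- subset_cells(dataset, idx)
  vr <- run_velocity(sub, config$velocity)
  tr <- population_transitions(
    embedding = sub$embedding, current = vr$current, deltaE = vr$deltaE,
    labels = sub$cell_meta$population, condition = cond,
    sigma = config$sigma, minimum = config$min_neighborhood,
    scale = config$scale, cell_ids = sub$cell_meta$cell_id,
    exclude_populations = config$exclude_populations)
  list(velocity = vr, transitions = tr)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order (simulate -> velocity
#' -> transitions -> enrich; spatial is independent), writes each stage's
#' outputs plus a run manifest with a config echo, the seed and md5
#' checksums of every file.  Reruns with an identical config and seed
#' produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param dry_run If `TRUE`, print the planned stages and write nothing.
#' @return The manifest list, invisibly (or the stage plan on a dry run).
#' @export
run_pipeline <- function(config = run_config(), out_dir, dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  order_all <- c("simulate", "velocity", "transitions", "enrich", "spatial")
  plan <- order_all[order_all %in% config$stages]
  if (dry_run) {
    message("planned stages: ", paste(plan, collapse = " -> "))
    return(invisible(plan))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list()

  for (stage in plan) {
    message("stage: ", stage)
    switch(stage,
      simulate = {
        lineage <- config$lineage
        set.seed(config$seed)
        programs <- default_gene_programs(lineage, config$n_genes)
        state$dataset <- simulate_dataset(lineage, programs, config$noise,
                                          seed = config$seed)
        write_dataset(state$dataset, file.path(out_dir, "sim"))
        state$spatial <- simulate_spatial(
          config$spatial_layout, config$spatial_animals,
          config$cells_per_animal, config$gcl_thickness,
          seed = config$seed)
        write_spatial(state$spatial, file.path(out_dir, "spatial.tsv"))
      },
      velocity = {
        if (is.null(state$dataset)) {
          simdir <- file.path(out_dir, "sim")
          if (!file.exists(file.path(simdir, "spliced.mtx")))
            stop("velocity stage needs a dataset: run the 'simulate' stage first")
          state$dataset <- read_dataset(simdir)
        }
        conds <- sort(unique(state$dataset$cell_meta$condition))
        state$per_condition <- lapply(stats::setNames(conds, conds),
                                      function(cd)
          .condition_transitions(state$dataset, cd, config))
        vdir <- file.path(out_dir, "velocity")
        dir.create(vdir, showWarnings = FALSE)
        for (cd in conds) {
          vr <- state$per_condition[[cd]]$velocity
          .write_tsv(data.frame(gene_id = names(vr$gamma_hat),
                                gamma = unname(vr$gamma_hat)),
                     file.path(vdir, paste0("gamma_", cd, ".tsv")))
          Matrix::writeMM(Matrix::Matrix(vr$velocity, sparse = TRUE),
                          file.path(vdir, paste0("velocity_", cd, ".mtx")))
          Matrix::writeMM(Matrix::Matrix(vr$current, sparse = TRUE),
                          file.path(vdir, paste0("current_", cd, ".mtx")))
        }
      },
      transitions = {
        if (is.null(state$per_condition))
          stop("transitions stage needs velocity results: run the 'velocity' stage first")
        trans <- do.call(rbind, lapply(state$per_condition,
                                       `[[`, "transitions"))
        rownames(trans) <- NULL
        state$comparison <- compare_conditions(trans,
                                               min_cells = config$min_cells)
        tdir <- file.path(out_dir, "transitions")
        dir.create(tdir, showWarnings = FALSE)
        .write_tsv(trans, file.path(tdir, "transition_mass.tsv"))
        .write_tsv(state$comparison, file.path(tdir, "comparisons.tsv"))
        jsonlite::write_json(state$comparison,
                             file.path(tdir, "comparisons.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA,
                             na = "null")
      },
      enrich = {
        if (is.null(state$dataset)) {
          simdir <- file.path(out_dir, "sim")
          if (!file.exists(file.path(simdir, "cells.tsv")))
            stop("enrich stage needs cell metadata: run the 'simulate' stage first")
          state$dataset <- read_dataset(simdir)
        }
        tab <- composition_table(state$dataset$cell_meta)
        p0 <- if (identical(config$p0, "auto")) NULL else config$p0
        state$enrichment <- binomial_enrichment(tab, p0 = p0)
        .write_tsv(state$enrichment, file.path(out_dir, "enrichment.tsv"))
      },
      spatial = {
        if (is.null(state$spatial)) {
          sp <- file.path(out_dir, "spatial.tsv")
          if (!file.exists(sp))
            stop("spatial stage needs spatial.tsv: run the 'simulate' stage first")
          state$spatial <- read_spatial(sp)
        }
        zones <- assign_zone(state$spatial)
        comp <- zone_composition(zones)
        tests <- compare_locations(comp)
        .write_tsv(zones, file.path(out_dir, "zones.tsv"))
        .write_tsv(comp, file.path(out_dir, "composition.tsv"))
        jsonlite::write_json(tests, file.path(out_dir, "location_tests.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA,
                             na = "null")
      })
  }

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "run_manifest.json"]
  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- sub(paste0("^", out_dir, "/?"), "", names(checksums))
  manifest <- list(config = .cfg_echo(config), stages_run = plan,
                   package_version = as.character(
                     utils::packageVersion("velofate")),
                   checksums = checksums)
  .write_manifest(manifest, file.path(out_dir, "run_manifest.json"))
  invisible(manifest)
}

#' Validate an on-disk dataset layout
#'
#' Checks the MatrixMarket headers, dimension agreement across
#' spliced/unspliced/metadata, label completeness, and that at least two
#' conditions are present.  Failures are collected into the report, not
#' raised.
#'
#' @param dir Directory in the [write_dataset()] layout.
#' @return List with `ok` (logical) and `failures` (character vector).
#' @export
validate_inputs <- function(dir) {
  failures <- character()
  need <- c("spliced.mtx", "unspliced.mtx", "genes.tsv", "cells.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    return(list(ok = FALSE,
                failures = paste("missing file:", missing)))
  }
  hdr_ok <- function(f) {
    first <- readLines(file.path(dir, f), n = 1)
    grepl("^%%MatrixMarket matrix coordinate", first)
  }
  for (f in c("spliced.mtx", "unspliced.mtx"))
    if (!hdr_ok(f)) failures <- c(failures,
                                  paste("bad MatrixMarket header:", f))
  S <- try(Matrix::readMM(file.path(dir, "spliced.mtx")), silent = TRUE)
  U <- try(Matrix::readMM(file.path(dir, "unspliced.mtx")), silent = TRUE)
  cells <- .read_tsv(file.path(dir, "cells.tsv"))
  genes <- .read_tsv(file.path(dir, "genes.tsv"))
  if (!inherits(S, "try-error") && !inherits(U, "try-error")) {
    if (!all(dim(S) == dim(U)))
      failures <- c(failures, "spliced/unspliced dimension mismatch")
    if (ncol(S) != nrow(cells))
      failures <- c(failures,
                    "matrix columns do not match cells.tsv rows")
    if (nrow(S) != nrow(genes))
      failures <- c(failures, "matrix rows do not match genes.tsv rows")
    if (any(S@x < 0) || any(U@x < 0))
      failures <- c(failures, "negative counts")
  }
  for (col in c("cell_id", "condition", "population"))
    if (!col %in% names(cells) || anyNA(cells[[col]]))
      failures <- c(failures, paste("cells.tsv column incomplete:", col))
  if ("condition" %in% names(cells) &&
      length(unique(cells$condition)) < 2)
    failures <- c(failures, "fewer than two conditions present")
  list(ok = length(failures) == 0, failures = failures)
}
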