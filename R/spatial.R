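#' Assign dentate-gyrus zones from signed offsets
#'
#' The tissue geometry is abstracted to a signed offset `d` from the
#' granule-cell-layer/hilus boundary in nucleus-width units (positive
#' toward the molecular layer), with local layer thickness `T`.  Bands are
#' left-closed/right-open:
#' Hilus `d < -2`; SGZ `-2 <= d < 0` (the two-nucleus band below the
#' layer); GL1 `0 <= d < T - 3`; GL2 `T - 3 <= d < T` (the three-nucleus
#' band below the molecular layer); ML `d >= T`.  `T` must be at least 4
#' nucleus widths (the layer is 4-8 nuclei thick), so GL1 is never empty.
#'
#' @param cells data.frame with `signed_offset` and `gcl_thickness`
#'   columns (e.g. from [simulate_spatial()]).
#' @return The input with a `zone` factor column (levels Hilus, SGZ, GL1,
#'   GL2, ML) appended.
#' @export
assign_zone <- function(cells) {
  d <- cells$signed_offset
  T_ <- cells$gcl_thickness
  if (any(!is.finite(d))) stop("'signed_offset' must be finite")
  if (any(T_ < 4)) stop("'gcl_thickness' must be >= 4 nucleus widths")
  zone <- ifelse(d < -2, "Hilus",
          ifelse(d < 0, "SGZ",
          ifelse(d < T_ - 3, "GL1",
          ifelse(d < T_, "GL2", "ML"))))
  cells$zone <- factor(zone, levels = c("Hilus", "SGZ", "GL1", "GL2", "ML"))
  cells
}

#' Per-animal zone composition of each population
#'
#' For each (animal, population), the percentage of that population's
#' cells in each zone (summing to 100), plus an aggregate `GL` row
#' (GL1 + GL2), reported alongside the zones as in the original
#' quantification.  Populations absent in an animal are simply not
#' represented for that animal (not zero-imputed).
#'
#' @param cells Zone-assigned data.frame from [assign_zone()] carrying
#'   `animal`, `population`, `condition` columns.
#' @return Long data.frame: `animal`, `condition`, `population`, `zone`,
#'   `n_cells`, `pct`, `aggregate` (TRUE for the GL rows).
#' @export
zone_composition <- function(cells) {
  need <- c("animal", "population", "condition", "zone")
  if (!all(need %in% names(cells)))
    stop("'cells' needs animal, population, condition and zone columns")
  zones <- levels(cells$zone)
  groups <- split(cells, list(cells$animal, cells$population), drop = TRUE)
  rows <- lapply(groups, function(g) {
    counts <- table(factor(g$zone, levels = zones))
    total <- sum(counts)
    base <- data.frame(animal = g$animal[1], condition = g$condition[1],
                       population = g$population[1],
                       zone = zones, n_cells = as.integer(counts),
                       pct = 100 * as.integer(counts) / total,
                       aggregate = FALSE, stringsAsFactors = FALSE)
    gl <- sum(counts[c("GL1", "GL2")])
    rbind(base, data.frame(animal = g$animal[1], condition = g$condition[1],
                           population = g$population[1], zone = "GL",
                           n_cells = as.integer(gl), pct = 100 * gl / total,
                           aggregate = TRUE, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled-variance unpaired t-test (two-sided)
#'
#' Classic two-sample t statistic with pooled variance and
#' df = n_x + n_y - 2.  Degenerate inputs (zero pooled variance) give
#' p = 1 when the means agree and p = 0 (flagged) when they differ.
#'
#' @param x,y Numeric samples with at least two values each.
#' @return List with `statistic`, `df`, `p.value`, `degenerate`.
#' @export
t_test_unpaired <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("both samples need at least two values")
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  dm <- mean(x) - mean(y)
  if (sp2 == 0) {
    return(list(statistic = if (dm == 0) 0 else sign(dm) * Inf, df = df,
                p.value = if (dm == 0) 1 else 0, degenerate = TRUE))
  }
  t <- dm / sqrt(sp2 * (1 / nx + 1 / ny))
  list(statistic = t, df = df, p.value = 2 * stats::pt(-abs(t), df),
       degenerate = FALSE)
}

#' Compare per-animal zone percentages between conditions
#'
#' For each (population, zone) pair (the GL aggregate included), runs a
#' two-tailed unpaired t-test on the per-animal zone percentages of the
#' two conditions, reporting means and SEM per condition.  Pairs with
#' fewer than two animals in a condition are skipped and listed in
#' `attr(, "skipped")`.
#'
#' @param composition Output of [zone_composition()].
#' @param conditions Length-2 ordering of the comparison; defaults to the
#'   sorted condition names.
#' @return data.frame: `population`, `zone`, per-condition n, mean, sem,
#'   `statistic`, `df`, `p_value`.
#' @export
compare_locations <- function(composition, conditions = NULL) {
  if (is.null(conditions))
    conditions <- sort(unique(composition$condition))
  if (length(conditions) != 2) stop("exactly two conditions are required")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  pairs <- unique(composition[, c("population", "zone")])
  skipped <- character()
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sub <- composition[composition$population == pairs$population[i] &
                       composition$zone == pairs$zone[i], ]
    x <- sub$pct[sub$condition == conditions[1]]
    y <- sub$pct[sub$condition == conditions[2]]
    if (length(x) < 2 || length(y) < 2) {
      skipped <<- c(skipped,
                    paste(pairs$population[i], pairs$zone[i], sep = "/"))
      return(NULL)
    }
    tt <- t_test_unpaired(x, y)
    data.frame(population = pairs$population[i], zone = pairs$zone[i],
               n_x = length(x), n_y = length(y),
               mean_x = mean(x), sem_x = sem(x),
               mean_y = mean(y), sem_y = sem(y),
               statistic = tt$statistic, df = tt$df, p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(population = character(), zone = character(),
                      n_x = integer(), n_y = integer(),
                      mean_x = numeric(), sem_x = numeric(),
                      mean_y = numeric(), sem_y = numeric(),
                      statistic = numeric(), df = numeric(),
                      p_value = numeric())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "conditions") <- conditions
  out
}
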