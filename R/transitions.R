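#' Signed square root
#'
#' Elementwise sign(x) * sqrt(|x|); the variance-stabilising transform
#' applied to expression differences and velocities before correlating
#' them.
#'
#' @param x Numeric vector or matrix.
#' @return Same shape as `x`.
#' @export
signed_sqrt <- function(x) sign(x) * sqrt(abs(x))

#' Embedding nearest neighbours
#'
#' For each cell, its `n` nearest cells in embedding space (Euclidean,
#' self excluded, ties broken by index).
#'
#' @param embedding Cells x 2 (or more) coordinate matrix.
#' @param n Neighbourhood size, between 1 and cells - 1.
#' @return Integer matrix, cells x n.
#' @export
embedding_neighbors <- function(embedding, n) {
  n_cells <- nrow(embedding)
  if (n_cells <= 1) stop("need at least two cells")
  if (n < 1 || n > n_cells - 1)
    stop("'n' must lie between 1 and cells - 1")
  .knn_indices(embedding, n, include_self = FALSE)
}

# Pearson correlation of each column of `m` with vector `v`; zero-variance
# columns (or zero-variance v) give 0 instead of NA
.safe_cor <- function(m, v) {
  vc <- v - mean(v)
  sv <- sum(vc^2)
  mc <- sweep(m, 2, colMeans(m))
  den <- sqrt(colSums(mc^2) * sv)
  num <- as.vector(crossprod(mc, vc))
  out <- ifelse(den > 0, num / den, 0)
  pmin(pmax(out, -1), 1)
}

#' Velocity-correlation matrix over neighbour pairs
#'
#' cc\[i, j\] is the Pearson correlation across genes between the
#' (optionally signed-sqrt-transformed) expression displacement from cell
#' `i` to its neighbour `j` (`current[, j] - current[, i]`) and cell `i`'s
#' extrapolated expression change `deltaE[, i]`.  A correlation of 1 means
#' the velocity points exactly at the neighbour.  Undefined correlations
#' (zero variance) are set to 0.
#'
#' @param current,deltaE Genes x cells matrices from the velocity stage.
#' @param neighbors Integer matrix from [embedding_neighbors()].
#' @param scale `"sqrt"` (signed square root of both vectors) or `"none"`.
#' @return Numeric matrix, cells x n, aligned with `neighbors`;
#'   entries lie in `[-1, 1]`.
#' @export
velocity_correlation <- function(current, deltaE, neighbors,
                                 scale = c("sqrt", "none")) {
  scale <- match.arg(scale)
  n_cells <- ncol(current)
  stopifnot(nrow(neighbors) == n_cells, ncol(deltaE) == n_cells)
  v_all <- if (scale == "sqrt") signed_sqrt(deltaE) else deltaE
  cc <- matrix(0, n_cells, ncol(neighbors))
  for (i in seq_len(n_cells)) {
    d <- current[, neighbors[i, ], drop = FALSE] - current[, i]
    if (scale == "sqrt") d <- signed_sqrt(d)
    cc[i, ] <- .safe_cor(d, v_all[, i])
  }
  cc
}

#' Transition probabilities from velocity correlations
#'
#' Row-wise exponential kernel over each cell's neighbour set:
#' tp\[i, j\] = exp(cc\[i, j\] / sigma) normalised over the neighbours of
#' `i`, computed with a max-shift for numerical stability.  Probabilities
#' are zero outside the neighbour set and each row sums to one.
#'
#' @param cc Correlation matrix from [velocity_correlation()].
#' @param sigma Kernel bandwidth, > 0 (default 0.05, the estimator's
#'   conventional setting).
#' @return Matrix of the same shape as `cc`, rows summing to 1.
#' @export
transition_probabilities <- function(cc, sigma = 0.05) {
  if (sigma <= 0) stop("'sigma' must be positive")
  shift <- apply(cc, 1, max)
  e <- exp((cc - shift) / sigma)
  e / rowSums(e)
}

#' Per-cell transition mass to each population
#'
#' For source cell `i` and target population `P`, the mass
#' m_i(P) = sum over neighbours `j` of `i` with label(j) = P of tp\[i, j\]
#' (mode `"sum"`).  Mode `"mean"` instead averages the per-neighbour
#' probabilities within each population.  Masses over populations
#' partition each row of `tp` exactly, so per cell they sum to 1 in mode
#' `"sum"`.  A population's mass to its own label is its population-level
#' self-renewal (retention of state identity).
#'
#' @param tp Transition-probability matrix from
#'   [transition_probabilities()].
#' @param neighbors Integer neighbour matrix aligned with `tp`.
#' @param labels Population label per cell (length = number of cells).
#' @param mode `"sum"` (default) or `"mean"`.
#' @return Cells x populations matrix with population colnames.
#' @export
population_mass <- function(tp, neighbors, labels, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (anyNA(labels)) stop("every cell must be labelled")
  stopifnot(length(labels) == nrow(tp))
  pops <- sort(unique(labels))
  lab_nb <- matrix(labels[neighbors], nrow = nrow(neighbors))
  out <- vapply(pops, function(p) {
    hit <- lab_nb == p
    m <- rowSums(tp * hit)
    if (mode == "mean") {
      cnt <- rowSums(hit)
      m <- ifelse(cnt > 0, m / cnt, NA_real_)
    }
    m
  }, numeric(nrow(tp)))
  colnames(out) <- pops
  out
}

#' Neighbourhood size for a source population
#'
#' n = max(minimum, population size), capped at cells - 1; the analysis
#' uses a floor of 300 cells so small populations still see a stable
#' neighbourhood.
#'
#' @param labels Population label per cell.
#' @param population Source population.
#' @param minimum Neighbourhood floor (default 300).
#' @return Integer neighbourhood size.
#' @export
choose_neighborhood <- function(labels, population, minimum = 300) {
  n_cells <- length(labels)
  if (n_cells <= 1) stop("need at least two cells")
  as.integer(min(max(minimum, sum(labels == population)), n_cells - 1L))
}

#' Per-population transition-mass summary for one condition
#'
#' For every source population, builds embedding neighbour sets of size
#' [choose_neighborhood()] (models with the same size are computed once and
#' shared), computes the velocity-correlation and transition-probability
#' matrices, and sums each source cell's transition mass per target
#' population.
#'
#' @param embedding Cells x 2 embedding of this condition's cells.
#' @param current,deltaE Kept-genes x cells matrices from [run_velocity()].
#' @param labels Population label per cell.
#' @param condition Condition tag attached to the output rows.
#' @param sigma Kernel bandwidth.
#' @param minimum Neighbourhood floor.
#' @param scale Correlation transform, `"sqrt"` or `"none"`.
#' @param mass_mode Passed to [population_mass()].
#' @param cell_ids Optional cell identifiers.
#' @param exclude_populations Labels removed before modelling (e.g.
#'   terminal clusters not derived from the lineage under study).
#' @return data.frame of class `population_transitions`: one row per
#'   (source cell, target population) with columns `cell_id`, `condition`,
#'   `source`, `target`, `mass`; neighbourhood sizes used are recorded in
#'   `attr(, "n_used")`.
#' @export
population_transitions <- function(embedding, current, deltaE, labels,
                                   condition = NA_character_,
                                   sigma = 0.05, minimum = 300,
                                   scale = "sqrt", mass_mode = "sum",
                                   cell_ids = NULL,
                                   exclude_populations = character()) {
  keep <- !(labels %in% exclude_populations)
  if (!all(keep)) {
    embedding <- embedding[keep, , drop = FALSE]
    current <- current[, keep, drop = FALSE]
    deltaE <- deltaE[, keep, drop = FALSE]
    if (!is.null(cell_ids)) cell_ids <- cell_ids[keep]
    labels <- labels[keep]
  }
  n_cells <- length(labels)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  pops <- sort(unique(labels))
  n_by_pop <- vapply(pops, function(p)
    choose_neighborhood(labels, p, minimum), integer(1))

  cache <- list()
  rows <- vector("list", length(pops))
  for (k in seq_along(pops)) {
    p <- pops[k]
    key <- as.character(n_by_pop[[p]])
    if (is.null(cache[[key]])) {
      nb <- embedding_neighbors(embedding, n_by_pop[[p]])
      cc <- velocity_correlation(current, deltaE, nb, scale = scale)
      tp <- transition_probabilities(cc, sigma = sigma)
      cache[[key]] <- population_mass(tp, nb, labels, mode = mass_mode)
    }
    mass <- cache[[key]]
    src <- which(labels == p)
    rows[[k]] <- data.frame(
      cell_id = rep(cell_ids[src], times = ncol(mass)),
      condition = condition,
      source = p,
      target = rep(colnames(mass), each = length(src)),
      mass = as.vector(mass[src, , drop = FALSE]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_used") <- n_by_pop
  attr(out, "sigma") <- sigma
  class(out) <- c("population_transitions", "data.frame")
  out
}

#' Wilcoxon rank-sum test (two-sided, midranks for ties)
#'
#' Exact mode enumerates all assignments of the pooled midranks to the two
#' groups and reports the probability of a rank sum at least as far from
#' its null mean as observed; it is used automatically when the pooled
#' sample size is at most `exact_limit`.  Otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param exact_limit Pooled-size ceiling for automatic exact enumeration.
#' @return List with `statistic` (Mann-Whitney U for `x`), `rank_sum`,
#'   `p.value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal"),
                              exact_limit = 20) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (mode == "auto") mode <- if (n <= exact_limit) "exact" else "normal"

  if (mode == "exact") {
    combos <- utils::combn(n, nx)
    w_all <- colSums(matrix(r[combos], nrow = nx))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    tie <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations tied
    } else {
      z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(statistic = w_obs - nx * (nx + 1) / 2, rank_sum = w_obs,
       p.value = p, method = mode)
}

#' Compare per-cell transition masses between conditions
#'
#' For every (source, target) population pair present in the pooled
#' summaries, runs a two-sided Wilcoxon rank-sum test on the per-cell
#' transition masses of the two conditions and reports box-plot summaries
#' (median, quartiles, and whiskers as data minima/maxima) per condition.
#' Pairs with fewer than `min_cells` source cells in either condition are
#' reported as not comparable rather than raising an error.  Raw p-values
#' are the primary readout; a Benjamini-Hochberg column is emitted
#' alongside for convenience.
#'
#' @param transitions A `population_transitions` data.frame covering both
#'   conditions (rbind of per-condition summaries).
#' @param conditions Length-2 character vector ordering the comparison
#'   (x vs y); defaults to the sorted condition names found.
#' @param min_cells Minimum source cells per condition for a pair to be
#'   tested.
#' @param exact_limit Passed to [wilcoxon_rank_sum()].
#' @return data.frame with one row per (source, target) pair.
#' @export
compare_conditions <- function(transitions, conditions = NULL, min_cells = 3,
                               exact_limit = 20) {
  if (is.null(conditions))
    conditions <- sort(unique(transitions$condition))
  if (length(conditions) != 2) stop("exactly two conditions are required")
  qs <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    c(median = q[2], q1 = q[1], q3 = q[3], min = min(v), max = max(v),
      mean = mean(v))
  }
  pairs <- unique(transitions[, c("source", "target")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sub <- transitions[transitions$source == pairs$source[i] &
                       transitions$target == pairs$target[i], ]
    x <- sub$mass[sub$condition == conditions[1]]
    y <- sub$mass[sub$condition == conditions[2]]
    base <- data.frame(source = pairs$source[i], target = pairs$target[i],
                       n_x = length(x), n_y = length(y),
                       stringsAsFactors = FALSE)
    if (length(x) < min_cells || length(y) < min_cells) {
      cbind(base, data.frame(comparable = FALSE,
                             mean_x = NA_real_, median_x = NA_real_,
                             q1_x = NA_real_, q3_x = NA_real_,
                             min_x = NA_real_, max_x = NA_real_,
                             mean_y = NA_real_, median_y = NA_real_,
                             q1_y = NA_real_, q3_y = NA_real_,
                             min_y = NA_real_, max_y = NA_real_,
                             statistic = NA_real_, p_value = NA_real_))
    } else {
      wt <- wilcoxon_rank_sum(x, y, exact_limit = exact_limit)
      sx <- qs(x); sy <- qs(y)
      cbind(base, data.frame(comparable = TRUE,
                             mean_x = sx["mean"], median_x = sx["median"],
                             q1_x = sx["q1"], q3_x = sx["q3"],
                             min_x = sx["min"], max_x = sx["max"],
                             mean_y = sy["mean"], median_y = sy["median"],
                             q1_y = sy["q1"], q3_y = sy["q3"],
                             min_y = sy["min"], max_y = sy["max"],
                             statistic = wt$statistic, p_value = wt$p.value))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjust <- NA_real_
  ok <- out$comparable
  out$p_adjust[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  attr(out, "conditions") <- conditions
  out
}
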