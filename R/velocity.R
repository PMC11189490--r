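#' Configuration for steady-state velocity estimation
#'
#' Defaults follow the estimator's conventional settings: pooling over 20
#' nearest cells, gamma fitted on the extreme 2% expression quantiles,
#' genes kept when their mean pooled spliced expression reaches 0.5, a unit
#' extrapolation horizon, and Malat1 excluded (a nuclear-retained lncRNA
#' whose spliced/unspliced ratio is uninformative).
#'
#' @param k_cells Pooling neighbourhood size (self included).
#' @param fit_quantile Extreme-quantile fraction in (0, 0.5).
#' @param spliced_average_min Gene filter threshold on mean pooled spliced
#'   expression.
#' @param delta_t Extrapolation horizon.
#' @param excluded_genes Identifiers always removed from the panel.
#' @param n_pcs Number of principal components for the pooling space.
#' @export
velocity_config <- function(k_cells = 20, fit_quantile = 0.02,
                            spliced_average_min = 0.5, delta_t = 1,
                            excluded_genes = "Malat1", n_pcs = 30) {
  stopifnot(k_cells >= 1, fit_quantile > 0, fit_quantile < 0.5,
            spliced_average_min >= 0, delta_t > 0, n_pcs >= 1)
  list(k_cells = as.integer(k_cells), fit_quantile = fit_quantile,
       spliced_average_min = spliced_average_min, delta_t = delta_t,
       excluded_genes = excluded_genes, n_pcs = as.integer(n_pcs))
}

# top-PC coordinates of log1p library-size-normalized spliced counts;
# the conventional metric space for expression-neighbour pooling
.pooling_space <- function(spliced, n_pcs) {
  sf <- colSums(spliced)
  sf[sf == 0] <- 1
  x <- log1p(sweep(spliced, 2, sf / mean(sf), `/`))
  rank <- min(n_pcs, ncol(x) - 1L, nrow(x))
  stats::prcomp(t(x), center = TRUE, rank. = rank)$x
}

# k nearest rows of `coords` per row (Euclidean); self included when
# include_self, ties broken by row index for determinism
.knn_indices <- function(coords, k, include_self = TRUE) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  if (!include_self) diag(d) <- Inf
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

#' Pool spliced/unspliced profiles over expression neighbours
#'
#' Each cell's pooled profile is the mean of the raw profiles over its
#' `k_cells` nearest neighbours (self included) in the top-principal-
#' component space of log1p library-size-normalised spliced counts.
#'
#' @param spliced,unspliced Genes x cells matrices.
#' @param k_cells Neighbourhood size; must not exceed the cell count.
#' @param n_pcs Principal components used for the neighbour metric.
#' @return List with pooled `spliced`, `unspliced` and the integer
#'   `neighbors` matrix (cells x k).
#' @export
pool_neighbors <- function(spliced, unspliced, k_cells = 20, n_pcs = 30) {
  n <- ncol(spliced)
  stopifnot(ncol(unspliced) == n, nrow(unspliced) == nrow(spliced))
  if (k_cells > n) stop("'k_cells' exceeds the number of cells")
  if (k_cells == 1) {
    return(list(spliced = spliced, unspliced = unspliced,
                neighbors = matrix(seq_len(n), ncol = 1)))
  }
  nb <- .knn_indices(.pooling_space(spliced, n_pcs), k_cells)
  A <- Matrix::sparseMatrix(i = as.vector(t(nb)),
                            j = rep(seq_len(n), each = k_cells),
                            x = 1 / k_cells, dims = c(n, n))
  ps <- as.matrix(spliced %*% A)
  pu <- as.matrix(unspliced %*% A)
  dimnames(ps) <- dimnames(pu) <- dimnames(spliced)
  list(spliced = ps, unspliced = pu, neighbors = nb)
}

#' Filter the gene panel on pooled expression
#'
#' Keeps genes whose mean pooled spliced expression is at least
#' `spliced_average_min` and which are not explicitly excluded.
#'
#' @param pooled_spliced Genes x cells matrix with gene rownames.
#' @param spliced_average_min Threshold on the row mean.
#' @param excluded_genes Identifiers dropped regardless of expression.
#' @return Character vector of kept gene identifiers.
#' @export
filter_genes <- function(pooled_spliced, spliced_average_min = 0.5,
                         excluded_genes = "Malat1") {
  ids <- rownames(pooled_spliced)
  if (is.null(ids)) stop("'pooled_spliced' needs gene rownames")
  keep <- rowMeans(pooled_spliced) >= spliced_average_min &
    !(ids %in% excluded_genes)
  if (!any(keep))
    stop("all genes filtered out: empty panel (lower 'spliced_average_min')")
  ids[keep]
}

#' Fit per-gene degradation/splicing ratio on extreme quantiles
#'
#' For each gene, the extreme set is the union of cells whose pooled
#' spliced expression falls in the bottom `fit_quantile` or top
#' `1 - fit_quantile` quantiles (all tied cells included); these cells are
#' assumed near steady state, where u = gamma * s.  gamma is the
#' least-squares slope through the origin of unspliced on spliced over that
#' set: sum(u*s) / sum(s^2).
#'
#' @param pooled_spliced,pooled_unspliced Genes x cells matrices (or
#'   single-gene numeric vectors).
#' @param fit_quantile Extreme-quantile fraction.
#' @return Named numeric vector of gamma estimates; genes with an undefined
#'   slope (all-zero spliced on the extreme set, or fewer than two extreme
#'   cells) are `NA` and listed in `attr(, "flagged")`.
#' @export
fit_gamma <- function(pooled_spliced, pooled_unspliced, fit_quantile = 0.02) {
  stopifnot(fit_quantile > 0, fit_quantile < 0.5)
  if (is.null(dim(pooled_spliced))) {
    pooled_spliced <- matrix(pooled_spliced, nrow = 1,
                             dimnames = list("gene", NULL))
    pooled_unspliced <- matrix(pooled_unspliced, nrow = 1)
  }
  G <- nrow(pooled_spliced)
  out <- numeric(G)
  for (g in seq_len(G)) {
    s <- pooled_spliced[g, ]
    u <- pooled_unspliced[g, ]
    q <- stats::quantile(s, c(fit_quantile, 1 - fit_quantile), names = FALSE)
    ext <- s <= q[1] | s >= q[2]
    ss <- sum(s[ext]^2)
    out[g] <- if (sum(ext) < 2 || ss == 0) NA_real_ else
      sum(u[ext] * s[ext]) / ss
  }
  names(out) <- rownames(pooled_spliced)
  attr(out, "flagged") <- names(out)[is.na(out)]
  out
}

#' Residual velocity and expression extrapolation
#'
#' velocity\[g, c\] = pooled_unspliced\[g, c\] - gamma\[g\] *
#' pooled_spliced\[g, c\]; a cell at its gene's steady state has velocity
#' zero, and unspliced excess above the gamma-line means rising expression.
#' `deltaE = delta_t * velocity`; `current` is the pooled spliced matrix;
#' the extrapolated expression `max(current + deltaE, 0)` is never
#' negative.
#'
#' @param pooled_spliced,pooled_unspliced Genes x cells matrices restricted
#'   to the kept genes.
#' @param gamma_hat Named gamma vector covering every kept gene.
#' @param delta_t Extrapolation horizon.
#' @return List with `velocity`, `deltaE`, `current`, `extrapolated`.
#' @export
compute_velocity <- function(pooled_spliced, pooled_unspliced, gamma_hat,
                             delta_t = 1) {
  ids <- rownames(pooled_spliced)
  if (!all(ids %in% names(gamma_hat)) || anyNA(gamma_hat[ids]))
    stop("missing gamma estimate for a kept gene")
  vel <- pooled_unspliced - gamma_hat[ids] * pooled_spliced
  deltaE <- delta_t * vel
  list(velocity = vel, deltaE = deltaE, current = pooled_spliced,
       extrapolated = pmax(pooled_spliced + deltaE, 0))
}

#' Run the steady-state velocity stage on a dataset
#'
#' Pools neighbours, filters the gene panel, fits gamma per gene, drops
#' genes whose fit is undefined or non-positive, and computes the residual
#' velocity with its extrapolated expression.
#'
#' @param dataset An `su_dataset` (see [simulate_dataset()]).
#' @param config A [velocity_config()].
#' @return An object of class `velocity_result`.
#' @export
run_velocity <- function(dataset, config = velocity_config()) {
  stopifnot(inherits(dataset, "su_dataset"))
  pooled <- pool_neighbors(dataset$spliced, dataset$unspliced,
                           k_cells = config$k_cells, n_pcs = config$n_pcs)
  kept <- filter_genes(pooled$spliced, config$spliced_average_min,
                       config$excluded_genes)
  gamma_hat <- fit_gamma(pooled$spliced[kept, , drop = FALSE],
                         pooled$unspliced[kept, , drop = FALSE],
                         config$fit_quantile)
  bad <- names(gamma_hat)[is.na(gamma_hat) | gamma_hat <= 0]
  kept <- setdiff(kept, bad)
  if (length(kept) == 0) stop("no gene survived the gamma fit")
  gamma_hat <- gamma_hat[kept]
  cv <- compute_velocity(pooled$spliced[kept, , drop = FALSE],
                         pooled$unspliced[kept, , drop = FALSE],
                         gamma_hat, config$delta_t)
  structure(
    c(list(pooled_spliced = pooled$spliced, pooled_unspliced = pooled$unspliced,
           gamma_hat = gamma_hat, kept_genes = kept, dropped_genes = bad,
           config = config),
      cv),
    class = "velocity_result"
  )
}

#' @export
print.velocity_result <- function(x, ...) {
  cat(sprintf("<velocity_result> %d kept genes x %d cells (%d dropped)\n",
              length(x$kept_genes), ncol(x$velocity), length(x$dropped_genes)))
  invisible(x)
}
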