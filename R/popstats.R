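#' Expected condition fraction over a cell set
#'
#' The null "probability of success" for composition enrichment: the
#' proportion of all analysed cells that originate from the given
#' condition.  In the study this was 62.96% (higher-order clustering) and
#' 57.39% (lineage reclustering) of cells from the injured samples.
#'
#' @param cell_meta data.frame with a `condition` column.
#' @param condition The condition counted as "success".
#' @return p0 in (0, 1).
#' @export
expected_fraction <- function(cell_meta, condition = "TBI") {
  cond <- cell_meta$condition
  if (!any(cond == condition) || all(cond == condition))
    stop("both the focal condition and at least one other must be present")
  mean(cond == condition)
}

# exact two-sided binomial p by the minimum-likelihood rule: the sum of
# P(X = k') over all k' no more likely than the observed k (the same
# relative-tolerance guard as the base binomial test, 1 + 1e-7)
.binom_two_sided <- function(k, n, p0) {
  d <- stats::dbinom(k, n, p0)
  all_d <- stats::dbinom(0:n, n, p0)
  min(1, sum(all_d[all_d <= d * (1 + 1e-7)]))
}

#' Binomial cluster-composition enrichment
#'
#' Tests, per cluster, whether the number of cells from the focal
#' condition deviates from its expected share `p0` of the analysed cells,
#' with an exact two-sided binomial test (minimum-likelihood two-sided
#' definition).  P-values are reported unadjusted.
#'
#' @param table data.frame with columns `cluster`, `cells_control`,
#'   `cells_tbi` (counts per cluster), or an `su_dataset`'s `cell_meta`
#'   via [composition_table()].
#' @param p0 Expected focal-condition fraction in (0, 1); defaults to the
#'   fraction computed from the table itself.
#' @return data.frame with per-cluster `n`, `k`, `observed_fraction`,
#'   `p0`, `p_value`, `direction` (`"enriched"`/`"depleted"`/`"none"` vs
#'   `p0`); empty clusters are flagged `testable = FALSE`.
#' @export
binomial_enrichment <- function(table, p0 = NULL) {
  need <- c("cluster", "cells_control", "cells_tbi")
  if (!all(need %in% names(table)))
    stop("'table' needs columns cluster, cells_control, cells_tbi")
  if (any(table$cells_control < 0 | table$cells_tbi < 0))
    stop("counts must be non-negative")
  n <- table$cells_control + table$cells_tbi
  if (all(n == 0)) stop("at least one cluster must be non-empty")
  if (is.null(p0)) p0 <- sum(table$cells_tbi) / sum(n)
  if (p0 <= 0 || p0 >= 1) stop("'p0' must lie strictly inside (0, 1)")
  k <- table$cells_tbi
  testable <- n > 0
  p <- rep(NA_real_, length(n))
  p[testable] <- mapply(.binom_two_sided, k[testable], n[testable],
                        MoreArgs = list(p0 = p0))
  frac <- ifelse(testable, k / n, NA_real_)
  data.frame(cluster = table$cluster, n = n, k = k,
             observed_fraction = frac, p0 = p0, p_value = p,
             direction = ifelse(!testable, NA_character_,
                         ifelse(frac > p0, "enriched",
                         ifelse(frac < p0, "depleted", "none"))),
             testable = testable,
             stringsAsFactors = FALSE)
}

#' Build a cluster-composition table from cell metadata
#'
#' @param cell_meta data.frame with `population` and `condition` columns.
#' @param condition Focal condition (counted in `cells_tbi`).
#' @return data.frame suitable for [binomial_enrichment()].
#' @export
composition_table <- function(cell_meta, condition = "TBI") {
  pops <- sort(unique(cell_meta$population))
  data.frame(
    cluster = pops,
    cells_control = vapply(pops, function(p)
      sum(cell_meta$population == p & cell_meta$condition != condition),
      numeric(1)),
    cells_tbi = vapply(pops, function(p)
      sum(cell_meta$population == p & cell_meta$condition == condition),
      numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Percentage overlap between two families of marker sets
#'
#' Entry (a, b) is 100 * |A_a intersect B_b| / |A_a|: the percentage of
#' genes of population `a` (rows) present in population `b`'s set
#' (columns).  Rows for empty sets are `NA` and flagged.
#'
#' @param marker_sets_a,marker_sets_b Named lists of gene-identifier
#'   vectors sharing a namespace.
#' @return Numeric percentage matrix with an `undefined_rows` attribute.
#' @export
overlap_matrix <- function(marker_sets_a, marker_sets_b) {
  a <- lapply(marker_sets_a, unique)
  b <- lapply(marker_sets_b, unique)
  out <- matrix(NA_real_, length(a), length(b),
                dimnames = list(names(a), names(b)))
  for (i in seq_along(a)) {
    if (length(a[[i]]) == 0) next
    out[i, ] <- vapply(b, function(s)
      100 * length(intersect(a[[i]], s)) / length(a[[i]]), numeric(1))
  }
  attr(out, "undefined_rows") <- names(a)[lengths(a) == 0]
  out
}

#' Pairwise common-gene counts across population gene sets
#'
#' Symmetric matrix of pairwise intersection sizes between population gene
#' lists (diagonal = set sizes); the similarity input for standard
#' agglomerative clustering of populations across studies (the original
#' analysis cut the dendrogram at three clusters).
#'
#' @param gene_lists Named list (population -> gene-identifier vector);
#'   names may be prefixed by study.
#' @return Symmetric non-negative integer matrix.
#' @export
similarity_counts <- function(gene_lists) {
  if (length(gene_lists) < 2) stop("need at least two populations")
  if (anyDuplicated(names(gene_lists))) stop("duplicate population names")
  sets <- lapply(gene_lists, unique)
  p <- length(sets)
  out <- matrix(0L, p, p, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(p)) for (j in i:p) {
    out[i, j] <- out[j, i] <- length(intersect(sets[[i]], sets[[j]]))
  }
  out
}

#' Nervous-system keyword list for pathway-term sorting
#'
#' The default keyword panel used to sort GO/KEGG term tables toward
#' nervous-system biology.
#'
#' @return Character vector of keywords.
#' @export
default_keywords <- function() {
  c("Synapse", "Axon", "Neuron", "Nervous", "Glia", "Astrocyte",
    "Microglia", "Injury", "Growth", "Tnf", "Neuro", "Age", "Myelin",
    "Sheath", "Reactive", "Ion", "Proliferation", "Genesis",
    "Development", "Morphology", "Formation", "Circuit", "Axonogenesis")
}

#' Keyword-based filtering of enrichment term tables
#'
#' Retains rows whose description contains at least one keyword
#' (case-insensitive substring match; the keyword panel is capitalised
#' inconsistently with GO descriptions, hence the case folding).  An empty
#' keyword list is the identity (unbiased output), not an error.
#'
#' @param term_table data.frame with a `description` column (e.g. term_id,
#'   description, p).
#' @param keywords Character vector; defaults to [default_keywords()].
#' @return The filtered data.frame.
#' @export
keyword_filter <- function(term_table, keywords = default_keywords()) {
  if (!"description" %in% names(term_table))
    stop("'term_table' needs a 'description' column")
  if (length(keywords) == 0) return(term_table)
  hit <- Reduce(`|`, lapply(keywords, function(k)
    grepl(k, term_table$description, ignore.case = TRUE)))
  term_table[hit, , drop = FALSE]
}
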