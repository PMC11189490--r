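# On-disk layout: spliced.mtx / unspliced.mtx (MatrixMarket coordinate),
# genes.tsv, cells.tsv, embedding.tsv, spatial.tsv, manifest.json

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

#' Write a dataset to its on-disk layout
#'
#' Writes `spliced.mtx`, `unspliced.mtx` (MatrixMarket coordinate),
#' `genes.tsv`, `cells.tsv` (cell_id, condition, population, animal,
#' latent_time), `embedding.tsv` and `manifest.json` (seed and noise
#' configuration echo) under `dir`.
#'
#' @param dataset An `su_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "su_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(dataset$spliced, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "spliced.mtx"))
  Matrix::writeMM(methods::as(Matrix::Matrix(dataset$unspliced, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "unspliced.mtx"))
  .write_tsv(dataset$gene_meta, file.path(dir, "genes.tsv"))
  .write_tsv(dataset$cell_meta, file.path(dir, "cells.tsv"))
  emb <- data.frame(cell_id = rownames(dataset$embedding),
                    dataset$embedding, check.names = FALSE)
  .write_tsv(emb, file.path(dir, "embedding.tsv"))
  .write_manifest(list(seed = dataset$seed, noise = dataset$noise,
                       n_genes = nrow(dataset$spliced),
                       n_cells = ncol(dataset$spliced)),
                  file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a dataset from its on-disk layout
#'
#' @param dir Directory written by [write_dataset()].
#' @return An `su_dataset` (without the generating lineage object).
#' @export
read_dataset <- function(dir) {
  S <- as.matrix(Matrix::readMM(file.path(dir, "spliced.mtx")))
  U <- as.matrix(Matrix::readMM(file.path(dir, "unspliced.mtx")))
  genes <- .read_tsv(file.path(dir, "genes.tsv"))
  cells <- .read_tsv(file.path(dir, "cells.tsv"))
  embdf <- .read_tsv(file.path(dir, "embedding.tsv"))
  emb <- as.matrix(embdf[, setdiff(names(embdf), "cell_id"), drop = FALSE])
  rownames(emb) <- embdf$cell_id
  dimnames(S) <- dimnames(U) <- list(genes$gene_id, cells$cell_id)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(list(spliced = S, unspliced = U, cell_meta = cells,
                 embedding = emb, gene_meta = genes,
                 noise = manifest$noise, seed = manifest$seed),
            class = "su_dataset")
}

#' Write / read a spatial cell set
#'
#' @param cells A `spatial_cellset` data.frame.
#' @param path TSV file path.
#' @return The path (write) or the data.frame (read).
#' @export
write_spatial <- function(cells, path) {
  .write_tsv(cells, path)
  invisible(path)
}

#' @rdname write_spatial
#' @export
read_spatial <- function(path) {
  out <- .read_tsv(path)
  class(out) <- c("spatial_cellset", "data.frame")
  out
}
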