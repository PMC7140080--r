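#' Write / read a count matrix as MatrixMarket MTX plus TSV sidecars
#'
#' The on-disk layout mirrors the common droplet-sequencing export:
#' `matrix.mtx` (genes x cells, MatrixMarket), `features.tsv` (gene name
#' and mitochondrial flag), `barcodes.tsv`, and `cell_metadata.tsv`
#' (condition, cluster and any truth labels).
#'
#' @param cm a `count_matrix`.
#' @param dir directory (created if missing).
#' @return `write_count_matrix()` returns `dir` invisibly;
#'   `read_count_matrix()` returns a `count_matrix`.
#' @export
write_count_matrix <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(cm$counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(cm$gene_meta, file.path(dir, "features.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(colnames(cm$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(cm$cell_meta, file.path(dir, "cell_metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  gene_meta <- utils::read.delim(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  cell_meta <- utils::read.delim(file.path(dir, "cell_metadata.tsv"))
  dimnames(counts) <- list(gene_meta$gene, barcodes)
  structure(list(counts = counts, gene_meta = gene_meta,
                 cell_meta = cell_meta), class = "count_matrix")
}

#' Read / write gene sets in GMT format
#'
#' GMT is tab-delimited: term id, description, then member genes, one term
#' per line. Writing then reading reproduces the same sets.
#'
#' @param path GMT file path.
#' @param gene_sets named list of character vectors.
#' @param descriptions optional per-term descriptions (defaults to the
#'   term ids).
#' @return `read_gmt()` returns a named list of character vectors;
#'   `write_gmt()` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE),
                 function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE),
                        `[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(gene_sets)
  lines <- vapply(seq_along(gene_sets), function(i)
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write interaction edge tables as TSV
#'
#' Columns: `source`, `target`, `level` (one of the systems-biology
#' levels, e.g. `ppi`, `tf`, `mirna`, `coexpression`, `drug`).
#'
#' @param edges data.frame with `source`, `target`, `level`.
#' @param path TSV path.
#' @return the table / the path.
#' @export
write_edge_table <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_table
#' @export
read_edge_table <- function(path) utils::read.delim(path)

#' Read / write a differential-expression table as TSV
#'
#' Columns: `gene`, `logFC`, `adj_p`.
#'
#' @param de_table data.frame.
#' @param path TSV path.
#' @return the table / the path.
#' @export
write_de_table <- function(de_table, path) {
  utils::write.table(de_table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) utils::read.delim(path)
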