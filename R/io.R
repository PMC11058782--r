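#' Read and write expression matrices as MTX triplets
#'
#' Standard single-cell exchange layout: `matrix.mtx` (genes x cells,
#' 1-based triplet indices) plus `genes.tsv` and `barcodes.tsv` with one
#' id per line.
#'
#' @param m counts `expr_matrix`.
#' @param dir directory to write to / read from (created if needed).
#' @return `write_expression_mtx()` returns the directory invisibly;
#'   `read_expression_mtx()` returns a counts `expr_matrix`.
#' @export
write_expression_mtx <- function(m, dir) {
  .assert_layer(m, "counts")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(
    methods::as(methods::as(Matrix::Matrix(em_values(m), sparse = TRUE), "CsparseMatrix"), "generalMatrix"),
    file.path(dir, "matrix.mtx")
  )
  writeLines(em_genes(m), file.path(dir, "genes.tsv"))
  writeLines(em_cells(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_expression_mtx
#' @export
read_expression_mtx <- function(dir) {
  mat <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(mat) <- readLines(file.path(dir, "genes.tsv"))
  colnames(mat) <- readLines(file.path(dir, "barcodes.tsv"))
  expr_matrix(mat, layer = "counts")
}

#' Read and write gene-set catalogs in GMT format
#'
#' GMT: one set per line -- name, description, then tab-separated gene
#' ids. Reading goes through [fgsea::gmtPathways()].
#'
#' @param sets named list of gene-id character vectors.
#' @param path GMT file path.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return `write_gmt()` returns `path` invisibly; `read_gmt()` returns a
#'   named list of gene-id vectors.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% names(sets)
  lines <- purrr::imap_chr(sets, function(g, nm) {
    paste(c(nm, descriptions[[match(nm, names(sets))]], g), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
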