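#' Expression matrix container
#'
#' A light wrapper around a genes x cells numeric matrix (dense or
#' `Matrix` sparse) carrying a layer tag that records which transformation
#' the values are on: raw `counts`, library-size log-normalized `lognorm`,
#' or gene-centred `relative` expression. All scoring functions check the
#' tag so that, e.g., a meta-module score can never silently be computed
#' on raw counts.
#'
#' @param values numeric matrix (base or `Matrix`), genes in rows with
#'   unique rownames, cells/spots in columns with unique colnames.
#' @param layer one of `"counts"`, `"lognorm"`, `"relative"`.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, layer = c("counts", "lognorm", "relative")) {
  layer <- match.arg(layer)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (gene ids) and colnames (cell ids)")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("gene and cell ids must be unique")
  }
  if (layer == "counts") {
    v <- if (inherits(values, "Matrix")) values@x else values
    if (any(v < 0) || any(v != round(v))) {
      stop("counts layer must contain non-negative integers")
    }
  }
  structure(list(values = values, layer = layer), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d cells, layer = %s\n",
    nrow(x$values), ncol(x$values), x$layer
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @rdname expr_matrix
#' @param m an `expr_matrix`.
#' @export
em_values <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  m$values
}

#' @rdname expr_matrix
#' @export
em_layer <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  m$layer
}

#' @rdname expr_matrix
#' @export
em_genes <- function(m) rownames(em_values(m))

#' @rdname expr_matrix
#' @export
em_cells <- function(m) colnames(em_values(m))

.assert_layer <- function(m, layer) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$layer != layer) {
    stop(sprintf("expected a '%s' layer, got '%s'", layer, m$layer))
  }
  invisible(m)
}
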