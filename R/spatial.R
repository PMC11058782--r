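.check_spots <- function(spots) {
  stopifnot(all(c("spot_id", "row", "col", "region") %in% names(spots)))
  if (anyDuplicated(spots[, c("row", "col")])) stop("spot coordinates must be unique")
  invisible(spots)
}

#' Score signatures on spatial spots
#'
#' Treats each spot as a cell: log-normalizes the spot counts, centres
#' per gene, bins genes by aggregate expression and computes the
#' bin-matched control score of every signature, appending one score
#' column per set to the spot table.
#'
#' @param spots spot tibble (`spot_id`, `row`, `col`, `region`).
#' @param expr counts `expr_matrix` with spots as columns (colnames must
#'   match `spot_id`).
#' @param sets named list of signature gene sets.
#' @param n_bins expression bins for control matching.
#' @param k control genes per signature gene.
#' @param seed integer seed for the control draws.
#' @return The spot tibble with one score column per signature.
#' @export
score_spots <- function(spots, expr, sets, n_bins = 30, k = 100, seed = 1L) {
  .check_spots(spots)
  stopifnot(setequal(em_cells(expr), spots$spot_id))
  ln <- lognormalize(expr)
  rel <- relative_expression(ln)
  bins <- bin_by_aggregate_expression(ln, n_bins = n_bins)
  scores <- score_states(rel, sets, bins, k = k, seed = seed)
  dplyr::left_join(spots, scores, by = c(spot_id = "cell_id"))
}

#' Gaussian smoothing of signature surfaces within regions
#'
#' Replaces each spot's value by a Gaussian-kernel weighted average over
#' the spots of the same region (`w = exp(-d^2 / (2 bw^2))` on Euclidean
#' spot-grid distance, self included). Bandwidth 0 returns the input
#' unchanged; a constant surface is unchanged for any bandwidth.
#'
#' @param spots spot tibble with score columns.
#' @param signatures character vector of score column names to smooth.
#' @param bandwidth kernel bandwidth in spot units (>= 0).
#' @return The spot tibble with the named columns smoothed.
#' @export
smooth_surface <- function(spots, signatures, bandwidth = 1.5) {
  .check_spots(spots)
  stopifnot(all(signatures %in% names(spots)), bandwidth >= 0)
  if (bandwidth == 0) return(spots)
  out <- spots
  for (reg in unique(spots$region)) {
    idx <- which(spots$region == reg)
    d2 <- outer(spots$row[idx], spots$row[idx], "-")^2 +
      outer(spots$col[idx], spots$col[idx], "-")^2
    w <- exp(-d2 / (2 * bandwidth^2))
    w <- w / rowSums(w)
    for (s in signatures) {
      out[[s]][idx] <- as.numeric(w %*% spots[[s]][idx])
    }
  }
  out
}

#' Spatially weighted correlation of signature surfaces in a region
#'
#' Smooths the signature surfaces with a Gaussian kernel within the
#' region (the local-neighbourhood weighting) and returns the Pearson
#' correlation matrix of the smoothed surfaces over the region's spots.
#' With bandwidth 0 this reduces exactly to plain Pearson correlation on
#' the raw scores. A constant surface has no defined correlation: its
#' entries are `NA` and the affected signatures are recorded in the
#' `"constant_surfaces"` attribute.
#'
#' @inheritParams smooth_surface
#' @param region region label to restrict to.
#' @return A `c x c` correlation matrix (signatures in the given order).
#' @export
weighted_correlation <- function(spots, signatures, region, bandwidth = 1.5) {
  .check_spots(spots)
  sub <- spots[spots$region == region, , drop = FALSE]
  if (nrow(sub) < 3) stop("need at least 3 spots in the region")
  sm <- smooth_surface(sub, signatures, bandwidth)
  m <- as.matrix(sm[, signatures])
  const <- apply(m, 2, function(x) stats::sd(x) == 0)
  cc <- suppressWarnings(stats::cor(m))
  diag(cc) <- 1
  attr(cc, "constant_surfaces") <- signatures[const]
  cc
}

#' Stack per-sample correlation matrices and reduce by mean
#'
#' Stacks the per-sample `c x c` signature correlation matrices into a
#' `(c, c, n)` array and reduces it to one `c x c` matrix by element-wise
#' mean over samples.
#'
#' @param matrices list of `c x c` correlation matrices sharing signature
#'   order (dimnames must match).
#' @return A list with `stack` (the `(c, c, n)` array) and `mean` (the
#'   reduced matrix).
#' @export
stack_and_reduce <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  dn <- dimnames(matrices[[1]])
  for (m in matrices) {
    if (!identical(dimnames(m), dn)) stop("matrices must share signature order")
  }
  stack <- array(
    unlist(matrices),
    dim = c(dim(matrices[[1]]), length(matrices)),
    dimnames = c(dn, list(NULL))
  )
  list(stack = stack, mean = apply(stack, c(1, 2), mean))
}

#' Tile plot of a signature surface
#'
#' @param spots spot tibble with a score column.
#' @param signature name of the score column to plot.
#' @return A ggplot object.
#' @export
plot_spatial_surface <- function(spots, signature) {
  .check_spots(spots)
  ggplot2::ggplot(spots, ggplot2::aes(
    x = .data$col, y = .data$row, fill = .data[[signature]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~region) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "column", y = "row")
}
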