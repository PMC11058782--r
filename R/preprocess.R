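#' Per-cell quality-control metrics
#'
#' Computes total UMI counts and the mitochondrial fraction per cell.
#' Mitochondrial genes are identified by an id prefix (default `"MT-"`);
#' the exact mitochondrial gene set is a configuration choice, not a claim
#' about any particular annotation.
#'
#' @param m `expr_matrix` on the counts layer.
#' @param mito_prefix prefix identifying mitochondrial gene ids.
#' @return A tibble with `cell_id`, `total_umi`, `mito_fraction`.
#' @export
qc_metrics <- function(m, mito_prefix = "MT-") {
  .assert_layer(m, "counts")
  v <- em_values(m)
  totals <- Matrix::colSums(v)
  mito <- startsWith(em_genes(m), mito_prefix)
  mito_counts <- if (any(mito)) Matrix::colSums(v[mito, , drop = FALSE]) else 0
  totals <- unname(as.numeric(totals))
  mito_counts <- unname(as.numeric(mito_counts))
  tibble::tibble(
    cell_id = em_cells(m),
    total_umi = totals,
    mito_fraction = ifelse(totals > 0, mito_counts / totals, 0)
  )
}

#' Filter cells on UMI totals and mitochondrial content
#'
#' Keeps cells whose total UMI count lies in `[umi_min, umi_max]` and whose
#' mitochondrial fraction is at most `mito_max`. Defaults follow the common
#' gliomasphere scRNA-seq gates of 4000-11000 UMIs and 20% mitochondrial
#' reads. Surviving cells keep their original order and values.
#'
#' @inheritParams qc_metrics
#' @param umi_min,umi_max inclusive bounds on per-cell total UMI counts.
#' @param mito_max maximum allowed mitochondrial fraction (proportion).
#' @return A filtered counts `expr_matrix`; the QC table with a `kept`
#'   flag is attached as attribute `"qc"`.
#' @export
qc_filter <- function(m, umi_min = 4000, umi_max = 11000, mito_max = 0.20,
                      mito_prefix = "MT-") {
  qc <- qc_metrics(m, mito_prefix = mito_prefix)
  qc$kept <- qc$total_umi >= umi_min & qc$total_umi <= umi_max &
    qc$mito_fraction <= mito_max
  if (!any(qc$kept)) {
    stop(sprintf(
      "no cells pass QC (umi in [%g, %g], mito <= %g)",
      umi_min, umi_max, mito_max
    ))
  }
  out <- expr_matrix(em_values(m)[, qc$kept, drop = FALSE], layer = "counts")
  attr(out, "qc") <- qc
  out
}

#' Library-size log-normalization
#'
#' Scales each cell to a common library size and log-transforms:
#' `log2(1 + count / total * scale)`. This is a deliberate, fully specified
#' stand-in for variance-stabilizing normalization: downstream meta-module
#' scoring only requires a monotone normalized layer.
#'
#' @inheritParams qc_metrics
#' @param scale target library size (counts per `scale` total).
#' @return An `expr_matrix` on the `lognorm` layer.
#' @export
lognormalize <- function(m, scale = 1e4) {
  .assert_layer(m, "counts")
  v <- em_values(m)
  totals <- Matrix::colSums(v)
  if (any(totals == 0)) {
    stop("cells with zero total counts cannot be normalized; run qc_filter first")
  }
  out <- log2(1 + sweep(as.matrix(v), 2, as.numeric(totals), "/") * scale)
  expr_matrix(out, layer = "lognorm")
}

#' Gene-centred relative expression
#'
#' Subtracts each gene's mean across cells, producing the relative
#' expression layer (Er) that meta-module scores are computed on. Genes
#' with constant expression become all-zero; the operation is idempotent.
#'
#' @param m `expr_matrix` on the lognorm layer.
#' @return An `expr_matrix` on the `relative` layer.
#' @export
relative_expression <- function(m) {
  .assert_layer(m, "lognorm")
  v <- as.matrix(em_values(m))
  expr_matrix(v - rowMeans(v), layer = "relative")
}

#' Median-of-ratios size factors for bulk counts
#'
#' For each sample, the size factor is the median over reference genes of
#' the ratio of the sample's count to the gene's geometric mean across
#' samples. Reference genes are those with nonzero counts in every sample.
#' Factors are returned unnormalized (not rescaled to geometric mean 1).
#'
#' @param counts genes x samples numeric matrix of bulk counts, or a counts
#'   `expr_matrix`.
#' @return A tibble with `sample` and `size_factor`.
#' @export
median_of_ratios <- function(counts) {
  if (inherits(counts, "expr_matrix")) {
    .assert_layer(counts, "counts")
    counts <- as.matrix(em_values(counts))
  }
  if (ncol(counts) < 2) stop("need at least 2 samples")
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero)) {
    stop("no gene has nonzero counts in every sample; size factors undefined")
  }
  ref <- counts[all_nonzero, , drop = FALSE]
  log_geo_mean <- rowMeans(log(ref))
  factors <- apply(ref, 2, function(col) {
    stats::median(exp(log(col) - log_geo_mean))
  })
  tibble::tibble(
    sample = colnames(counts) %||% as.character(seq_len(ncol(counts))),
    size_factor = as.numeric(factors)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
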