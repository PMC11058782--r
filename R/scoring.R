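#' Bin genes by aggregate expression
#'
#' Ranks genes by their mean normalized expression across cells and
#' partitions the ranking into `n_bins` quantile bins of near-equal size
#' (sizes differ by at most one; the lowest-expression bins take the
#' remainder). Ties in mean expression are broken by gene id order so the
#' assignment is deterministic.
#'
#' @param m `expr_matrix` on the lognorm layer (binning is done on the
#'   normalized, uncentred values).
#' @param n_bins number of expression bins (default 30).
#' @return A tibble with `gene`, `mean_expr`, `bin`.
#' @export
bin_by_aggregate_expression <- function(m, n_bins = 30) {
  .assert_layer(m, "lognorm")
  if (n_bins < 1) stop("n_bins must be >= 1")
  g <- em_genes(m)
  if (length(g) < n_bins) stop("need at least `n_bins` genes")
  means <- rowMeans(as.matrix(em_values(m)))
  ord <- order(means, g)
  n <- length(g)
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  bin_sorted <- rep(seq_len(n_bins), times = sizes)
  bin <- integer(n)
  bin[ord] <- bin_sorted
  tibble::tibble(gene = g, mean_expr = means, bin = bin)
}

#' Sample an expression-matched control gene multiset
#'
#' For each gene of a signature, draws `k` genes uniformly from the same
#' expression bin (without replacement when the bin holds at least `k`
#' genes, with replacement otherwise), yielding a control multiset of
#' size `k * length(set)` whose aggregate-expression profile matches the
#' signature's.
#'
#' @param set character vector of signature gene ids.
#' @param bins tibble from [bin_by_aggregate_expression()].
#' @param k control genes drawn per signature gene (default 100).
#' @param seed integer seed making the draw reproducible.
#' @return Character vector (multiset) of control gene ids, with the seed
#'   stored in attribute `"seed"`.
#' @export
sample_control_set <- function(set, bins, k = 100, seed = 1L) {
  missing <- setdiff(set, bins$gene)
  if (length(missing) > 0) {
    stop(
      "signature genes absent from the bin assignment: ",
      paste(missing, collapse = ", ")
    )
  }
  bin_of <- stats::setNames(bins$bin, bins$gene)
  members <- split(bins$gene, bins$bin)
  ctrl <- withr::with_seed(seed, {
    unlist(lapply(set, function(g) {
      pool <- members[[as.character(bin_of[[g]])]]
      sample(pool, k, replace = length(pool) < k)
    }), use.names = FALSE)
  })
  attr(ctrl, "seed") <- seed
  ctrl
}

.resolve_set_genes <- function(set, genes, set_name = "signature") {
  present <- intersect(set, genes)
  if (length(present) < length(set)) {
    frac <- length(present) / length(set)
    if (frac < 0.5) {
      stop(sprintf(
        "fewer than 50%% of %s genes are present in the matrix (%d of %d)",
        set_name, length(present), length(set)
      ))
    }
    warning(sprintf(
      "dropping %d %s gene(s) absent from the matrix",
      length(set) - length(present), set_name
    ))
  }
  present
}

#' Score a meta-module against a control multiset
#'
#' Per-cell score: mean relative expression over the signature genes minus
#' the mean over the control multiset (control genes count with their
#' multiplicity). Signature genes absent from the matrix are dropped with
#' a warning; fewer than half present is an error.
#'
#' @param m `expr_matrix` on the relative layer.
#' @param set character vector of signature gene ids.
#' @param control control gene multiset, e.g. from [sample_control_set()].
#' @return A tibble with `cell_id`, `score`.
#' @export
score_metamodule <- function(m, set, control) {
  .assert_layer(m, "relative")
  genes <- em_genes(m)
  set <- .resolve_set_genes(set, genes)
  if (!all(control %in% genes)) stop("control genes absent from the matrix")
  v <- em_values(m)
  set_mean <- colMeans(v[match(set, genes), , drop = FALSE])
  ctrl_mean <- colMeans(v[match(control, genes), , drop = FALSE])
  tibble::tibble(cell_id = em_cells(m), score = as.numeric(set_mean - ctrl_mean))
}

#' Score an arbitrary signature with bin-matched controls
#'
#' Convenience composition of [sample_control_set()] and
#' [score_metamodule()]: draws the expression-matched control multiset for
#' the signature and returns the per-cell score.
#'
#' @inheritParams score_metamodule
#' @inheritParams sample_control_set
#' @export
score_signature <- function(m, set, bins, k = 100, seed = 1L) {
  set <- .resolve_set_genes(set, em_genes(m))
  ctrl <- sample_control_set(set, bins, k = k, seed = seed)
  score_metamodule(m, set, ctrl)
}

#' Score several signatures into one table
#'
#' Scores each set of a named catalog with its own bin-matched control
#' draw (set `i` uses `seed + i - 1` so the whole table is reproducible
#' from one seed) and returns a wide per-cell score table.
#'
#' @inheritParams score_signature
#' @param catalog named list of gene-id character vectors; for four-state
#'   classification it must contain sets named `NPC`, `OPC`, `AC`, `MES`.
#' @return A tibble with `cell_id` and one score column per catalog set.
#' @export
score_states <- function(m, catalog, bins, k = 100, seed = 1L) {
  stopifnot(is.list(catalog), !is.null(names(catalog)))
  scores <- purrr::imap(catalog, function(set, nm) {
    i <- match(nm, names(catalog))
    score_signature(m, set, bins, k = k, seed = seed + i - 1L)$score
  })
  dplyr::bind_cols(tibble::tibble(cell_id = em_cells(m)), tibble::as_tibble(scores))
}

.state_priority <- c("NPC", "OPC", "AC", "MES")

.require_state_cols <- function(scores) {
  missing <- setdiff(.state_priority, names(scores))
  if (length(missing) > 0) {
    stop("score table lacks state column(s): ", paste(missing, collapse = ", "))
  }
  invisible(scores)
}

#' Assign each cell the state with the highest score
#'
#' Argmax over the four meta-module scores. Exact ties are broken by the
#' fixed priority NPC > OPC > AC > MES and flagged in `tie_flag`.
#'
#' @param scores tibble with `cell_id` and numeric columns `NPC`, `OPC`,
#'   `AC`, `MES` (extra columns ignored), e.g. from [score_states()].
#' @return A tibble with `cell_id`, `state`, `tie_flag`.
#' @export
classify_states <- function(scores) {
  .require_state_cols(scores)
  sm <- as.matrix(scores[, .state_priority])
  if (any(!is.finite(sm))) stop("scores must be finite")
  top <- apply(sm, 1, max)
  is_top <- sm == top
  idx <- apply(is_top, 1, which.max)  # first TRUE in priority order
  tibble::tibble(
    cell_id = scores$cell_id,
    state = .state_priority[idx],
    tie_flag = rowSums(is_top) > 1
  )
}

#' Two-dimensional butterfly state projection
#'
#' Computes the state-map coordinates: `y = max(OPC, NPC) - max(AC, MES)`
#' separates the OPC/NPC family (`y > 0`) from AC/MES; within the family,
#' `x = log2(|score difference| + 1)` of the two family scores (reported
#' unsigned; the family indexes the half-plane). Cells with `y == 0` fall
#' to the AC/MES family and are flagged.
#'
#' @inheritParams classify_states
#' @return A tibble with `cell_id`, `x`, `y`, `family`, `assigned_state`,
#'   `tie_flag`, `boundary_flag`.
#' @export
butterfly_coordinates <- function(scores) {
  .require_state_cols(scores)
  sm <- as.matrix(scores[, .state_priority])
  if (any(!is.finite(sm))) stop("scores must be finite")
  y <- pmax(scores$OPC, scores$NPC) - pmax(scores$AC, scores$MES)
  family <- ifelse(y > 0, "OPC/NPC", "AC/MES")
  x <- ifelse(
    y > 0,
    log2(abs(scores$OPC - scores$NPC) + 1),
    log2(abs(scores$AC - scores$MES) + 1)
  )
  cls <- classify_states(scores)
  tibble::tibble(
    cell_id = scores$cell_id,
    x = x, y = y, family = family,
    assigned_state = cls$state,
    tie_flag = cls$tie_flag,
    boundary_flag = y == 0
  )
}

#' Scatter plot of the butterfly state projection
#'
#' @param coords tibble from [butterfly_coordinates()].
#' @param colour_by name of the column used for the point colour.
#' @return A ggplot object. The x axis is mirrored by family so the two
#'   half-planes open left and right.
#' @export
plot_butterfly <- function(coords, colour_by = "assigned_state") {
  df <- dplyr::mutate(
    coords,
    x_signed = ifelse(.data$family == "OPC/NPC", .data$x, -.data$x)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$x_signed, y = .data$y,
    colour = .data[[colour_by]]
  )) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(
      x = "log2(|within-family score difference| + 1)",
      y = "max(OPC, NPC) - max(AC, MES)"
    ) +
    ggplot2::theme_minimal()
}
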