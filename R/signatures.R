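# Vectorized two-sided rank-sum (Mann-Whitney) test of group vs rest per
# gene, normal approximation with tie correction and continuity
# correction (matches wilcox.test(exact = FALSE)).
.rank_sum_rows <- function(v, in_group) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  n <- n1 + n2
  ranks <- t(apply(v, 1, rank))
  r1 <- rowSums(ranks[, in_group, drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  tiesum <- apply(v, 1, function(x) {
    t <- rle(sort(x))$lengths
    sum(t^3 - t)
  })
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tiesum / (n * (n - 1)))
  z <- u - n1 * n2 / 2
  correction <- sign(z) * 0.5
  z <- ifelse(sigma2 > 0, (z - correction) / sqrt(sigma2), 0)
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = pmin(1, p))
}

#' Derive per-cluster marker genes
#'
#' For each cluster, tests every gene cluster-vs-rest with a two-sided
#' rank-sum test on the log-normalized layer, computes the log2
#' fold-change (difference of group means on the log2 layer) and the
#' fraction of expressing cells, and retains upregulated genes passing
#' `lfc >= min_lfc` and in-group expressing fraction `>= min_pct`.
#' P-values are BH-adjusted within each cluster over the retained genes
#' and the result is sorted by adjusted p, then |lfc|, then gene id.
#'
#' @param m `expr_matrix` on the lognorm layer.
#' @param labels cluster labels: a character vector aligned to the cells,
#'   or a data frame with `cell_id` and `cluster` columns.
#' @param min_lfc minimum log2 fold-change (default 0.5).
#' @param min_pct minimum in-group expressing fraction (default 0.75).
#' @return A tibble with `cluster`, `gene`, `lfc`, `pct_in`, `pct_out`,
#'   `z`, `p`, `p_adj`, sorted within cluster.
#' @export
derive_cluster_markers <- function(m, labels, min_lfc = 0.5, min_pct = 0.75) {
  .assert_layer(m, "lognorm")
  v <- as.matrix(em_values(m))
  if (is.data.frame(labels)) {
    stopifnot(all(c("cell_id", "cluster") %in% names(labels)))
    labels <- labels$cluster[match(em_cells(m), labels$cell_id)]
  }
  if (length(labels) != ncol(v)) stop("labels must cover every cell")
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 clusters")
  if (any(tab < 3)) {
    stop("every cluster needs at least 3 cells; too small: ",
         paste(names(tab)[tab < 3], collapse = ", "))
  }
  purrr::map_dfr(sort(names(tab)), function(cl) {
    ing <- labels == cl
    lfc <- rowMeans(v[, ing, drop = FALSE]) - rowMeans(v[, !ing, drop = FALSE])
    pct_in <- rowMeans(v[, ing, drop = FALSE] > 0)
    pct_out <- rowMeans(v[, !ing, drop = FALSE] > 0)
    keep <- lfc >= min_lfc & pct_in >= min_pct
    if (!any(keep)) return(NULL)
    ts <- .rank_sum_rows(v[keep, , drop = FALSE], ing)
    out <- tibble::tibble(
      cluster = cl, gene = rownames(v)[keep],
      lfc = lfc[keep], pct_in = pct_in[keep], pct_out = pct_out[keep],
      z = ts$z, p = ts$p, p_adj = stats::p.adjust(ts$p, "BH")
    )
    dplyr::arrange(out, .data$p_adj, dplyr::desc(abs(.data$lfc)), .data$gene)
  })
}

#' Select the top of a ranked marker list as a signature
#'
#' Takes the first `n` genes in the marker table's sort order (most
#' significantly upregulated first). If fewer than `n` genes are
#' available the whole list is returned with a warning.
#'
#' @param markers tibble from [derive_cluster_markers()], optionally
#'   pre-filtered; if it holds several clusters, `cluster` must be given.
#' @param n signature size (default 150).
#' @param cluster cluster to select from when `markers` spans several.
#' @return Character vector of gene ids.
#' @export
select_top_signature <- function(markers, n = 150, cluster = NULL) {
  if (!is.null(cluster)) {
    markers <- markers[markers$cluster == cluster, ]
  } else if (length(unique(markers$cluster)) > 1) {
    stop("markers table spans several clusters; pass `cluster`")
  }
  if (nrow(markers) < n) {
    warning(sprintf(
      "only %d genes available for a signature of %d; returning all",
      nrow(markers), n
    ))
    n <- nrow(markers)
  }
  markers$gene[seq_len(n)]
}

#' Genes common to several upregulated sets
#'
#' Counts, for every gene, in how many of the input sets it appears and
#' keeps genes present in at least `min_membership` sets. Input order is
#' irrelevant.
#'
#' @param sets named list of gene-id character vectors (>= 2 sets).
#' @param min_membership minimum number of sets a gene must appear in
#'   (default 3).
#' @return A tibble with `gene`, `n_sets`, `sets` (comma-separated set
#'   names), sorted by descending membership then gene id.
#' @export
common_upregulated <- function(sets, min_membership = 3) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  long <- purrr::imap_dfr(sets, function(g, nm) {
    tibble::tibble(set = nm, gene = unique(g))
  })
  out <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_sets = dplyr::n(),
      sets = paste(sort(.data$set), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_sets >= min_membership) |>
    dplyr::arrange(dplyr::desc(.data$n_sets), .data$gene)
  out
}

# Enrichment score from sorted hit positions on a ranking of length N.
# `w` are the hit weights (|stat|^weight_exp at the hit positions, in hit
# order); falls back to equal weights when they sum to zero. Sign ties
# (max deviation equal in both directions) resolve positive.
.es_from_hits <- function(pos, w, n_total) {
  k <- length(pos)
  if (k == 0) stop("empty gene set")
  if (k == n_total) return(1)
  if (sum(w) == 0) w <- rep(1, k)
  cumh <- cumsum(w) / sum(w)
  miss <- (pos - seq_len(k)) / (n_total - k)
  dev_after <- cumh - miss
  dev_before <- c(0, cumh[-k]) - miss
  ma <- max(dev_after)
  mi <- min(dev_before)
  # sign ties (equal deviation both ways, up to fp noise) resolve positive
  if (ma >= -mi - 1e-9) ma else mi
}

# Null ES values for `n_perm` random position sets of size k (shared for
# all sets of the same size within one call).
.null_es <- function(k, w_full, n_total, n_perm) {
  posm <- vapply(
    seq_len(n_perm),
    function(b) sort.int(sample.int(n_total, k)),
    integer(k)
  )
  posm <- matrix(posm, nrow = k)
  wm <- matrix(w_full[posm], nrow = k)
  sw <- colSums(wm)
  if (any(sw == 0)) {
    wm[, sw == 0] <- 1
    sw <- colSums(wm)
  }
  cumh <- apply(wm, 2, cumsum) / rep(sw, each = k)
  cumh <- matrix(cumh, nrow = k)
  miss <- (posm - seq_len(k)) / (n_total - k)
  dev_after <- cumh - miss
  dev_before <- rbind(0, cumh[-k, , drop = FALSE]) - miss
  ma <- apply(dev_after, 2, max)
  mi <- apply(dev_before, 2, min)
  ifelse(ma >= -mi - 1e-9, ma, mi)
}

#' Pre-ranked permutation gene-set enrichment
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment on a signed gene
#' ranking: genes are sorted by decreasing statistic, set members ("hits")
#' increment the running sum by `|stat|^weight_exp` (normalized to 1 over
#' hits), non-members decrement by `1/(N - Nh)`; the enrichment score ES
#' is the signed extreme deviation. Significance comes from gene-set
#' permutations: `n_perm` random same-size sets form the null, NES is ES
#' divided by the mean null |ES| of matching sign, p is the empirical
#' tail probability among same-sign nulls, and q is a BH adjustment over
#' all sets scored in the call.
#'
#' @param ranking two-column data frame (`gene`, `stat`) or a named
#'   numeric vector of per-gene signed statistics; gene ids must be
#'   unique. Ties in `stat` are broken by gene id for determinism.
#' @param sets a named list of gene-id vectors, or a single character
#'   vector (treated as one set named `"set"`).
#' @param n_perm number of gene-set permutations (default 1000).
#' @param weight_exp exponent on `|stat|` in the hit increments; 0 gives
#'   the classic unweighted KS statistic.
#' @param min_overlap minimum set/ranking overlap (default 3).
#' @param seed integer seed for the permutations.
#' @return A `preranked_enrichment` object; `tidy()` returns the result
#'   table (`set`, `size`, `ES`, `NES`, `p`, `q`, `n_perm`, `seed`).
#' @export
preranked_enrichment <- function(ranking, sets, n_perm = 1000, weight_exp = 1,
                                 min_overlap = 3, seed = 1L) {
  if (is.data.frame(ranking)) {
    stopifnot(all(c("gene", "stat") %in% names(ranking)))
    stat <- stats::setNames(ranking$stat, ranking$gene)
  } else {
    stat <- ranking
  }
  if (anyDuplicated(names(stat))) stop("duplicate genes in the ranking")
  if (all(stat == 0)) stop("all-zero ranking statistics")
  if (!is.list(sets)) sets <- list(set = sets)
  stopifnot(!is.null(names(sets)))
  ord <- order(-stat, names(stat))
  stat <- stat[ord]
  genes <- names(stat)
  n_total <- length(stat)
  w_full <- abs(stat)^weight_exp

  res <- withr::with_seed(seed, {
    rows <- vector("list", length(sets))
    null_by_size <- list()
    for (i in seq_along(sets)) {
      pos <- sort.int(match(intersect(sets[[i]], genes), genes))
      k <- length(pos)
      if (k < min_overlap) {
        stop(sprintf(
          "set '%s' overlaps the ranking in %d gene(s); need >= %d",
          names(sets)[i], k, min_overlap
        ))
      }
      es <- .es_from_hits(pos, w_full[pos], n_total)
      key <- as.character(k)
      if (is.null(null_by_size[[key]])) {
        null_by_size[[key]] <- .null_es(k, w_full, n_total, n_perm)
      }
      null <- null_by_size[[key]]
      pool <- if (es >= 0) null[null >= 0] else null[null < 0]
      if (length(pool) == 0) pool <- abs(null) * sign(es + (es == 0))
      nes <- es / mean(abs(pool))
      p <- (1 + sum(abs(pool) >= abs(es))) / (1 + length(pool))
      rows[[i]] <- tibble::tibble(
        set = names(sets)[i], size = k, ES = es, NES = nes, p = p
      )
    }
    dplyr::bind_rows(rows)
  })
  res$q <- stats::p.adjust(res$p, "BH")
  res$n_perm <- n_perm
  res$seed <- seed
  structure(
    list(
      results = res,
      ranking = tibble::tibble(gene = genes, stat = as.numeric(stat)),
      sets = sets, weight_exp = weight_exp
    ),
    class = "preranked_enrichment"
  )
}

#' @export
print.preranked_enrichment <- function(x, ...) {
  cat(sprintf(
    "<preranked_enrichment> %d set(s) on %d ranked genes, %d permutations\n",
    nrow(x$results), nrow(x$ranking), x$results$n_perm[1]
  ))
  print(x$results)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname preranked_enrichment
#' @param x a `preranked_enrichment` object.
#' @param ... unused.
#' @export
tidy.preranked_enrichment <- function(x, ...) x$results

#' @rdname preranked_enrichment
#' @export
glance.preranked_enrichment <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x$results),
    n_genes = nrow(x$ranking),
    n_perm = x$results$n_perm[1],
    weight_exp = x$weight_exp,
    seed = x$results$seed[1],
    n_q_lt_0.25 = sum(x$results$q < 0.25)
  )
}

#' Running-sum plot for one enriched set
#'
#' @param object a `preranked_enrichment` object.
#' @param set name of the set to plot (default: first).
#' @param ... unused.
#' @export
autoplot.preranked_enrichment <- function(object, set = NULL, ...) {
  set <- set %||% object$results$set[1]
  genes <- object$ranking$gene
  hits <- genes %in% object$sets[[set]]
  w <- abs(object$ranking$stat)^object$weight_exp
  w[!hits] <- 0
  if (sum(w) == 0) w[hits] <- 1
  inc <- w / sum(w)
  dec <- (!hits) / sum(!hits)
  path <- cumsum(inc - dec)
  df <- tibble::tibble(rank = seq_along(path), running_sum = path)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running_sum)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_rug(
      data = df[hits, ], sides = "b", length = ggplot2::unit(0.02, "npc")
    ) +
    ggplot2::labs(
      title = set, x = "rank in ordered list", y = "running enrichment sum"
    ) +
    ggplot2::theme_minimal()
}

#' Up/down/no-change calls from paired enrichment results
#'
#' Applies the q-value gate used for paired longitudinal comparisons: a
#' result with `q >= q_threshold` is called `no_change` (the boundary is
#' inclusive); otherwise the sign of NES gives `enriched_up` or
#' `enriched_down`.
#'
#' @param results data frame with `NES` and `q` columns (e.g. one
#'   [preranked_enrichment()] result per patient, row-bound); extra
#'   columns such as a patient id are preserved.
#' @param q_threshold significance gate on q (default 0.25).
#' @return The input tibble with a `call` column added.
#' @export
classify_paired_enrichment <- function(results, q_threshold = 0.25) {
  stopifnot(all(c("NES", "q") %in% names(results)))
  dplyr::mutate(
    tibble::as_tibble(results),
    call = dplyr::case_when(
      q >= q_threshold ~ "no_change",
      NES > 0 ~ "enriched_up",
      NES < 0 ~ "enriched_down",
      TRUE ~ "no_change"
    )
  )
}

#' Temporal state scores from proteomic log2 ratios
#'
#' For each state marker set and timepoint, the score is the mean of the
#' finite log2 ratios of the detected markers; infinite values (ratios
#' against a zero denominator) are excluded and the number of markers
#' actually used is reported.
#'
#' @param ratios long tibble with columns `gene`, `timepoint`,
#'   `log2_ratio`.
#' @param sets named list of state marker gene sets.
#' @return A tibble with `state`, `timepoint`, `score`, `n_used`.
#' @export
proteomic_state_scores <- function(ratios, sets) {
  stopifnot(all(c("gene", "timepoint", "log2_ratio") %in% names(ratios)))
  stopifnot(is.list(sets), !is.null(names(sets)))
  purrr::imap_dfr(sets, function(g, nm) {
    ratios |>
      dplyr::filter(.data$gene %in% g) |>
      dplyr::group_by(timepoint = .data$timepoint) |>
      dplyr::summarise(
        score = mean(.data$log2_ratio[is.finite(.data$log2_ratio)]),
        n_used = sum(is.finite(.data$log2_ratio)),
        .groups = "drop"
      ) |>
      dplyr::mutate(state = nm, .before = 1)
  })
}
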