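#' Kinase-activity z-scores from phosphosite fold changes
#'
#' Kinase-substrate enrichment: for every kinase with at least
#' `min_substrates` detected substrate sites, the activity z-score is
#' `z = (ms - mb) * sqrt(m) / sd_b`, where `ms` is the mean substrate
#' log2 fold-change, `mb` and `sd_b` are the mean and standard deviation
#' of all site log2 fold-changes (the background), and `m` is the number
#' of substrate sites used. Sites with non-finite log2FC are excluded
#' before any statistic is computed; sites annotated to several kinases
#' count for each. Two-sided normal p-values; significant when
#' `p <= p_threshold`.
#'
#' @param table tibble with `site` and `log2fc` columns (site ids unique).
#' @param map tibble with `kinase` and `site` columns.
#' @param min_substrates minimum detected substrates per reported kinase
#'   (default 5).
#' @param p_threshold significance threshold on p (default 0.01).
#' @return A `ksea_result` object; `tidy()` returns the kinase table
#'   (`kinase`, `z`, `m`, `p`, `significant`), and `$excluded` lists
#'   kinases below the substrate floor with their detected counts.
#' @export
ksea_zscores <- function(table, map, min_substrates = 5, p_threshold = 0.01) {
  stopifnot(all(c("site", "log2fc") %in% names(table)))
  stopifnot(all(c("kinase", "site") %in% names(map)))
  if (nrow(table) == 0 || nrow(map) == 0) stop("empty table or map")
  if (anyDuplicated(table$site)) stop("site ids must be unique")
  tab <- table[is.finite(table$log2fc), ]
  bg_mean <- mean(tab$log2fc)
  bg_sd <- stats::sd(tab$log2fc)
  if (is.na(bg_sd) || bg_sd == 0) stop("degenerate background: sd of log2FC is 0")
  fc <- stats::setNames(tab$log2fc, tab$site)
  per_kinase <- map |>
    dplyr::filter(.data$site %in% names(fc)) |>
    dplyr::distinct(.data$kinase, .data$site) |>
    dplyr::group_by(kinase = .data$kinase) |>
    dplyr::summarise(
      m = dplyr::n(), ms = mean(fc[.data$site]), .groups = "drop"
    )
  all_kinases <- unique(map$kinase)
  missing <- setdiff(all_kinases, per_kinase$kinase)
  excluded <- dplyr::bind_rows(
    tibble::tibble(kinase = missing, m = 0L),
    dplyr::select(
      dplyr::filter(per_kinase, .data$m < min_substrates), "kinase", "m"
    )
  ) |>
    dplyr::mutate(reason = sprintf(
      "only %d detected substrate(s); floor is %d", .data$m, min_substrates
    )) |>
    dplyr::arrange(.data$kinase)
  res <- per_kinase |>
    dplyr::filter(.data$m >= min_substrates) |>
    dplyr::mutate(
      z = (.data$ms - bg_mean) * sqrt(.data$m) / bg_sd,
      p = 2 * stats::pnorm(-abs(.data$z)),
      significant = .data$p <= p_threshold
    ) |>
    dplyr::select("kinase", "z", "m", "p", "significant") |>
    dplyr::arrange(dplyr::desc(abs(.data$z)))
  structure(
    list(
      results = res, excluded = excluded,
      background = tibble::tibble(
        n_sites = nrow(tab), mean = bg_mean, sd = bg_sd
      ),
      min_substrates = min_substrates, p_threshold = p_threshold
    ),
    class = "ksea_result"
  )
}

#' @export
print.ksea_result <- function(x, ...) {
  cat(sprintf(
    "<ksea_result> %d kinase(s) scored against %d background sites (%d excluded)\n",
    nrow(x$results), x$background$n_sites, nrow(x$excluded)
  ))
  print(x$results)
  invisible(x)
}

#' @rdname ksea_zscores
#' @param x a `ksea_result` object.
#' @param ... unused.
#' @export
tidy.ksea_result <- function(x, ...) x$results

#' @rdname ksea_zscores
#' @export
glance.ksea_result <- function(x, ...) {
  tibble::tibble(
    n_kinases = nrow(x$results),
    n_excluded = nrow(x$excluded),
    n_significant = sum(x$results$significant),
    n_background_sites = x$background$n_sites,
    min_substrates = x$min_substrates,
    p_threshold = x$p_threshold
  )
}

#' Bar chart of kinase activity z-scores
#'
#' @param object a `ksea_result` object.
#' @param ... unused.
#' @export
autoplot.ksea_result <- function(object, ...) {
  df <- dplyr::mutate(
    object$results,
    kinase = stats::reorder(.data$kinase, .data$z)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$z, y = .data$kinase, fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "activity z-score", y = NULL) +
    ggplot2::theme_minimal()
}
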