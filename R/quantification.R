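#' Division number from dye dilution
#'
#' A proliferation dye halves at each division, so the division number X
#' solves `2^X = B` with `B = mfi_initial / mfi_final`, i.e.
#' `X = log2(B)`. When the final MFI exceeds the initial one beyond the
#' tolerance (a labeling artifact) X is clipped at 0 with a warning, and
#' the time per division is `elapsed / X` (undefined when X = 0).
#'
#' @param records tibble with `mfi_initial`, `mfi_final`, `elapsed`
#'   columns (MFIs > 0, elapsed > 0).
#' @param tol relative tolerance above which `mfi_final > mfi_initial`
#'   triggers the artifact warning (default 0.05).
#' @return The input tibble with `b_ratio`, `divisions`,
#'   `time_per_division` (hours, `NA` when no division occurred) and
#'   `clipped` columns added.
#' @export
division_number <- function(records, tol = 0.05) {
  stopifnot(all(c("mfi_initial", "mfi_final", "elapsed") %in% names(records)))
  if (any(records$mfi_initial <= 0) || any(records$mfi_final <= 0)) {
    stop("MFIs must be positive")
  }
  if (any(records$elapsed <= 0)) stop("elapsed must be positive")
  b <- records$mfi_initial / records$mfi_final
  x <- log2(b)
  clipped <- records$mfi_final > records$mfi_initial * (1 + tol)
  if (any(clipped)) {
    warning(sprintf(
      "%d record(s) gained fluorescence beyond tolerance (labeling artifact); divisions clipped at 0",
      sum(clipped)
    ))
  }
  x <- pmax(x, 0)
  dplyr::mutate(
    tibble::as_tibble(records),
    b_ratio = b,
    divisions = x,
    time_per_division = ifelse(x > 0, .data$elapsed / x, NA_real_),
    clipped = clipped
  )
}

#' Fraction of cells of a class attached to vessels
#'
#' A cell is attached when its Euclidean distance to the nearest vessel
#' polyline is at most the scene's contact radius. Returns
#' attached / total within the class.
#'
#' @param scene a vessel scene: list with `cells` (tibble `cell_id`, `x`,
#'   `y`, `class`, `region`), `segments` (tibble `segment_id`, `vertex`,
#'   `x`, `y`) and `contact_radius`, e.g. from [simulate_vessel_scene()].
#' @param class cell class to quantify (e.g. `"NesHI"`).
#' @return A tibble with `class`, `n_cells`, `n_attached`, `fraction`.
#' @export
vascular_association <- function(scene, class) {
  cells <- scene$cells[scene$cells$class == class, ]
  if (nrow(cells) == 0) stop("no cells of class ", class)
  d <- .dist_to_vessels(cells$x, cells$y, scene$segments)
  att <- d <= scene$contact_radius
  tibble::tibble(
    class = class, n_cells = nrow(cells), n_attached = sum(att),
    fraction = mean(att)
  )
}

#' Percentage of invasive-front cells co-opting vessels
#'
#' Restricted to cells in the `invasive_front` region: the percentage
#' within the scene's contact radius of a vessel segment, together with
#' the raw counts (the inputs of an infiltrating-cell density).
#'
#' @inheritParams vascular_association
#' @return A tibble with `n_front_cells`, `n_cooption`,
#'   `percent_cooption`.
#' @export
vessel_cooption_percentage <- function(scene) {
  if (!"region" %in% names(scene$cells)) stop("cells lack region labels")
  front <- scene$cells[scene$cells$region == "invasive_front", ]
  if (nrow(front) == 0) stop("no cells in the invasive_front region")
  d <- .dist_to_vessels(front$x, front$y, scene$segments)
  att <- d <= scene$contact_radius
  tibble::tibble(
    n_front_cells = nrow(front), n_cooption = sum(att),
    percent_cooption = 100 * mean(att)
  )
}

#' Percentage of Nestin-positive nuclei in a region
#'
#' `100 x (positive nuclei) / (total nuclei)` within the region.
#'
#' @param nuclei tibble with `status` (`"positive"`/`"negative"`) and
#'   `region` columns.
#' @param region region to quantify.
#' @return A tibble with `region`, `n_nuclei`, `n_positive`,
#'   `percent_positive`.
#' @export
nestin_positive_percentage <- function(nuclei, region) {
  stopifnot(all(c("status", "region") %in% names(nuclei)))
  stopifnot(all(nuclei$status %in% c("positive", "negative")))
  sub <- nuclei[nuclei$region == region, ]
  if (nrow(sub) == 0) stop("no nuclei in region ", region)
  tibble::tibble(
    region = region, n_nuclei = nrow(sub),
    n_positive = sum(sub$status == "positive"),
    percent_positive = 100 * mean(sub$status == "positive")
  )
}

#' Reporter reprogramming rate over a timelapse
#'
#' Percentage of double-positive (GFP+dTomato+) cells among all GFP+
#' cells at each timepoint.
#'
#' @param counts tibble with `timepoint`, `n_double_positive`,
#'   `n_single_positive` columns (non-negative counts).
#' @return The input tibble with `percent_double_positive` added.
#' @export
reprogramming_rate <- function(counts) {
  stopifnot(all(
    c("timepoint", "n_double_positive", "n_single_positive") %in% names(counts)
  ))
  if (any(counts$n_double_positive < 0) || any(counts$n_single_positive < 0)) {
    stop("counts must be non-negative")
  }
  total <- counts$n_double_positive + counts$n_single_positive
  if (any(total == 0)) stop("timepoint with no cells")
  dplyr::mutate(
    tibble::as_tibble(counts),
    percent_double_positive = 100 * .data$n_double_positive / total
  )
}

#' Reporter fluorescence area fraction over a timelapse
#'
#' The area of tdTomato-expressing cells divided by the total cell area,
#' per timepoint.
#'
#' @param areas tibble with `timepoint`, `area_dtomato`, `area_total`
#'   columns (areas non-negative, `area_dtomato <= area_total`,
#'   `area_total > 0`).
#' @return The input tibble with `area_fraction` added.
#' @export
fluorescence_area_fraction <- function(areas) {
  stopifnot(all(c("timepoint", "area_dtomato", "area_total") %in% names(areas)))
  if (any(areas$area_total <= 0)) stop("total area must be positive")
  if (any(areas$area_dtomato < 0) || any(areas$area_dtomato > areas$area_total)) {
    stop("tdTomato area must lie in [0, total area]")
  }
  dplyr::mutate(
    tibble::as_tibble(areas),
    area_fraction = .data$area_dtomato / .data$area_total
  )
}
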