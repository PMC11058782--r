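#' Simulation configuration for synthetic gliomasphere counts
#'
#' Bundles the parameters of the negative-binomial state-mixture
#' generator. Defaults describe the study conditions the rest of the
#' package is exercised under: 3000 cells x 2000 genes, four transcriptional
#' states (NPC/OPC/AC/MES) at equal basal frequency plus a 10% hybrid
#' intermediate, 30 marker genes per state shifted by one log2 unit in the
#' cells of their state.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param state_proportions named simplex over `NPC`, `OPC`, `AC`, `MES`,
#'   `HYBRID`; must sum to 1.
#' @param markers_per_state planted marker genes per state.
#' @param marker_effect log2-units shift of a state's markers in its cells.
#'   Hybrid cells carry half the effect on both the AC and MES markers.
#' @param nb_dispersion negative-binomial dispersion `alpha`
#'   (variance = mu + alpha * mu^2).
#' @param reprogram_fraction default fraction of non-hybrid cells
#'   reprogrammed to hybrid by [simulate_treated_counts()].
#' @param gene_mean_meanlog,gene_mean_sdlog lognormal distribution of
#'   baseline per-gene mean counts; the defaults put typical library sizes
#'   in the mid-thousands at 2000 genes.
#' @param seed integer seed; every draw of the generator flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 3000, n_genes = 2000,
                       state_proportions = c(
                         NPC = 0.225, OPC = 0.225, AC = 0.225,
                         MES = 0.225, HYBRID = 0.10
                       ),
                       markers_per_state = 30, marker_effect = 1,
                       nb_dispersion = 0.5, reprogram_fraction = 0.25,
                       gene_mean_meanlog = log(2), gene_mean_sdlog = 1,
                       seed = 1L) {
  states <- c("NPC", "OPC", "AC", "MES", "HYBRID")
  if (!setequal(names(state_proportions), states)) {
    stop("state_proportions must be named over NPC, OPC, AC, MES, HYBRID")
  }
  state_proportions <- state_proportions[states]
  if (abs(sum(state_proportions) - 1) > 1e-9) {
    stop("state_proportions must sum to 1")
  }
  if (any(state_proportions < 0)) stop("state_proportions must be non-negative")
  if (markers_per_state * 4 > n_genes) {
    stop("n_genes too small for 4 x markers_per_state marker genes")
  }
  if (reprogram_fraction < 0 || reprogram_fraction > 1) {
    stop("reprogram_fraction must be in [0, 1]")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  structure(
    list(
      n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
      state_proportions = state_proportions,
      markers_per_state = as.integer(markers_per_state),
      marker_effect = marker_effect, nb_dispersion = nb_dispersion,
      reprogram_fraction = reprogram_fraction,
      gene_mean_meanlog = gene_mean_meanlog,
      gene_mean_sdlog = gene_mean_sdlog,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Per-gene log2 mean-shift profile for one cell state.
.state_mu <- function(base_mu, marker_sets, state, effect) {
  mu <- base_mu
  if (state == "HYBRID") {
    mu[marker_sets$AC] <- mu[marker_sets$AC] * 2^(effect / 2)
    mu[marker_sets$MES] <- mu[marker_sets$MES] * 2^(effect / 2)
  } else {
    mu[marker_sets[[state]]] <- mu[marker_sets[[state]]] * 2^effect
  }
  mu
}

# Draws NB counts for the given per-cell states; assumes RNG state is set.
.draw_counts <- function(cfg, base_mu, marker_sets, states_per_cell) {
  size <- 1 / cfg$nb_dispersion
  counts <- matrix(0L, cfg$n_genes, length(states_per_cell))
  for (st in unique(states_per_cell)) {
    idx <- which(states_per_cell == st)
    mu <- .state_mu(base_mu, marker_sets, st, cfg$marker_effect)
    counts[, idx] <- stats::rnbinom(
      cfg$n_genes * length(idx),
      size = size, mu = mu
    )
  }
  counts
}

# Gene-level parameters (baseline means, marker identities) are always
# drawn from the config seed, so samples simulated under the same config
# share one gene universe whatever their run seed.
.gene_params <- function(cfg) {
  withr::with_seed(cfg$seed, {
    genes <- sprintf("g%05d", seq_len(cfg$n_genes))
    base_mu <- stats::rlnorm(
      cfg$n_genes, cfg$gene_mean_meanlog, cfg$gene_mean_sdlog
    )
    marker_genes <- sample(genes, 4 * cfg$markers_per_state)
    marker_sets <- split(
      marker_genes,
      rep(c("NPC", "OPC", "AC", "MES"), each = cfg$markers_per_state)
    )
    marker_sets <- lapply(marker_sets, function(g) match(g, genes))
    marker_of <- rep(NA_character_, cfg$n_genes)
    for (st in names(marker_sets)) marker_of[marker_sets[[st]]] <- st
    list(
      genes = genes, base_mu = base_mu, marker_sets = marker_sets,
      catalog = lapply(marker_sets, function(i) genes[i]),
      marker_of = marker_of
    )
  })
}

# Cell-level draws; assumes the RNG state has been set by the caller.
.gen_state_counts <- function(cfg, gp) {
  cells <- sprintf("c%05d", seq_len(cfg$n_cells))
  states <- sample(
    names(cfg$state_proportions), cfg$n_cells,
    replace = TRUE, prob = cfg$state_proportions
  )
  counts <- .draw_counts(cfg, gp$base_mu, gp$marker_sets, states)
  dimnames(counts) <- list(gp$genes, cells)
  c(gp, list(counts = counts, cells = cells, states = states))
}

#' Simulate a naive state-mixture count matrix
#'
#' Draws negative-binomial counts for a mixture of four transcriptional
#' states plus a hybrid intermediate. Baseline gene means are lognormal;
#' marker genes of a state are shifted up by `marker_effect` log2 units in
#' the cells of that state; hybrid cells carry half the effect on both the
#' AC and MES marker sets simultaneously. Identical config and seed give
#' bit-identical output.
#'
#' @param config a [sim_config()].
#' @return A list with `expr` (counts `expr_matrix`), `cell_meta` (tibble
#'   `cell_id`, `state`), `catalog` (the four planted marker sets), and
#'   `truth` (list of `cells`, `genes` tibbles and the config).
#' @export
simulate_state_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gp <- .gene_params(config)
  g <- withr::with_seed(config$seed, .gen_state_counts(config, gp))
  list(
    expr = expr_matrix(g$counts, layer = "counts"),
    cell_meta = tibble::tibble(cell_id = g$cells, state = g$states),
    catalog = g$catalog,
    truth = list(
      cells = tibble::tibble(
        cell_id = g$cells, state = g$states, reprogrammed = FALSE
      ),
      genes = tibble::tibble(gene = g$genes, marker_of = g$marker_of),
      config = config
    )
  )
}

#' Simulate therapy-induced reprogramming toward the hybrid state
#'
#' Regenerates a naive mixture under `config`, then reprograms each
#' non-hybrid cell to the hybrid state independently with probability
#' `reprogram_fraction`, redrawing its counts from the hybrid profile.
#' With fraction 0 the output is bit-identical to
#' [simulate_state_counts()] under the same seed; with fraction 1 every
#' cell ends hybrid.
#'
#' @inheritParams simulate_state_counts
#' @param reprogram_fraction probability a non-hybrid cell reprograms.
#' @param seed seed for this run (defaults to the config seed).
#' @return As [simulate_state_counts()]; `truth$cells` records
#'   `original_state`, `state` (final) and a `reprogrammed` flag.
#' @export
simulate_treated_counts <- function(config,
                                    reprogram_fraction = config$reprogram_fraction,
                                    seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (reprogram_fraction < 0 || reprogram_fraction > 1) {
    stop("reprogram_fraction must be in [0, 1]")
  }
  gp <- .gene_params(config)
  res <- withr::with_seed(seed, {
    g <- .gen_state_counts(config, gp)
    eligible <- g$states != "HYBRID"
    flip <- stats::runif(config$n_cells) < reprogram_fraction & eligible
    if (any(flip)) {
      idx <- which(flip)
      mu <- .state_mu(g$base_mu, g$marker_sets, "HYBRID", config$marker_effect)
      g$counts[, idx] <- stats::rnbinom(
        config$n_genes * length(idx),
        size = 1 / config$nb_dispersion, mu = mu
      )
    }
    g$flip <- flip
    g
  })
  final <- ifelse(res$flip, "HYBRID", res$states)
  list(
    expr = expr_matrix(res$counts, layer = "counts"),
    cell_meta = tibble::tibble(cell_id = res$cells, state = final),
    catalog = res$catalog,
    truth = list(
      cells = tibble::tibble(
        cell_id = res$cells, original_state = res$states,
        state = final, reprogrammed = res$flip
      ),
      genes = tibble::tibble(gene = res$genes, marker_of = res$marker_of),
      config = config, reprogram_fraction = reprogram_fraction
    )
  )
}

# Separable Gaussian smoothing of a matrix-shaped field.
.smooth_grid <- function(mat, scale) {
  if (scale <= 0) return(mat)
  kern <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * scale^2))
    k / rowSums(k)
  }
  kern(nrow(mat)) %*% mat %*% t(kern(ncol(mat)))
}

#' Simulate a spatial sample with two correlated signature surfaces
#'
#' Generates a pair of Gaussian-random-field score surfaces on a regular
#' spot grid with a target cross-correlation, adds independent observation
#' noise, and labels each spot as infiltrative cortex or cellular tumor
#' (by default the top half of rows is cortex). With `colocalization = 1`
#' and `noise_sd = 0` the two surfaces are identical.
#'
#' @param n_row,n_col grid dimensions in spots (each >= 2).
#' @param colocalization target cross-correlation in `[-1, 1]`.
#' @param noise_sd standard deviation of iid per-spot observation noise.
#' @param field_scale Gaussian autocorrelation scale of the fields, in
#'   spot units.
#' @param region_map optional tibble `(row, col, region)` overriding the
#'   default half-split region labels.
#' @param signature_names names of the two score columns.
#' @param seed integer seed.
#' @return A list with `spots` (tibble `spot_id`, `row`, `col`, `region`,
#'   two score columns) and `truth`.
#' @export
simulate_spatial_sample <- function(n_row = 50, n_col = 50,
                                    colocalization = 0.7, noise_sd = 0.1,
                                    field_scale = 3, region_map = NULL,
                                    signature_names = c("sig1", "sig2"),
                                    seed = 1L) {
  if (n_row < 2 || n_col < 2) stop("grid must be at least 2 x 2")
  if (abs(colocalization) > 1) stop("|colocalization| must be <= 1")
  stopifnot(length(signature_names) == 2)
  spots <- tidyr::expand_grid(row = seq_len(n_row), col = seq_len(n_col))
  spots$spot_id <- sprintf("s%05d", seq_len(nrow(spots)))
  if (is.null(region_map)) {
    spots$region <- ifelse(
      spots$row <= n_row / 2, "infiltrative_cortex", "cellular_tumor"
    )
  } else {
    spots <- dplyr::left_join(spots, region_map, by = c("row", "col"))
    if (anyNA(spots$region)) stop("region_map does not cover every spot")
  }
  fields <- withr::with_seed(seed, {
    f1 <- .smooth_grid(matrix(stats::rnorm(n_row * n_col), n_row), field_scale)
    f2 <- .smooth_grid(matrix(stats::rnorm(n_row * n_col), n_row), field_scale)
    f1 <- f1[cbind(spots$row, spots$col)]
    f2 <- f2[cbind(spots$row, spots$col)]
    s1 <- numeric(length(f1)); s2 <- numeric(length(f1))
    # The pair is calibrated within each labeled region: smoothed fields
    # have few effective degrees of freedom, so the sample correlation of
    # two independent fields over a region is far from its expectation.
    # Standardizing and empirically orthogonalizing per region makes the
    # planted cross-correlation hold exactly in-sample (before noise).
    for (reg in unique(spots$region)) {
      idx <- spots$region == reg
      std <- function(x) (x - mean(x)) / stats::sd(x)
      a <- std(f1[idx])
      b <- std(f2[idx])
      b <- std(b - mean(a * b) / mean(a * a) * a)
      s1[idx] <- a
      s2[idx] <- colocalization * a + sqrt(1 - colocalization^2) * b
    }
    list(
      s1 = s1 + stats::rnorm(length(s1), sd = noise_sd),
      s2 = s2 + stats::rnorm(length(s2), sd = noise_sd)
    )
  })
  spots[[signature_names[1]]] <- fields$s1
  spots[[signature_names[2]]] <- fields$s2
  spots <- dplyr::relocate(spots, "spot_id")
  list(
    spots = spots,
    truth = list(
      colocalization = colocalization, noise_sd = noise_sd,
      field_scale = field_scale, seed = seed
    )
  )
}

#' Simulate a site-level phospho log2FC table with planted kinase activity
#'
#' Background sites draw log2 fold-changes from `N(0, noise_sd^2)`;
#' substrate sites of active kinases are additionally shifted by the
#' kinase's planted effect (sites of several active kinases accumulate
#' their effects). Filler background sites are appended up to `n_sites`.
#'
#' @param map tibble with columns `kinase`, `site`.
#' @param active named numeric vector, kinase -> log2FC effect; every name
#'   must appear in `map`.
#' @param n_sites total number of sites in the table (at least the number
#'   of mapped sites).
#' @param noise_sd background standard deviation of site log2FCs.
#' @param seed integer seed.
#' @return A list with `table` (tibble `site`, `log2fc`, `p_adj`) and
#'   `truth` (the planted effects).
#' @export
simulate_phospho_table <- function(map, active = numeric(), n_sites = 500,
                                   noise_sd = 0.5, seed = 1L) {
  stopifnot(is.data.frame(map), all(c("kinase", "site") %in% names(map)))
  if (length(active) > 0 && !all(names(active) %in% map$kinase)) {
    stop("active kinases absent from the map: ",
         paste(setdiff(names(active), map$kinase), collapse = ", "))
  }
  sites <- unique(map$site)
  if (n_sites < length(sites)) stop("n_sites smaller than the mapped sites")
  filler <- sprintf("bg%05d_S1", seq_len(n_sites - length(sites)))
  all_sites <- c(sites, filler)
  tab <- withr::with_seed(seed, {
    fc <- stats::rnorm(length(all_sites), 0, noise_sd)
    names(fc) <- all_sites
    for (k in names(active)) {
      subs <- map$site[map$kinase == k]
      fc[subs] <- fc[subs] + active[[k]]
    }
    fc
  })
  z <- tab / noise_sd
  tibble_out <- tibble::tibble(
    site = all_sites,
    log2fc = as.numeric(tab),
    p_adj = stats::p.adjust(2 * stats::pnorm(-abs(z)), "BH")
  )
  list(
    table = tibble_out,
    truth = list(active = active, noise_sd = noise_sd, seed = seed)
  )
}

#' Simulate dye-dilution records
#'
#' A proliferation dye halves at each division, so after `x_true` divisions
#' the final mean fluorescence intensity is `mfi_initial / 2^x_true`, here
#' multiplied by lognormal measurement noise with log-sd `cv`.
#'
#' @param x_true numeric vector of true division numbers (>= 0).
#' @param mfi_initial initial MFI (fluorescence units).
#' @param cv log-scale standard deviation of the multiplicative noise.
#' @param elapsed elapsed time in hours.
#' @param seed integer seed.
#' @return A list with `records` (tibble `record_id`, `mfi_initial`,
#'   `mfi_final`, `elapsed`) and `truth` (`x_true`).
#' @export
simulate_dye_dilution <- function(x_true, mfi_initial = 800, cv = 0.1,
                                  elapsed = 72, seed = 1L) {
  if (any(x_true < 0)) stop("x_true must be >= 0")
  noise <- withr::with_seed(seed, stats::rlnorm(length(x_true), 0, cv))
  list(
    records = tibble::tibble(
      record_id = sprintf("r%04d", seq_along(x_true)),
      mfi_initial = mfi_initial,
      mfi_final = mfi_initial / 2^x_true * noise,
      elapsed = elapsed
    ),
    truth = tibble::tibble(
      record_id = sprintf("r%04d", seq_along(x_true)), x_true = x_true
    )
  )
}

.dist_point_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) {
    rep(0, length(px))
  } else {
    pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  }
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

# Min distance from points (x, y) to every polyline in `segments`
# (tibble segment_id, vertex, x, y with vertices ordered within segment).
.dist_to_vessels <- function(x, y, segments) {
  d <- rep(Inf, length(x))
  for (sid in unique(segments$segment_id)) {
    sv <- segments[segments$segment_id == sid, ]
    sv <- sv[order(sv$vertex), ]
    for (i in seq_len(nrow(sv) - 1)) {
      d <- pmin(d, .dist_point_segment(
        x, y, sv$x[i], sv$y[i], sv$x[i + 1], sv$y[i + 1]
      ))
    }
  }
  d
}

#' Simulate a vessel co-culture scene
#'
#' Places vessel segments and cells of two reporter classes (`NesHI`,
#' `NesLO`) in a 2-D field. Each cell attaches to a vessel with its
#' class's `association_bias` probability: attached cells are placed
#' within `contact_radius` of a segment, unattached cells are
#' rejection-sampled strictly beyond it, so the planted bias is the exact
#' attachment probability. The left half of the field is labeled
#' `invasive_front`, the right half `core`.
#'
#' @param n_cells total cells (split evenly between classes).
#' @param n_segments number of straight vessel segments (>= 1).
#' @param association_bias named vector of attachment probabilities per
#'   class, e.g. `c(NesHI = 0.8, NesLO = 0.3)`.
#' @param contact_radius attachment distance threshold (distance units).
#' @param field_size width and height of the field.
#' @param seed integer seed.
#' @return A list with `cells` (tibble `cell_id`, `x`, `y`, `class`,
#'   `region`), `segments` (tibble `segment_id`, `vertex`, `x`, `y`),
#'   `contact_radius`, and `truth` (per-cell attachment flags).
#' @export
simulate_vessel_scene <- function(n_cells = 400, n_segments = 5,
                                  association_bias = c(NesHI = 0.8, NesLO = 0.3),
                                  contact_radius = 5,
                                  field_size = c(500, 500), seed = 1L) {
  if (n_segments < 1) stop("need at least one vessel segment")
  if (n_cells < 1) stop("scene must contain cells")
  stopifnot(!is.null(names(association_bias)))
  withr::with_seed(seed, {
    segments <- purrr::map_dfr(seq_len(n_segments), function(i) {
      tibble::tibble(
        segment_id = sprintf("v%02d", i), vertex = 1:2,
        x = stats::runif(2, 0, field_size[1]),
        y = stats::runif(2, 0, field_size[2])
      )
    })
    classes <- rep(names(association_bias), length.out = n_cells)
    attached <- stats::runif(n_cells) < association_bias[classes]
    x <- numeric(n_cells); y <- numeric(n_cells)
    seg_ids <- unique(segments$segment_id)
    for (i in seq_len(n_cells)) {
      if (attached[i]) {
        sv <- segments[segments$segment_id == sample(seg_ids, 1), ]
        t <- stats::runif(1)
        px <- sv$x[1] + t * (sv$x[2] - sv$x[1])
        py <- sv$y[1] + t * (sv$y[2] - sv$y[1])
        ang <- stats::runif(1, 0, 2 * pi)
        r <- stats::runif(1, 0, contact_radius)
        x[i] <- px + r * cos(ang); y[i] <- py + r * sin(ang)
      } else {
        repeat {
          x[i] <- stats::runif(1, 0, field_size[1])
          y[i] <- stats::runif(1, 0, field_size[2])
          if (.dist_to_vessels(x[i], y[i], segments) > contact_radius) break
        }
      }
    }
    cells <- tibble::tibble(
      cell_id = sprintf("cell%04d", seq_len(n_cells)),
      x = x, y = y, class = classes,
      region = ifelse(x < field_size[1] / 2, "invasive_front", "core")
    )
    list(
      cells = cells, segments = segments, contact_radius = contact_radius,
      truth = tibble::tibble(
        cell_id = cells$cell_id, class = classes, attached = attached
      )
    )
  })
}
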