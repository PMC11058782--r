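#' Signed ranking statistic from a bulk contrast
#'
#' Scales bulk counts by median-of-ratios size factors and ranks genes by
#' the log2 fold-change of scaled group means (with a pseudocount), the
#' input expected by [preranked_enrichment()].
#'
#' @param counts genes x samples bulk count matrix.
#' @param group character/factor vector of sample groups.
#' @param treated,reference group levels contrasted as
#'   `log2(treated / reference)`.
#' @param pseudocount added to both scaled means (default 1).
#' @return A tibble with `gene`, `stat`.
#' @export
bulk_contrast_ranking <- function(counts, group, treated, reference,
                                  pseudocount = 1) {
  stopifnot(length(group) == ncol(counts))
  stopifnot(treated %in% group, reference %in% group)
  sf <- median_of_ratios(counts)$size_factor
  scaled <- sweep(counts, 2, sf, "/")
  mt <- rowMeans(scaled[, group == treated, drop = FALSE])
  mr <- rowMeans(scaled[, group == reference, drop = FALSE])
  tibble::tibble(
    gene = rownames(counts),
    stat = log2((mt + pseudocount) / (mr + pseudocount))
  )
}

# Sum single-cell counts into n_rep pseudo-bulk replicates (cells split
# round-robin so replicates are balanced).
.pseudobulk <- function(m, n_rep = 3, prefix = "s") {
  v <- as.matrix(em_values(m))
  grp <- rep_len(seq_len(n_rep), ncol(v))
  out <- vapply(
    seq_len(n_rep),
    function(i) rowSums(v[, grp == i, drop = FALSE]),
    numeric(nrow(v))
  )
  colnames(out) <- sprintf("%s%d", prefix, seq_len(n_rep))
  out
}

.write_csv_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  readr::write_csv(x, tmp)
  file.rename(tmp, path)
  invisible(path)
}

.write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

# Run manifest: parameters, seeds, versions and file checksums, written
# beside every stage's outputs so a run can be reproduced bit-identically.
.write_manifest <- function(dir, stage, params, inputs = character(),
                            outputs = character()) {
  checks <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  .write_json_atomic(
    list(
      stage = stage,
      params = params,
      package = "gliomastate",
      package_version = as.character(utils::packageVersion("gliomastate")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      input_md5 = checks(inputs),
      output_md5 = checks(outputs)
    ),
    file.path(dir, sprintf("manifest_%s.json", stage))
  )
}

.check_known_keys <- function(params, known, stage) {
  unknown <- setdiff(names(params), known)
  if (length(unknown) > 0) {
    stop(sprintf(
      "unknown config key(s) for stage '%s': %s",
      stage, paste(unknown, collapse = ", ")
    ))
  }
  invisible(params)
}

#' Run one pipeline stage on files
#'
#' File-in/file-out façade over the package's functions: each stage reads
#' its documented inputs, writes its outputs atomically into `out_dir`,
#' and drops a JSON run manifest (parameters, seed, package and R
#' versions, input/output checksums). Unknown configuration keys are
#' rejected. Stages: `simulate` (naive counts + metadata + marker-set
#' GMT + truth), `qc`, `score` (scores, states and butterfly
#' coordinates), `markers`, `enrich`, `spatial` (weighted correlation),
#' `ksea`, `quant` (dye-dilution divisions).
#'
#' @param stage stage name.
#' @param config named list of stage parameters, or the path of a YAML
#'   file with one top-level section per stage.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the stage's main result and the paths
#'   written.
#' @export
run_stage <- function(stage = c(
                        "simulate", "qc", "score", "markers",
                        "enrich", "spatial", "ksea", "quant"
                      ),
                      config = list(), out_dir = ".") {
  stage <- match.arg(stage)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    config <- config[[stage]] %||% list()
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(key) {
    if (is.null(config[[key]])) stop(sprintf("stage '%s' needs config key '%s'", stage, key))
    config[[key]]
  }
  need_file <- function(key) {
    p <- need(key)
    if (!file.exists(p)) stop("input not found: ", p)
    p
  }
  switch(stage,
    simulate = {
      .check_known_keys(config, c(
        "n_cells", "n_genes", "markers_per_state", "marker_effect",
        "nb_dispersion", "reprogram_fraction", "seed", "treated"
      ), stage)
      cfg <- do.call(sim_config, config[setdiff(names(config), "treated")])
      sim <- if (isTRUE(config$treated)) {
        simulate_treated_counts(cfg)
      } else {
        simulate_state_counts(cfg)
      }
      mtx_dir <- file.path(out_dir, "counts")
      write_expression_mtx(sim$expr, mtx_dir)
      .write_csv_atomic(sim$cell_meta, file.path(out_dir, "cell_meta.csv"))
      write_gmt(sim$catalog, file.path(out_dir, "state_markers.gmt"))
      .write_csv_atomic(sim$truth$cells, file.path(out_dir, "truth_cells.csv"))
      .write_csv_atomic(sim$truth$genes, file.path(out_dir, "truth_genes.csv"))
      .write_json_atomic(
        unclass(cfg)[setdiff(names(cfg), "state_proportions")],
        file.path(out_dir, "truth_params.json")
      )
      outs <- file.path(out_dir, c(
        "cell_meta.csv", "state_markers.gmt", "truth_cells.csv",
        "truth_genes.csv", "truth_params.json"
      ))
      .write_manifest(out_dir, stage, unclass(cfg), outputs = outs)
      invisible(list(result = sim, paths = c(mtx_dir, outs)))
    },
    qc = {
      .check_known_keys(config, c(
        "input", "umi_min", "umi_max", "mito_max", "mito_prefix"
      ), stage)
      m <- read_expression_mtx(need_file("input"))
      kept <- qc_filter(
        m,
        umi_min = config$umi_min %||% 4000,
        umi_max = config$umi_max %||% 11000,
        mito_max = config$mito_max %||% 0.20,
        mito_prefix = config$mito_prefix %||% "MT-"
      )
      mtx_dir <- file.path(out_dir, "counts_qc")
      write_expression_mtx(kept, mtx_dir)
      qc_path <- file.path(out_dir, "qc_report.csv")
      .write_csv_atomic(attr(kept, "qc"), qc_path)
      .write_manifest(
        out_dir, stage, config,
        inputs = file.path(need("input"), "matrix.mtx"), outputs = qc_path
      )
      invisible(list(result = kept, paths = c(mtx_dir, qc_path)))
    },
    score = {
      .check_known_keys(config, c("input", "gmt", "n_bins", "k", "seed"), stage)
      m <- read_expression_mtx(need_file("input"))
      sets <- read_gmt(need_file("gmt"))
      ln <- lognormalize(m)
      bins <- bin_by_aggregate_expression(ln, n_bins = config$n_bins %||% 30)
      scores <- score_states(
        relative_expression(ln), sets, bins,
        k = config$k %||% 100, seed = config$seed %||% 1L
      )
      coords <- butterfly_coordinates(scores)
      p1 <- file.path(out_dir, "state_scores.csv")
      p2 <- file.path(out_dir, "butterfly_coordinates.csv")
      .write_csv_atomic(scores, p1)
      .write_csv_atomic(coords, p2)
      .write_manifest(
        out_dir, stage, config,
        inputs = c(file.path(need("input"), "matrix.mtx"), need("gmt")),
        outputs = c(p1, p2)
      )
      invisible(list(result = list(scores = scores, coords = coords), paths = c(p1, p2)))
    },
    markers = {
      .check_known_keys(config, c("input", "cell_meta", "min_lfc", "min_pct"), stage)
      m <- read_expression_mtx(need_file("input"))
      meta <- readr::read_csv(need_file("cell_meta"), show_col_types = FALSE)
      names(meta)[names(meta) == "state"] <- "cluster"
      mk <- derive_cluster_markers(
        lognormalize(m), meta,
        min_lfc = config$min_lfc %||% 0.5, min_pct = config$min_pct %||% 0.75
      )
      p <- file.path(out_dir, "cluster_markers.csv")
      .write_csv_atomic(mk, p)
      .write_manifest(
        out_dir, stage, config,
        inputs = c(file.path(need("input"), "matrix.mtx"), need("cell_meta")),
        outputs = p
      )
      invisible(list(result = mk, paths = p))
    },
    enrich = {
      .check_known_keys(config, c(
        "ranking", "gmt", "n_perm", "weight_exp", "seed", "q_threshold"
      ), stage)
      ranking <- readr::read_tsv(
        need_file("ranking"),
        col_names = c("gene", "stat"), show_col_types = FALSE
      )
      sets <- read_gmt(need_file("gmt"))
      enr <- preranked_enrichment(
        ranking, sets,
        n_perm = config$n_perm %||% 1000,
        weight_exp = config$weight_exp %||% 1,
        seed = config$seed %||% 1L
      )
      calls <- classify_paired_enrichment(
        tidy(enr),
        q_threshold = config$q_threshold %||% 0.25
      )
      p <- file.path(out_dir, "enrichment.csv")
      .write_csv_atomic(calls, p)
      .write_manifest(
        out_dir, stage, config,
        inputs = c(need("ranking"), need("gmt")), outputs = p
      )
      invisible(list(result = calls, paths = p))
    },
    spatial = {
      .check_known_keys(config, c("spots", "signatures", "bandwidth"), stage)
      spots <- readr::read_csv(need_file("spots"), show_col_types = FALSE)
      sigs <- need("signatures")
      mats <- lapply(unique(spots$region), function(reg) {
        weighted_correlation(
          spots, sigs, reg,
          bandwidth = config$bandwidth %||% 1.5
        )
      })
      names(mats) <- unique(spots$region)
      out <- purrr::imap_dfr(mats, function(m, reg) {
        df <- as.data.frame(as.table(m))
        names(df) <- c("signature_a", "signature_b", "correlation")
        df$region <- reg
        df
      })
      p <- file.path(out_dir, "spatial_correlation.csv")
      .write_csv_atomic(out, p)
      .write_manifest(out_dir, stage, config, inputs = need("spots"), outputs = p)
      invisible(list(result = mats, paths = p))
    },
    ksea = {
      .check_known_keys(config, c(
        "phospho", "map", "min_substrates", "p_threshold"
      ), stage)
      tab <- readr::read_tsv(need_file("phospho"), show_col_types = FALSE)
      map <- readr::read_tsv(need_file("map"), show_col_types = FALSE)
      res <- ksea_zscores(
        tab, map,
        min_substrates = config$min_substrates %||% 5,
        p_threshold = config$p_threshold %||% 0.01
      )
      p <- file.path(out_dir, "kinase_activity.csv")
      .write_csv_atomic(tidy(res), p)
      .write_manifest(
        out_dir, stage, config,
        inputs = c(need("phospho"), need("map")), outputs = p
      )
      invisible(list(result = res, paths = p))
    },
    quant = {
      .check_known_keys(config, c("dye"), stage)
      rec <- readr::read_csv(need_file("dye"), show_col_types = FALSE)
      res <- division_number(rec)
      p <- file.path(out_dir, "divisions.csv")
      .write_csv_atomic(res, p)
      .write_manifest(out_dir, stage, config, inputs = need("dye"), outputs = p)
      invisible(list(result = res, paths = p))
    }
  )
}

#' Run the full synthetic study workflow
#'
#' End-to-end run on synthetic data: simulate a naive and a treated
#' (hybrid-reprogrammed) sample, QC-filter, normalize and score the four
#' state meta-modules, classify cells and compute the butterfly
#' projection, derive hybrid-state markers and select the top signature,
#' build a pseudo-bulk treated-vs-naive ranking with median-of-ratios
#' scaling, and test the signature's enrichment. All artifacts plus a run
#' manifest are written under `out_dir`.
#'
#' @param out_dir output directory.
#' @param seed integer seed driving every random stage.
#' @param config a [sim_config()] (its seed is overridden by `seed`).
#' @param signature_size therapy-signature size (default 150; fewer
#'   available genes are kept with a warning).
#' @param n_perm permutations for the enrichment test.
#' @param umi_min,umi_max,mito_max QC gates passed to [qc_filter()].
#' @return A list with `accuracy` (4-way classification accuracy vs truth
#'   on non-hybrid cells), `signature`, `enrichment` (tidy tibble with
#'   call), and `paths`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = sim_config(seed = seed),
                         signature_size = 150, n_perm = 1000,
                         umi_min = 4000, umi_max = 11000, mito_max = 0.20) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- as.integer(seed)
  naive <- simulate_state_counts(config)
  treated <- simulate_treated_counts(config, seed = config$seed + 1L)

  # QC + scoring on both samples
  classify_sample <- function(sim, seed) {
    ln <- lognormalize(qc_filter(sim$expr, umi_min, umi_max, mito_max))
    bins <- bin_by_aggregate_expression(ln)
    scores <- score_states(relative_expression(ln), sim$catalog, bins, seed = seed)
    list(ln = ln, scores = scores, coords = butterfly_coordinates(scores))
  }
  cn <- classify_sample(naive, seed)
  ct <- classify_sample(treated, seed)
  scores <- cn$scores
  coords <- cn$coords
  truth <- naive$truth$cells
  joined <- dplyr::inner_join(
    coords, truth[truth$state != "HYBRID", ],
    by = "cell_id"
  )
  accuracy <- mean(joined$assigned_state == joined$state)

  # Therapy-enriched state: largest classified-proportion increase under
  # treatment (hybrid reprogramming raises its component families)
  prop <- function(coords) {
    table(factor(coords$assigned_state, levels = .state_priority)) /
      nrow(coords)
  }
  shift <- prop(ct$coords) - prop(cn$coords)
  enriched_state <- names(shift)[which.max(shift)]

  # Therapy-induced signature: top markers of the enriched state in the
  # naive sample (classified states as clusters)
  mk <- derive_cluster_markers(
    cn$ln,
    data.frame(cell_id = cn$coords$cell_id, cluster = cn$coords$assigned_state)
  )
  signature <- suppressWarnings(
    select_top_signature(mk, n = signature_size, cluster = enriched_state)
  )

  # Pseudo-bulk contrast and enrichment of the signature
  bulk <- cbind(
    .pseudobulk(naive$expr, prefix = "naive_"),
    .pseudobulk(treated$expr, prefix = "treated_")
  )
  ranking <- bulk_contrast_ranking(
    bulk,
    group = rep(c("naive", "treated"), each = 3),
    treated = "treated", reference = "naive"
  )
  enr <- preranked_enrichment(
    ranking, list(therapy_signature = signature),
    n_perm = n_perm, seed = seed
  )
  calls <- classify_paired_enrichment(tidy(enr))

  paths <- c(
    scores = file.path(out_dir, "state_scores.csv"),
    coords = file.path(out_dir, "butterfly_coordinates.csv"),
    markers = file.path(out_dir, "cluster_markers.csv"),
    signature = file.path(out_dir, "therapy_signature.gmt"),
    ranking = file.path(out_dir, "bulk_ranking.tsv"),
    enrichment = file.path(out_dir, "enrichment.csv")
  )
  .write_csv_atomic(scores, paths[["scores"]])
  .write_csv_atomic(coords, paths[["coords"]])
  .write_csv_atomic(mk, paths[["markers"]])
  write_gmt(list(therapy_signature = signature), paths[["signature"]])
  readr::write_tsv(ranking, paths[["ranking"]], col_names = FALSE)
  .write_csv_atomic(calls, paths[["enrichment"]])
  .write_manifest(
    out_dir, "pipeline",
    params = list(
      seed = seed, signature_size = signature_size, n_perm = n_perm,
      umi_min = umi_min, umi_max = umi_max, mito_max = mito_max,
      config = unclass(config)[setdiff(names(config), "state_proportions")],
      state_proportions = as.list(config$state_proportions)
    ),
    outputs = unname(paths)
  )
  list(
    accuracy = accuracy, signature = signature, enrichment = calls,
    paths = paths
  )
}
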