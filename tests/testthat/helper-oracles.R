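# Small fixture builders and independent oracles shared across tests.

make_counts <- function(vals, genes = NULL, cells = NULL) {
  vals <- as.matrix(vals)
  rownames(vals) <- genes %||% sprintf("g%03d", seq_len(nrow(vals)))
  colnames(vals) <- cells %||% sprintf("c%03d", seq_len(ncol(vals)))
  expr_matrix(vals, layer = "counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent enrichment-score oracle: full running sum over all N ranks,
# extreme deviation, sign ties resolving positive (documented contract).
brute_force_es <- function(stat, hits, weight_exp = 0) {
  stopifnot(length(stat) == length(hits))
  if (all(hits)) return(1)
  w <- abs(stat)^weight_exp
  w[!hits] <- 0
  if (sum(w) == 0) w[hits] <- 1
  inc <- w / sum(w)
  dec <- (!hits) / sum(!hits)
  path <- cumsum(inc - dec)
  ma <- max(path)
  mi <- min(path)
  if (ma >= -mi - 1e-9) ma else mi
}

# Independent point-to-polyline distance oracle: scalar loops, distance
# taken as the minimum over both endpoints and (when the perpendicular
# foot falls inside the segment) the point-to-line distance.
brute_force_dist <- function(px, py, segments) {
  best <- Inf
  for (sid in unique(segments$segment_id)) {
    sv <- segments[segments$segment_id == sid, ]
    sv <- sv[order(sv$vertex), ]
    for (i in seq_len(nrow(sv) - 1)) {
      a <- c(sv$x[i], sv$y[i]); b <- c(sv$x[i + 1], sv$y[i + 1]); p <- c(px, py)
      best <- min(best, sqrt(sum((p - a)^2)), sqrt(sum((p - b)^2)))
      len2 <- sum((b - a)^2)
      if (len2 > 0) {
        tt <- sum((p - a) * (b - a)) / len2
        if (tt > 0 && tt < 1) {
          foot <- a + tt * (b - a)
          best <- min(best, sqrt(sum((p - foot)^2)))
        }
      }
    }
  }
  best
}

# Deterministic small state simulation used by several test files.
small_sim <- function(n_cells = 400, n_genes = 300, effect = 1, seed = 11,
                      markers = 15) {
  simulate_state_counts(sim_config(
    n_cells = n_cells, n_genes = n_genes, markers_per_state = markers,
    marker_effect = effect, seed = seed
  ))
}

score_pipeline <- function(sim, seed = 1) {
  ln <- lognormalize(sim$expr)
  bins <- bin_by_aggregate_expression(ln)
  rel <- relative_expression(ln)
  score_states(rel, sim$catalog, bins, seed = seed)
}
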