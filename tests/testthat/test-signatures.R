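test_that("rank-sum statistics match wilcox.test on every gene", {
  set.seed(41)
  v <- matrix(rnorm(20 * 30), 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:30)))
  v[3, ] <- round(v[3, ])  # force ties
  ing <- rep(c(TRUE, FALSE), c(12, 18))
  got <- gliomastate:::.rank_sum_rows(v, ing)
  ref <- apply(v, 1, function(x) {
    wilcox.test(x[ing], x[!ing], exact = FALSE, correct = TRUE)$p.value
  })
  expect_equal(got$p, unname(ref), tolerance = 1e-10)
})

test_that("planted state markers top their cluster's marker list", {
  sim <- small_sim(n_cells = 600, n_genes = 400, effect = 1.5, seed = 13)
  mk <- derive_cluster_markers(lognormalize(sim$expr), sim$truth$cells$state)
  truth <- sim$truth$genes
  for (st in c("NPC", "OPC", "AC", "MES")) {
    top <- head(mk$gene[mk$cluster == st], 10)
    planted <- truth$gene[truth$marker_of %in% st]
    expect_gte(sum(top %in% planted), 8)
  }
})

test_that("marker thresholds have exact semantics", {
  # one gene identical in both groups, one gene with a single zero in-group
  v <- rbind(
    same = rep(2, 10),
    almost = c(0, rep(3, 4), rep(0.1, 5)),
    up = c(rep(4, 5), rep(1, 5))
  )
  colnames(v) <- sprintf("c%02d", 1:10)
  m <- expr_matrix(v, layer = "lognorm")
  labels <- rep(c("a", "b"), each = 5)
  mk <- derive_cluster_markers(m, labels, min_lfc = 0.5, min_pct = 1.0)
  expect_false("same" %in% mk$gene)    # lfc 0 < 0.5
  expect_false("almost" %in% mk$gene)  # pct_in 0.8 < 1.0
  expect_true("up" %in% mk$gene[mk$cluster == "a"])
  expect_error(derive_cluster_markers(m, rep("a", 10)), "2 clusters")
  expect_error(derive_cluster_markers(m, c(rep("a", 2), rep("b", 8))), "3 cells")
})

test_that("select_top_signature honours the sort order and warns when short", {
  mk <- tibble::tibble(
    cluster = "x", gene = paste0("g", 1:5),
    lfc = 5:1, p_adj = c(0.001, 0.002, 0.01, 0.02, 0.04)
  )
  expect_equal(select_top_signature(mk, n = 1), "g1")
  expect_equal(select_top_signature(mk, n = 3), paste0("g", 1:3))
  expect_warning(out <- select_top_signature(mk, n = 10), "available")
  expect_equal(out, mk$gene)
  expect_identical(select_top_signature(mk, n = 3), select_top_signature(mk, n = 3))
})

test_that("common_upregulated counts set membership, order-invariantly", {
  four <- list(a = c("x", "y"), b = c("x", "y"), c = c("x", "y"), d = c("x", "y"))
  out <- common_upregulated(four, min_membership = 3)
  expect_equal(out$gene, c("x", "y"))
  expect_equal(out$n_sets, c(4, 4))

  disjoint <- list(a = "x", b = "y", c = "z", d = "w")
  expect_equal(nrow(common_upregulated(disjoint, 3)), 0)

  set.seed(44)
  sets <- lapply(1:4, function(i) sample(paste0("g", 1:30), 15))
  names(sets) <- paste0("s", 1:4)
  out2 <- common_upregulated(sets, 3)
  counts <- table(unlist(lapply(sets, unique)))
  oracle <- sort(names(counts)[counts >= 3])
  expect_equal(sort(out2$gene), oracle)
  shuffled <- common_upregulated(rev(sets), 3)
  expect_equal(
    dplyr::arrange(out2[, c("gene", "n_sets")], gene),
    dplyr::arrange(shuffled[, c("gene", "n_sets")], gene)
  )
})

test_that("single-gene sets at the extremes give ES of +1 and -1", {
  stat <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  top <- preranked_enrichment(stat, list(s = "a"), n_perm = 10,
                              weight_exp = 0, min_overlap = 1, seed = 1)
  expect_equal(tidy(top)$ES, 1)
  bottom <- preranked_enrichment(stat, list(s = "e"), n_perm = 10,
                                 weight_exp = 0, min_overlap = 1, seed = 1)
  expect_equal(tidy(bottom)$ES, -1)
})

test_that("streaming ES equals the brute-force running-sum oracle exhaustively", {
  set.seed(45)
  stat <- sort(rnorm(8), decreasing = TRUE)
  names(stat) <- paste0("g", 1:8)
  for (i in 1:255) {
    hits <- as.logical(intToBits(i)[1:8])
    pos <- which(hits)
    for (we in c(0, 1)) {
      mine <- gliomastate:::.es_from_hits(pos, abs(stat[pos])^we, 8)
      oracle <- brute_force_es(stat, hits, we)
      expect_equal(mine, oracle, tolerance = 1e-12)
    }
  }
})

test_that("ES is antisymmetric under ranking negation", {
  set.seed(46)
  for (rep in 1:20) {
    stat <- rnorm(40)
    names(stat) <- sprintf("g%02d", 1:40)
    set <- sample(names(stat), 8)
    es1 <- tidy(preranked_enrichment(stat, list(s = set), n_perm = 5,
                                     weight_exp = 0, seed = 1))$ES
    es2 <- tidy(preranked_enrichment(-stat, list(s = set), n_perm = 5,
                                     weight_exp = 0, seed = 1))$ES
    expect_equal(es1, -es2, tolerance = 1e-12)
  }
})

test_that("enrichment validates its inputs and is seed-reproducible", {
  stat <- setNames(rnorm(20), paste0("g", 1:20))
  expect_error(
    preranked_enrichment(stat, list(s = c("g1", "g2")), seed = 1),
    "need >= 3"
  )
  expect_error(
    preranked_enrichment(setNames(rep(0, 5), paste0("g", 1:5)),
                         list(s = "g1"), min_overlap = 1),
    "all-zero"
  )
  expect_error(
    preranked_enrichment(setNames(c(1, 2), c("a", "a")), list(s = "a"),
                         min_overlap = 1),
    "duplicate"
  )
  a <- tidy(preranked_enrichment(stat, list(s = paste0("g", 1:5)),
                                 n_perm = 50, seed = 3))
  b <- tidy(preranked_enrichment(stat, list(s = paste0("g", 1:5)),
                                 n_perm = 50, seed = 3))
  expect_identical(a, b)
})

test_that("ES agrees with fgsea on a shared ranking", {
  set.seed(47)
  stat <- rnorm(100)
  names(stat) <- sprintf("g%03d", 1:100)
  sets <- list(
    up = names(sort(stat, decreasing = TRUE))[1:10],
    rand = sample(names(stat), 15)
  )
  mine <- tidy(preranked_enrichment(stat, sets, n_perm = 10, seed = 1))
  ref <- suppressWarnings(fgsea::fgsea(sets, stat, nPermSimple = 101))
  expect_equal(mine$ES, ref$ES[match(mine$set, ref$pathway)], tolerance = 1e-6)
})

test_that("paired calls follow the q threshold with an inclusive boundary", {
  grid <- tibble::tibble(
    patient = paste0("p", 1:6),
    NES = c(2.0, -1.8, 3.0, -2.5, 0.5, -0.5),
    q = c(0.01, 0.24, 0.25, 0.26, 0.249, 0.3)
  )
  calls <- classify_paired_enrichment(grid)
  expect_equal(calls$call, c(
    "enriched_up", "enriched_down", "no_change", "no_change",
    "enriched_up", "no_change"
  ))
  expect_equal(calls$patient, grid$patient)  # extra columns preserved
})

test_that("proteomic state scores average finite log2 ratios only", {
  sets <- list(MES = c("m1", "m2", "m3"))
  zero <- tidyr::expand_grid(gene = c("m1", "m2", "m3"), timepoint = "6h")
  zero$log2_ratio <- 0
  expect_equal(proteomic_state_scores(zero, sets)$score, 0)

  inf_tab <- tibble::tibble(
    gene = c("m1", "m2", "m3"), timepoint = "6h",
    log2_ratio = c(Inf, 1, 1)
  )
  out <- proteomic_state_scores(inf_tab, sets)
  expect_equal(out$score, 1)
  expect_equal(out$n_used, 2)

  fix <- tibble::tibble(
    gene = rep(c("m1", "m2"), 2),
    timepoint = rep(c("6h", "72h"), each = 2),
    log2_ratio = c(0.5, 1.5, -1, 3)
  )
  out2 <- proteomic_state_scores(fix, list(MES = c("m1", "m2")))
  expect_equal(out2$score[out2$timepoint == "6h"], 1.0)
  expect_equal(out2$score[out2$timepoint == "72h"], 1.0)
})

test_that("tidy, glance and autoplot work on enrichment objects", {
  stat <- setNames(rnorm(30), paste0("g", 1:30))
  e <- preranked_enrichment(stat, list(s = paste0("g", 1:6)), n_perm = 20, seed = 2)
  expect_s3_class(tidy(e), "tbl_df")
  expect_equal(glance(e)$n_sets, 1)
  expect_s3_class(autoplot(e), "ggplot")
})
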