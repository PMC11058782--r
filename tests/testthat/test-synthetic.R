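test_that("the generator is deterministic and its truth is complete", {
  cfg <- sim_config(n_cells = 150, n_genes = 200, seed = 42)
  a <- simulate_state_counts(cfg)
  b <- simulate_state_counts(cfg)
  expect_identical(em_values(a$expr), em_values(b$expr))
  expect_identical(a$truth$cells, b$truth$cells)
  # every cell and gene appears exactly once in the truth
  expect_setequal(a$truth$cells$cell_id, em_cells(a$expr))
  expect_false(anyDuplicated(a$truth$cells$cell_id) > 0)
  expect_setequal(a$truth$genes$gene, em_genes(a$expr))
  # the catalog holds the four planted marker sets
  expect_named(a$catalog, c("NPC", "OPC", "AC", "MES"), ignore.order = TRUE)
  for (st in names(a$catalog)) {
    expect_setequal(
      a$catalog[[st]],
      a$truth$genes$gene[!is.na(a$truth$genes$marker_of) &
                           a$truth$genes$marker_of == st]
    )
  }
})

test_that("config invariants are enforced", {
  expect_error(sim_config(state_proportions = c(
    NPC = 0.5, OPC = 0.5, AC = 0.5, MES = 0, HYBRID = 0
  )), "sum to 1")
  expect_error(sim_config(n_genes = 50, markers_per_state = 30), "too small")
  expect_error(sim_config(reprogram_fraction = 1.5), "\\[0, 1\\]")
})

test_that("planted marker effects are recovered from the generated counts", {
  cfg <- sim_config(n_cells = 1500, n_genes = 1000, marker_effect = 1, seed = 2)
  sim <- simulate_state_counts(cfg)
  counts <- em_values(sim$expr)
  truth <- sim$truth
  # mean log2 ratio of a state's markers, state cells vs other pure states
  diffs <- vapply(c("NPC", "OPC", "AC", "MES"), function(st) {
    mk <- truth$genes$gene[truth$genes$marker_of %in% st]
    own <- truth$cells$state == st
    other <- !(truth$cells$state %in% c(st, "HYBRID"))
    mean(log2(rowMeans(counts[mk, own]) / rowMeans(counts[mk, other])))
  }, numeric(1))
  expect_true(all(abs(diffs - 1) < 0.1))
})

test_that("no marker effect means chance-level classification", {
  sim <- small_sim(n_cells = 400, n_genes = 300, effect = 0, seed = 4)
  cls <- classify_states(score_pipeline(sim))
  truth <- sim$truth$cells
  non_hyb <- truth$state != "HYBRID"
  acc <- mean(cls$state[non_hyb] == truth$state[non_hyb])
  expect_lt(acc, 0.40)  # chance is 0.25
})

test_that("treatment reprogramming hits the planted fraction", {
  cfg <- sim_config(n_cells = 200, n_genes = 150, markers_per_state = 10, seed = 5)
  none <- simulate_treated_counts(cfg, reprogram_fraction = 0)
  expect_identical(
    em_values(none$expr), em_values(simulate_state_counts(cfg)$expr)
  )
  all_h <- simulate_treated_counts(cfg, reprogram_fraction = 1)
  expect_true(all(all_h$truth$cells$state == "HYBRID"))

  cfg2 <- sim_config(n_cells = 4000, n_genes = 150, markers_per_state = 10, seed = 6)
  t25 <- simulate_treated_counts(cfg2, reprogram_fraction = 0.25)
  tc <- t25$truth$cells
  eligible <- tc$original_state != "HYBRID"
  n_flip <- sum(tc$reprogrammed)
  ci <- qbinom(c(0.005, 0.995), sum(eligible), 0.25)
  expect_gte(n_flip, ci[1])
  expect_lte(n_flip, ci[2])
  expect_true(all(tc$state[tc$reprogrammed] == "HYBRID"))
  expect_error(simulate_treated_counts(cfg2, reprogram_fraction = -0.1), "\\[0, 1\\]")
})

test_that("spatial surfaces carry the planted cross-correlation per region", {
  s_id <- simulate_spatial_sample(
    n_row = 10, n_col = 10, colocalization = 1, noise_sd = 0, seed = 3
  )
  expect_equal(s_id$spots$sig1, s_id$spots$sig2, tolerance = 1e-12)

  s0 <- simulate_spatial_sample(
    n_row = 20, n_col = 20, colocalization = 0, noise_sd = 0, seed = 4
  )
  for (reg in unique(s0$spots$region)) {
    sub <- s0$spots[s0$spots$region == reg, ]
    expect_lt(abs(cor(sub$sig1, sub$sig2)), 1e-10)
  }

  rm <- tidyr::expand_grid(row = 1:6, col = 1:6)
  rm$region <- ifelse(rm$col <= 3, "infiltrative_cortex", "cellular_tumor")
  s_map <- simulate_spatial_sample(
    n_row = 6, n_col = 6, region_map = rm, seed = 5
  )
  expect_equal(unname(table(s_map$spots$region)["cellular_tumor"]), 18,
               ignore_attr = TRUE)
  expect_error(simulate_spatial_sample(colocalization = 1.2), "colocalization")
  expect_error(simulate_spatial_sample(n_row = 1), "2 x 2")
})

test_that("phospho tables plant kinase effects on the mapped substrates", {
  map <- tibble::tibble(
    kinase = rep(c("K1", "K2"), each = 8),
    site = sprintf("p%02d_S1", 1:16)
  )
  pt <- simulate_phospho_table(map, active = c(K1 = 3), n_sites = 200,
                               noise_sd = 0.5, seed = 6)
  expect_identical(
    pt$table,
    simulate_phospho_table(map, active = c(K1 = 3), n_sites = 200,
                           noise_sd = 0.5, seed = 6)$table
  )
  k1_sites <- map$site[map$kinase == "K1"]
  fc <- setNames(pt$table$log2fc, pt$table$site)
  expect_gt(mean(fc[k1_sites]), 2)                       # shifted by ~3
  expect_lt(abs(mean(fc[setdiff(pt$table$site, k1_sites)])), 0.2)
  expect_error(
    simulate_phospho_table(map, active = c(KX = 1)), "absent"
  )

  # no planted activity: significant calls stay at the chance level
  sig_rate <- mean(vapply(1:30, function(s) {
    null <- simulate_phospho_table(map, n_sites = 200, seed = s)
    mean(tidy(ksea_zscores(null$table, map))$significant)
  }, numeric(1)))
  expect_lt(sig_rate, 0.1)  # nominal rate at p <= 0.01 is 1%
})

test_that("dye dilution follows the 2^X halving law", {
  exact <- simulate_dye_dilution(3, mfi_initial = 800, cv = 0, seed = 1)
  expect_equal(exact$records$mfi_final, 100)
  none <- simulate_dye_dilution(0, cv = 0, seed = 1)
  expect_equal(none$records$mfi_final, none$records$mfi_initial)

  noisy <- simulate_dye_dilution(rep(3, 50), cv = 0.1, seed = 2)
  est <- division_number(noisy$records)$divisions
  expect_lt(mean(abs(est - 3)), 0.2)
  expect_error(simulate_dye_dilution(-1), ">= 0")
})

test_that("vessel scenes place cells at the planted association bias", {
  all_on <- simulate_vessel_scene(
    n_cells = 60, association_bias = c(NesHI = 1, NesLO = 1), seed = 2
  )
  d <- vapply(seq_len(60), function(i) {
    brute_force_dist(all_on$cells$x[i], all_on$cells$y[i], all_on$segments)
  }, numeric(1))
  expect_true(all(d <= all_on$contact_radius + 1e-6))

  sym <- simulate_vessel_scene(
    n_cells = 400, association_bias = c(NesHI = 0.5, NesLO = 0.5), seed = 3
  )
  fr <- vapply(c("NesHI", "NesLO"),
               function(cl) vascular_association(sym, cl)$fraction, numeric(1))
  expect_lt(abs(fr[1] - fr[2]), 2.58 * sqrt(2 * 0.25 / 200))

  biased <- simulate_vessel_scene(
    n_cells = 400, association_bias = c(NesHI = 0.8, NesLO = 0.3), seed = 4
  )
  for (cl in c("NesHI", "NesLO")) {
    va <- vascular_association(biased, cl)
    p <- c(NesHI = 0.8, NesLO = 0.3)[[cl]]
    ci <- qbinom(c(0.005, 0.995), va$n_cells, p)
    expect_gte(va$n_attached, ci[1])
    expect_lte(va$n_attached, ci[2])
  }
  # truth stores one attachment flag per cell
  expect_setequal(biased$truth$cell_id, biased$cells$cell_id)
  expect_error(simulate_vessel_scene(n_segments = 0), "segment")
})
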