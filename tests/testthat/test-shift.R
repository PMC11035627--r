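test_that("vectorized rank-sum p-values match stats::wilcox.test", {
  set.seed(41)
  in_a <- rep(c(TRUE, FALSE), c(25, 30))
  for (i in 1:10) {
    x <- matrix(c(rnbinom(25, mu = 5, size = 2), rnbinom(30, mu = 8, size = 2)),
                nrow = 1)
    ours <- regenscreen:::wilcoxon_rows(x, in_a)
    ref <- suppressWarnings(
      stats::wilcox.test(x[1, in_a], x[1, !in_a], correct = TRUE)$p.value)
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("marker criteria are applied literally", {
  sim <- simulate_sc(sc_sim_params(n_genes = 200, n_cells_per_population = 100,
                                   n_planted_markers = 20), seed = 42)
  mk <- sc_find_markers(sim$counts, sim$cells)
  # genes never expressed are outside the BH family and never pass
  silent <- mk$gene_id[Matrix::rowSums(sim$counts) == 0]
  if (length(silent) > 0) {
    expect_true(all(is.na(mk$fdr[mk$gene_id %in% silent])))
    expect_false(any(mk$passes[mk$gene_id %in% silent]))
  }
  # every passing gene satisfies all three criteria
  pass <- mk[mk$passes, ]
  expect_true(all(pass$fdr < 0.01))
  expect_true(all(abs(pass$log2fc) > 1))
  expect_true(all(pmin(pass$pct_reference, pass$pct_contrast) >= 0.10))
  # "either" rule is at least as permissive
  mk_either <- sc_find_markers(sim$counts, sim$cells, pct_rule = "either")
  expect_true(all(mk$passes <= mk_either$passes))
})

test_that("permuted population labels yield almost no markers", {
  sim <- simulate_sc(sc_sim_params(n_genes = 400, n_cells_per_population = 150,
                                   n_planted_markers = 40), seed = 43)
  n_pass <- vapply(1:5, function(i) {
    set.seed(100 + i)
    shuffled <- sim$cells
    shuffled$population <- sample(shuffled$population)
    sum(sc_find_markers(sim$counts, shuffled)$passes)
  }, numeric(1))
  expect_lte(max(n_pass), 0.01 * 400)
})

test_that("z-score profiles satisfy the pooled-zero identity", {
  sim <- simulate_sc(sc_sim_params(n_genes = 100, n_cells_per_population = 80,
                                   n_planted_markers = 20), seed = 44)
  prof <- zscore_profiles(sim$counts, sim$cells, n_per_pop = 50, seed = 3)
  expect_equal(prof$n_reference, rep(50L, 100))
  resid <- prof$n_reference * prof$mean_z_reference +
    prof$n_contrast * prof$mean_z_contrast
  expect_equal(resid, rep(0, 100), tolerance = 1e-9)
  # equal subsamples imply mirrored means
  expect_equal(prof$mean_z_reference, -prof$mean_z_contrast, tolerance = 1e-9)
  # markers elevated in the reference population have positive reference z
  planted <- sim$truth$gene_id[sim$truth$class == "marker"]
  expect_gte(mean(prof$mean_z_reference[match(planted, prof$gene_id)] > 0),
             0.95)
  # requesting more cells than available falls back with a warning per pool
  w <- testthat::capture_warnings(
    zscore_profiles(sim$counts, sim$cells, n_per_pop = 500, seed = 3))
  expect_match(w, "using all", all = TRUE)
  expect_length(w, 2L)
})

test_that("bulk Tg DEG extraction is empty on identical arms and antisymmetric", {
  set.seed(45)
  m <- matrix(rnbinom(100 * 3, mu = 60, size = 10), nrow = 100)
  x <- counts_tbl(cbind(m, m))
  colnames(x)[-1] <- paste0("s", 1:6)
  sheet <- tibble::tibble(column_id = paste0("s", 1:6),
                          group = rep(c("control", "tg"), each = 3))
  expect_equal(nrow(bulk_deg_tg(x, sheet)), 0L)

  sim <- simulate_shift_pair(shift_sim_params(n_common_genes = 100,
                                              n_null_genes = 20,
                                              n_cells_per_population = 30),
                             seed = 46)
  fwd <- bulk_deg_tg(sim$bulk$counts, sim$bulk$samples)
  swapped <- sim$bulk$samples
  swapped$group <- ifelse(swapped$group == "tg", "control", "tg")
  rev <- bulk_deg_tg(sim$bulk$counts, swapped)
  shared <- intersect(fwd$gene_id, rev$gene_id)
  expect_gt(length(shared), 0)
  expect_equal(fwd$direction[match(shared, fwd$gene_id)],
               -rev$direction[match(shared, rev$gene_id)])
  # planted Tg effects are recovered
  planted <- sim$truth$gene_id[sim$truth$class != "null"]
  expect_gte(mean(planted %in% fwd$gene_id), 0.8)
})

test_that("concordance is 1 when all directions agree and is order invariant", {
  markers <- tibble::tibble(gene_id = c("a", "b", "c"),
                            log2fc = c(2, -1.5, 3), p = 0, fdr = 0,
                            pct_reference = 1, pct_contrast = 1, passes = TRUE)
  tg <- tibble::tibble(gene_id = c("c", "a", "b"),
                       log2fc = c(0.5, 1, -2), p = 0, fdr = 0,
                       direction = c(1, 1, -1))
  rep1 <- shift_consistency(markers, tg)
  expect_equal(rep1$concordance_fraction, 1)
  rep2 <- shift_consistency(markers[3:1, ], tg[c(2, 3, 1), ])
  expect_equal(rep2$concordance_fraction, 1)
  expect_setequal(rep1$common, rep2$common)
  # empty intersection is NA with a warning
  expect_warning(
    rep0 <- shift_consistency(markers[0, ], tg),
    "undefined")
  expect_true(is.na(rep0$concordance_fraction))
  g <- glance(rep1)
  expect_equal(g$n_common, 3L)
  expect_s3_class(autoplot(rep1), "ggplot")
})

test_that("simultaneously flipping both contrasts leaves concordance unchanged", {
  sim <- simulate_shift_pair(shift_sim_params(n_common_genes = 150,
                                              n_null_genes = 30,
                                              n_cells_per_population = 40),
                             seed = 47)
  mk <- sc_find_markers(sim$sc$counts, sim$sc$cells)
  tg <- bulk_deg_tg(sim$bulk$counts, sim$bulk$samples)
  base <- shift_consistency(mk, tg)$concordance_fraction
  mk_flip <- mk
  mk_flip$log2fc <- -mk_flip$log2fc
  tg_flip <- tg
  tg_flip$log2fc <- -tg_flip$log2fc
  tg_flip$direction <- -tg_flip$direction
  flipped <- shift_consistency(mk_flip, tg_flip)$concordance_fraction
  expect_equal(base, flipped)
})
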