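# helper: sample sheet + expression tibble from explicit condition means
expr_from_cond_means <- function(cond_means, n_rep = 3) {
  # cond_means: genes x 12 matrix of per-condition TPM-scale means,
  # replicated exactly (no noise) so scores are deterministic
  sheet <- tiny_design_sheet(n_rep)
  cond <- sub("_r\\d+$", "", sheet$column_id)
  m <- cond_means[, cond, drop = FALSE]
  colnames(m) <- sheet$column_id
  list(expr = counts_tbl(m, rownames(cond_means)), samples = sheet)
}

test_that("a gene dominating all comparisons scores the maximum of 8", {
  d <- default_design()
  expect_equal(length(d$reg_distal_conditions) *
                 length(d$dev_distal_conditions), 8L)
  cm <- matrix(10, nrow = 2, ncol = 12,
               dimnames = list(c("dominant", "flat"), d$conditions$condition))
  cm["dominant", c("regD1", "regD2")] <- 1000
  fx <- expr_from_cond_means(cm)
  sc <- specificity_score(fx$expr, fx$samples, c("dominant", "flat"))
  expect_equal(sc$score[sc$gene_id == "dominant"], 8L)
  # all six means exactly equal -> strict inequality scores no point
  expect_equal(sc$score[sc$gene_id == "flat"], 0L)
  expect_equal(sc$rank[sc$gene_id == "dominant"], 1L)
})

test_that("specificity scores equal the independent double-loop oracle", {
  set.seed(21)
  n <- 200
  d <- default_design()
  cm <- matrix(exp(runif(n * 12, 0, 8)), nrow = n,
               dimnames = list(sprintf("g%03d", 1:n), d$conditions$condition))
  fx <- expr_from_cond_means(cm)
  sc <- specificity_score(fx$expr, fx$samples, rownames(cm))
  for (g in rownames(cm)) {
    expect_identical(sc$score[sc$gene_id == g],
                     score_oracle(cm[g, d$reg_distal_conditions],
                                  cm[g, d$dev_distal_conditions]))
  }
  # ranks are a permutation
  expect_setequal(sc$rank, seq_len(n))
})

test_that("score is invariant under global column scaling", {
  set.seed(22)
  d <- default_design()
  cm <- matrix(exp(runif(50 * 12, 0, 6)), nrow = 50,
               dimnames = list(sprintf("g%03d", 1:50), d$conditions$condition))
  fx <- expr_from_cond_means(cm)
  scaled <- fx$expr
  scaled[-1] <- scaled[-1] * 37.5
  s1 <- specificity_score(fx$expr, fx$samples, rownames(cm))
  s2 <- specificity_score(scaled, fx$samples, rownames(cm))
  expect_identical(s1$score[order(s1$gene_id)], s2$score[order(s2$gene_id)])
})

test_that("raising a regeneration replicate never decreases a gene's score", {
  set.seed(23)
  sim <- simulate_bulk(bulk_sim_params(n_genes = 40,
                                       n_planted_regspecific = 2,
                                       n_planted_distal_shared = 2,
                                       n_planted_proximal = 2), seed = 30)
  expr <- tpm(sim$counts, sim$lengths)
  gene <- expr$gene_id[5]
  base_score <- function(e) {
    specificity_score(e, sim$samples, gene)$score
  }
  s0 <- base_score(expr)
  bumped <- expr
  bumped[bumped$gene_id == gene, "regD1_r1"] <-
    bumped[bumped$gene_id == gene, "regD1_r1"] + 500
  expect_gte(base_score(bumped), s0)
})

test_that("screen outputs nest and planted classes behave as designed", {
  sim <- simulate_bulk(bulk_sim_params(n_genes = 800,
                                       n_planted_regspecific = 10,
                                       n_planted_distal_shared = 10,
                                       n_planted_proximal = 10), seed = 31)
  fit <- run_screen_pipeline(sim$counts, sim$samples, sim$lengths)
  expect_true(all(fit$screen2_genes %in% fit$screen1_genes))
  expect_true(all(fit$scores$gene_id %in% fit$screen2_genes))
  proximal <- sim$truth$gene_id[sim$truth$class == "proximal"]
  expect_length(intersect(fit$screen2_genes, proximal), 0L)
  rs <- sim$truth$gene_id[sim$truth$class == "regspecific"]
  expect_true(all(rs %in% fit$screen1_genes))
  expect_equal(sort(unique(
    fit$scores$score[fit$scores$gene_id %in% rs])), 8L)
})

test_that("signal-free data yield roughly alpha-level screen-1 survivors", {
  sim <- simulate_bulk(bulk_sim_params(n_genes = 1000,
                                       n_planted_regspecific = 0,
                                       n_planted_distal_shared = 0,
                                       n_planted_proximal = 0), seed = 32)
  fit <- run_screen_pipeline(sim$counts, sim$samples, sim$lengths)
  # union of four alpha = 0.05 tests: expected survivor fraction is below
  # 1 - 0.95^4 ~ 0.185 and above a single test's floor
  frac <- length(fit$screen1_genes) / 1000
  expect_lt(frac, 0.25)
  expect_gt(frac, 0.02)
})

test_that("an empty screen-1 result degrades gracefully", {
  m <- matrix(50, nrow = 5, ncol = 36)  # constant counts: nothing differential
  sheet <- tiny_design_sheet(3)
  colnames(m) <- sheet$column_id
  counts <- counts_tbl(m)
  lengths <- tibble::tibble(gene_id = counts$gene_id, length = 1000)
  expect_warning(fit <- run_screen_pipeline(counts, sheet, lengths),
                 "screen 1")
  expect_equal(nrow(fit$scores), 0L)
  expect_length(fit$top_genes, 0L)
})

test_that("tidy and glance summarise a screen fit", {
  sim <- simulate_bulk(bulk_sim_params(n_genes = 150,
                                       n_planted_regspecific = 5,
                                       n_planted_distal_shared = 5,
                                       n_planted_proximal = 5), seed = 33)
  fit <- run_screen_pipeline(sim$counts, sim$samples, sim$lengths)
  g <- glance(fit)
  expect_equal(g$n_genes, 150L)
  expect_equal(g$n_scored, nrow(tidy(fit)))
  expect_s3_class(autoplot(fit), "ggplot")
})
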