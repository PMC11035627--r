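test_that("tpm matches hand-derived values and is scale invariant", {
  # single expressed gene takes the whole million
  one <- tpm(counts_tbl(matrix(7, ncol = 1), "g1"),
             tibble::tibble(gene_id = "g1", length = 500))
  expect_equal(one$s1, 1e6)
  # counts (10, 10), lengths (100, 200): rates 0.1 vs 0.05 -> 2:1 split
  two <- tpm(counts_tbl(matrix(c(10, 10), ncol = 1), c("a", "b")),
             tibble::tibble(gene_id = c("a", "b"), length = c(100, 200)))
  expect_equal(two$s1, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # doubling all counts in a column changes nothing
  lengths <- tibble::tibble(gene_id = sprintf("g%03d", 1:20),
                            length = seq(100, 2000, by = 100))
  m <- matrix(rpois(20 * 3, 50), nrow = 20)
  expect_equal(tpm(counts_tbl(m), lengths), tpm(counts_tbl(2 * m), lengths))
  expect_error(tpm(counts_tbl(m), lengths[1:5, ]), "lengths")
})

test_that("tpm and cpm columns sum to one million", {
  set.seed(1)
  m <- matrix(rpois(50 * 4, 30), nrow = 50)
  lengths <- tibble::tibble(gene_id = sprintf("g%03d", 1:50),
                            length = runif(50, 200, 5000))
  for (x in list(tpm(counts_tbl(m), lengths), cpm(counts_tbl(m)))) {
    expect_equal(colSums(as.matrix(x[-1])), rep(1e6, 4),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # brute-force cpm for one column
  expect_equal(cpm(counts_tbl(m))$s2, m[, 2] / sum(m[, 2]) * 1e6)
  # all-zero column passes through as zeros with a warning
  mz <- m; mz[, 3] <- 0
  expect_warning(z <- cpm(counts_tbl(mz)), "all-zero")
  expect_equal(z$s3, rep(0, 50))
})

test_that("cpm agrees with the edgeR implementation", {
  skip_if_not_installed("edgeR")
  set.seed(2)
  m <- matrix(rnbinom(40 * 5, mu = 100, size = 10), nrow = 40)
  ours <- as.matrix(cpm(counts_tbl(m))[-1])
  theirs <- edgeR::cpm(m, lib.size = colSums(m))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("log_z rows are standardized with population sd, constants map to zero", {
  x <- counts_tbl(rbind(c(5, 5, 5, 5, 5),
                        c(1, 10, 100, 1000, 3)))
  z <- log_z(x)
  zm <- as.matrix(z[-1])
  expect_equal(zm[1, ], rep(0, 5), ignore_attr = TRUE)
  expect_equal(mean(zm[2, ]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(zm[2, ]^2)), 1, tolerance = 1e-9)
  # hand-computed z for the 5-value row
  v <- log2(c(1, 10, 100, 1000, 3) + 1)
  expect_equal(zm[2, ], (v - mean(v)) / sqrt(mean((v - mean(v))^2)),
               ignore_attr = TRUE)
})

test_that("bh_adjust reproduces step-up values and matches the quadratic oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("de_test degenerate and symmetry properties hold", {
  set.seed(4)
  m <- matrix(rnbinom(100 * 3, mu = 80, size = 10), nrow = 100)
  x <- counts_tbl(cbind(m, m))
  colnames(x)[-1] <- paste0("s", 1:6)
  same <- de_test(x, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(same$log2fc, rep(0, 100))
  expect_equal(same$p, rep(1, 100))

  sim <- simulate_bulk(bulk_sim_params(n_genes = 150), seed = 6)
  a <- sim$samples$column_id[sim$samples$condition == "devD1"]
  b <- sim$samples$column_id[sim$samples$condition == "regD1"]
  ab <- de_test(sim$counts, a, b)
  ba <- de_test(sim$counts, b, a)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)

  expect_error(de_test(sim$counts, a[1], b), "replicate")
})

test_that("all-zero genes are excluded from the BH family", {
  m <- rbind(matrix(rpois(20 * 4, 50), nrow = 20), rep(0, 4))
  x <- counts_tbl(m)
  res <- de_test(x, c("s1", "s2"), c("s3", "s4"))
  expect_equal(res$p[21], 1)
  expect_equal(res$fdr[21], 1)
  # fdr of tested genes is a valid BH output of their p-values
  expect_equal(res$fdr[1:20], bh_oracle(res$p[1:20]), tolerance = 1e-12)
})

test_that("exact NB p-values agree with edgeR's exact test in rank and scale", {
  skip_if_not_installed("edgeR")
  sim <- simulate_bulk(bulk_sim_params(n_genes = 400, library_size_cv = 0),
                       seed = 9)
  a <- sim$samples$column_id[sim$samples$condition == "devD1"]
  b <- sim$samples$column_id[sim$samples$condition == "regD1"]
  ours <- de_test(sim$counts, a, b)
  m <- as.matrix(sim$counts[-1])[, c(a, b)]
  rownames(m) <- sim$counts$gene_id
  y <- edgeR::DGEList(counts = m, group = rep(c("a", "b"), each = 3))
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateCommonDisp(y)
  theirs <- edgeR::exactTest(y)$table$PValue
  expect_gt(cor(log10(ours$p + 1e-300), log10(theirs + 1e-300),
                method = "spearman"), 0.97)
})

test_that("the Welch-t backend detects the same strong signals", {
  sim <- simulate_bulk(bulk_sim_params(n_genes = 300, n_planted_regspecific = 15,
                                       regspecific_fold = 8), seed = 10)
  a <- sim$samples$column_id[sim$samples$condition == "devD1"]
  b <- sim$samples$column_id[sim$samples$condition == "regD1"]
  res <- de_test(sim$counts, a, b, method = "t")
  planted <- sim$truth$gene_id[sim$truth$class == "regspecific"]
  expect_gt(mean(res$p[match(planted, res$gene_id)] < 0.05), 0.8)
})
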