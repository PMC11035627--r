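#' Single-cell marker detection between two cell populations
#'
#' Per gene, counts are CPM-normalized per cell and compared between the
#' reference and contrast populations with a two-sided Wilcoxon rank-sum
#' test (normal approximation with tie and continuity corrections), BH
#' adjusted over the tested genes. The marker criteria are: (i)
#' `fdr < fdr_threshold`, (ii) natural-scale fold change above
#' `fc_threshold` in either direction (fold computed as
#' `(mean CPM_ref + 1) / (mean CPM_con + 1)`), and (iii) non-zero
#' expression in at least `pct_threshold` of cells — in both populations
#' (`pct_rule = "both"`, the default) or in at least one
#' (`pct_rule = "either"`). Genes with zero counts everywhere are excluded
#' from the BH family and never pass.
#'
#' @param sc genes x cells count matrix (`dgCMatrix` or dense, with gene
#'   rownames and cell colnames).
#' @param cells data frame with `cell_id`, `population` (values
#'   `reference` / `contrast`, both non-empty, >= 20 cells each).
#' @param fdr_threshold,fc_threshold,pct_threshold the three marker
#'   criteria (defaults 0.01, 2, 0.10).
#' @param pct_rule `"both"` or `"either"`.
#' @return tibble `gene_id`, `log2fc` (reference over contrast), `p`,
#'   `fdr`, `pct_reference`, `pct_contrast`, `passes`.
#' @export
sc_find_markers <- function(sc, cells, fdr_threshold = 0.01,
                            fc_threshold = 2, pct_threshold = 0.10,
                            pct_rule = c("both", "either")) {
  pct_rule <- match.arg(pct_rule)
  stopifnot(all(c("cell_id", "population") %in% names(cells)))
  if (!all(cells$population %in% c("reference", "contrast"))) {
    abort("population must be 'reference' or 'contrast'")
  }
  n_ref <- sum(cells$population == "reference")
  n_con <- sum(cells$population == "contrast")
  if (n_ref < 20 || n_con < 20) abort("each population needs >= 20 cells")
  m <- as.matrix(sc)[, cells$cell_id, drop = FALSE]
  is_ref <- cells$population == "reference"

  norm <- as.matrix(cpm(m))
  mean_ref <- rowMeans(norm[, is_ref, drop = FALSE])
  mean_con <- rowMeans(norm[, !is_ref, drop = FALSE])
  log2fc <- log2((mean_ref + 1) / (mean_con + 1))
  pct_ref <- rowMeans(m[, is_ref, drop = FALSE] > 0)
  pct_con <- rowMeans(m[, !is_ref, drop = FALSE] > 0)

  tested <- rowSums(m) > 0
  p <- rep(NA_real_, nrow(m))
  p[tested] <- wilcoxon_rows(norm[tested, , drop = FALSE], is_ref)
  fdr <- rep(NA_real_, nrow(m))
  fdr[tested] <- bh_adjust(p[tested])

  fold_ok <- log2fc > log2(fc_threshold) | log2fc < -log2(fc_threshold)
  pct_ok <- if (pct_rule == "both") {
    pct_ref >= pct_threshold & pct_con >= pct_threshold
  } else {
    pct_ref >= pct_threshold | pct_con >= pct_threshold
  }
  passes <- tested & !is.na(fdr) & fdr < fdr_threshold & fold_ok & pct_ok
  tibble(gene_id = rownames(m), log2fc = unname(log2fc), p = unname(p),
         fdr = unname(fdr), pct_reference = unname(pct_ref),
         pct_contrast = unname(pct_con), passes = unname(passes))
}

# internal: row-wise two-sided Wilcoxon rank-sum p-values, normal
# approximation with tie and continuity corrections (x columns split by
# the logical `in_a`).
wilcoxon_rows <- function(x, in_a) {
  n1 <- sum(in_a)
  n2 <- sum(!in_a)
  n <- n1 + n2
  p <- numeric(nrow(x))
  mu <- n1 * n2 / 2
  base_var <- n1 * n2 / 12
  for (i in seq_len(nrow(x))) {
    r <- rank(x[i, ])
    w <- sum(r[in_a]) - n1 * (n1 + 1) / 2
    ties <- rle(sort.int(x[i, ], method = "quick"))$lengths
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- base_var * ((n + 1) - tie_term)
    if (v <= 0) { p[i] <- 1; next }
    z <- (abs(w - mu) - 0.5) / sqrt(v)
    p[i] <- min(1, 2 * pnorm(-max(z, 0)))
  }
  p
}

#' Mean z-score profiles of two cell populations
#'
#' Subsamples `n_per_pop` cells without replacement from each population
#' (all cells, with a warning, if a population is smaller), converts
#' log2(CPM + 1) expression of every gene to a z-score across the pooled
#' cells, and averages the z-scores per population. With the pooled
#' z-scoring, `n_ref * mean_z_reference + n_con * mean_z_contrast = 0` for
#' every gene.
#'
#' @inheritParams sc_find_markers
#' @param n_per_pop cells to subsample per population (default 1000).
#' @param seed integer seed for the subsampling.
#' @return tibble `gene_id`, `mean_z_reference`, `mean_z_contrast`,
#'   `n_reference`, `n_contrast`.
#' @export
zscore_profiles <- function(sc, cells, n_per_pop = 1000, seed = 1) {
  stopifnot(all(c("cell_id", "population") %in% names(cells)))
  pick <- function(pop) {
    ids <- cells$cell_id[cells$population == pop]
    if (length(ids) < n_per_pop) {
      warn(paste0("population '", pop, "' has ", length(ids), " < ",
                  n_per_pop, " cells; using all of them"))
      return(ids)
    }
    sample(ids, n_per_pop)
  }
  set.seed(derive_seed(seed, 1L))
  ref_ids <- pick("reference")
  set.seed(derive_seed(seed, 2L))
  con_ids <- pick("contrast")
  m <- as.matrix(sc)[, c(ref_ids, con_ids), drop = FALSE]
  z <- zscore_rows(log2(as.matrix(cpm(m)) + 1))
  is_ref <- seq_len(ncol(z)) <= length(ref_ids)
  tibble(gene_id = rownames(m),
         mean_z_reference = unname(rowMeans(z[, is_ref, drop = FALSE])),
         mean_z_contrast = unname(rowMeans(z[, !is_ref, drop = FALSE])),
         n_reference = length(ref_ids),
         n_contrast = length(con_ids))
}

#' Bulk transgenic-vs-control differential genes with directions
#'
#' Runs [de_test()] (control as group A, Tg as group B) and keeps genes
#' with `fdr < fdr_threshold`; the perturbation direction is the sign of
#' the Tg-over-control log2 fold change.
#'
#' @param counts wide bulk counts tibble.
#' @param samples data frame with `column_id`, `group` (values
#'   `tg` / `control`, >= 2 replicates each).
#' @param fdr_threshold BH FDR cut-off (default 0.01).
#' @param method DE method passed to [de_test()].
#' @return tibble `gene_id`, `log2fc`, `p`, `fdr`, `direction` (+1/-1)
#'   restricted to significant genes; the full [de_test()] table is
#'   attached as attribute `"full"`.
#' @export
bulk_deg_tg <- function(counts, samples, fdr_threshold = 0.01,
                        method = "exact") {
  stopifnot(all(c("column_id", "group") %in% names(samples)))
  if (!all(samples$group %in% c("tg", "control"))) {
    abort("group must be 'tg' or 'control'")
  }
  res <- de_test(counts,
                 samples$column_id[samples$group == "control"],
                 samples$column_id[samples$group == "tg"],
                 method = method)
  sig <- res %>%
    filter(.data$fdr < fdr_threshold) %>%
    mutate(direction = sign(.data$log2fc)) %>%
    select("gene_id", "log2fc", "p", "fdr", "direction")
  attr(sig, "full") <- res
  sig
}

#' Developmental-shift concordance between two contrasts
#'
#' Intersects the passing single-cell markers (limb bud vs blastema) with
#' the bulk Tg DEGs and asks, gene by gene, whether the transgene pushed
#' expression in the direction of the limb-bud state: a gene is concordant
#' when `sign(log2fc reference-over-contrast)` equals
#' `sign(log2fc Tg-over-control)`. The headline statistic is the fraction
#' of concordant genes among the common set.
#'
#' @param markers [sc_find_markers()] output.
#' @param tg [bulk_deg_tg()] output.
#' @return object of class `shift_report` with the gene sets, a per-gene
#'   direction table, and `concordance_fraction` (`NA` with a warning when
#'   the common set is empty).
#' @examples
#' sim <- simulate_shift_pair(shift_sim_params(n_common_genes = 100,
#'   n_null_genes = 50, n_cells_per_population = 50), seed = 1)
#' rep <- shift_consistency(
#'   sc_find_markers(sim$sc$counts, sim$sc$cells),
#'   bulk_deg_tg(sim$bulk$counts, sim$bulk$samples))
#' glance(rep)
#' @export
shift_consistency <- function(markers, tg) {
  deg_ref <- markers$gene_id[markers$passes]
  deg_tg <- tg$gene_id
  common <- intersect(deg_ref, deg_tg)
  genes <- tibble(gene_id = common) %>%
    left_join(markers %>% select("gene_id", ref_log2fc = "log2fc"),
              by = "gene_id") %>%
    left_join(tg %>% select("gene_id", tg_log2fc = "log2fc"),
              by = "gene_id") %>%
    mutate(reference_direction = sign(.data$ref_log2fc),
           perturbation_direction = sign(.data$tg_log2fc),
           concordant = .data$reference_direction ==
             .data$perturbation_direction)
  frac <- if (length(common) == 0) {
    warn("no genes common to both DEG sets; concordance undefined")
    NA_real_
  } else {
    mean(genes$concordant)
  }
  structure(list(deg_bl_dev = deg_ref, deg_tg = deg_tg, common = common,
                 genes = genes, concordance_fraction = frac),
            class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat("<shift_report> |DEG_bl-dev| = ", length(x$deg_bl_dev),
      ", |DEG_Tg| = ", length(x$deg_tg),
      ", common = ", length(x$common),
      ", concordance = ",
      ifelse(is.na(x$concordance_fraction), "NA",
             sprintf("%.3f", x$concordance_fraction)), "\n", sep = "")
  invisible(x)
}

#' @describeIn shift_consistency per-gene direction table for the common
#'   genes.
#' @param x a `shift_report` object.
#' @param ... unused.
#' @method tidy shift_report
#' @export
tidy.shift_report <- function(x, ...) {
  x$genes
}

#' @describeIn shift_consistency one-row summary (set sizes and the
#'   concordance fraction).
#' @method glance shift_report
#' @export
glance.shift_report <- function(x, ...) {
  tibble(n_deg_bl_dev = length(x$deg_bl_dev),
         n_deg_tg = length(x$deg_tg),
         n_common = length(x$common),
         concordance_fraction = x$concordance_fraction)
}

#' @describeIn shift_consistency scatter of the two log2 fold changes,
#'   coloured by concordance.
#' @param object a `shift_report` object.
#' @method autoplot shift_report
#' @export
autoplot.shift_report <- function(object, ...) {
  ggplot2::ggplot(object$genes,
                  ggplot2::aes(x = .data$ref_log2fc, y = .data$tg_log2fc,
                               colour = .data$concordant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log2 FC limb bud / blastema (single cell)",
                  y = "log2 FC Tg / control (bulk)",
                  title = sprintf("Shift concordance = %.2f",
                                  object$concordance_fraction)) +
    ggplot2::theme_minimal()
}
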