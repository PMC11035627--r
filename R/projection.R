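#' Sample-level PCA on a gene subset
#'
#' SVD-based PCA with samples as observations over the selected genes
#' (typically a z-scored DEG panel). Genes are centred across samples
#' before decomposition. The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive, making output files stable
#' across runs and platforms.
#'
#' @param expr wide expression tibble (`gene_id` + sample columns),
#'   typically [log_z()] output.
#' @param genes character vector of genes to project on (non-empty).
#' @param k number of components (`<= min(n_samples, n_genes)`).
#' @return object of class `sample_pca` with `scores` (tibble, one row per
#'   sample), `variance` (tibble with `component`,
#'   `explained_variance_fraction`), and `loadings` (genes x k matrix).
#' @export
pca_samples <- function(expr, genes = NULL, k = 2) {
  m <- counts_to_matrix(expr)
  if (is.null(genes)) genes <- rownames(m)
  if (length(genes) == 0) abort("gene subset must be non-empty")
  missing_genes <- setdiff(genes, rownames(m))
  if (length(missing_genes) > 0) {
    abort(paste0("genes not in expression matrix: ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  x <- t(m[genes, , drop = FALSE])
  if (k > min(dim(x))) abort("k exceeds min(n_samples, n_genes)")
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(k)
  rot <- fit$rotation[, keep, drop = FALSE]
  scores <- fit$x[, keep, drop = FALSE]
  flip <- vapply(keep, function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  ev <- fit$sdev^2
  structure(list(
    scores = dplyr::bind_cols(tibble(sample = rownames(x)),
                              as_tibble(as.data.frame(scores))),
    variance = tibble(component = paste0("PC", keep),
                      explained_variance_fraction = (ev / sum(ev))[keep]),
    loadings = rot,
    center = fit$center
  ), class = "sample_pca")
}

#' @export
print.sample_pca <- function(x, ...) {
  cat("<sample_pca> ", nrow(x$scores), " samples, ",
      nrow(x$variance), " components\n", sep = "")
  print(x$variance)
  invisible(x)
}

#' @describeIn pca_samples per-sample score table.
#' @param x a `sample_pca` object.
#' @param ... unused.
#' @method tidy sample_pca
#' @export
tidy.sample_pca <- function(x, ...) {
  x$scores
}

#' @describeIn pca_samples explained-variance summary.
#' @method glance sample_pca
#' @export
glance.sample_pca <- function(x, ...) {
  tidyr::pivot_wider(x$variance, names_from = "component",
                     values_from = "explained_variance_fraction")
}

#' @describeIn pca_samples PC1/PC2 scatter of the samples.
#' @param object a `sample_pca` object.
#' @method autoplot sample_pca
#' @export
autoplot.sample_pca <- function(object, ...) {
  pcs <- setdiff(names(object$scores), "sample")
  if (length(pcs) < 2) abort("need at least 2 components to plot")
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]],
                               label = .data$sample)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 2.5) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", pcs[1],
                  100 * object$variance$explained_variance_fraction[1]),
      y = sprintf("%s (%.1f%%)", pcs[2],
                  100 * object$variance$explained_variance_fraction[2]),
      title = "Sample PCA") +
    ggplot2::theme_minimal()
}

#' Z-score values for a gene panel heatmap
#'
#' Per-gene z-scores of log2(expr + 1) across the selected samples, in the
#' input gene order — the numeric substrate of patterning-gene heatmaps.
#' Genes absent from the matrix are reported in a warning and skipped;
#' fewer than two samples is an error (z-scores would be undefined).
#'
#' @param expr wide TPM/CPM expression tibble.
#' @param genes character vector of panel genes (row order preserved).
#' @param columns optional sample subset.
#' @return tibble of z-scores with one row per found panel gene.
#' @export
gene_panel_heatmap_values <- function(expr, genes, columns = NULL) {
  m <- counts_to_matrix(expr)
  if (!is.null(columns)) m <- m[, columns, drop = FALSE]
  if (ncol(m) < 2) abort("need >= 2 samples to z-score a gene panel")
  found <- genes[genes %in% rownames(m)]
  missing_genes <- setdiff(genes, found)
  if (length(missing_genes) > 0) {
    warn(paste0("panel gene(s) not found, skipped: ",
                paste(missing_genes, collapse = ", ")))
  }
  z <- zscore_rows(log2(m[found, , drop = FALSE] + 1))
  matrix_to_tibble(z)
}
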