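#' Transcripts-per-million normalization
#'
#' Per column: `rate_g = count_g / length_g`; `tpm_g = 1e6 * rate_g /
#' sum(rate)`. Non-zero columns sum to exactly 1e6 (relative tolerance
#' 1e-9); an all-zero column stays all-zero with a warning.
#'
#' @param counts wide counts tibble (`gene_id` + numeric sample columns).
#' @param lengths data frame with columns `gene_id`, `length` (nucleotides,
#'   strictly positive), covering every gene in `counts`.
#' @return tibble of the same shape with TPM values; attribute `unit` is
#'   `"tpm"`.
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b"), s1 = c(10, 10))
#' lengths <- tibble::tibble(gene_id = c("a", "b"), length = c(100, 200))
#' tpm(counts, lengths)
#' @export
tpm <- function(counts, lengths) {
  m <- counts_to_matrix(counts)
  stopifnot(all(c("gene_id", "length") %in% names(lengths)))
  idx <- match(rownames(m), lengths$gene_id)
  if (anyNA(idx)) abort("gene lengths missing for some genes in counts")
  len <- as.numeric(lengths$length[idx])
  if (any(!is.finite(len)) || any(len <= 0)) abort("gene lengths must be > 0")
  rate <- m / len
  out <- scale_to_million(rate)
  res <- matrix_to_tibble(out)
  attr(res, "unit") <- "tpm"
  res
}

#' Counts-per-million normalization
#'
#' TPM with unit gene lengths: each non-zero column is scaled to sum to 1e6.
#'
#' @param counts wide counts tibble (`gene_id` + numeric sample columns), or
#'   a numeric matrix / `Matrix::dgCMatrix` with gene rownames (single-cell
#'   use).
#' @return same container type as the input with CPM values; for tibbles the
#'   `unit` attribute is `"cpm"`.
#' @export
cpm <- function(counts) {
  if (is.data.frame(counts)) {
    m <- counts_to_matrix(counts)
    res <- matrix_to_tibble(scale_to_million(m))
    attr(res, "unit") <- "cpm"
    return(res)
  }
  if (inherits(counts, "sparseMatrix")) {
    cs <- Matrix::colSums(counts)
    zero <- cs == 0
    if (any(zero)) warn(paste0(sum(zero), " all-zero column(s) left as zeros"))
    cs[zero] <- 1
    return(counts %*% Matrix::Diagonal(x = 1e6 / cs, names = FALSE))
  }
  scale_to_million(as.matrix(counts))
}

# internal: scale dense columns to sum to 1e6, zero columns stay zero
scale_to_million <- function(m) {
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " all-zero column(s) left as zeros"))
    cs[zero] <- 1
  }
  sweep(m, 2, cs, "/") * 1e6
}

#' Log transform and per-gene z-score
#'
#' `v -> log2(v + 1)`, then each gene (row) is centred and scaled across the
#' selected columns using the population (n-denominator) standard
#' deviation, matching heatmap z-scoring conventions. Constant genes map to
#' an all-zero row.
#'
#' @param expr wide expression tibble in TPM or CPM units.
#' @param columns optional character vector of sample columns to z-score
#'   over (default: all).
#' @return tibble of z-scores (attribute `unit` = `"zscore"`).
#' @export
log_z <- function(expr, columns = NULL) {
  m <- counts_to_matrix(expr)
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, colnames(m))
    if (length(missing_cols) > 0) {
      abort(paste0("unknown column(s): ", paste(missing_cols, collapse = ", ")))
    }
    m <- m[, columns, drop = FALSE]
  }
  res <- matrix_to_tibble(zscore_rows(log2(m + 1)))
  attr(res, "unit") <- "zscore"
  res
}

# internal: population-sd row z-score; constant rows -> 0
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  centered <- m - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  sd_pop[sd_pop == 0] <- Inf
  centered / sd_pop
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up BH adjustment (monotone after sorting, capped at 1).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must be finite and in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

# ---------------------------------------------------------------------------
# library-size normalization

# internal: median-of-ratios size factors against the geometric-mean
# reference, falling back to total-count scaling when < 50 genes have
# all-positive counts. Factors are centred so their geometric mean is 1.
size_factors <- function(m) {
  pos <- rowSums(m > 0) == ncol(m)
  if (sum(pos) < 50) {
    sf <- colSums(m)
    sf <- sf / exp(mean(log(sf[sf > 0])))
    sf[sf == 0] <- 1
    return(sf)
  }
  logm <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(median(col - ref)))
  sf / exp(mean(log(sf)))
}

# internal: pooled method-of-moments common dispersion on normalized counts,
# floored at 1e-4. E[var] = mu + phi mu^2; E[mean^2] = mu^2 + var/n.
estimate_common_dispersion <- function(z, groups, floor = 1e-4) {
  num <- 0
  den <- 0
  for (g in unique(groups)) {
    sub <- z[, groups == g, drop = FALSE]
    if (ncol(sub) < 2) next
    mu <- rowMeans(sub)
    v <- apply(sub, 1, var)
    keep <- mu > 0
    num <- num + sum(v[keep] - mu[keep])
    den <- den + sum(mu[keep]^2 - v[keep] / ncol(sub))
  }
  if (den <= 0) return(floor)
  max(floor, num / den)
}

# ---------------------------------------------------------------------------
# exact conditional negative-binomial test

# internal: two-sided exact test of H0: equal relative abundance, given the
# rounded normalized group sums sa, sb (vectors over genes) and common
# dispersion phi. Conditional on the total t = sa + sb, the group-B sum
# follows a negative-hypergeometric (beta-binomial) law with shape
# parameters r_a = n_a/phi, r_b = n_b/phi, which is free of the mean.
# Two-sided p = sum of all outcome probabilities <= the observed one
# ("doubletail"). Totals above `enum_limit` use a continuity-corrected
# Gaussian approximation of the same conditional law.
exact_nb_pvalues <- function(sa, sb, n_a, n_b, phi, enum_limit = 20000) {
  ra <- n_a / phi
  rb <- n_b / phi
  t_all <- sa + sb
  p <- rep(1, length(sa))
  for (i in seq_along(sa)) {
    t <- t_all[i]
    if (t == 0) next
    if (t <= enum_limit) {
      s <- 0:t
      lga <- lgamma(s + ra)
      lgb <- if (ra == rb) rev(lga) else lgamma(t - s + rb)
      lfact <- lgamma(s + 1)
      lfact_rev <- rev(lfact)
      logp <- lga - lfact - lgamma(ra) + lgb - lfact_rev - lgamma(rb) -
        (lgamma(t + ra + rb) - lgamma(t + 1) - lgamma(ra + rb))
      obs <- logp[sb[i] + 1]
      p[i] <- min(1, sum(exp(logp[logp <= obs + 1e-10])))
    } else {
      mu <- t * rb / (ra + rb)
      v <- t * (ra * rb / (ra + rb)^2) * (ra + rb + t) / (ra + rb + 1)
      zstat <- (abs(sb[i] - mu) - 0.5) / sqrt(v)
      p[i] <- min(1, 2 * pnorm(-max(zstat, 0)))
    }
  }
  p
}

#' Two-group differential-expression test on counts
#'
#' The default method is an exact conditional negative-binomial test:
#' library sizes are equalized by median-of-ratios scaling, a common
#' dispersion is estimated by pooled method of moments (floored at 1e-4),
#' and each gene is tested two-sidedly on the conditional distribution of
#' its group-B sum given the total. `method = "t"` runs a Welch t-test on
#' `log2(normalized count + 1)` instead, for speed. Fold changes are
#' `log2((mean_b + 0.5) / (mean_a + 0.5))` on library-size-normalized
#' counts. Genes with zero counts in all columns are excluded from the BH
#' family and reported with `p = 1`, `fdr = 1`.
#'
#' @param counts wide counts tibble (`gene_id` + sample columns).
#' @param cols_a,cols_b character vectors of column names for groups A and
#'   B (>= 2 each).
#' @param method `"exact"` (default) or `"t"`.
#' @return tibble with `gene_id`, `log2fc` (B over A), `p`, `fdr`,
#'   `mean_a`, `mean_b`.
#' @examples
#' sim <- simulate_bulk(bulk_sim_params(n_genes = 50), seed = 1)
#' a <- sim$samples$column_id[sim$samples$condition == "devD1"]
#' b <- sim$samples$column_id[sim$samples$condition == "regD1"]
#' de_test(sim$counts, a, b)
#' @export
de_test <- function(counts, cols_a, cols_b, method = c("exact", "t")) {
  method <- match.arg(method)
  m <- counts_to_matrix(counts)
  if (any(m < 0) || any(m != round(m))) abort("counts must be non-negative integers")
  missing_cols <- setdiff(c(cols_a, cols_b), colnames(m))
  if (length(missing_cols) > 0) {
    abort(paste0("unknown column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (length(cols_a) < 2 || length(cols_b) < 2) {
    abort("each group needs at least 2 replicate columns")
  }
  sub <- m[, c(cols_a, cols_b), drop = FALSE]
  groups <- rep(c("a", "b"), c(length(cols_a), length(cols_b)))
  sf <- size_factors(sub)
  z <- sweep(sub, 2, sf, "/")
  mean_a <- rowMeans(z[, groups == "a", drop = FALSE])
  mean_b <- rowMeans(z[, groups == "b", drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  tested <- rowSums(sub) > 0
  p <- rep(1, nrow(sub))
  if (any(tested)) {
    if (method == "exact") {
      phi <- estimate_common_dispersion(z[tested, , drop = FALSE], groups)
      sa <- round(rowSums(z[tested, groups == "a", drop = FALSE]))
      sb <- round(rowSums(z[tested, groups == "b", drop = FALSE]))
      p[tested] <- exact_nb_pvalues(sa, sb, length(cols_a), length(cols_b), phi)
    } else {
      lz <- log2(z + 1)
      xa <- lz[tested, groups == "a", drop = FALSE]
      xb <- lz[tested, groups == "b", drop = FALSE]
      p[tested] <- welch_t_rows(xa, xb)
    }
  }
  fdr <- rep(1, nrow(sub))
  fdr[tested] <- bh_adjust(p[tested])
  tibble(gene_id = rownames(sub), log2fc = unname(log2fc), p = unname(p),
         fdr = unname(fdr), mean_a = unname(mean_a), mean_b = unname(mean_b))
}

# internal: row-wise Welch t-test p-values
welch_t_rows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
  se2 <- va / na + vb / nb
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  tt <- (mb - ma) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  p[!is.finite(p)] <- 1
  pmin(1, p)
}
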