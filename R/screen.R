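#' Screen 1: differential expression within corresponding pairs
#'
#' Tests every gene within each of the four corresponding regeneration /
#' development condition pairs and keeps genes differential (raw
#' `p < alpha`) in at least one pair (`rule = "union"`, the default) or in
#' all four (`rule = "all"`).
#'
#' @param counts wide counts tibble.
#' @param samples sample sheet (see [validate_sample_sheet()]).
#' @param design study design.
#' @param alpha raw p-value threshold.
#' @param rule `"union"` or `"all"` aggregation over the four pairs.
#' @param method DE method passed to [de_test()].
#' @return list with `genes` (character vector) and `pair_results` (named
#'   list of [de_test()] tibbles, one per corresponding pair).
#' @export
screen1_corresponding_pairs <- function(counts, samples, design = default_design(),
                                        alpha = 0.05,
                                        rule = c("union", "all"),
                                        method = "exact") {
  rule <- match.arg(rule)
  samples <- validate_sample_sheet(samples, design)
  pairs <- design$corresponding_pairs
  pair_results <- list()
  hit <- NULL
  for (i in seq_len(nrow(pairs))) {
    cols_dev <- samples$column_id[samples$condition == pairs$development[i]]
    cols_reg <- samples$column_id[samples$condition == pairs$regeneration[i]]
    res <- de_test(counts, cols_dev, cols_reg, method = method)
    pair_results[[paste0(pairs$regeneration[i], "_vs_", pairs$development[i])]] <- res
    this_hit <- res$p < alpha
    hit <- if (is.null(hit)) this_hit else if (rule == "union") hit | this_hit else hit & this_hit
  }
  list(genes = pair_results[[1]]$gene_id[hit], pair_results = pair_results)
}

#' Screen 2: distal over proximal during regeneration
#'
#' Within `gene_set`, keeps genes significantly (`p < alpha`) *higher* in
#' the distal (blastema) than the proximal (stump) region in at least one
#' (`rule = "any"`) or both (`rule = "both"`) stage-matched regeneration
#' contrasts (`regD1` vs `regP1`, `regD2` vs `regP2`). The direction
#' requirement is strict: genes higher proximally are excluded regardless
#' of significance.
#'
#' @inheritParams screen1_corresponding_pairs
#' @param gene_set character vector of candidate genes (typically the
#'   screen-1 survivors).
#' @param rule `"any"` or `"both"`.
#' @return list with `genes` and `contrast_results`.
#' @export
screen2_distal_over_proximal <- function(counts, samples, gene_set,
                                         design = default_design(),
                                         alpha = 0.05,
                                         rule = c("any", "both"),
                                         method = "exact") {
  rule <- match.arg(rule)
  samples <- validate_sample_sheet(samples, design)
  contrasts <- list(c("regP1", "regD1"), c("regP2", "regD2"))
  contrast_results <- list()
  hit <- NULL
  for (ct in contrasts) {
    cols_prox <- samples$column_id[samples$condition == ct[1]]
    cols_dist <- samples$column_id[samples$condition == ct[2]]
    res <- de_test(counts, cols_prox, cols_dist, method = method)
    contrast_results[[paste0(ct[2], "_vs_", ct[1])]] <- res
    this_hit <- res$p < alpha & res$mean_b > res$mean_a
    hit <- if (is.null(hit)) this_hit else if (rule == "any") hit | this_hit else hit & this_hit
  }
  all_genes <- contrast_results[[1]]$gene_id
  list(genes = intersect(gene_set, all_genes[hit]),
       contrast_results = contrast_results)
}

#' Regeneration-specificity point score (0-8)
#'
#' For each gene, every regeneration-distal condition mean (`regD1`,
#' `regD2`, replicate-mean TPM) is compared against every
#' development-distal condition mean (`devD1..devD4`); one point per
#' strictly higher regeneration mean, for a maximum of 2 x 4 = 8 points.
#' Ranking is by score (descending), ties broken by the larger worst-case
#' *relative* margin `min over reg of (log2(reg mean + 1) -
#' log2(max dev mean + 1))`, then by gene id. The margin is on the log
#' scale so that ranking reflects regeneration specificity rather than
#' absolute abundance: an absolute-TPM margin lets noisy high-abundance
#' genes outrank genuinely regeneration-specific low-abundance ones.
#'
#' @param expr wide TPM expression tibble.
#' @param samples sample sheet.
#' @param gene_set genes to score.
#' @param design study design.
#' @return tibble `gene_id`, `score` (0-8), `margin`, `rank`.
#' @export
specificity_score <- function(expr, samples, gene_set,
                              design = default_design()) {
  samples <- validate_sample_sheet(samples)
  m <- counts_to_matrix(expr)
  missing_genes <- setdiff(gene_set, rownames(m))
  if (length(missing_genes) > 0) {
    abort(paste0("genes not in expression matrix: ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  if (length(gene_set) == 0) {
    return(tibble(gene_id = character(), score = integer(),
                  margin = numeric(), rank = integer()))
  }
  cond_means <- function(condition) {
    cols <- samples$column_id[samples$condition == condition]
    rowMeans(m[gene_set, cols, drop = FALSE])
  }
  reg_means <- vapply(design$reg_distal_conditions, cond_means,
                      numeric(length(gene_set)))
  dev_means <- vapply(design$dev_distal_conditions, cond_means,
                      numeric(length(gene_set)))
  reg_means <- matrix(reg_means, nrow = length(gene_set))
  dev_means <- matrix(dev_means, nrow = length(gene_set))
  score <- integer(length(gene_set))
  for (r in seq_len(ncol(reg_means))) {
    for (d in seq_len(ncol(dev_means))) {
      score <- score + as.integer(reg_means[, r] > dev_means[, d])
    }
  }
  max_dev <- apply(dev_means, 1, max)
  margin <- apply(log2(reg_means + 1) - log2(max_dev + 1), 1, min)
  out <- tibble(gene_id = gene_set, score = score, margin = margin) %>%
    arrange(desc(.data$score), desc(.data$margin), .data$gene_id) %>%
    mutate(rank = dplyr::row_number())
  out
}

#' Run the full three-step regeneration-specificity screen
#'
#' Chains [screen1_corresponding_pairs()], [screen2_distal_over_proximal()]
#' and [specificity_score()] on a counts table: (1) differential within a
#' corresponding development/regeneration pair, (2) distal-over-proximal
#' during regeneration, (3) the 0-8 specificity point score with ranking.
#' Scored genes are a subset of screen-2 survivors, which are a subset of
#' screen-1 survivors.
#'
#' @inheritParams screen1_corresponding_pairs
#' @param lengths gene-length tibble for TPM normalization.
#' @param top_k size of the reported top candidate list.
#' @param screen1_rule,screen2_rule aggregation rules for the two screens.
#' @param score_mode `"mean"` (default: strict replicate-mean TPM
#'   inequality) or `"significant"` (a point additionally requires
#'   `p < 0.05` in that regeneration-vs-development contrast).
#' @return object of class `regen_screen` with elements `scores`
#'   (specificity tibble), `screen1_genes`, `screen2_genes`, `top_genes`,
#'   `n_genes`, and `params`.
#' @examples
#' sim <- simulate_bulk(bulk_sim_params(n_genes = 200,
#'   n_planted_regspecific = 5, n_planted_distal_shared = 5,
#'   n_planted_proximal = 5), seed = 1)
#' fit <- run_screen_pipeline(sim$counts, sim$samples, sim$lengths)
#' glance(fit)
#' @export
run_screen_pipeline <- function(counts, samples, lengths,
                                design = default_design(), alpha = 0.05,
                                top_k = 10,
                                screen1_rule = "union", screen2_rule = "any",
                                score_mode = c("mean", "significant"),
                                method = "exact") {
  score_mode <- match.arg(score_mode)
  samples <- validate_sample_sheet(samples, design)
  s1 <- screen1_corresponding_pairs(counts, samples, design, alpha,
                                    rule = screen1_rule, method = method)
  if (length(s1$genes) == 0) {
    warn("no genes passed screen 1; returning an empty table")
    s2 <- list(genes = character())
    scores <- specificity_score(tpm(counts, lengths), samples, character(),
                                design)
  } else {
    s2 <- screen2_distal_over_proximal(counts, samples, s1$genes, design,
                                       alpha, rule = screen2_rule,
                                       method = method)
    expr <- tpm(counts, lengths)
    scores <- specificity_score(expr, samples, s2$genes, design)
    if (score_mode == "significant" && nrow(scores) > 0) {
      scores <- apply_significance_score(counts, samples, design, scores,
                                         method)
    }
  }
  structure(list(
    scores = scores,
    screen1_genes = s1$genes,
    screen2_genes = s2$genes,
    top_genes = head(scores$gene_id, top_k),
    n_genes = nrow(counts),
    params = list(alpha = alpha, top_k = top_k, screen1_rule = screen1_rule,
                  screen2_rule = screen2_rule, score_mode = score_mode,
                  method = method)
  ), class = "regen_screen")
}

# internal: recompute points requiring per-comparison significance
apply_significance_score <- function(counts, samples, design, scores, method) {
  genes <- scores$gene_id
  score <- setNames(integer(length(genes)), genes)
  for (r in design$reg_distal_conditions) {
    cols_r <- samples$column_id[samples$condition == r]
    for (d in design$dev_distal_conditions) {
      cols_d <- samples$column_id[samples$condition == d]
      res <- de_test(counts, cols_d, cols_r, method = method)
      idx <- match(genes, res$gene_id)
      point <- res$p[idx] < 0.05 & res$mean_b[idx] > res$mean_a[idx]
      score <- score + as.integer(point)
    }
  }
  scores$score <- as.integer(score[scores$gene_id])
  scores %>%
    arrange(desc(.data$score), desc(.data$margin), .data$gene_id) %>%
    mutate(rank = dplyr::row_number())
}

#' @export
print.regen_screen <- function(x, ...) {
  cat("<regen_screen> ", x$n_genes, " genes -> ",
      length(x$screen1_genes), " (screen 1) -> ",
      length(x$screen2_genes), " (screen 2); top scores:\n", sep = "")
  print(head(x$scores, 5))
  invisible(x)
}

#' @describeIn run_screen_pipeline per-gene specificity table
#'   (`gene_id`, `score`, `margin`, `rank`, screen flags).
#' @param x a `regen_screen` object.
#' @param ... unused.
#' @method tidy regen_screen
#' @export
tidy.regen_screen <- function(x, ...) {
  x$scores %>%
    mutate(passed_screen1 = TRUE, passed_screen2 = TRUE)
}

#' @describeIn run_screen_pipeline one-row summary of per-step gene counts.
#' @method glance regen_screen
#' @export
glance.regen_screen <- function(x, ...) {
  tibble(n_genes = x$n_genes,
         n_screen1 = length(x$screen1_genes),
         n_screen2 = length(x$screen2_genes),
         n_scored = nrow(x$scores),
         max_score = if (nrow(x$scores)) max(x$scores$score) else NA_integer_)
}

#' @describeIn run_screen_pipeline bar chart of the specificity-score
#'   distribution among scored genes.
#' @param object a `regen_screen` object.
#' @method autoplot regen_screen
#' @export
autoplot.regen_screen <- function(object, ...) {
  df <- object$scores %>% dplyr::count(.data$score)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$score, levels = 0:8),
                                   y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "regeneration-specificity score (0-8)",
                  y = "genes",
                  title = "Specificity-score distribution") +
    ggplot2::theme_minimal()
}
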