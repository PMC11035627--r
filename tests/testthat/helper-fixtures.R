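# small fixture builders shared across test files

# minimal 12-condition sample sheet with `n_rep` replicates per condition
tiny_design_sheet <- function(n_rep = 3) {
  d <- default_design()$conditions
  out <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    data.frame(column_id = paste0(d$condition[i], "_r", seq_len(n_rep)),
               process = d$process[i], axis = d$axis[i],
               timepoint = d$timepoint_index[i], replicate = seq_len(n_rep))
  }))
  tibble::as_tibble(out)
}

# wide counts tibble from a plain matrix with default ids
counts_tbl <- function(m, gene_ids = sprintf("g%03d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% paste0("s", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                   tibble::as_tibble(as.data.frame(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent quadratic-time step-up BH oracle
bh_oracle <- function(p) {
  n <- length(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    # step-up: min over all j with p_(j) >= p_i of p_(j) * n / j
    candidates <- vapply(seq_len(n), function(j) {
      sort(p)[j] * n / j
    }, numeric(1))
    rank_i <- sum(p <= p[i])
    adj[i] <- min(1, min(candidates[rank_i:n]))
  }
  adj
}

# independent double-loop specificity-score oracle on condition means
score_oracle <- function(reg_means, dev_means) {
  score <- 0L
  for (r in seq_along(reg_means)) {
    for (d in seq_along(dev_means)) {
      if (reg_means[r] > dev_means[d]) score <- score + 1L
    }
  }
  score
}
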