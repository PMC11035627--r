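#' Parameters for the bulk count simulator
#'
#' Counts are negative-binomial with variance `mu + phi * mu^2`; per-gene
#' baseline relative abundances are drawn log-uniformly over three orders of
#' magnitude, library sizes are log-normal. Planted gene classes:
#' * `regspecific` — elevated `regspecific_fold`-fold only in the
#'   regeneration-distal conditions (`regD1`, `regD2`),
#' * `distal_shared` — elevated `planted_fold`-fold in every distal
#'   condition of both processes,
#' * `proximal` — elevated `planted_fold`-fold in every proximal condition.
#'
#' @param n_genes,n_replicates simulation size (replicates per condition).
#' @param library_size_mean,library_size_cv log-normal library-size model.
#' @param dispersion NB dispersion `phi` (>= 0; 0 gives Poisson counts).
#' @param n_planted_regspecific,regspecific_fold regeneration-specific
#'   planting.
#' @param n_planted_distal_shared,n_planted_proximal,planted_fold shared
#'   patterning-gene planting.
#' @param gene_length_range log-uniform range for gene lengths (nt).
#' @return validated parameter list of class `bulk_sim_params`.
#' @export
bulk_sim_params <- function(n_genes = 5000, n_replicates = 3,
                            library_size_mean = 1e6, library_size_cv = 0.1,
                            dispersion = 0.1,
                            n_planted_regspecific = 20, regspecific_fold = 8,
                            n_planted_distal_shared = 50,
                            n_planted_proximal = 50, planted_fold = 8,
                            gene_length_range = c(200, 10000)) {
  p <- list(n_genes = as.integer(n_genes),
            n_replicates = as.integer(n_replicates),
            library_size_mean = library_size_mean,
            library_size_cv = library_size_cv,
            dispersion = dispersion,
            n_planted_regspecific = as.integer(n_planted_regspecific),
            regspecific_fold = regspecific_fold,
            n_planted_distal_shared = as.integer(n_planted_distal_shared),
            n_planted_proximal = as.integer(n_planted_proximal),
            planted_fold = planted_fold,
            gene_length_range = gene_length_range)
  if (p$n_genes < 1 || p$n_replicates < 2) abort("need n_genes >= 1 and n_replicates >= 2")
  if (p$library_size_mean <= 0 || p$library_size_cv < 0) abort("invalid library-size model")
  if (p$dispersion < 0) abort("dispersion must be >= 0")
  n_planted <- p$n_planted_regspecific + p$n_planted_distal_shared + p$n_planted_proximal
  if (n_planted > p$n_genes) abort("planted gene counts exceed n_genes")
  if (any(c(p$regspecific_fold, p$planted_fold) <= 1)) abort("folds must be > 1")
  if (length(p$gene_length_range) != 2 || p$gene_length_range[1] <= 0 ||
      diff(p$gene_length_range) < 0) abort("invalid gene_length_range")
  structure(p, class = "bulk_sim_params")
}

# internal: NB draw with variance mu + phi mu^2 (phi = 0 -> Poisson)
rnb <- function(n, mu, phi) {
  if (phi == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / phi)
}

# internal: log-normal draws with given mean and coefficient of variation
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a bulk development/regeneration dataset with planted truth
#'
#' Generates NB counts for every condition of `design` with `n_replicates`
#' replicates each, planting the gene classes described in
#' [bulk_sim_params()]. One master seed drives the run; per-column
#' sub-seeds are derived deterministically, so identical `(params, seed)`
#' give bitwise-identical output.
#'
#' @param params a [bulk_sim_params()] object.
#' @param seed integer master seed.
#' @param design study design (default [default_design()]).
#' @return list with `counts` (wide tibble), `samples` (sample sheet with
#'   `condition` labels), `lengths` (gene length tibble), `truth` (tibble
#'   `gene_id`, `class`).
#' @export
simulate_bulk <- function(params, seed, design = default_design()) {
  stopifnot(inherits(params, "bulk_sim_params"))
  if (missing(seed)) abort("a seed is required for simulation")
  p <- params
  gene_ids <- sprintf("g%05d", seq_len(p$n_genes))
  set.seed(derive_seed(seed, 0L))
  baseline <- exp(runif(p$n_genes, log(1), log(1000)))
  lengths <- exp(runif(p$n_genes, log(p$gene_length_range[1]),
                       log(p$gene_length_range[2])))
  classes <- rep("null", p$n_genes)
  planted_idx <- sample.int(p$n_genes, p$n_planted_regspecific +
                              p$n_planted_distal_shared + p$n_planted_proximal)
  classes[planted_idx] <- rep(c("regspecific", "distal_shared", "proximal"),
                              c(p$n_planted_regspecific,
                                p$n_planted_distal_shared,
                                p$n_planted_proximal))

  cond <- design$conditions
  samples <- tidyr::expand_grid(condition = cond$condition,
                                replicate = seq_len(p$n_replicates)) %>%
    left_join(cond, by = "condition") %>%
    mutate(column_id = paste0(.data$condition, "_r", .data$replicate),
           timepoint = .data$timepoint_index) %>%
    select("column_id", "process", "axis", "timepoint", "replicate",
           "condition")

  lib_sizes <- rlnorm_mean_cv(nrow(samples), p$library_size_mean,
                              p$library_size_cv)

  counts <- matrix(0L, nrow = p$n_genes, ncol = nrow(samples),
                   dimnames = list(gene_ids, samples$column_id))
  for (j in seq_len(nrow(samples))) {
    w <- baseline
    is_distal <- samples$axis[j] == "distal"
    is_reg <- samples$process[j] == "regeneration"
    if (is_reg && is_distal) {
      w[classes == "regspecific"] <- w[classes == "regspecific"] * p$regspecific_fold
    }
    if (is_distal) {
      w[classes == "distal_shared"] <- w[classes == "distal_shared"] * p$planted_fold
    } else {
      w[classes == "proximal"] <- w[classes == "proximal"] * p$planted_fold
    }
    mu <- lib_sizes[j] * w / sum(w)
    set.seed(derive_seed(seed, j))
    counts[, j] <- rnb(p$n_genes, mu, p$dispersion)
  }

  list(counts = matrix_to_tibble(counts),
       samples = samples,
       lengths = tibble(gene_id = gene_ids, length = lengths),
       truth = tibble(gene_id = gene_ids, class = classes))
}

#' Parameters for the two-population single-cell simulator
#'
#' @param n_genes,n_cells_per_population simulation size.
#' @param capture_depth_mean mean per-cell total count (log-normal,
#'   `depth_cv`).
#' @param depth_cv coefficient of variation of per-cell depth.
#' @param dispersion NB dispersion.
#' @param n_planted_markers,marker_fold markers elevated `marker_fold`-fold
#'   in the reference population.
#' @param dropout_extra extra Bernoulli zeroing probability in \[0, 1\].
#' @return validated list of class `sc_sim_params`.
#' @export
sc_sim_params <- function(n_genes = 1000, n_cells_per_population = 500,
                          capture_depth_mean = 2000, depth_cv = 0.3,
                          dispersion = 0.1, n_planted_markers = 50,
                          marker_fold = 4, dropout_extra = 0) {
  p <- list(n_genes = as.integer(n_genes),
            n_cells_per_population = as.integer(n_cells_per_population),
            capture_depth_mean = capture_depth_mean, depth_cv = depth_cv,
            dispersion = dispersion,
            n_planted_markers = as.integer(n_planted_markers),
            marker_fold = marker_fold, dropout_extra = dropout_extra)
  if (p$n_cells_per_population < 2) abort("need >= 2 cells per population")
  if (p$n_planted_markers > p$n_genes) abort("n_planted_markers > n_genes")
  if (p$marker_fold <= 2) abort("marker_fold must be > 2")
  if (p$dropout_extra < 0 || p$dropout_extra > 1) abort("dropout_extra in [0,1]")
  if (p$dispersion < 0) abort("dispersion must be >= 0")
  structure(p, class = "sc_sim_params")
}

# internal: simulate one population block of NB counts with dropout
sc_population_block <- function(n_genes, n_cells, w, depth_mean, depth_cv,
                                phi, dropout, seed, seed_offset) {
  set.seed(derive_seed(seed, seed_offset))
  depths <- rlnorm_mean_cv(n_cells, depth_mean, depth_cv)
  block <- matrix(0L, nrow = n_genes, ncol = n_cells)
  prob <- w / sum(w)
  for (j in seq_len(n_cells)) {
    set.seed(derive_seed(seed, seed_offset + j))
    x <- rnb(n_genes, depths[j] * prob, phi)
    if (dropout > 0) x <- x * (runif(n_genes) >= dropout)
    block[, j] <- as.integer(x)
  }
  block
}

#' Simulate a two-population single-cell dataset with planted markers
#'
#' NB counts with optional extra dropout for a `reference` (limb bud) and a
#' `contrast` (blastema) population; planted markers are elevated
#' `marker_fold`-fold in the reference population.
#'
#' @param params an [sc_sim_params()] object.
#' @param seed integer master seed.
#' @return list with `counts` (sparse `dgCMatrix`, genes x cells), `cells`
#'   (tibble `cell_id`, `population`), `truth` (tibble `gene_id`, `class`
#'   in marker/null).
#' @export
simulate_sc <- function(params, seed) {
  stopifnot(inherits(params, "sc_sim_params"))
  if (missing(seed)) abort("a seed is required for simulation")
  p <- params
  gene_ids <- sprintf("g%05d", seq_len(p$n_genes))
  set.seed(derive_seed(seed, 0L))
  baseline <- exp(runif(p$n_genes, log(1), log(1000)))
  classes <- rep("null", p$n_genes)
  classes[sample.int(p$n_genes, p$n_planted_markers)] <- "marker"
  # markers emulate detectably expressed population markers: their baseline
  # abundance is drawn from the expressed part of the range
  baseline[classes == "marker"] <-
    exp(runif(p$n_planted_markers, log(10), log(1000)))
  w_ref <- baseline
  w_ref[classes == "marker"] <- w_ref[classes == "marker"] * p$marker_fold
  nc <- p$n_cells_per_population
  ref <- sc_population_block(p$n_genes, nc, w_ref, p$capture_depth_mean,
                             p$depth_cv, p$dispersion, p$dropout_extra,
                             seed, 1L)
  con <- sc_population_block(p$n_genes, nc, baseline, p$capture_depth_mean,
                             p$depth_cv, p$dispersion, p$dropout_extra,
                             seed, nc + 2L)
  counts <- cbind(ref, con)
  rownames(counts) <- gene_ids
  colnames(counts) <- c(sprintf("ref_c%04d", seq_len(nc)),
                        sprintf("con_c%04d", seq_len(nc)))
  cells <- tibble(cell_id = colnames(counts),
                  population = rep(c("reference", "contrast"), each = nc))
  list(counts = methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                        "CsparseMatrix"), "generalMatrix"),
       cells = cells,
       truth = tibble(gene_id = gene_ids, class = classes))
}

#' Parameters for the paired shift simulator
#'
#' Generates a single-cell reference contrast (limb bud vs blastema) and a
#' bulk transgenic-vs-control contrast that share `n_common_genes`
#' differential genes. Each common gene has a random single-cell direction;
#' with probability `concordance_rate` the bulk Tg effect points the same
#' way (toward the limb-bud state), otherwise it opposes it. Common genes
#' draw their abundance weights from the upper part of the expression range
#' (markers are moderately-to-highly expressed); `n_null_genes` fillers span
#' the full range.
#'
#' @param n_common_genes planted common differential genes.
#' @param concordance_rate probability a common gene's Tg direction matches
#'   its developmental direction.
#' @param tg_effect_log2 bulk Tg effect size (log2 fold, > 0).
#' @param n_null_genes non-differential filler genes.
#' @param sc_marker_fold single-cell fold for common genes (> 2).
#' @param n_cells_per_population,capture_depth_mean,depth_cv,dispersion
#'   single-cell generator settings.
#' @param n_replicates_bulk,bulk_library_size bulk generator settings.
#' @return validated list of class `shift_sim_params`.
#' @export
shift_sim_params <- function(n_common_genes = 2000, concordance_rate = 0.8,
                             tg_effect_log2 = 2, n_null_genes = 500,
                             sc_marker_fold = 4,
                             n_cells_per_population = 400,
                             capture_depth_mean = 2000, depth_cv = 0.3,
                             dispersion = 0.1, n_replicates_bulk = 4,
                             bulk_library_size = 1e6) {
  p <- list(n_common_genes = as.integer(n_common_genes),
            concordance_rate = concordance_rate,
            tg_effect_log2 = tg_effect_log2,
            n_null_genes = as.integer(n_null_genes),
            sc_marker_fold = sc_marker_fold,
            n_cells_per_population = as.integer(n_cells_per_population),
            capture_depth_mean = capture_depth_mean, depth_cv = depth_cv,
            dispersion = dispersion,
            n_replicates_bulk = as.integer(n_replicates_bulk),
            bulk_library_size = bulk_library_size)
  if (p$concordance_rate < 0 || p$concordance_rate > 1) {
    abort("concordance_rate must be in [0, 1]")
  }
  if (p$tg_effect_log2 <= 0) abort("tg_effect_log2 must be > 0")
  if (p$sc_marker_fold <= 2) abort("sc_marker_fold must be > 2")
  if (p$n_cells_per_population < 2) abort("need >= 2 cells per population")
  if (p$n_replicates_bulk < 2) abort("need >= 2 bulk replicates per arm")
  structure(p, class = "shift_sim_params")
}

#' Simulate a paired single-cell + bulk Tg dataset with known concordance
#'
#' @param params a [shift_sim_params()] object.
#' @param seed integer master seed.
#' @return list with `sc` (as [simulate_sc()]: `counts`, `cells`), `bulk`
#'   (`counts` wide tibble, `samples` tibble with `column_id`, `group` in
#'   tg/control), and `truth` (tibble `gene_id`, `class` in
#'   concordant/discordant/null, `sc_direction`, `tg_direction`).
#' @export
simulate_shift_pair <- function(params, seed) {
  stopifnot(inherits(params, "shift_sim_params"))
  if (missing(seed)) abort("a seed is required for simulation")
  p <- params
  n_genes <- p$n_common_genes + p$n_null_genes
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  common <- seq_len(p$n_common_genes)

  set.seed(derive_seed(seed, 0L))
  w_base <- exp(runif(n_genes, log(0.5), log(200)))
  w_base[common] <- exp(runif(p$n_common_genes, log(10), log(200)))
  sc_dir <- integer(n_genes)
  sc_dir[common] <- sample(c(1L, -1L), p$n_common_genes, replace = TRUE)
  concordant <- logical(n_genes)
  concordant[common] <- runif(p$n_common_genes) < p$concordance_rate
  tg_dir <- integer(n_genes)
  tg_dir[common] <- ifelse(concordant[common], sc_dir[common], -sc_dir[common])

  w_ref <- w_base
  w_con <- w_base
  up_ref <- sc_dir == 1L
  up_con <- sc_dir == -1L
  w_ref[up_ref] <- w_ref[up_ref] * p$sc_marker_fold
  w_con[up_con] <- w_con[up_con] * p$sc_marker_fold

  nc <- p$n_cells_per_population
  ref <- sc_population_block(n_genes, nc, w_ref, p$capture_depth_mean,
                             p$depth_cv, p$dispersion, 0, seed, 1L)
  con <- sc_population_block(n_genes, nc, w_con, p$capture_depth_mean,
                             p$depth_cv, p$dispersion, 0, seed, nc + 2L)
  sc_counts <- cbind(ref, con)
  rownames(sc_counts) <- gene_ids
  colnames(sc_counts) <- c(sprintf("ref_c%04d", seq_len(nc)),
                           sprintf("con_c%04d", seq_len(nc)))
  cells <- tibble(cell_id = colnames(sc_counts),
                  population = rep(c("reference", "contrast"), each = nc))

  w_tg <- w_base * 2^(p$tg_effect_log2 * tg_dir)
  nrep <- p$n_replicates_bulk
  bulk <- matrix(0L, nrow = n_genes, ncol = 2 * nrep,
                 dimnames = list(gene_ids,
                                 c(sprintf("control_r%d", seq_len(nrep)),
                                   sprintf("tg_r%d", seq_len(nrep)))))
  set.seed(derive_seed(seed, 2L * nc + 10L))
  lib <- rlnorm_mean_cv(2 * nrep, p$bulk_library_size, 0.1)
  for (j in seq_len(2 * nrep)) {
    w <- if (j <= nrep) w_base else w_tg
    set.seed(derive_seed(seed, 2L * nc + 10L + j))
    bulk[, j] <- rnb(n_genes, lib[j] * w / sum(w), p$dispersion)
  }
  bulk_samples <- tibble(column_id = colnames(bulk),
                         group = rep(c("control", "tg"), each = nrep))

  truth_class <- rep("null", n_genes)
  truth_class[common] <- ifelse(concordant[common], "concordant", "discordant")
  list(sc = list(counts = methods::as(methods::as(
         Matrix::Matrix(sc_counts, sparse = TRUE),
         "CsparseMatrix"), "generalMatrix"),
       cells = cells),
       bulk = list(counts = matrix_to_tibble(bulk), samples = bulk_samples),
       truth = tibble(gene_id = gene_ids, class = truth_class,
                      sc_direction = sc_dir, tg_direction = tg_dir))
}
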