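#' The fixed 12-condition development/regeneration study design
#'
#' Limb development is sampled at four timepoints in two axial regions
#' (distal `devD1..devD4`, proximal `devP1..devP4`); larval regeneration at
#' two timepoints in the same two regions (`regD1`, `regD2`, `regP1`,
#' `regP2`). Each regeneration condition has a *corresponding pair* on the
#' development side, matched by tissue stage/shape rather than by timepoint
#' index: `regD1~devD1`, `regD2~devD2`, `regP1~devP3`, `regP2~devP4`.
#'
#' @return An object of class `regen_design`: a list with
#'   * `conditions` — tibble with `condition`, `process`, `axis`,
#'     `timepoint_index` (12 rows),
#'   * `corresponding_pairs` — tibble with `regeneration` and `development`
#'     condition labels (4 rows),
#'   * `reg_distal_conditions` — `c("regD1", "regD2")`,
#'   * `dev_distal_conditions` — `c("devD1", ..., "devD4")`.
#' @examples
#' d <- default_design()
#' d$corresponding_pairs
#' @export
default_design <- function() {
  conditions <- tibble(
    condition = c(paste0("devD", 1:4), paste0("devP", 1:4),
                  paste0("regD", 1:2), paste0("regP", 1:2)),
    process = rep(c("development", "regeneration"), c(8L, 4L)),
    axis = c(rep("distal", 4), rep("proximal", 4),
             rep("distal", 2), rep("proximal", 2)),
    timepoint_index = c(1:4, 1:4, 1:2, 1:2)
  )
  structure(
    list(
      conditions = conditions,
      corresponding_pairs = tibble(
        regeneration = c("regD1", "regD2", "regP1", "regP2"),
        development  = c("devD1", "devD2", "devP3", "devP4")
      ),
      reg_distal_conditions = c("regD1", "regD2"),
      dev_distal_conditions = paste0("devD", 1:4)
    ),
    class = "regen_design"
  )
}

#' @export
print.regen_design <- function(x, ...) {
  cat("<regen_design> ", nrow(x$conditions), " conditions, ",
      nrow(x$corresponding_pairs), " corresponding pairs\n", sep = "")
  print(x$corresponding_pairs)
  invisible(x)
}

#' Condition label for a sample-sheet row
#'
#' Builds the short condition labels used throughout the package
#' (`devD1`, `regP2`, ...) from the `process`/`axis`/`timepoint` encoding of
#' a sample sheet. `tg`/`control` samples keep their process name as label.
#'
#' @param process character vector in
#'   `c("development", "regeneration", "tg", "control")`.
#' @param axis character vector in `c("distal", "proximal", "na")`.
#' @param timepoint integer timepoint index (>= 1).
#' @return character vector of condition labels.
#' @export
condition_label <- function(process, axis, timepoint) {
  ifelse(process %in% c("tg", "control"),
         as.character(process),
         paste0(ifelse(process == "development", "dev", "reg"),
                ifelse(axis == "distal", "D", "P"),
                timepoint))
}

#' Validate a sample sheet against the study design
#'
#' Checks column presence, enum values, uniqueness of the
#' (process, axis, timepoint, replicate) key, and — when `design` is given —
#' that every design condition is represented by at least `min_replicates`
#' samples. Missing conditions are reported as `process/axis/t<timepoint>`.
#'
#' @param samples data frame with columns `column_id`, `process`, `axis`,
#'   `timepoint`, `replicate`.
#' @param design optional `regen_design` whose conditions must be covered.
#' @param min_replicates minimum replicate count per required condition.
#' @return the sample sheet as a tibble, with a `condition` label column
#'   appended, invisibly usable downstream.
#' @export
validate_sample_sheet <- function(samples, design = NULL, min_replicates = 2L) {
  required <- c("column_id", "process", "axis", "timepoint", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  samples <- as_tibble(samples)
  ok_proc <- c("development", "regeneration", "tg", "control")
  if (!all(samples$process %in% ok_proc)) {
    abort(paste0("invalid process value(s): ",
                 paste(unique(setdiff(samples$process, ok_proc)), collapse = ", ")))
  }
  if (!all(samples$axis %in% c("distal", "proximal", "na"))) {
    abort("invalid axis value(s); expected distal/proximal/na")
  }
  if (anyDuplicated(samples$column_id)) abort("column_id values must be unique")
  key <- paste(samples$process, samples$axis, samples$timepoint, samples$replicate)
  if (anyDuplicated(key)) {
    abort("(process, axis, timepoint, replicate) must be unique across the sheet")
  }
  samples$condition <- condition_label(samples$process, samples$axis,
                                       samples$timepoint)
  if (!is.null(design)) {
    counts <- table(samples$condition)
    need <- design$conditions
    have <- as.integer(counts[need$condition])
    have[is.na(have)] <- 0L
    short <- need[have < min_replicates, ]
    if (nrow(short) > 0) {
      labels <- paste0(short$process, "/", short$axis, "/t", short$timepoint_index)
      abort(paste0("sample sheet is missing (or has < ", min_replicates,
                   " replicates for) condition(s): ",
                   paste(labels, collapse = ", ")))
    }
  }
  samples
}

# internal: column ids belonging to one condition label
columns_for_condition <- function(samples, condition) {
  samples <- validate_sample_sheet(samples)
  samples$column_id[samples$condition == condition]
}

#' Aggregate homeologous gene copies
#'
#' In the allotetraploid *Xenopus laevis* genome, most genes exist as `.L`
#' and `.S` homeologs; gene-level expression is the sum of the two copies.
#' Rows of `x` whose `gene_id` appears in `mapping` are summed into their
#' `group_id`; unmapped genes pass through under their own id. Row order is
#' first occurrence; the grand total of the matrix is conserved.
#'
#' @param x wide counts/expression tibble: `gene_id` column plus numeric
#'   sample columns.
#' @param mapping data frame with columns `gene_id`, `group_id`. May map
#'   only a subset of genes. A `group_id` that collides with the id of an
#'   unmapped gene is an error.
#' @return tibble of the same shape with aggregated rows.
#' @examples
#' x <- tibble::tibble(gene_id = c("hoxc12.L", "hoxc12.S", "shh.L"),
#'                     s1 = c(3, 1.5, 2))
#' aggregate_homeologs(x, data.frame(gene_id = c("hoxc12.L", "hoxc12.S"),
#'                                   group_id = "hoxc12"))
#' @export
aggregate_homeologs <- function(x, mapping) {
  stopifnot(is.data.frame(x), "gene_id" %in% names(x))
  if (nrow(mapping) == 0 || is.null(mapping)) return(as_tibble(x))
  stopifnot(all(c("gene_id", "group_id") %in% names(mapping)))
  mapping <- as_tibble(mapping)
  if (anyDuplicated(mapping$gene_id)) abort("mapping gene_id values must be unique")
  ids <- as.character(x$gene_id)
  new_id <- ids
  hit <- match(ids, mapping$gene_id)
  new_id[!is.na(hit)] <- mapping$group_id[hit[!is.na(hit)]]
  passthrough <- ids[is.na(hit)]
  clash <- intersect(unique(mapping$group_id), passthrough)
  if (length(clash) > 0) {
    abort(paste0("group_id collides with existing unmapped gene id(s): ",
                 paste(clash, collapse = ", ")))
  }
  first <- !duplicated(new_id)
  order_ids <- new_id[first]
  num_cols <- setdiff(names(x), "gene_id")
  m <- as.matrix(x[num_cols])
  agg <- rowsum(m, group = new_id, reorder = FALSE)
  agg <- agg[order_ids, , drop = FALSE]
  dplyr::bind_cols(tibble(gene_id = order_ids),
                   as_tibble(as.data.frame(agg, check.names = FALSE)))
}

#' Merge .L/.S homeolog suffixes into gene-level ids
#'
#' Convenience builder for an [aggregate_homeologs()] mapping that strips a
#' trailing `.L`/`.S` suffix. Suffix inference is genome-version-fragile, so
#' this is never applied implicitly; callers must opt in.
#'
#' @param gene_ids character vector of gene ids.
#' @return mapping tibble (`gene_id`, `group_id`) covering only ids that end
#'   in `.L` or `.S`.
#' @export
homeolog_suffix_map <- function(gene_ids) {
  has_suffix <- grepl("\\.(L|S)$", gene_ids)
  tibble(gene_id = gene_ids[has_suffix],
         group_id = sub("\\.(L|S)$", "", gene_ids[has_suffix]))
}
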