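#' Read and write the package's plain-text formats
#'
#' All tabular formats are tab-separated with a header row, UTF-8, no
#' quoting; counts tables have `gene_id` as their first column. Sparse
#' single-cell matrices use Matrix Market coordinate triplets (1-based,
#' integer values) with companion `features.tsv` / `cells.tsv` files
#' defining row and column identities.
#'
#' @param path file path (for the sparse reader/writer, the `.mtx` path;
#'   companions are looked up / written next to it).
#' @param x object to write.
#' @name regenscreen_io
NULL

#' @rdname regenscreen_io
#' @export
read_counts_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(out)[1] != "gene_id") {
    abort(paste0(path, ": first column must be 'gene_id'"))
  }
  out
}

#' @rdname regenscreen_io
#' @export
write_counts_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname regenscreen_io
#' @export
read_sample_sheet <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_sheet(out)
}

#' @rdname regenscreen_io
#' @export
read_homeolog_map <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "group_id") %in% names(out))) {
    abort(paste0(path, ": expected columns gene_id, group_id"))
  }
  out
}

#' @rdname regenscreen_io
#' @export
read_sc_mtx <- function(path) {
  dir <- dirname(path)
  m <- methods::as(methods::as(Matrix::readMM(path), "CsparseMatrix"),
                   "generalMatrix")
  features <- readr::read_tsv(file.path(dir, "features.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  if (nrow(features) != nrow(m) || nrow(cells) != ncol(m)) {
    abort(paste0(path, ": companion file dimensions do not match the matrix"))
  }
  rownames(m) <- features$gene_id
  colnames(m) <- cells$cell_id
  list(counts = m, cells = cells)
}

#' @rdname regenscreen_io
#' @param cells cell annotation tibble (`cell_id`, `population`).
#' @export
write_sc_mtx <- function(x, cells, path) {
  dir <- dirname(path)
  Matrix::writeMM(x, path)
  readr::write_tsv(tibble(gene_id = rownames(x)),
                   file.path(dir, "features.tsv"), progress = FALSE)
  readr::write_tsv(cells, file.path(dir, "cells.tsv"), progress = FALSE)
  invisible(path)
}
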