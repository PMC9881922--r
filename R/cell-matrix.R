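#' Cells-by-genes count container
#'
#' A light container for snRNA-seq expression: a sparse cells x genes raw
#' count matrix, an optional normalized layer of the same shape, and tibbles
#' of per-cell and per-gene metadata. Rows of `cell_meta` align with matrix
#' rows (barcodes), rows of `gene_meta` with matrix columns (gene ids).
#'
#' @param counts Sparse (or dense) cells x genes non-negative integer matrix
#'   with barcodes as rownames and gene ids as colnames.
#' @param cell_meta Tibble with a `barcode` column matching `rownames(counts)`.
#' @param gene_meta Tibble with a `gene_id` column matching
#'   `colnames(counts)`; a `biotype` column and a logical `mito` column are
#'   expected by downstream stages.
#' @param norm Optional normalized layer (same shape as `counts`).
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_meta, gene_meta, norm = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  cell_meta <- as_tibble(cell_meta)
  gene_meta <- as_tibble(gene_meta)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_bad_arg("counts must carry barcode rownames and gene_id colnames")
  }
  if (!identical(rownames(counts), cell_meta$barcode)) {
    stop_bad_arg("cell_meta$barcode must match rownames(counts)")
  }
  if (!identical(colnames(counts), gene_meta$gene_id)) {
    stop_bad_arg("gene_meta$gene_id must match colnames(counts)")
  }
  if (any(counts@x < 0)) stop_bad_arg("counts must be non-negative")
  structure(list(counts = counts, norm = norm,
                 cell_meta = cell_meta, gene_meta = gene_meta),
            class = "cell_matrix")
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' @exportS3Method base::print
print.cell_matrix <- function(x, ...) {
  cat("<cell_matrix> ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes; ", if (is.null(x$norm)) "raw only" else "raw + normalized",
      "\n", sep = "")
  invisible(x)
}

#' Turn a cell_matrix into a long tibble
#'
#' One row per non-zero entry of the requested layer, joined with cell and
#' gene metadata columns.
#'
#' @param x A [cell_matrix()].
#' @param layer `"counts"` or `"norm"`.
#' @param ... Unused.
#' @return A tibble with `barcode`, `gene_id`, `value` plus metadata columns.
#' @export
tidy.cell_matrix <- function(x, layer = c("counts", "norm"), ...) {
  layer <- match.arg(layer)
  m <- if (layer == "counts") x$counts else x$norm
  if (is.null(m)) stop_bad_arg("normalized layer not present; run normalize_log()")
  tm <- methods::as(m, "TsparseMatrix")
  tibble(barcode = rownames(m)[tm@i + 1L],
         gene_id = colnames(m)[tm@j + 1L],
         value = tm@x) |>
    left_join(x$cell_meta, by = "barcode") |>
    left_join(x$gene_meta, by = "gene_id")
}

#' Summary statistics of a cell_matrix
#'
#' @param x A [cell_matrix()].
#' @param ... Unused.
#' @return A one-row tibble: cell and gene counts, total UMIs, median UMIs
#'   per cell, median genes detected per cell, sparsity.
#' @export
glance.cell_matrix <- function(x, ...) {
  umi <- Matrix::rowSums(x$counts)
  det <- Matrix::rowSums(x$counts > 0)
  tibble(
    n_cells = nrow(x$counts), n_genes = ncol(x$counts),
    total_umi = sum(umi), median_umi = median(umi),
    median_genes_detected = median(det),
    sparsity = 1 - Matrix::nnzero(x$counts) / prod(dim(x$counts))
  )
}

#' Write a cell_matrix as Matrix Market triplets with sidecar tables
#'
#' CellRanger triplet dialect: `matrix.mtx` holds the features x barcodes
#' sparse matrix, `barcodes.tsv` one barcode per line, `features.tsv` three
#' tab-separated columns (id, name, biotype). Cell metadata beyond the
#' barcode is written to `cell_meta.tsv`.
#'
#' @param x A [cell_matrix()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_matrix_mtx <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::t(x$counts), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  readr::write_lines(rownames(x$counts), file.path(dir, "barcodes.tsv"))
  feat <- tibble(id = x$gene_meta$gene_id, name = x$gene_meta$gene_id,
                 biotype = x$gene_meta$biotype %||%
                   rep("unknown", nrow(x$gene_meta)))
  readr::write_tsv(feat, file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(x$cell_meta, file.path(dir, "cell_meta.tsv"))
  invisible(dir)
}

#' Read a cell_matrix written by [write_matrix_mtx()]
#'
#' @param dir Directory holding `matrix.mtx`, `barcodes.tsv`, `features.tsv`
#'   and optionally `cell_meta.tsv`.
#' @return A [cell_matrix()].
#' @export
read_matrix_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  barcodes <- readr::read_lines(file.path(dir, "barcodes.tsv"))
  feat <- readr::read_tsv(file.path(dir, "features.tsv"),
                          col_names = c("id", "name", "biotype"),
                          col_types = "ccc", progress = FALSE)
  counts <- Matrix::t(m)
  rownames(counts) <- barcodes
  colnames(counts) <- feat$id
  meta_path <- file.path(dir, "cell_meta.tsv")
  cell_meta <- if (file.exists(meta_path)) {
    readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble(barcode = barcodes)
  }
  gene_meta <- tibble(gene_id = feat$id, biotype = feat$biotype,
                      mito = feat$biotype == "mitochondrial")
  cell_matrix(counts, cell_meta, gene_meta)
}
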