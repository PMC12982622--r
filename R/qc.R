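#' Read a gene x cell count matrix
#'
#' Accepts Matrix Market (`.mtx`, 1-based indices, with companion
#' `features.tsv` / `barcodes.tsv` giving row and column ids) or a dense
#' CSV/TSV with gene ids in the first column and cell ids as header.
#'
#' @param path `.mtx` file or delimited text file.
#' @param features,barcodes optional paths to the id files; default to
#'   `features.tsv` / `barcodes.tsv` next to the `.mtx`.
#' @return counts matrix (sparse `dgCMatrix` for mtx input) with dimnames.
#' @export
read_counts <- function(path, features = NULL, barcodes = NULL) {
  if (grepl("\\.mtx$", path)) {
    counts <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    dirn <- dirname(path)
    if (is.null(features)) features <- file.path(dirn, "features.tsv")
    if (is.null(barcodes)) barcodes <- file.path(dirn, "barcodes.tsv")
    feat <- data.table::fread(features, header = FALSE, sep = "\t")
    bc <- data.table::fread(barcodes, header = FALSE, sep = "\t")
    if (nrow(feat) != nrow(counts)) {
      stop("features file has ", nrow(feat), " rows but matrix has ",
           nrow(counts))
    }
    if (nrow(bc) != ncol(counts)) {
      stop("barcodes file has ", nrow(bc), " rows but matrix has ",
           ncol(counts), " columns")
    }
    dimnames(counts) <- list(feat[[1]], bc[[1]])
    counts
  } else {
    d <- data.table::fread(path)
    ids <- as.character(d[[1]])
    counts <- as.matrix(d[, -1, drop = FALSE])
    rownames(counts) <- ids
    counts
  }
}

#' Write counts as Matrix Market + id files
#'
#' @param counts gene x cell matrix with dimnames.
#' @param dir output directory (gets `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`).
#' @export
write_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' QC thresholds
#'
#' Defaults mirror a typical droplet-data quality-control recipe: at least
#' 100 detected features per cell, library size within `[2^9, 2^16]`, cell
#' types with at least 20 cells, genes detected in at least 16 cells with a
#' counts-per-cell ratio above 0.005.
#'
#' @param min_features_per_cell minimum number of nonzero genes per cell.
#' @param libsize_range allowed range (low, high) of total counts per cell.
#' @param min_cells_per_celltype cell types below this size are dropped.
#' @param min_cells_per_gene minimum number of cells a gene is detected in.
#' @param min_cpc minimum counts-per-cell ratio (gene total / n cells,
#'   computed after cell filtering).
#' @return list of class `sslmm_qc`.
#' @export
qc_thresholds <- function(min_features_per_cell = 100,
                          libsize_range = c(2^9, 2^16),
                          min_cells_per_celltype = 20,
                          min_cells_per_gene = 16, min_cpc = 0.005) {
  stopifnot(libsize_range[1] < libsize_range[2], min_cpc >= 0)
  structure(list(min_features_per_cell = min_features_per_cell,
                 libsize_range = libsize_range,
                 min_cells_per_celltype = min_cells_per_celltype,
                 min_cells_per_gene = min_cells_per_gene,
                 min_cpc = min_cpc), class = "sslmm_qc")
}

#' Filter cells then genes by QC thresholds
#'
#' Cells are filtered first (detected features, library size, then
#' cell-type size), then genes (detection count, then counts-per-cell ratio
#' computed on the retained cells). Each removed cell/gene is attributed to
#' the first rule it violates, so the report counts are conserved:
#' `in = kept + sum(removed by rule)`.
#'
#' @param counts gene x cell matrix (dense or sparse).
#' @param meta cell metadata data.frame aligned with columns of `counts`;
#'   needs a `cell_type` column if the cell-type rule is active.
#' @param thr [qc_thresholds()].
#' @return list with filtered `counts`, `meta` and a `report` list.
#' @export
filter_qc <- function(counts, meta, thr = qc_thresholds()) {
  stopifnot(nrow(meta) == ncol(counts))
  nfeat <- Matrix::colSums(counts > 0)
  libsz <- Matrix::colSums(counts)
  rule_feat <- nfeat < thr$min_features_per_cell
  rule_lib <- !rule_feat & (libsz < thr$libsize_range[1] |
                              libsz > thr$libsize_range[2])
  rule_ct <- rep(FALSE, ncol(counts))
  if (!is.null(meta$cell_type) && thr$min_cells_per_celltype > 0) {
    keep_pre <- !(rule_feat | rule_lib)
    ct_sizes <- table(meta$cell_type[keep_pre])
    small <- names(ct_sizes)[ct_sizes < thr$min_cells_per_celltype]
    rule_ct <- keep_pre & meta$cell_type %in% small
  }
  keep_cells <- !(rule_feat | rule_lib | rule_ct)
  if (!any(keep_cells)) stop("QC removed all cells")
  counts <- counts[, keep_cells, drop = FALSE]
  meta <- meta[keep_cells, , drop = FALSE]
  ndet <- Matrix::rowSums(counts > 0)
  cpc <- Matrix::rowSums(counts) / ncol(counts)
  g_det <- ndet < thr$min_cells_per_gene
  g_cpc <- !g_det & cpc <= thr$min_cpc
  keep_genes <- !(g_det | g_cpc)
  if (!any(keep_genes)) stop("QC removed all genes")
  report <- list(cells_in = length(keep_cells), cells_kept = sum(keep_cells),
                 cells_removed = c(features = sum(rule_feat),
                                   libsize = sum(rule_lib),
                                   celltype_size = sum(rule_ct)),
                 genes_in = length(keep_genes), genes_kept = sum(keep_genes),
                 genes_removed = c(detection = sum(g_det), cpc = sum(g_cpc)))
  out_counts <- counts[keep_genes, , drop = FALSE]
  # library size of the kept cells over *all* genes passing cell QC, i.e.
  # computed before gene filtering (what log(library_size) should use)
  attr(out_counts, "library_size_prefilter") <- as.numeric(libsz[keep_cells])
  list(counts = out_counts, meta = meta, report = report)
}
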