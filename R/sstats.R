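#' Log-transform a count matrix
#'
#' Elementwise `y = ln(1 + count)`. Sparse inputs stay sparse (zeros map to
#' zero).
#'
#' @param counts gene x cell matrix of nonnegative counts (base matrix or
#'   `Matrix` sparse matrix).
#' @return Matrix of the same shape and dimnames.
#' @export
log1p_transform <- function(counts) {
  mn <- if (inherits(counts, "sparseMatrix")) min(counts@x, 0) else min(counts)
  if (is.na(mn) || mn < 0) stop("counts must be nonnegative")
  if (inherits(counts, "sparseMatrix")) {
    counts@x <- log1p(counts@x)
    counts
  } else {
    log1p(counts)
  }
}

#' Compute the summary statistics sufficient for per-gene LMM fitting
#'
#' Accumulates, over cell chunks, the cross-products
#' `X'X, X'Y', Z'X, Z'Y', Z'Z` and the per-gene squared norms `y'y` that make
#' LMM estimation independent of the number of cells. Only one chunk of the
#' expression matrix is densified at a time.
#'
#' @param X fixed-effect design (n cells x p), rows aligned with columns of Y.
#' @param Z random-effect design (n x q) with a `"partition"` attribute, or a
#'   0-column matrix for a fixed-effects-only model.
#' @param Y gene x cell expression matrix (typically `log1p_transform()` of
#'   counts), dense or sparse. Cell alignment is verified against
#'   `rownames(X)` when both carry cell ids.
#' @param chunk_size number of cells processed per block (default 10000).
#' @param transform optional function applied to each densified chunk before
#'   accumulation (e.g. `log1p` to go straight from counts to log-scale
#'   statistics without materializing the transformed matrix).
#' @return An object of class `sslmm_sstats` with fields `XX, XY, ZX, ZY, ZZ,
#'   Ynorm, n, partition, gene_ids`.
#' @export
compute_sstats <- function(X, Z = NULL, Y, chunk_size = 10000,
                           transform = NULL) {
  X <- as.matrix(X)
  if (is.null(Z)) Z <- matrix(numeric(0), nrow(X), 0)
  part <- attr(Z, "partition")
  if (is.null(part)) part <- if (ncol(Z) > 0) stats::setNames(ncol(Z), "z") else integer(0)
  Z <- as.matrix(Z)
  n <- nrow(X)
  if (nrow(Z) != n) stop("X and Z have different numbers of rows")
  if (ncol(Y) != n) stop("Y has ", ncol(Y), " cells but X has ", n, " rows")
  if (!is.null(rownames(X)) && !is.null(colnames(Y)) &&
      !identical(rownames(X), colnames(Y))) {
    stop("cell ids of Y columns do not match rows of X")
  }
  m <- nrow(Y)
  p <- ncol(X); q <- ncol(Z)
  XX <- crossprod(X)
  ZZ <- crossprod(Z)
  ZX <- crossprod(Z, X)
  XY <- matrix(0, p, m)
  ZY <- matrix(0, q, m)
  Ynorm <- numeric(m)
  starts <- seq(1, n, by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1, n)
    Yc <- as.matrix(Y[, idx, drop = FALSE])      # m x |chunk|
    if (!is.null(transform)) Yc <- transform(Yc)
    XY <- XY + crossprod(X[idx, , drop = FALSE], t(Yc))
    if (q > 0) ZY <- ZY + crossprod(Z[idx, , drop = FALSE], t(Yc))
    Ynorm <- Ynorm + rowSums(Yc * Yc)
  }
  gene_ids <- rownames(Y)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(m))
  rownames(XY) <- colnames(X); colnames(XY) <- gene_ids
  if (q > 0) { rownames(ZY) <- colnames(Z); colnames(ZY) <- gene_ids }
  names(Ynorm) <- gene_ids
  structure(list(XX = XX, XY = XY, ZX = ZX, ZY = ZY, ZZ = ZZ,
                 Ynorm = Ynorm, n = n, partition = part,
                 gene_ids = gene_ids),
            class = "sslmm_sstats")
}

#' @export
print.sslmm_sstats <- function(x, ...) {
  cat("LMM summary statistics: n =", x$n, "cells, p =", ncol(x$XX),
      "fixed effects, q =", ncol(x$ZZ), "random effects (K =",
      length(x$partition), "), m =", length(x$gene_ids), "genes\n")
  invisible(x)
}

#' Merge summary statistics computed on disjoint sets of cells
#'
#' All fields are elementwise sums and `n` adds, so statistics can be
#' accumulated in parallel or streamed and combined.
#'
#' @param a,b `sslmm_sstats` over identical design columns and gene ids.
#' @return Merged `sslmm_sstats`.
#' @export
merge_sstats <- function(a, b) {
  stopifnot(inherits(a, "sslmm_sstats"), inherits(b, "sslmm_sstats"))
  if (!identical(a$gene_ids, b$gene_ids)) stop("gene ids differ")
  if (!identical(dim(a$XX), dim(b$XX)) || !identical(dim(a$ZZ), dim(b$ZZ))) {
    stop("design shapes differ")
  }
  if (!identical(a$partition, b$partition)) stop("random-effect partitions differ")
  structure(list(XX = a$XX + b$XX, XY = a$XY + b$XY, ZX = a$ZX + b$ZX,
                 ZY = a$ZY + b$ZY, ZZ = a$ZZ + b$ZZ,
                 Ynorm = a$Ynorm + b$Ynorm, n = a$n + b$n,
                 partition = a$partition, gene_ids = a$gene_ids),
            class = "sslmm_sstats")
}

#' Drop the random part of a summary-statistics object
#'
#' Produces the statistics of the nested fixed-effects-only model (K = 0);
#' fitting it gives the reduced likelihood for variance-component LRTs.
#'
#' @param ss `sslmm_sstats`.
#' @return `sslmm_sstats` with empty Z blocks.
#' @export
drop_random <- function(ss) {
  stopifnot(inherits(ss, "sslmm_sstats"))
  p <- ncol(ss$XX)
  ss$ZX <- matrix(numeric(0), 0, p)
  ss$ZY <- matrix(numeric(0), 0, length(ss$gene_ids))
  ss$ZZ <- matrix(numeric(0), 0, 0)
  ss$partition <- integer(0)
  ss
}

#' Write / read a summary-statistics archive
#'
#' The archive is a directory of plain-text TSV matrices plus a JSON header
#' (`meta.json` holding `n`, the partition and gene ids), so fitting can run
#' later without the raw expression matrix.
#'
#' @param ss `sslmm_sstats`.
#' @param dir archive directory (created if needed).
#' @return `write_sstats` returns `dir` invisibly; `read_sstats` returns the
#'   restored `sslmm_sstats`.
#' @export
write_sstats <- function(ss, dir) {
  stopifnot(inherits(ss, "sslmm_sstats"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(M, f) {
    # format explicitly: full 17 significant digits so fits from a restored
    # archive agree with in-memory fits to rounding
    d <- data.table::as.data.table(as.matrix(M))
    for (j in seq_along(d)) d[[j]] <- formatC(d[[j]], digits = 17, format = "g")
    data.table::fwrite(d, file.path(dir, f), sep = "\t", col.names = TRUE)
  }
  wm(ss$XX, "XX.tsv"); wm(ss$XY, "XY.tsv"); wm(ss$ZX, "ZX.tsv")
  wm(ss$ZY, "ZY.tsv"); wm(ss$ZZ, "ZZ.tsv")
  jsonlite::write_json(
    list(n = ss$n, partition = as.list(ss$partition),
         gene_ids = ss$gene_ids, Ynorm = unname(ss$Ynorm),
         xnames = colnames(ss$XX), znames = colnames(ss$ZZ)),
    file.path(dir, "meta.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_sstats
#' @export
read_sstats <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  rm_ <- function(f) {
    d <- data.table::fread(file.path(dir, f), sep = "\t",
                           colClasses = "numeric")
    M <- as.matrix(d)
    if (length(M) == 0) M <- matrix(numeric(0), 0, 0)
    storage.mode(M) <- "double"
    M
  }
  XX <- rm_("XX.tsv"); XY <- rm_("XY.tsv"); ZX <- rm_("ZX.tsv")
  ZY <- rm_("ZY.tsv"); ZZ <- rm_("ZZ.tsv")
  p <- ncol(XX)
  if (nrow(ZX) == 0) ZX <- matrix(numeric(0), 0, p)
  if (nrow(ZY) == 0) ZY <- matrix(numeric(0), 0, length(meta$gene_ids))
  dimnames(XX) <- list(meta$xnames, meta$xnames)
  rownames(XY) <- meta$xnames; colnames(XY) <- meta$gene_ids
  if (ncol(ZZ) > 0) {
    dimnames(ZZ) <- list(meta$znames, meta$znames)
    rownames(ZX) <- meta$znames; colnames(ZX) <- meta$xnames
    rownames(ZY) <- meta$znames; colnames(ZY) <- meta$gene_ids
  }
  part <- unlist(meta$partition)
  if (is.null(part)) part <- integer(0)
  structure(list(XX = XX, XY = XY, ZX = ZX, ZY = ZY, ZZ = ZZ,
                 Ynorm = stats::setNames(meta$Ynorm, meta$gene_ids),
                 n = meta$n, partition = part, gene_ids = meta$gene_ids),
            class = "sslmm_sstats")
}
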