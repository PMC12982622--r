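#' Declare the fixed- and random-effect structure of a per-gene LMM
#'
#' A model specification is a small parsed representation of the model
#' `y = X beta + Z b + e` for one gene: an ordered list of fixed terms and an
#' ordered list of random grouping factors (one variance component each).
#'
#' Supported fixed-term kinds (and nothing else; this is deliberately not a
#' general formula language):
#' * `"1"` — intercept (at most one);
#' * `"<col>"` — a metadata column: numeric columns enter as covariates,
#'   character/factor columns as treatment-coded dummies with the
#'   lexicographically first level as reference;
#' * `"log(<col>)"` — natural log of a positive numeric column;
#' * `"<a>:<b>"` — interaction of two categoricals, coded *nested*: one
#'   dummy per level of `a` for each non-reference level of `b`, so each
#'   interaction coefficient is the `b` effect within that level of `a`
#'   (e.g. the condition effect within a cell type).
#'
#' @param fixed character vector of fixed terms, or a single string with
#'   terms separated by `+`.
#' @param random character vector of grouping-factor column names (may be
#'   empty for a fixed-effects-only model).
#' @param intercept logical; prepend an intercept term unless `fixed`
#'   already contains `"1"`. Default `TRUE`.
#' @return An object of class `sslmm_spec`.
#' @examples
#' model_spec("log(library_size) + cell_type + cell_type:condition", "subject")
#' @export
model_spec <- function(fixed = character(), random = character(),
                       intercept = TRUE) {
  if (length(fixed) == 1 && grepl("+", fixed, fixed = TRUE)) {
    fixed <- strsplit(fixed, "+", fixed = TRUE)[[1]]
  }
  fixed <- trimws(fixed)
  fixed <- fixed[nzchar(fixed)]
  if (length(random) == 1 && grepl("+", random, fixed = TRUE)) {
    random <- strsplit(random, "+", fixed = TRUE)[[1]]
  }
  random <- trimws(random)
  random <- random[nzchar(random)]
  if (sum(fixed == "1") > 1) stop("at most one intercept term is allowed")
  if (intercept && !"1" %in% fixed) fixed <- c("1", fixed)
  if (length(fixed) == 0) stop("model must contain at least one fixed term")
  structure(list(fixed = fixed, random = random), class = "sslmm_spec")
}

#' @export
print.sslmm_spec <- function(x, ...) {
  cat("LMM specification\n")
  cat("  fixed : ", paste(x$fixed, collapse = " + "), "\n", sep = "")
  cat("  random: ",
      if (length(x$random)) paste(x$random, collapse = " + ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

## Resolve a metadata column, failing with the column name.
.meta_col <- function(meta, col) {
  if (!col %in% names(meta)) {
    stop("metadata column '", col, "' not found", call. = FALSE)
  }
  v <- meta[[col]]
  if (anyNA(v)) stop("metadata column '", col, "' contains missing values",
                     call. = FALSE)
  v
}

.as_factor <- function(v) {
  if (is.factor(v)) factor(v, levels = sort(levels(droplevels(v))))
  else factor(v, levels = sort(unique(as.character(v))))
}

## Treatment-coded dummy block for a categorical: levels sorted, first = ref.
.dummy_block <- function(f, prefix) {
  lev <- levels(f)
  if (length(lev) < 2) {
    return(matrix(numeric(0), nrow = length(f), ncol = 0))
  }
  out <- vapply(lev[-1], function(l) as.numeric(f == l), numeric(length(f)))
  colnames(out) <- paste0(prefix, lev[-1])
  out
}

#' Build the fixed-effect design matrix X
#'
#' Columns appear in the order the terms were declared. Categoricals are
#' treatment-coded against the lexicographically first level; an interaction
#' `a:b` emits, for every level of `a`, the non-reference dummies of `b`
#' (nested coding), so each interaction coefficient is directly the `b`
#' contrast within one level of `a`.
#'
#' @param meta data.frame of cell metadata, one row per cell.
#' @param spec an [model_spec()] object.
#' @return Numeric matrix `n x p` with column names; attribute `"term"` maps
#'   each column back to its declaring term.
#' @export
build_fixed_matrix <- function(meta, spec) {
  stopifnot(inherits(spec, "sslmm_spec"))
  n <- nrow(meta)
  if (is.null(n) || n < 2) stop("need at least 2 cells")
  cols <- list(); terms <- character(0)
  for (term in spec$fixed) {
    if (term == "1") {
      blk <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    } else if (grepl("^log\\(.+\\)$", term)) {
      col <- sub("^log\\((.+)\\)$", "\\1", term)
      v <- .meta_col(meta, col)
      if (!is.numeric(v)) stop("log() term requires a numeric column: ", col)
      if (any(v <= 0)) stop("log() term requires positive values: ", col)
      blk <- matrix(log(v), n, 1, dimnames = list(NULL, term))
      if (stats::sd(blk) == 0) warning("covariate '", term, "' is constant")
    } else if (grepl(":", term, fixed = TRUE)) {
      ab <- strsplit(term, ":", fixed = TRUE)[[1]]
      if (length(ab) != 2) stop("only two-way interactions are supported: ", term)
      fa <- .as_factor(.meta_col(meta, ab[1]))
      fb <- .as_factor(.meta_col(meta, ab[2]))
      if (nlevels(fb) < 2) stop("interaction factor '", ab[2],
                                "' has fewer than 2 levels")
      blk <- do.call(cbind, lapply(levels(fa), function(la) {
        sub <- .dummy_block(fb, paste0(ab[2]))
        sub <- sub * as.numeric(fa == la)
        colnames(sub) <- paste0(ab[1], la, ":", colnames(sub))
        sub
      }))
    } else {
      v <- .meta_col(meta, term)
      if (is.numeric(v)) {
        blk <- matrix(v, n, 1, dimnames = list(NULL, term))
        if (stats::sd(v) == 0) warning("covariate '", term, "' is constant")
      } else {
        f <- .as_factor(v)
        if (nlevels(f) < 2) {
          warning("categorical '", term, "' has a single level; no columns emitted")
        }
        blk <- .dummy_block(f, term)
      }
    }
    cols[[length(cols) + 1]] <- blk
    terms <- c(terms, rep(term, ncol(blk)))
  }
  X <- do.call(cbind, cols)
  rownames(X) <- if (!is.null(meta$cell_id)) as.character(meta$cell_id) else NULL
  attr(X, "term") <- terms
  X
}

#' Build the random-effect design matrix Z
#'
#' One indicator (one-hot) block per grouping factor, concatenated in the
#' declared order; the returned `"partition"` attribute records the block
#' sizes `q_1 ... q_K`.
#'
#' @inheritParams build_fixed_matrix
#' @return Numeric matrix `n x q` with attribute `"partition"` (named integer
#'   vector of block sizes).
#' @export
build_random_matrix <- function(meta, spec) {
  stopifnot(inherits(spec, "sslmm_spec"))
  if (length(spec$random) == 0) {
    Z <- matrix(numeric(0), nrow = nrow(meta), ncol = 0)
    attr(Z, "partition") <- integer(0)
    return(Z)
  }
  blocks <- lapply(spec$random, function(col) {
    f <- .as_factor(.meta_col(meta, col))
    if (nlevels(f) < 2) {
      if (length(spec$random) == 1) {
        stop("grouping factor '", col,
             "' has a single level: variance component unidentifiable")
      }
      warning("grouping factor '", col, "' has a single level")
    }
    B <- vapply(levels(f), function(l) as.numeric(f == l),
                numeric(length(f)))
    colnames(B) <- paste0(col, levels(f))
    B
  })
  Z <- do.call(cbind, blocks)
  part <- vapply(blocks, ncol, integer(1))
  names(part) <- spec$random
  rownames(Z) <- if (!is.null(meta$cell_id)) as.character(meta$cell_id) else NULL
  attr(Z, "partition") <- part
  Z
}

#' Check estimability (full column rank) of a fixed-effect design
#'
#' @param X fixed-effect design matrix.
#' @param tol relative tolerance on the QR rank decision.
#' @return Invisibly, `list(rank, p, full_rank)`. Errors if rank < p, naming
#'   a set of columns involved in the collinearity.
#' @export
check_estimability <- function(X, tol = 1e-10) {
  p <- ncol(X)
  qrx <- qr(X, tol = tol)
  r <- qrx$rank
  if (r < p) {
    bad <- colnames(X)[qrx$pivot[(r + 1):p]]
    if (is.null(bad)) bad <- qrx$pivot[(r + 1):p]
    stop("design matrix X is rank deficient (rank ", r, " < p = ", p,
         "); collinear columns: ", paste(bad, collapse = ", "))
  }
  invisible(list(rank = r, p = p, full_rank = TRUE))
}

#' Replace Z by an equivalent lower-dimensional random-effect design
#'
#' Computes `Ztilde = Z V_r` where `V_r` holds the eigenvectors of `Z'Z` with
#' nonzero eigenvalue, so that `Ztilde Ztilde' = Z Z'` exactly and any LMM fit
#' using `Ztilde` has the same likelihood and estimates as with `Z`. Useful
#' when a grouping structure has many collinear columns, or when `q > n`.
#'
#' Only meaningful for a single variance component (the rotation mixes
#' columns, so per-block partitions are not preserved).
#'
#' @param Z random-effect design matrix (n x q).
#' @param tol eigenvalues below `tol * max(eigenvalue)` are treated as zero.
#' @return n x r matrix with attribute `"partition" = r`.
#' @export
reduce_random_effects <- function(Z, tol = 1e-10) {
  if (ncol(Z) == 0 || all(Z == 0)) stop("Z has no nonzero columns")
  A <- crossprod(Z)
  ee <- eigen(A, symmetric = TRUE)
  keep <- ee$values > tol * max(ee$values)
  r <- sum(keep)
  Zt <- Z %*% ee$vectors[, keep, drop = FALSE]
  colnames(Zt) <- paste0("re", seq_len(r))
  attr(Zt, "partition") <- stats::setNames(r, "reduced")
  Zt
}
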