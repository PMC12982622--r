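## run expr with a local RNG state seeded at `seed`, restoring the caller's
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Construct negative-binomial per-gene parameters
#'
#' @param mu per-gene NB mean (>= 0).
#' @param size per-gene NB dispersion parameter r (`Var = mu + mu^2/r`).
#' @param gene_ids gene identifiers.
#' @return list of class `sslmm_nb`.
#' @export
nb_params <- function(mu, size, gene_ids = NULL) {
  stopifnot(length(mu) == length(size), all(mu >= 0), all(size > 0))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_along(mu))
  structure(list(gene_ids = as.character(gene_ids), mu = as.numeric(mu),
                 size = as.numeric(size)), class = "sslmm_nb")
}

#' Method-of-moments NB parameters from a reference count matrix
#'
#' Per gene, `mu = sample mean` and, with `s2` the sample variance,
#' `size = mu^2 / (s2 - mu)` when `s2 > mu`; otherwise the gene is treated
#' as (quasi-)Poisson via the dispersion cap. Sizes are clipped to
#' `[1e-2, 1e8]`.
#'
#' @param ref_counts gene x cell count matrix (dense or sparse), >= 2 cells.
#' @param size_cap dispersion value standing in for "Poisson" (default 1e8).
#' @param size_floor lower clip (default 1e-2).
#' @return [nb_params()] object.
#' @export
mme_dispersion <- function(ref_counts, size_cap = 1e8, size_floor = 1e-2) {
  nc <- ncol(ref_counts)
  if (nc < 2) stop("need at least 2 reference cells (variance undefined)")
  mu <- Matrix::rowMeans(ref_counts)
  ex2 <- Matrix::rowSums(ref_counts * ref_counts)
  s2 <- (ex2 - nc * mu^2) / (nc - 1)
  size <- ifelse(s2 > mu & mu > 0, mu^2 / (s2 - mu), size_cap)
  size <- pmin(pmax(size, size_floor), size_cap)
  ids <- rownames(ref_counts)
  if (is.null(ids)) ids <- paste0("gene", seq_along(mu))
  nb_params(as.numeric(mu), as.numeric(size), ids)
}

#' Synthetic NB reference counts (stand-in for a real reference atlas)
#'
#' Draws per-gene `(mu, size)` log-uniformly over the given decade ranges and
#' samples counts i.i.d. NB across cells. Serves as a self-contained,
#' download-free reference for the simulator; the drawn truth is attached as
#' attributes `mu` and `size` for round-trip checks.
#'
#' @param m_genes,n_cells matrix dimensions.
#' @param seed RNG seed (deterministic output).
#' @param mean_range_log10 log10 range of NB means (default c(-2, 2)).
#' @param size_range_log10 log10 range of NB sizes (default c(-1, 1.5)).
#' @return integer gene x cell matrix with dimnames and truth attributes.
#' @export
synth_reference <- function(m_genes, n_cells, seed = 1,
                            mean_range_log10 = c(-2, 2),
                            size_range_log10 = c(-1, 1.5)) {
  stopifnot(m_genes >= 1, n_cells >= 1)
  .with_seed(seed, {
    mu <- 10^stats::runif(m_genes, mean_range_log10[1], mean_range_log10[2])
    size <- 10^stats::runif(m_genes, size_range_log10[1], size_range_log10[2])
    counts <- matrix(stats::rnbinom(m_genes * n_cells,
                                    size = rep(size, times = n_cells),
                                    mu = rep(mu, times = n_cells)),
                     nrow = m_genes, ncol = n_cells)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(paste0("gene", seq_len(m_genes)),
                             paste0("cell", seq_len(n_cells)))
    attr(counts, "mu") <- mu
    attr(counts, "size") <- size
    counts
  })
}

#' Simulation design for multi-subject multi-cell-type scRNA-seq data
#'
#' Defaults follow the published simulation study: 25 subjects, 12 cell
#' types, 2 conditions, 6000 genes of which 480 are differentially expressed
#' each in a single designated cell type, with |log fold change| uniform on
#' \[0.5, 1\] and random sign.
#'
#' @param n_cells number of cells.
#' @param n_subjects,n_celltypes,n_conditions population structure.
#' @param n_genes,n_de genes to draw from the reference / DE genes among them.
#' @param logfc_range range of |log fold change| (natural log scale).
#' @param sigma_subject SD of the per-gene, per-subject random effect on the
#'   log-mean scale.
#' @param libsize_lognormal_sd SD of the log-normal cell-level library factor.
#' @param seed RNG seed.
#' @return list of class `sslmm_design`.
#' @export
sim_design <- function(n_cells = 20000, n_subjects = 25, n_celltypes = 12,
                       n_conditions = 2, n_genes = 6000, n_de = 480,
                       logfc_range = c(0.5, 1.0), sigma_subject = 0.25,
                       libsize_lognormal_sd = 0.35, seed = 1) {
  stopifnot(n_de <= n_genes, n_cells >= 1, n_subjects >= 1,
            n_celltypes >= 1, n_conditions >= 1)
  structure(list(n_cells = n_cells, n_subjects = n_subjects,
                 n_celltypes = n_celltypes, n_conditions = n_conditions,
                 n_genes = n_genes, n_de = n_de, logfc_range = logfc_range,
                 sigma_subject = sigma_subject,
                 libsize_lognormal_sd = libsize_lognormal_sd,
                 seed = as.integer(seed)), class = "sslmm_design")
}

#' Simulate a multi-subject multi-cell-type scRNA-seq dataset
#'
#' Cells receive subject, cell type and condition labels uniformly at
#' random. The count of gene g in cell i is drawn
#' `NB(mean = mu_g * L_i * exp(u_{g,s(i)} + beta_g * 1[treated & target]),
#' size = r_g)` where `L_i` is a log-normal library factor,
#' `u_{g,s} ~ N(0, sigma_subject^2)` is a per-gene per-subject random
#' intercept, and each DE gene carries effect `beta_g` in one designated
#' target cell type under the non-reference condition. The RNG seed is split
#' deterministically across the assignment (`seed`), effect (`seed + 1`) and
#' count (`seed + 2`) streams.
#'
#' @param nb [nb_params()] (e.g. from [mme_dispersion()] of a reference);
#'   must contain at least `design$n_genes` genes with `mu > 0`, from which
#'   genes are sampled without replacement.
#' @param design [sim_design()].
#' @return list of class `sslmm_sim`: integer `counts` (gene x cell),
#'   `metadata` data.frame (`cell_id, subject, cell_type, condition,
#'   library_size`), `truth` data.frame (`gene_id, target_cell_type, logfc`;
#'   exactly `n_de` rows), plus the `design` and selected `nb` parameters.
#' @export
simulate_dataset <- function(nb, design) {
  stopifnot(inherits(nb, "sslmm_nb"), inherits(design, "sslmm_design"))
  ok <- which(nb$mu > 0)
  if (length(ok) < design$n_genes) {
    stop("reference provides ", length(ok), " expressed genes; need ",
         design$n_genes)
  }
  n <- design$n_cells; m <- design$n_genes
  subjects <- paste0("S", formatC(seq_len(design$n_subjects), width = 2, flag = "0"))
  celltypes <- paste0("CT", formatC(seq_len(design$n_celltypes), width = 2, flag = "0"))
  conditions <- paste0("cond", seq_len(design$n_conditions))
  asg <- .with_seed(design$seed, {
    list(genes = sort(sample(ok, m)),
         subj = sample.int(design$n_subjects, n, replace = TRUE),
         ct = sample.int(design$n_celltypes, n, replace = TRUE),
         cond = sample.int(design$n_conditions, n, replace = TRUE),
         libf = exp(stats::rnorm(n, 0, design$libsize_lognormal_sd)))
  })
  eff <- .with_seed(design$seed + 1L, {
    de_idx <- if (design$n_de > 0) sort(sample.int(m, design$n_de)) else integer(0)
    list(de_idx = de_idx,
         target = sample.int(design$n_celltypes, design$n_de, replace = TRUE),
         logfc = stats::runif(design$n_de, design$logfc_range[1],
                              design$logfc_range[2]) *
           sample(c(-1, 1), design$n_de, replace = TRUE),
         u = matrix(stats::rnorm(m * design$n_subjects, 0, design$sigma_subject),
                    nrow = m))
  })
  mu <- nb$mu[asg$genes]; size <- nb$size[asg$genes]
  gene_ids <- nb$gene_ids[asg$genes]
  beta <- numeric(m); beta[eff$de_idx] <- eff$logfc
  target <- integer(m); target[eff$de_idx] <- eff$target
  treated <- asg$cond == design$n_conditions   # last condition is "treated"
  counts <- matrix(0L, m, n)
  .with_seed(design$seed + 2L, {
    for (g in seq_len(m)) {
      lmean <- log(mu[g]) + log(asg$libf) + eff$u[g, asg$subj]
      if (beta[g] != 0) {
        hit <- treated & asg$ct == target[g]
        if (any(hit)) lmean[hit] <- lmean[hit] + beta[g]
      }
      counts[g, ] <- as.integer(stats::rnbinom(n, size = size[g],
                                               mu = exp(lmean)))
    }
  })
  dimnames(counts) <- list(gene_ids, paste0("cell", seq_len(n)))
  metadata <- data.frame(cell_id = colnames(counts),
                         subject = subjects[asg$subj],
                         cell_type = celltypes[asg$ct],
                         condition = conditions[asg$cond],
                         library_size = colSums(counts),
                         stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_ids[eff$de_idx],
                      target_cell_type = celltypes[target[eff$de_idx]],
                      logfc = beta[eff$de_idx], stringsAsFactors = FALSE)
  structure(list(counts = counts, metadata = metadata, truth = truth,
                 design = design,
                 nb = nb_params(mu, size, gene_ids)),
            class = "sslmm_sim")
}

#' @export
print.sslmm_sim <- function(x, ...) {
  cat("Simulated scRNA-seq dataset:", nrow(x$counts), "genes x",
      ncol(x$counts), "cells;", nrow(x$truth), "DE genes;",
      x$design$n_subjects, "subjects,", x$design$n_celltypes, "cell types,",
      x$design$n_conditions, "conditions\n")
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = P(score_pos > score_neg)` with ties counted half, computed from
#' mid-ranks; higher scores should indicate the positive class.
#'
#' @param scores numeric per-gene scores.
#' @param labels binary truth labels (0/1 or logical).
#' @return scalar AUC.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) stop("need at least one positive and one negative")
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Uniform QQ table with pointwise 95% band
#'
#' For sorted p-values, the i-th order statistic of m uniforms is
#' `Beta(i, m - i + 1)`; the table reports its mean `i/(m+1)` as the expected
#' quantile and the 2.5/97.5% Beta quantiles as the pointwise band, on the
#' raw scale and as `-log10`.
#'
#' @param pvals p-values in \[0, 1\].
#' @return data.frame with columns `expected, observed, lower, upper` (raw
#'   scale, one row per order statistic, ascending) and their
#'   `neglog10_*` counterparts.
#' @export
qq_uniform <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be in [0, 1]")
  }
  m <- length(pvals)
  i <- seq_len(m)
  obs <- sort(pvals)
  exp_ <- i / (m + 1)
  lo <- stats::qbeta(0.025, i, m - i + 1)
  hi <- stats::qbeta(0.975, i, m - i + 1)
  data.frame(expected = exp_, observed = obs, lower = lo, upper = hi,
             neglog10_expected = -log10(exp_),
             neglog10_observed = -log10(pmax(obs, .Machine$double.xmin)),
             neglog10_lower = -log10(hi), neglog10_upper = -log10(pmax(lo, .Machine$double.xmin)))
}

#' Write a simulated dataset to disk
#'
#' Counts as Matrix Market `.mtx` with `features.tsv`/`barcodes.tsv`,
#' metadata and truth as TSV, and a JSON snapshot of the design (including
#' the seed).
#'
#' @param sim `sslmm_sim`.
#' @param dir output directory.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sslmm_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, dir)
  data.table::fwrite(sim$metadata, file.path(dir, "metadata.tsv"), sep = "\t")
  data.table::fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  jsonlite::write_json(unclass(sim$design), file.path(dir, "design.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
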