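## tag errors with the pipeline stage they arose in
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

.log <- function(..., verbose = TRUE) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
}

#' End-to-end differential-expression run configuration
#'
#' @param counts gene x cell count matrix, or path to `.mtx`/CSV/TSV.
#' @param meta cell metadata data.frame, or path to TSV/CSV (one row per
#'   cell, aligned with the columns of `counts`).
#' @param fixed,random model specification strings (see [model_spec()]).
#' @param method `"REML"` or `"ML"`.
#' @param qc [qc_thresholds()], or `NULL` to skip filtering.
#' @param test_terms fixed terms whose coefficients are t-tested (default:
#'   the last declared term, typically the cell_type:condition interaction).
#' @param varcomp_tests also run the variance-component z-test and LRT.
#' @param fitter [fitter_config()].
#' @param out optional output directory for result TSVs.
#' @param verbose log progress to stderr.
#' @return list of class `sslmm_runcfg`.
#' @export
run_config <- function(counts, meta, fixed, random, method = "REML",
                       qc = qc_thresholds(), test_terms = NULL,
                       varcomp_tests = FALSE, fitter = NULL, out = NULL,
                       verbose = TRUE) {
  if (is.null(fitter)) fitter <- fitter_config(method = method)
  structure(list(counts = counts, meta = meta, fixed = fixed,
                 random = random, method = method, qc = qc,
                 test_terms = test_terms, varcomp_tests = varcomp_tests,
                 fitter = fitter, out = out, verbose = verbose),
            class = "sslmm_runcfg")
}

#' Run the full differential-expression pipeline
#'
#' read -> QC filter -> log1p -> design matrices -> summary statistics ->
#' per-gene LMM fits -> t-tests (+ optional variance-component tests) ->
#' BH adjustment across genes (per tested coefficient). Deterministic given
#' inputs. The `library_size` used for the `log(library_size)` covariate is
#' recomputed as total counts per cell after cell filtering and before gene
#' filtering.
#'
#' @param config [run_config()].
#' @return list with `fits` (`sslmm_fit`), `results` (data.frame, one row
#'   per gene x tested term), `qc_report`, `sstats`. If `config$out` is set,
#'   writes `results.tsv`, `fits.tsv` and `qc_report.json` there.
#' @export
run_de <- function(config) {
  stopifnot(inherits(config, "sslmm_runcfg"))
  v <- config$verbose
  counts <- .stage("read", {
    if (is.character(config$counts)) read_counts(config$counts) else config$counts
  })
  meta <- .stage("read", {
    if (is.character(config$meta)) {
      as.data.frame(data.table::fread(config$meta))
    } else config$meta
  })
  .log("read: ", nrow(counts), " genes x ", ncol(counts), " cells", verbose = v)
  qc_report <- NULL
  if (!is.null(config$qc)) {
    fq <- .stage("qc", filter_qc(counts, meta, config$qc))
    counts <- fq$counts; meta <- fq$meta; qc_report <- fq$report
    .log("qc: kept ", qc_report$cells_kept, " cells, ",
         qc_report$genes_kept, " genes", verbose = v)
  }
  meta$library_size <- .stage("qc", {
    ls0 <- attr(counts, "library_size_prefilter")
    if (!is.null(ls0)) ls0 else Matrix::colSums(counts)
  })
  ds <- .stage("designs", {
    spec <- model_spec(config$fixed, config$random)
    X <- build_fixed_matrix(meta, spec)
    check_estimability(X)
    Z <- build_random_matrix(meta, spec)
    list(X = X, Z = Z, spec = spec)
  })
  .log("designs: p = ", ncol(ds$X), ", q = ", ncol(ds$Z), verbose = v)
  ss <- .stage("sstats",
               compute_sstats(ds$X, ds$Z, counts, transform = log1p))
  .log("sstats done (n = ", ss$n, ")", verbose = v)
  fits <- .stage("fit", fit_all(ss, config$fitter))
  .log("fit: ", sum(fits$converged), "/", length(fits$gene_ids),
       " genes converged", verbose = v)
  results <- .stage("test", {
    terms <- config$test_terms
    if (is.null(terms)) terms <- utils::tail(ds$spec$fixed, 1)
    coefs <- colnames(ds$X)[attr(ds$X, "term") %in% terms]
    if (length(coefs) == 0) stop("no coefficients belong to the tested terms")
    res <- lapply(coefs, function(cf) {
      r <- t_test(fits, cf)
      r$fdr <- bh_adjust(r$p_value)
      r
    })
    if (isTRUE(config$varcomp_tests) && length(ss$partition) > 0) {
      zr <- z_test_varcomp(fits, 1)
      zr$fdr <- bh_adjust(zr$p_value)
      fit0 <- fit_all(drop_random(ss), config$fitter)
      lr <- lrt_varcomp(fits, fit0)
      lr$fdr <- bh_adjust(lr$p_value)
      res <- c(res, list(zr, lr))
    }
    do.call(rbind, res)
  })
  if (!is.null(config$out)) {
    .stage("write", {
      dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
      rr <- results
      for (j in which(vapply(rr, is.numeric, logical(1)))) {
        rr[[j]] <- formatC(rr[[j]], digits = 17, format = "g")
      }
      data.table::fwrite(rr, file.path(config$out, "results.tsv"), sep = "\t")
      write_fits(fits, file.path(config$out, "fits.tsv"))
      if (!is.null(qc_report)) {
        jsonlite::write_json(qc_report, file.path(config$out, "qc_report.json"),
                             digits = NA, auto_unbox = TRUE)
      }
    })
    .log("wrote results to ", config$out, verbose = v)
  }
  list(fits = fits, results = results, qc_report = qc_report, sstats = ss)
}

#' Simulation study: power (ROC/AUC) and type-I error of the DE pipeline
#'
#' Simulates a multi-subject multi-cell-type dataset, fits the cell-type x
#' condition interaction model per gene
#' (`~ log(library_size) + cell_type + cell_type:condition` with a subject
#' random intercept), scores each gene, and evaluates (1) recovery of the
#' designated DE genes by ROC/AUC and (2) calibration of null-gene p-values
#' (QQ against Uniform(0,1), empirical rejection over an alpha grid).
#'
#' Gene scoring for the ROC (`score`): `"minp"` (default) ranks genes by the
#' minimum p-value across the per-cell-type interaction terms;
#' `"bonferroni"` uses the Bonferroni-adjusted minimum. Calibration uses one
#' interaction p-value per null gene (a seeded random pick of one cell type
#' per gene) so the values are independent across genes.
#'
#' @param design [sim_design()].
#' @param nb optional [nb_params()] reference; default draws a synthetic NB
#'   reference (`ref_genes` x `ref_cells`, seed `design$seed + 1000`) and
#'   estimates parameters by [mme_dispersion()].
#' @param fitter [fitter_config()].
#' @param score gene-level ROC score, see above.
#' @param alpha_grid type-I error evaluation points.
#' @param ref_genes,ref_cells synthetic reference dimensions.
#' @param chunk_size cells per summary-statistics chunk.
#' @param keep_fits return the full `sslmm_fit` object (memory!).
#' @param verbose log progress.
#' @return list with `auc`, `type1` (data.frame alpha/rejection rate/count),
#'   `qq` (from [qq_uniform()]), `gene_scores`, `labels`, `null_p`,
#'   `p_interaction` (gene x cell-type p-value matrix), `truth`, `n_genes`,
#'   and optionally `fits`.
#' @export
run_simulation_study <- function(design, nb = NULL,
                                 fitter = fitter_config(),
                                 score = c("minp", "bonferroni"),
                                 alpha_grid = c(0.01, 0.05, 0.1),
                                 ref_genes = 8000, ref_cells = 2000,
                                 chunk_size = 10000, keep_fits = FALSE,
                                 verbose = TRUE) {
  score <- match.arg(score)
  v <- verbose
  if (is.null(nb)) {
    .log("drawing synthetic NB reference (", ref_genes, " genes x ",
         ref_cells, " cells)", verbose = v)
    ref <- synth_reference(ref_genes, ref_cells, seed = design$seed + 1000L)
    nb <- mme_dispersion(ref)
    rm(ref)
  }
  .log("simulating ", design$n_genes, " genes x ", design$n_cells, " cells",
       verbose = v)
  sim <- .stage("simulate", simulate_dataset(nb, design))
  meta <- sim$metadata
  spec <- model_spec("log(library_size) + cell_type + cell_type:condition",
                     "subject")
  X <- build_fixed_matrix(meta, spec)
  check_estimability(X)
  Z <- build_random_matrix(meta, spec)
  .log("computing summary statistics", verbose = v)
  ss <- compute_sstats(X, Z, sim$counts, chunk_size = chunk_size,
                       transform = log1p)
  truth <- sim$truth
  gene_ids <- rownames(sim$counts)
  rm(sim)
  .log("fitting ", length(gene_ids), " genes", verbose = v)
  fits <- fit_all(ss, fitter)
  inter_cols <- colnames(X)[attr(X, "term") == "cell_type:condition"]
  pmat <- vapply(inter_cols, function(cf) t_test(fits, cf)$p_value,
                 numeric(length(gene_ids)))
  rownames(pmat) <- gene_ids
  labels <- gene_ids %in% truth$gene_id
  minp <- apply(pmat, 1, min, na.rm = TRUE)
  gs <- switch(score,
               minp = -log10(minp),
               bonferroni = -log10(pmin(minp * ncol(pmat), 1)))
  auc <- if (any(labels) && !all(labels)) roc_auc(gs, labels) else NA_real_
  null_idx <- which(!labels)
  pick <- .with_seed(design$seed + 3L,
                     sample.int(ncol(pmat), length(null_idx), replace = TRUE))
  null_p <- pmat[cbind(null_idx, pick)]
  null_p <- null_p[!is.na(null_p)]
  type1 <- data.frame(alpha = alpha_grid,
                      rejection = vapply(alpha_grid,
                                         function(a) mean(null_p < a),
                                         numeric(1)),
                      n_null = length(null_p))
  out <- list(auc = auc, type1 = type1, qq = qq_uniform(null_p),
              gene_scores = gs, labels = labels, null_p = null_p,
              p_interaction = pmat, truth = truth,
              n_genes = length(gene_ids))
  if (keep_fits) out$fits <- fits
  .log("AUC = ", round(auc, 4), "; rejection@0.05 = ",
       round(type1$rejection[type1$alpha == 0.05], 4), verbose = v)
  out
}
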