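test_that("Matrix Market semantics and cross-format equality", {
  dir <- withr::local_tempdir()
  # 2x2 toy with a single entry (1,1) = 3
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 1", "1 1 3"), file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  got <- read_counts(file.path(dir, "matrix.mtx"))
  expect_equal(unname(as.matrix(got)), matrix(c(3, 0, 0, 0), 2, 2))
  expect_equal(dimnames(got), list(c("gA", "gB"), c("c1", "c2")))

  # the same toy as dense CSV parses to the same matrix
  csv <- file.path(dir, "toy.csv")
  writeLines(c("gene,c1,c2", "gA,3,0", "gB,0,0"), csv)
  dense <- read_counts(csv)
  expect_equal(unname(dense), unname(as.matrix(got)))

  # write -> read round trip is the identity
  withr::with_seed(401, {
    M <- matrix(rpois(30, 2), 5, 6,
                dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
    d2 <- file.path(dir, "rt")
    write_counts(M, d2)
    back <- read_counts(file.path(d2, "matrix.mtx"))
    expect_equal(as.matrix(back), M * 1.0)
  })

  # id/dimension mismatches are rejected
  writeLines("gA", file.path(dir, "features.tsv"))
  expect_error(read_counts(file.path(dir, "matrix.mtx")), "features")
})

test_that("QC filter rules, ordering and report conservation", {
  # thresholds wide open -> identity
  withr::with_seed(411, {
    M <- matrix(rpois(200 * 30, 3), 200, 30,
                dimnames = list(paste0("g", 1:200), paste0("c", 1:30)))
    meta <- data.frame(cell_id = colnames(M),
                       cell_type = rep(c("A", "B"), 15))
    thr0 <- qc_thresholds(min_features_per_cell = 0,
                          libsize_range = c(0, Inf),
                          min_cells_per_celltype = 0,
                          min_cells_per_gene = 0, min_cpc = 0)
    out <- filter_qc(M, meta, thr0)
    expect_equal(out$counts, M, ignore_attr = TRUE)
    expect_equal(out$meta, meta)
  })

  # counts-per-cell rule at the 0.005 threshold: total 4 over 1000 cells
  # (cpc 0.004) is removed, total 6 (cpc 0.006) is kept
  n <- 1000
  M <- rbind(g_low = c(rep(1L, 4), rep(0L, n - 4)),
             g_keep = c(rep(1L, 6), rep(0L, n - 6)),
             g_big = rep(600L, n))
  meta <- data.frame(cell_id = paste0("c", 1:n), cell_type = "A")
  thr <- qc_thresholds(min_features_per_cell = 0, libsize_range = c(1, Inf),
                       min_cells_per_celltype = 0, min_cells_per_gene = 0,
                       min_cpc = 0.005)
  out <- filter_qc(M, meta, thr)
  expect_setequal(rownames(out$counts), c("g_keep", "g_big"))
  expect_equal(unname(out$report$genes_removed["cpc"]), 1)

  # library-size window [2^9, 2^16]: a 256-count cell is removed
  M2 <- rbind(g1 = c(256L, 600L, 700L), g2 = c(0L, 0L, 0L))
  colnames(M2) <- c("c1", "c2", "c3")
  meta2 <- data.frame(cell_id = c("c1", "c2", "c3"), cell_type = "A")
  thr2 <- qc_thresholds(min_features_per_cell = 0,
                        libsize_range = c(2^9, 2^16),
                        min_cells_per_celltype = 0,
                        min_cells_per_gene = 0, min_cpc = 0)
  out2 <- filter_qc(M2, meta2, thr2)
  expect_equal(colnames(out2$counts), c("c2", "c3"))
  expect_equal(unname(out2$report$cells_removed["libsize"]), 1)

  # first-triggering-rule attribution conserves totals
  withr::with_seed(412, {
    M3 <- matrix(rpois(100 * 60, 10), 100, 60,
                 dimnames = list(paste0("g", 1:100), paste0("c", 1:60)))
    M3[, 1:5] <- 0L                     # fails the feature rule
    M3[, 6] <- 50L                      # passes features, fails libsize high
    meta3 <- data.frame(cell_id = colnames(M3),
                        cell_type = rep(c("A", "B", "C"), 20))
    thr3 <- qc_thresholds(min_features_per_cell = 10,
                          libsize_range = c(2, 2000),
                          min_cells_per_celltype = 10,
                          min_cells_per_gene = 2, min_cpc = 0.001)
    out3 <- filter_qc(M3, meta3, thr3)
    rep3 <- out3$report
    expect_equal(rep3$cells_kept + sum(rep3$cells_removed), rep3$cells_in)
    expect_equal(rep3$genes_kept + sum(rep3$genes_removed), rep3$genes_in)
    expect_equal(unname(rep3$cells_removed["features"]), 5)
  })
  expect_error(filter_qc(M2, meta2, qc_thresholds(min_features_per_cell = 99)),
               "all cells")
})

test_that("end-to-end pipeline: shapes, determinism, module composition", {
  nb <- nb_params(mu = rep(c(2, 6, 15), 40), size = rep(c(3, 8), 60))
  des <- sim_design(n_cells = 1200, n_subjects = 6, n_celltypes = 3,
                    n_genes = 90, n_de = 9, seed = 31)
  sim <- simulate_dataset(nb, des)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  thr <- qc_thresholds(min_features_per_cell = 1, libsize_range = c(1, Inf),
                       min_cells_per_celltype = 0, min_cells_per_gene = 2,
                       min_cpc = 0.005)
  cfg <- run_config(sim$counts, sim$metadata,
                    fixed = "log(library_size) + cell_type + cell_type:condition",
                    random = "subject", qc = thr, varcomp_tests = TRUE,
                    out = out1, verbose = FALSE)
  res <- run_de(cfg)

  n_terms <- 3 + 2    # 3 interaction coefficients + z + lrt
  m_kept <- res$qc_report$genes_kept
  expect_equal(nrow(res$results), m_kept * n_terms)
  expect_equal(sort(unique(res$results$test_kind)), c("lrt", "t", "z"))

  # rerun with identical config: byte-identical outputs
  cfg2 <- cfg; cfg2$out <- out2
  run_de(cfg2)
  for (f in c("results.tsv", "fits.tsv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }

  # pipeline rows equal a manual composition of the module calls
  fq <- filter_qc(sim$counts, sim$metadata, thr)
  meta <- fq$meta
  meta$library_size <- attr(fq$counts, "library_size_prefilter")
  spec <- model_spec("log(library_size) + cell_type + cell_type:condition",
                     "subject")
  X <- build_fixed_matrix(meta, spec)
  Z <- build_random_matrix(meta, spec)
  ss <- compute_sstats(X, Z, log1p_transform(fq$counts))
  fits <- fit_all(ss)
  cf <- colnames(X)[attr(X, "term") == "cell_type:condition"][1]
  manual <- t_test(fits, cf)
  auto <- res$results[res$results$term == cf, ]
  expect_equal(auto$p_value, manual$p_value, tolerance = 1e-12)
  expect_equal(auto$estimate, manual$estimate, tolerance = 1e-12)
})

test_that("simulation-study driver emits calibrated metrics on a smoke design", {
  des <- sim_design(n_cells = 2000, n_subjects = 8, n_celltypes = 3,
                    n_genes = 200, n_de = 20, seed = 37)
  res <- run_simulation_study(des, ref_genes = 600, ref_cells = 400,
                              verbose = FALSE)
  expect_true(is.finite(res$auc) && res$auc > 0.5)
  expect_equal(dim(res$p_interaction), c(200, 3))
  expect_equal(sum(res$labels), 20)
  expect_equal(nrow(res$type1), 3)
  expect_true(all(res$type1$rejection >= 0 & res$type1$rejection <= 1))
  # degenerate-label contract: no DE genes -> AUC is an error
  expect_error(roc_auc(res$gene_scores, rep(0, 200)), "positive")
})

test_that("command-line interface drives simulate and run end to end", {
  dir <- withr::local_tempdir()
  cfgfile <- file.path(dir, "sim.json")
  jsonlite::write_json(
    list(design = list(n_cells = 400, n_subjects = 4, n_celltypes = 2,
                       n_genes = 60, n_de = 6, seed = 41),
         reference = list(m_genes = 200, n_cells = 300, seed = 42)),
    cfgfile, auto_unbox = TRUE)
  simdir <- file.path(dir, "sim")
  expect_equal(sslmm_cli(c("simulate", "--config", cfgfile, "--out", simdir)), 0L)
  expect_true(file.exists(file.path(simdir, "matrix.mtx")))

  outdir <- file.path(dir, "out")
  st <- sslmm_cli(c("run",
                    "--counts", file.path(simdir, "matrix.mtx"),
                    "--meta", file.path(simdir, "metadata.tsv"),
                    "--fixed", "log(library_size) + cell_type + cell_type:condition",
                    "--random", "subject", "--no-qc",
                    "--out", outdir))
  expect_equal(st, 0L)
  expect_true(file.exists(file.path(outdir, "results.tsv")))
  res <- data.table::fread(file.path(outdir, "results.tsv"))
  expect_true(all(c("gene_id", "term", "p_value", "fdr") %in% names(res)))
  expect_error(sslmm_cli(c("nope")), "unknown subcommand")
})
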