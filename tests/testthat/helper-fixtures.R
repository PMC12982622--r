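# Fixture builders shared across test files. All randomness is seeded at the
# call site so every test is reproducible in isolation.

# metadata for n cells with subject / cell_type / condition / library_size
make_meta <- function(n, n_subj = 5, n_ct = 3, n_cond = 2, seed = 1) {
  withr::with_seed(seed, data.frame(
    cell_id = paste0("c", seq_len(n)),
    subject = paste0("S", formatC(sample.int(n_subj, n, TRUE), width = 2, flag = "0")),
    cell_type = paste0("CT", formatC(sample.int(n_ct, n, TRUE), width = 2, flag = "0")),
    condition = c("ctl", "trt", letters[3:9])[sample.int(n_cond, n, TRUE)],
    library_size = stats::rpois(n, 2000) + 1L,
    stringsAsFactors = FALSE))
}

# a small random LMM instance: designs + m Gaussian genes with a true
# subject effect, plus its summary statistics
make_instance <- function(n = 80, m = 3, n_subj = 6, sd_subj = 0.7,
                          seed = 1) {
  meta <- make_meta(n, n_subj = n_subj, seed = seed)
  spec <- model_spec("log(library_size) + condition", "subject")
  X <- build_fixed_matrix(meta, spec)
  Z <- build_random_matrix(meta, spec)
  Y <- withr::with_seed(seed + 1, {
    subj <- as.integer(factor(meta$subject))
    t(vapply(seq_len(m), function(g) {
      u <- stats::rnorm(n_subj, 0, sd_subj)
      1 + 0.3 * log(meta$library_size) + u[subj] + stats::rnorm(n)
    }, numeric(n)))
  })
  rownames(Y) <- paste0("g", seq_len(m))
  colnames(Y) <- meta$cell_id
  list(meta = meta, spec = spec, X = X, Z = Z, Y = Y,
       ss = compute_sstats(X, Z, Y))
}

# balanced one-way layout and its closed-form REML (ANOVA) estimates
make_oneway <- function(S = 10, c_per = 40, mu = 2, sb2 = 0.5, seed = 1) {
  n <- S * c_per
  subj <- rep(seq_len(S), each = c_per)
  y <- withr::with_seed(seed,
    mu + stats::rnorm(S, 0, sqrt(sb2))[subj] + stats::rnorm(n))
  meta <- data.frame(cell_id = paste0("c", seq_len(n)),
                     subject = factor(subj))
  spec <- model_spec("1", "subject")
  X <- build_fixed_matrix(meta, spec)
  Z <- build_random_matrix(meta, spec)
  gm <- tapply(y, subj, mean)
  msb <- c_per * sum((gm - mean(y))^2) / (S - 1)
  msw <- sum((y - gm[subj])^2) / (n - S)
  list(y = y, X = X, Z = Z, subj = subj,
       ss = compute_sstats(X, Z, matrix(y, 1, n, dimnames = list("g1", NULL))),
       msw = msw, msb = msb, theta_anova = (msb - msw) / c_per)
}

# dense evaluation of the GLS blocks (independent of the Woodbury path)
dense_quadratics <- function(X, Z, y, gamma, partition) {
  n <- nrow(X)
  gvec <- rep(gamma, times = partition)
  H <- diag(n) + Z %*% (gvec * t(Z))
  Hi <- solve(H)
  list(XHiX = t(X) %*% Hi %*% X,
       XHiy = drop(t(X) %*% Hi %*% y),
       yHiy = drop(t(y) %*% Hi %*% y),
       ZHiZ = t(Z) %*% Hi %*% Z,
       ZHiX = t(Z) %*% Hi %*% X,
       ZHiy = drop(t(Z) %*% Hi %*% y),
       logdetH = as.numeric(determinant(H, logarithm = TRUE)$modulus))
}

# textbook BH step-up, written independently of stats::p.adjust
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
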