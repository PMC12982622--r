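test_that("lambda_max agrees with the dense spectrum", {
  expect_equal(lambda_max(diag(4)), 1)
  # subject blocks of sizes (3, 2): Z'Z = diag(3, 2)
  Z <- cbind(c(1, 1, 1, 0, 0), c(0, 0, 0, 1, 1))
  expect_equal(lambda_max(crossprod(Z)), 3)
  expect_error(lambda_max(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
  withr::with_seed(5, {
    Z <- matrix(rnorm(30 * 6), 30, 6)
    lam_dense <- max(eigen(tcrossprod(Z), symmetric = TRUE,
                           only.values = TRUE)$values)
    expect_equal(lambda_max(crossprod(Z)), lam_dense, tolerance = 1e-10)
  })
})

test_that("Woodbury/Sylvester GLS blocks match dense H construction", {
  inst <- make_instance(n = 70, m = 2, seed = 51)
  part <- attr(inst$Z, "partition")
  # H = I at gamma = 0
  q0 <- gls_quadratics(inst$ss, 0, 1)
  expect_equal(q0$XHiX, inst$ss$XX)
  expect_equal(q0$yHiy, inst$ss$Ynorm[[1]])
  expect_equal(q0$logdetH, 0)

  for (gamma in c(0.7, -0.01, 3)) {
    qd <- gls_quadratics(inst$ss, gamma, 2)
    dd <- dense_quadratics(inst$X, inst$Z, inst$Y[2, ], gamma, part)
    for (f in c("XHiX", "XHiy", "yHiy", "ZHiZ", "ZHiX", "ZHiy")) {
      expect_lt(max(abs(qd[[f]] - dd[[f]])) / max(abs(dd[[f]])), 1e-10)
    }
    expect_equal(qd$logdetH, dd$logdetH, tolerance = 1e-10)
  }

  # gamma below -1/lambda_max leaves the admissible region
  lam <- lambda_max(inst$ss$ZZ)
  expect_error(gls_quadratics(inst$ss, -1 / lam * 1.01, 1), "admissible")
})

test_that("profiled likelihood: OLS at gamma = 0, dense agreement elsewhere", {
  inst <- make_instance(n = 60, m = 2, seed = 61)
  pl0 <- profile_loglik(inst$ss, 0, 1, "REML")
  bols <- drop(solve(crossprod(inst$X), crossprod(inst$X, inst$Y[1, ])))
  expect_equal(unname(pl0$beta_hat), unname(bols), tolerance = 1e-10)

  n <- inst$ss$n; p <- ncol(inst$X)
  for (method in c("REML", "ML")) {
    for (gamma in c(0.4, 1.2)) {
      pl <- profile_loglik(inst$ss, gamma, 2, method)
      dd <- dense_quadratics(inst$X, inst$Z, inst$Y[2, ], gamma,
                             attr(inst$Z, "partition"))
      bh <- solve(dd$XHiX, dd$XHiy)
      rss <- dd$yHiy - sum(dd$XHiy * bh)
      if (method == "REML") {
        s2 <- rss / (n - p)
        ll <- -0.5 * ((n - p) * log(2 * pi * s2) + dd$logdetH +
                        as.numeric(determinant(dd$XHiX)$modulus) + (n - p))
      } else {
        s2 <- rss / n
        ll <- -0.5 * (n * log(2 * pi * s2) + dd$logdetH + n)
      }
      expect_equal(pl$loglik, ll, tolerance = 1e-10)
      expect_equal(pl$sigma2_hat, s2, tolerance = 1e-12)
    }
  }
})

test_that("score matches finite differences; information is symmetric PSD", {
  meta <- make_meta(90, n_subj = 6, seed = 71)
  spec <- model_spec("log(library_size)", "subject + cell_type")
  X <- build_fixed_matrix(meta, spec)
  Z <- build_random_matrix(meta, spec)
  y <- withr::with_seed(72, rnorm(90) + 0.5 * Z[, 2])
  ss <- compute_sstats(X, Z, matrix(y, 1, 90, dimnames = list("g", NULL)))
  h <- 1e-5
  for (method in c("REML", "ML")) {
    gamma <- c(0.3, 0.1)
    si <- score_and_information(ss, gamma, 1, method)
    fd <- vapply(1:2, function(k) {
      gp <- gamma; gm <- gamma
      gp[k] <- gp[k] + h; gm[k] <- gm[k] - h
      (profile_loglik(ss, gp, 1, method)$loglik -
         profile_loglik(ss, gm, 1, method)$loglik) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(si$score - fd) / pmax(abs(fd), 1e-4)), 1e-5)
    expect_equal(si$info, t(si$info))
    expect_true(all(eigen(si$info, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))
  }
})

test_that("score vanishes at the converged optimum and the ANOVA closed form", {
  ow <- make_oneway(S = 10, c_per = 30, seed = 81)
  f <- fit_gene(ow$ss, 1)
  expect_true(f$converged)
  si <- score_and_information(ow$ss, f$gamma, 1, "REML")
  expect_lt(max(abs(si$score)), 1e-4)
  # closed-form ANOVA REML solution (interior when MSB > MSW)
  expect_gt(ow$msb, ow$msw)
  si2 <- score_and_information(ow$ss, ow$theta_anova / ow$msw, 1, "REML")
  expect_lt(max(abs(si2$score)), 1e-6)
  expect_equal(f$sigma2, ow$msw, tolerance = 1e-8)
  expect_equal(unname(f$theta), ow$theta_anova, tolerance = 1e-8)
})

test_that("summary-statistics fits match the dense reference to 6+ decimals", {
  for (s in 1:3) {
    inst <- make_instance(n = 100 + 30 * s, m = 1, n_subj = 5 + s,
                          seed = 200 + s)
    for (method in c("REML", "ML")) {
      cfg <- fitter_config(method)
      f1 <- fit_gene(inst$ss, 1, cfg)
      f2 <- dense_reference_fit(inst$X, inst$Z, inst$Y[1, ], cfg)
      expect_true(f1$converged)
      expect_lt(max(abs(f1$beta - f2$beta)), 1e-6)
      expect_lt(abs(f1$sigma2 - f2$sigma2), 1e-6)
      expect_lt(max(abs(f1$theta - f2$theta)), 1e-6)
      expect_lt(max(abs(f1$se_theta - f2$se_theta)), 1e-6)
      expect_lt(abs(f1$loglik - f2$loglik), 1e-6)
    }
  }
})

test_that("variance-component SEs match a dense likelihood Hessian check", {
  # the (theta, sigma2) expected information from summary statistics equals
  # the dense-projection version computed inside dense_reference_fit
  inst <- make_instance(n = 90, m = 1, seed = 91)
  for (method in c("REML", "ML")) {
    cfg <- fitter_config(method)
    f1 <- fit_gene(inst$ss, 1, cfg)
    f2 <- dense_reference_fit(inst$X, inst$Z, inst$Y[1, ], cfg)
    expect_equal(unname(f1$se_theta), unname(f2$se_theta), tolerance = 1e-8)
  }
})

test_that("REML fits agree with lmer on small instances", {
  skip_if_not_installed("lme4")
  ow <- make_oneway(S = 12, c_per = 30, sb2 = 0.6, seed = 101)
  f <- fit_gene(ow$ss, 1)
  d <- data.frame(y = ow$y, subject = factor(ow$subj))
  lf <- lme4::lmer(y ~ 1 + (1 | subject), d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  # 1e-5: the two optimizers have different stopping rules
  expect_equal(unname(f$theta), vc$vcov[1], tolerance = 1e-5)
  expect_equal(f$sigma2, vc$vcov[2], tolerance = 1e-5)
  expect_equal(unname(f$beta), unname(lme4::fixef(lf)), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
})

test_that("negative variance components are estimated without error", {
  # no subject effect: theta fluctuates around 0 and goes negative for some
  # genes; fits must stay clean and the loglik never falls below gamma = 0
  withr::with_seed(111, {
    n <- 300; S <- 10
    subj <- sample(S, n, TRUE)
    meta <- data.frame(cell_id = 1:n, subject = factor(subj))
    spec <- model_spec("1", "subject")
    X <- build_fixed_matrix(meta, spec)
    Z <- build_random_matrix(meta, spec)
    m <- 60
    Y <- matrix(rnorm(m * n), m, n, dimnames = list(paste0("g", 1:m), NULL))
    ss <- compute_sstats(X, Z, Y)
    fits <- fit_all(ss)
    expect_true(all(fits$converged))
    expect_true(any(fits$theta < 0))       # sign symmetry under the null
    expect_false(any(fits$degenerate))
    ll0 <- vapply(1:m, function(g) profile_loglik(ss, 0, g)$loglik, numeric(1))
    expect_true(all(fits$loglik >= ll0 - 1e-10))  # ascent from the OLS start
  })
})

test_that("parameter recovery at known truth (K = 1)", {
  # 60 replicate genes, sigma_b^2 = 0.5, sigma^2 = 1: estimator means land
  # within 3 Monte-Carlo SEs of truth
  withr::with_seed(121, {
    n <- 1000; S <- 25; m <- 60
    subj <- sample(S, n, TRUE)
    meta <- data.frame(cell_id = 1:n, subject = factor(subj))
    spec <- model_spec("1", "subject")
    X <- build_fixed_matrix(meta, spec)
    Z <- build_random_matrix(meta, spec)
    Y <- t(vapply(1:m, function(g) {
      rnorm(S, 0, sqrt(0.5))[subj] + rnorm(n)
    }, numeric(n)))
    rownames(Y) <- paste0("g", 1:m)
    fits <- fit_all(compute_sstats(X, Z, Y))
    for (v in list(c(mean(fits$theta), 0.5, stats::sd(fits$theta)),
                   c(mean(fits$sigma2), 1, stats::sd(fits$sigma2)))) {
      expect_lt(abs(v[1] - v[2]), 3 * v[3] / sqrt(m))
    }
  })
})

test_that("fit_all: single gene reduces to fit_gene; order invariance; flags", {
  inst <- make_instance(n = 80, m = 5, seed = 131)
  fits <- fit_all(inst$ss)
  f3 <- fit_gene(inst$ss, 3)
  expect_equal(fits$beta[, 3], f3$beta)
  expect_equal(fits$loglik[3], f3$loglik)
  # permuted gene order gives the same per-gene answers
  fp <- fit_all(inst$ss, genes = c(4, 1, 5, 2, 3))
  expect_equal(fp$loglik, fits$loglik[c(4, 1, 5, 2, 3)])
  expect_equal(fp$theta[1, ], fits$theta[1, c(4, 1, 5, 2, 3)])

  # a zero-variance gene yields an NA fit with a reason, not an error
  Yc <- inst$Y
  Yc[2, ] <- 7
  ssc <- compute_sstats(inst$X, inst$Z, Yc)
  fc <- fit_all(ssc)
  expect_true(fc$degenerate[2])
  expect_true(is.na(fc$loglik[2]))
  expect_match(fc$reason[2], "residual")
  expect_false(any(fc$degenerate[-2]))
})

test_that("ML and REML agree asymptotically", {
  ow <- make_oneway(S = 25, c_per = 160, sb2 = 0.5, seed = 141)  # n = 4000
  fr <- fit_gene(ow$ss, 1, fitter_config("REML"))
  fm <- fit_gene(ow$ss, 1, fitter_config("ML"))
  # theta differs O(1/S) between criteria; both near truth
  expect_lt(abs(fr$theta - fm$theta), 0.1)
  expect_lt(abs(fr$sigma2 - fm$sigma2), 0.01)
})

test_that("dense reference fit: OLS reduction, n guard, eigen route", {
  withr::with_seed(151, {
    n <- 40
    X <- cbind(1, rnorm(n))
    y <- drop(X %*% c(2, 1)) + rnorm(n)
    f <- dense_reference_fit(X, NULL, y)
    b <- drop(solve(crossprod(X), crossprod(X, y)))
    expect_equal(unname(f$beta), b, tolerance = 1e-10)
    expect_equal(f$sigma2, sum((y - X %*% b)^2) / (n - 2), tolerance = 1e-10)
  })
  inst <- make_instance(n = 50, m = 1, seed = 152)
  cfg <- fitter_config(dense_oracle_max_n = 40)
  expect_error(dense_reference_fit(inst$X, inst$Z, inst$Y[1, ], cfg),
               "dense_oracle_max_n")
  # shared-eigensystem dense route agrees with the per-iteration Cholesky one
  ec <- dense_eigen_cache(inst$X, inst$Z)
  fe <- dense_reference_fit(inst$X, inst$Z, inst$Y[1, ], eigen_cache = ec)
  fc <- dense_reference_fit(inst$X, inst$Z, inst$Y[1, ])
  expect_equal(fe$beta, fc$beta, tolerance = 1e-8)
  expect_equal(fe$theta, fc$theta, tolerance = 1e-8)
  expect_equal(fe$loglik, fc$loglik, tolerance = 1e-8)
})

test_that("fit table export round-trips at full precision", {
  inst <- make_instance(n = 60, m = 3, seed = 161)
  fits <- fit_all(inst$ss)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fits(fits, path)
  back <- as.data.frame(data.table::fread(path))
  expect_equal(back$sigma2, fits$sigma2, tolerance = 1e-15)
  expect_equal(back$loglik, fits$loglik, tolerance = 1e-15)
  expect_equal(back$theta_subject, unname(fits$theta[1, ]), tolerance = 1e-15)
})
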