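#' Fitter configuration
#'
#' @param method estimation criterion, `"REML"` (default) or `"ML"`.
#' @param max_iter maximum Fisher-scoring iterations per gene.
#' @param tol_loglik stop when an accepted step improves the profile
#'   log-likelihood by less than this.
#' @param tol_grad score (gradient in gamma) max-norm below which a stalled
#'   line search still counts as converged.
#' @param tol_param primary stopping rule: converge when the Newton step
#'   (the scoring estimate of the remaining parameter error) falls below
#'   this, relative to `1 + |gamma|`. Chosen so that balanced designs match
#'   closed-form REML answers to ~1e-8 even when the likelihood is flat.
#' @param boundary_eps keep gamma above `-1/lambda_max + boundary_eps`.
#' @param gamma_init starting value for every variance ratio (default 0, the
#'   OLS start, which is always interior).
#' @param dense_oracle_max_n refuse [dense_reference_fit()] above this n.
#' @return list of class `sslmm_config`.
#' @export
fitter_config <- function(method = c("REML", "ML"), max_iter = 200,
                          tol_loglik = 1e-8, tol_grad = 1e-4,
                          tol_param = 1e-9, boundary_eps = 1e-8,
                          gamma_init = 0, dense_oracle_max_n = 3000) {
  method <- match.arg(toupper(method[1]), c("REML", "ML"))
  stopifnot(tol_loglik > 0, tol_grad > 0, tol_param > 0, boundary_eps > 0,
            max_iter >= 1)
  structure(list(method = method, max_iter = as.integer(max_iter),
                 tol_loglik = tol_loglik, tol_grad = tol_grad,
                 tol_param = tol_param, boundary_eps = boundary_eps,
                 gamma_init = gamma_init,
                 dense_oracle_max_n = dense_oracle_max_n),
            class = "sslmm_config")
}

#' Largest eigenvalue of Z'Z
#'
#' The admissible region for the variance ratios is
#' `gamma_k > -1/lambda_max`, where `lambda_max` is the largest eigenvalue of
#' `Z'Z` (equivalently the largest nonzero eigenvalue of `ZZ'`).
#'
#' @param ZZ the q x q Gram matrix `Z'Z` (symmetric PSD).
#' @return scalar largest eigenvalue.
#' @export
lambda_max <- function(ZZ) {
  if (ncol(ZZ) == 0) return(0)
  if (max(abs(ZZ - t(ZZ))) > 1e-8 * max(1, max(abs(ZZ)))) {
    stop("ZZ must be symmetric")
  }
  max(eigen(ZZ, symmetric = TRUE, only.values = TRUE)$values)
}

## block index list from a partition vector
.blocks <- function(partition) {
  ends <- cumsum(partition)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
}

.gene_index <- function(ss, gene) {
  if (is.character(gene)) {
    g <- match(gene, ss$gene_ids)
    if (is.na(g)) stop("unknown gene id: ", gene)
    g
  } else as.integer(gene)
}

#' GLS building blocks for one gene at a given gamma
#'
#' With `H = I + Z Gamma Z'` (`Gamma = blockdiag(gamma_k I_qk)`), the matrix
#' inversion lemma gives `H^-1 = I - Z (I_q + Gamma A)^-1 Gamma Z'` and the
#' determinant identity `log|H| = log|I_q + Gamma A|`, with `A = Z'Z`. Every
#' quantity the profile likelihood needs is therefore available from the
#' summary statistics at `O(p^3 + q^3)` cost, independent of the number of
#' cells. `I_q + Gamma A` is factorized by LU (it is nonsymmetric when the
#' gamma components differ) and `M^-1 Gamma`, symmetric in exact arithmetic
#' by the push-through identity, is symmetrized to suppress rounding.
#'
#' @param ss `sslmm_sstats`.
#' @param gamma numeric vector of variance ratios, one per component.
#' @param gene gene id or index.
#' @return list with `XHiX` (p x p), `XHiy` (p), `yHiy`, `ZHiZ` (q x q),
#'   `ZHiX` (q x p), `ZHiy` (q), `logdetH`, plus internals reused by the
#'   fitter.
#' @export
gls_quadratics <- function(ss, gamma, gene) {
  stopifnot(inherits(ss, "sslmm_sstats"))
  g <- .gene_index(ss, gene)
  q <- ncol(ss$ZZ)
  if (q == 0 || length(gamma) == 0) {
    return(list(XHiX = ss$XX, XHiy = ss$XY[, g], yHiy = ss$Ynorm[[g]],
                ZHiZ = ss$ZZ, ZHiX = ss$ZX, ZHiy = ss$ZY[, g],
                logdetH = 0, W = matrix(0, 0, 0), gvec = numeric(0)))
  }
  if (length(gamma) != length(ss$partition)) {
    stop("gamma must have one entry per variance component")
  }
  gvec <- rep(gamma, times = ss$partition)
  A <- ss$ZZ
  M <- diag(q) + gvec * A                      # (I + Gamma A); rows scaled
  dt <- determinant(M, logarithm = TRUE)
  if (dt$sign <= 0 || !is.finite(dt$modulus)) {
    stop("I + Gamma A is singular or indefinite: gamma outside the ",
         "admissible region (gamma_k <= -1/lambda_max)")
  }
  W <- tryCatch(solve(M, diag(gvec, q)), error = function(e) {
    stop("I + Gamma A is numerically singular at gamma = ",
         paste(signif(gamma, 6), collapse = ", "))
  })
  W <- (W + t(W)) / 2
  zy <- ss$ZY[, g]
  Wzx <- W %*% ss$ZX
  Wzy <- W %*% zy
  AW <- A %*% W
  list(XHiX = ss$XX - crossprod(ss$ZX, Wzx),
       XHiy = drop(ss$XY[, g] - crossprod(ss$ZX, Wzy)),
       yHiy = ss$Ynorm[[g]] - sum(zy * Wzy),
       ZHiZ = A - AW %*% A,
       ZHiX = ss$ZX - AW %*% ss$ZX,
       ZHiy = drop(zy - AW %*% zy),
       logdetH = as.numeric(dt$modulus),
       W = W, gvec = gvec)
}

## Profile beta and sigma2 out of the likelihood given the GLS blocks.
## Constants are kept explicitly so likelihood differences (LRT) are valid:
##   ML :  l = -1/2 [ n log(2 pi s2) + log|H| + n ]
##   REML: l = -1/2 [ (n-p) log(2 pi s2) + log|H| + log|X'H^-1 X| + (n-p) ]
.profile_from_quad <- function(quad, n, p, method, rss_tol = 1e-12) {
  R <- tryCatch(chol(quad$XHiX), error = function(e) NULL)
  if (is.null(R)) {
    return(list(loglik = NA_real_, degenerate = TRUE, reason = "XHiX not PD"))
  }
  beta <- drop(backsolve(R, forwardsolve(t(R), quad$XHiy)))
  rss <- quad$yHiy - sum(quad$XHiy * beta)
  if (!is.finite(rss) || rss <= rss_tol * max(quad$yHiy, 1)) {
    return(list(loglik = NA_real_, degenerate = TRUE,
                reason = "nonpositive residual sum of squares"))
  }
  if (method == "REML") {
    df <- n - p
    sigma2 <- rss / df
    ll <- -0.5 * (df * log(2 * pi * sigma2) + quad$logdetH +
                    2 * sum(log(diag(R))) + df)
  } else {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + quad$logdetH + n)
  }
  list(loglik = ll, sigma2 = sigma2, beta = beta, rss = rss, R = R,
       degenerate = FALSE)
}

## REML/ML score and expected information in gamma, from the GLS blocks.
## score_k = -1/2 [ tr(P Zk Zk') - y'P Zk Zk' P y / s2 ]  (REML; ML uses
## H^-1 in the trace), info_kl = 1/2 || Zk' P Zl ||_F^2.
.score_info_gamma <- function(quad, prof, partition, method) {
  K <- length(partition)
  bl <- .blocks(partition)
  U <- forwardsolve(t(prof$R), t(quad$ZHiX))        # R'^-1 (Z'H^-1X)'
  ZPZ <- quad$ZHiZ - crossprod(U)
  ZPy <- drop(quad$ZHiy - quad$ZHiX %*% prof$beta)  # Z'H^-1 (y - X beta)
  Tr <- if (method == "REML") ZPZ else quad$ZHiZ
  score <- numeric(K)
  info <- matrix(0, K, K)
  dTr <- diag(Tr)
  for (k in seq_len(K)) {
    score[k] <- -0.5 * (sum(dTr[bl[[k]]]) -
                          sum(ZPy[bl[[k]]]^2) / prof$sigma2)
    for (l in k:K) {
      info[k, l] <- info[l, k] <- 0.5 * sum(Tr[bl[[k]], bl[[l]]]^2)
    }
  }
  list(score = score, info = info, ZPZ = ZPZ, ZPy = ZPy)
}

#' Profiled log-likelihood of the variance ratios for one gene
#'
#' Evaluates the ML or REML log-likelihood at `gamma` with the fixed effects
#' and residual variance replaced by their closed-form maximizers:
#' `beta = (X'H^-1X)^-1 X'H^-1 y`, `RSS = y'H^-1y - beta'X'H^-1y`,
#' `sigma2 = RSS/(n-p)` (REML) or `RSS/n` (ML). Additive constants are fixed
#' (see source) so differences between nested fits are valid LRT statistics.
#'
#' @inheritParams gls_quadratics
#' @param method `"REML"` or `"ML"`.
#' @return list with `loglik`, `sigma2_hat`, `beta_hat`.
#' @export
profile_loglik <- function(ss, gamma, gene, method = c("REML", "ML")) {
  method <- match.arg(toupper(method[1]), c("REML", "ML"))
  quad <- gls_quadratics(ss, gamma, gene)
  prof <- .profile_from_quad(quad, ss$n, ncol(ss$XX), method)
  if (isTRUE(prof$degenerate)) {
    return(list(loglik = NA_real_, sigma2_hat = NA_real_, beta_hat = NULL,
                degenerate = TRUE, reason = prof$reason))
  }
  list(loglik = prof$loglik, sigma2_hat = prof$sigma2, beta_hat = prof$beta,
       degenerate = FALSE)
}

#' Score vector and expected information for the variance ratios
#'
#' @inheritParams profile_loglik
#' @return list with `score` (length K) and `info` (K x K, symmetric PSD).
#' @export
score_and_information <- function(ss, gamma, gene, method = c("REML", "ML")) {
  method <- match.arg(toupper(method[1]), c("REML", "ML"))
  quad <- gls_quadratics(ss, gamma, gene)
  prof <- .profile_from_quad(quad, ss$n, ncol(ss$XX), method)
  if (isTRUE(prof$degenerate)) stop("degenerate gene: ", prof$reason)
  si <- .score_info_gamma(quad, prof, ss$partition, method)
  if (!all(is.finite(si$score))) stop("non-finite score for gene ", gene)
  list(score = si$score, info = si$info)
}

## Expected information of the full likelihood in (theta_1..theta_K, sigma2),
## evaluated at the optimum; P replaces H^-1 under REML. Uses the Neumann-type
## expansions H^-r = I - Z G_r Z' with
##   G2 = 2W - WAW,  G3 = 3W - 3WAW + WAWAW   (W = M^-1 Gamma, A = Z'Z)
## so every trace reduces to q x q / p x p products.
.theta_information_ss <- function(ss, quad, prof, si, method) {
  part <- ss$partition
  K <- length(part)
  bl <- .blocks(part)
  A <- ss$ZZ
  W <- quad$W
  n <- ss$n
  WA <- W %*% A
  WAW <- WA %*% W
  G2 <- 2 * W - WAW
  G3 <- 3 * W - 3 * WAW + WA %*% WAW
  ZH2Z <- A - A %*% G2 %*% A
  trH2 <- n - sum(G2 * A)
  if (method == "REML") {
    Binv <- chol2inv(prof$R)
    ZH2X <- ss$ZX - A %*% (G2 %*% ss$ZX)
    XH2X <- ss$XX - crossprod(ss$ZX, G2 %*% ss$ZX)
    XH3X <- ss$XX - crossprod(ss$ZX, G3 %*% ss$ZX)
    BX <- Binv %*% t(quad$ZHiX)                 # p x q
    ZP2Z <- ZH2Z - ZH2X %*% BX - crossprod(BX, t(ZH2X)) +
      crossprod(BX, XH2X %*% BX)
    BX2 <- Binv %*% XH2X
    trsq <- trH2 - 2 * sum(Binv * XH3X) + sum(BX2 * t(BX2))
    Tq <- si$ZPZ
    Tsq <- ZP2Z
  } else {
    Tq <- quad$ZHiZ
    Tsq <- ZH2Z
    trsq <- trH2
  }
  info <- matrix(0, K + 1, K + 1)
  dTsq <- diag(Tsq)
  for (k in seq_len(K)) {
    for (l in k:K) {
      info[k, l] <- info[l, k] <- 0.5 * sum(Tq[bl[[k]], bl[[l]]]^2)
    }
    info[k, K + 1] <- info[K + 1, k] <- 0.5 * sum(dTsq[bl[[k]]])
  }
  info[K + 1, K + 1] <- 0.5 * trsq
  info / prof$sigma2^2
}

## Shared Fisher-scoring driver. quadfun(gamma) must return the GLS blocks.
.fit_driver <- function(quadfun, n, p, partition, lower, cfg) {
  K <- length(partition)
  method <- cfg$method
  gamma <- rep(cfg$gamma_init, length.out = K)
  quad <- quadfun(gamma)
  prof <- .profile_from_quad(quad, n, p, method)
  if (isTRUE(prof$degenerate)) {
    return(list(degenerate = TRUE, reason = prof$reason, niter = 0L,
                converged = FALSE))
  }
  # profile likelihood at gamma = 0 (the no-random-effect null); free when
  # starting from the OLS point, used by the directed likelihood-root z-test
  loglik_null <- if (K == 0 || all(gamma == 0)) {
    prof$loglik
  } else {
    p0 <- .profile_from_quad(quadfun(rep(0, K)), n, p, method)
    if (isTRUE(p0$degenerate)) NA_real_ else p0$loglik
  }
  niter <- 0L
  converged <- (K == 0)
  polished <- FALSE
  si <- NULL
  while (!converged) {
    si <- .score_info_gamma(quad, prof, partition, method)
    if (!all(is.finite(si$score))) break
    delta <- tryCatch(solve(si$info, si$score), error = function(e)
      solve(si$info + diag(1e-8 * max(diag(si$info), 1), K), si$score))
    gscale <- 1 + max(abs(gamma))
    # Newton decrement = scoring estimate of the remaining parameter error
    if (max(abs(delta)) < cfg$tol_param * gscale) { converged <- TRUE; break }
    if (niter >= cfg$max_iter) break
    step <- 1
    accepted <- FALSE
    for (h in 1:40) {
      gnew <- gamma + step * delta
      if (all(gnew > lower)) {
        qn <- tryCatch(quadfun(gnew), error = function(e) NULL)
        if (!is.null(qn)) {
          pn <- .profile_from_quad(qn, n, p, method)
          if (!isTRUE(pn$degenerate) && is.finite(pn$loglik) &&
              pn$loglik >= prof$loglik) {
            accepted <- TRUE
            break
          }
        }
      }
      step <- step / 2
    }
    if (!accepted) {
      # line search stalled (likelihood flat at machine precision): call it
      # converged if the scoring step or the score itself is already small
      converged <- polished || max(abs(delta)) < 1e-5 * gscale ||
        max(abs(si$score)) < cfg$tol_grad
      break
    }
    dl <- pn$loglik - prof$loglik
    gamma <- gnew; quad <- qn; prof <- pn
    niter <- niter + 1L
    if (dl < cfg$tol_loglik) {                 # safeguard secondary exit:
      if (polished) { converged <- TRUE; break }  # two consecutive sub-tol
      polished <- TRUE                         # improvements
    } else {
      polished <- FALSE
    }
  }
  # Refinement on the score root: near the optimum the likelihood changes
  # fall below machine resolution while the parameter may still be ~1e-7 off
  # (flat directions). A few scoring steps with strictly decreasing Newton
  # decrements push the score to its root without needing the line search.
  if (converged && K > 0) {
    d_prev <- Inf
    for (i in 1:5) {
      s2 <- .score_info_gamma(quad, prof, partition, method)
      if (!all(is.finite(s2$score))) break
      dl2 <- tryCatch(solve(s2$info, s2$score), error = function(e) NULL)
      if (is.null(dl2)) break
      nd <- max(abs(dl2))
      if (!is.finite(nd) || nd >= d_prev || nd < 1e-14) break
      gnew <- gamma + dl2
      if (!all(gnew > lower)) break
      qn <- tryCatch(quadfun(gnew), error = function(e) NULL)
      if (is.null(qn)) break
      pn <- .profile_from_quad(qn, n, p, method)
      if (isTRUE(pn$degenerate) || !is.finite(pn$loglik)) break
      gamma <- gnew; quad <- qn; prof <- pn; d_prev <- nd
    }
  }
  if (K > 0) si <- .score_info_gamma(quad, prof, partition, method)
  list(degenerate = FALSE, gamma = gamma, quad = quad, prof = prof, si = si,
       niter = niter, converged = converged, loglik_null = loglik_null)
}

.na_genefit <- function(gene_id, p, K, n, reason, method) {
  list(gene_id = gene_id, beta = rep(NA_real_, p),
       cov_beta = matrix(NA_real_, p, p), sigma2 = NA_real_,
       gamma = rep(NA_real_, K), theta = rep(NA_real_, K),
       se_theta = rep(NA_real_, K), loglik = NA_real_,
       loglik_null = NA_real_, method = method,
       n = n, df_resid = n - p, n_iter = 0L, converged = FALSE,
       degenerate = TRUE, reason = reason)
}

.genefit_from_state <- function(st, ss_or_names, gene_id, n, p, partition,
                                method, se_fun) {
  K <- length(partition)
  prof <- st$prof
  cov_beta <- prof$sigma2 * chol2inv(prof$R)
  se_theta <- if (K > 0) se_fun(st) else numeric(0)
  fit <- list(gene_id = gene_id, beta = prof$beta, cov_beta = cov_beta,
              sigma2 = prof$sigma2, gamma = st$gamma,
              theta = prof$sigma2 * st$gamma, se_theta = se_theta,
              loglik = prof$loglik, loglik_null = st$loglik_null,
              method = method, n = n,
              df_resid = n - p, n_iter = st$niter,
              converged = st$converged, degenerate = FALSE, reason = "")
  fit
}

#' Fit the LMM for one gene from summary statistics
#'
#' Fisher scoring (expected-information Newton) on the variance ratios with
#' step-halving; accepted steps never decrease the profiled log-likelihood
#' and iterates stay strictly inside `gamma_k > -1/lambda_max`. The variance
#' components `theta_k = sigma2 * gamma_k` may legitimately be negative
#' (that is the point of the reparameterization: the null `theta_k = 0` is
#' interior, so Wald-type tests are valid). Non-convergence is reported via
#' the `converged` flag, never an error; genes with (near-)zero variance are
#' returned as NA fits with a reason code.
#'
#' @param ss `sslmm_sstats`.
#' @param gene gene id or index.
#' @param config [fitter_config()].
#' @return A per-gene fit: list with `beta`, `cov_beta`, `sigma2`, `gamma`,
#'   `theta`, `se_theta`, `loglik`, `n_iter`, `converged`, `df_resid`.
#' @export
fit_gene <- function(ss, gene, config = fitter_config()) {
  stopifnot(inherits(ss, "sslmm_sstats"))
  g <- .gene_index(ss, gene)
  n <- ss$n; p <- ncol(ss$XX); K <- length(ss$partition)
  lam <- lambda_max(ss$ZZ)
  lower <- if (K > 0) -1 / lam + config$boundary_eps else numeric(0)
  quadfun <- function(gamma) gls_quadratics(ss, gamma, g)
  st <- .fit_driver(quadfun, n, p, ss$partition, lower, config)
  if (isTRUE(st$degenerate)) {
    return(.na_genefit(ss$gene_ids[g], p, K, n, st$reason, config$method))
  }
  se_fun <- function(st) {
    info <- .theta_information_ss(ss, st$quad, st$prof, st$si, config$method)
    V <- tryCatch(solve(info), error = function(e) matrix(NA_real_, K + 1, K + 1))
    sqrt(pmax(diag(V)[seq_len(K)], 0))
  }
  fit <- .genefit_from_state(st, ss, ss$gene_ids[g], n, p, ss$partition,
                             config$method, se_fun)
  names(fit$beta) <- colnames(ss$XX)
  dimnames(fit$cov_beta) <- list(colnames(ss$XX), colnames(ss$XX))
  fit
}

#' Fit all genes from summary statistics
#'
#' Genes are fitted independently in stored id order; per-gene failures are
#' reported as flags, never abort the batch. Cost per gene is
#' `O(p^3 + q^3)` per iteration, independent of the number of cells.
#'
#' @inheritParams fit_gene
#' @param genes optional subset (ids or indices); default all.
#' @return Object of class `sslmm_fit`: matrices `beta`, `se_beta` (p x m),
#'   array `cov_beta` (p x p x m), `theta`/`se_theta`/`gamma` (K x m),
#'   vectors `sigma2`, `loglik`, `n_iter`, `converged`, `degenerate`, plus
#'   `gene_ids`, `method`, `n`, `df_resid`, `partition`.
#' @export
fit_all <- function(ss, config = fitter_config(), genes = NULL) {
  stopifnot(inherits(ss, "sslmm_sstats"))
  if (is.null(genes)) genes <- seq_along(ss$gene_ids)
  gidx <- vapply(genes, function(g) .gene_index(ss, g), integer(1))
  m <- length(gidx)
  p <- ncol(ss$XX); K <- length(ss$partition)
  beta <- se_beta <- matrix(NA_real_, p, m,
                            dimnames = list(colnames(ss$XX), ss$gene_ids[gidx]))
  cov_beta <- array(NA_real_, c(p, p, m))
  theta <- se_theta <- gamma <- matrix(NA_real_, max(K, 1), m)[seq_len(K), , drop = FALSE]
  rownames(theta) <- rownames(se_theta) <- rownames(gamma) <- names(ss$partition)
  sigma2 <- loglik <- loglik_null <- rep(NA_real_, m)
  n_iter <- integer(m)
  converged <- degenerate <- logical(m)
  reason <- character(m)
  for (j in seq_len(m)) {
    f <- fit_gene(ss, gidx[j], config)
    degenerate[j] <- f$degenerate
    reason[j] <- f$reason
    n_iter[j] <- f$n_iter
    converged[j] <- f$converged
    if (!f$degenerate) {
      beta[, j] <- f$beta
      cov_beta[, , j] <- f$cov_beta
      se_beta[, j] <- sqrt(pmax(diag(f$cov_beta), 0))
      sigma2[j] <- f$sigma2
      loglik[j] <- f$loglik
      loglik_null[j] <- f$loglik_null
      if (K > 0) {
        theta[, j] <- f$theta
        se_theta[, j] <- f$se_theta
        gamma[, j] <- f$gamma
      }
    }
  }
  structure(list(beta = beta, se_beta = se_beta, cov_beta = cov_beta,
                 sigma2 = sigma2, theta = theta, se_theta = se_theta,
                 gamma = gamma, loglik = loglik, loglik_null = loglik_null,
                 n_iter = n_iter,
                 converged = converged, degenerate = degenerate,
                 reason = reason, gene_ids = ss$gene_ids[gidx],
                 method = config$method, n = ss$n, df_resid = ss$n - p,
                 partition = ss$partition, xnames = colnames(ss$XX)),
            class = "sslmm_fit")
}

#' @export
print.sslmm_fit <- function(x, ...) {
  cat("LMM fits (", x$method, "): ", length(x$gene_ids), " genes, p = ",
      nrow(x$beta), ", K = ", length(x$partition), "; converged: ",
      sum(x$converged), ", degenerate: ", sum(x$degenerate), "\n", sep = "")
  invisible(x)
}

#' Export per-gene fits as a data.frame / TSV
#'
#' One row per gene: `beta_*`, `se_*`, `sigma2`, `theta_*`, `se_theta_*`,
#' `loglik`, `niter`, `converged`. Written TSVs round-trip at 17 significant
#' digits.
#'
#' @param x `sslmm_fit`.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.sslmm_fit <- function(x, row.names = NULL, optional = FALSE, ...) {
  d <- data.frame(gene_id = x$gene_ids, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(x$beta))) {
    d[[paste0("beta_", x$xnames[i])]] <- x$beta[i, ]
    d[[paste0("se_", x$xnames[i])]] <- x$se_beta[i, ]
  }
  d$sigma2 <- x$sigma2
  for (k in seq_len(nrow(x$theta))) {
    nm <- rownames(x$theta)[k]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("vc", k)
    d[[paste0("theta_", nm)]] <- x$theta[k, ]
    d[[paste0("se_theta_", nm)]] <- x$se_theta[k, ]
  }
  d$loglik <- x$loglik
  d$niter <- x$n_iter
  d$converged <- x$converged
  d
}

#' Write fits to a TSV file
#' @param fit `sslmm_fit`.
#' @param path output file.
#' @export
write_fits <- function(fit, path) {
  d <- as.data.frame(fit)
  num <- vapply(d, is.numeric, logical(1))
  for (j in which(num)) d[[j]] <- formatC(d[[j]], digits = 17, format = "g")
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' Spectral cache for the dense reference oracle
#'
#' Full symmetric eigendecomposition of the dense `n x n` matrix `ZZ'`,
#' with the fixed and random designs rotated into the eigenbasis, shared
#' across all genes of a panel by [dense_reference_fit()].
#'
#' @param X,Z dense design matrices (single random component).
#' @return list with `vectors`, `d` (eigenvalues), `CX`, `CZ`.
#' @export
dense_eigen_cache <- function(X, Z) {
  ee <- eigen(tcrossprod(as.matrix(Z)), symmetric = TRUE)
  list(vectors = ee$vectors, d = pmax(ee$values, 0),
       CX = crossprod(ee$vectors, as.matrix(X)),
       CZ = crossprod(ee$vectors, as.matrix(Z)))
}

#' Dense-matrix reference fit (verification oracle)
#'
#' Fits the same criterion as [fit_gene()], but every quantity is obtained
#' from the explicitly formed n x n covariance `H = I + Z Gamma Z'`: Cholesky
#' factorization for `log|H|`, dense triangular solves for the GLS blocks,
#' and a dense projection matrix for the variance-component standard errors.
#' O(n^3) per iteration; intended for tests and validation only and refuses
#' n above `config$dense_oracle_max_n`.
#'
#' For single-component models a precomputed spectral factorization of the
#' dense `ZZ'` ([dense_eigen_cache()]) can be supplied: `H` is then handled
#' through its full n x n eigensystem (still dense covariance algebra, no
#' low-dimensional identities), which amortizes the `O(n^3)` factorization
#' across genes when the oracle is run over a panel. The two dense routes
#' (Cholesky per iteration vs shared eigensystem) agree to rounding and are
#' cross-checked in the test suite.
#'
#' @param X,Z dense design matrices (Z may have 0 columns); `Z` should carry
#'   a `"partition"` attribute (defaults to one component).
#' @param y numeric response vector (one gene).
#' @param config [fitter_config()].
#' @param partition optional override of the Z block structure.
#' @param eigen_cache optional [dense_eigen_cache()] of the same `Z`
#'   (K = 1 only); standard errors are skipped on this route.
#' @return Same shape as [fit_gene()].
#' @export
dense_reference_fit <- function(X, Z, y, config = fitter_config(),
                                partition = NULL, eigen_cache = NULL) {
  X <- as.matrix(X)
  if (is.null(Z)) Z <- matrix(numeric(0), nrow(X), 0)
  if (is.null(partition)) {
    partition <- attr(Z, "partition")
    if (is.null(partition)) {
      partition <- if (ncol(Z) > 0) stats::setNames(ncol(Z), "z") else integer(0)
    }
  }
  Z <- as.matrix(Z)
  n <- nrow(X); p <- ncol(X); q <- ncol(Z); K <- length(partition)
  if (n > config$dense_oracle_max_n) {
    stop("n = ", n, " exceeds dense_oracle_max_n = ", config$dense_oracle_max_n)
  }
  if (!is.null(eigen_cache)) {
    if (K != 1) stop("eigen_cache route supports a single component only")
    lam <- max(eigen_cache$d)
    lower <- -1 / lam + config$boundary_eps
    Cy <- drop(crossprod(eigen_cache$vectors, y))
    Call <- cbind(eigen_cache$CX, Cy, eigen_cache$CZ)
    d <- eigen_cache$d
    quadfun_e <- function(gamma) {
      ev <- 1 + gamma * d
      if (any(ev <= 0)) stop("H not positive definite at gamma = ", gamma)
      S <- Call / sqrt(ev)
      Sx <- S[, seq_len(p), drop = FALSE]
      Sy <- S[, p + 1]
      Sz <- S[, p + 1 + seq_len(q), drop = FALSE]
      list(XHiX = crossprod(Sx), XHiy = drop(crossprod(Sx, Sy)),
           yHiy = sum(Sy^2), ZHiZ = crossprod(Sz),
           ZHiX = crossprod(Sz, Sx), ZHiy = drop(crossprod(Sz, Sy)),
           logdetH = sum(log(ev)))
    }
    st <- .fit_driver(quadfun_e, n, p, partition, lower, config)
    if (isTRUE(st$degenerate)) {
      return(.na_genefit("gene", p, K, n, st$reason, config$method))
    }
    fit <- .genefit_from_state(st, NULL, "gene", n, p, partition,
                               config$method,
                               function(st) rep(NA_real_, K))
    names(fit$beta) <- colnames(X)
    return(fit)
  }
  lam <- if (q > 0) max(eigen(tcrossprod(Z), symmetric = TRUE,
                              only.values = TRUE)$values) else 0
  lower <- if (K > 0) -1 / lam + config$boundary_eps else numeric(0)
  env <- new.env()
  quadfun <- function(gamma) {
    gvec <- rep(gamma, times = partition)
    H <- diag(n)
    if (q > 0) H <- H + Z %*% (gvec * t(Z))
    R <- chol(H)                               # fails if H not PD: boundary
    S <- forwardsolve(t(R), cbind(X, y, Z))
    Sx <- S[, seq_len(p), drop = FALSE]
    Sy <- S[, p + 1]
    Sz <- S[, p + 1 + seq_len(q), drop = FALSE]
    env$R_H <- R                               # kept for the SE step
    list(XHiX = crossprod(Sx), XHiy = drop(crossprod(Sx, Sy)),
         yHiy = sum(Sy^2), ZHiZ = crossprod(Sz),
         ZHiX = crossprod(Sz, Sx), ZHiy = drop(crossprod(Sz, Sy)),
         logdetH = 2 * sum(log(diag(R))))
  }
  st <- .fit_driver(quadfun, n, p, partition, lower, config)
  if (isTRUE(st$degenerate)) {
    return(.na_genefit("gene", p, K, n, st$reason, config$method))
  }
  se_fun <- function(st) {
    Hi <- chol2inv(env$R_H)
    if (config$method == "REML") {
      HiX <- Hi %*% X
      B <- chol2inv(st$prof$R)
      Pm <- Hi - HiX %*% B %*% t(HiX)
    } else {
      Pm <- Hi
    }
    PZ <- Pm %*% Z
    bl <- .blocks(partition)
    Tq <- crossprod(Z, PZ)
    Tsq <- crossprod(PZ)
    info <- matrix(0, K + 1, K + 1)
    for (k in seq_len(K)) {
      for (l in k:K) info[k, l] <- info[l, k] <- 0.5 * sum(Tq[bl[[k]], bl[[l]]]^2)
      info[k, K + 1] <- info[K + 1, k] <- 0.5 * sum(diag(Tsq)[bl[[k]]])
    }
    info[K + 1, K + 1] <- 0.5 * sum(Pm * Pm)
    info <- info / st$prof$sigma2^2
    V <- tryCatch(solve(info), error = function(e) matrix(NA_real_, K + 1, K + 1))
    sqrt(pmax(diag(V)[seq_len(K)], 0))
  }
  fit <- .genefit_from_state(st, NULL, "gene", n, p, partition,
                             config$method, se_fun)
  names(fit$beta) <- colnames(X)
  fit
}
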