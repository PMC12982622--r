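.de_row <- function(gene_id, term, estimate, se, statistic, df, p, kind) {
  data.frame(gene_id = gene_id, term = term, estimate = estimate, se = se,
             statistic = statistic, df = df, p_value = p, fdr = NA_real_,
             test_kind = kind, stringsAsFactors = FALSE)
}

#' t-tests of a fixed-effect contrast across genes
#'
#' For each gene, tests `H0: c'beta = 0` with `t = c'beta / sqrt(c'Cov c)`
#' on `df = n - p` residual degrees of freedom (two-sided). A single
#' coefficient can be tested by naming it.
#'
#' @param fit `sslmm_fit` from [fit_all()] (or a single-gene fit from
#'   [fit_gene()]).
#' @param contrast either a coefficient name, or a numeric weight vector of
#'   length p (named vectors are matched to coefficients by name).
#' @param name label for the output `term` column (defaults to the
#'   coefficient name or `"contrast"`).
#' @return data.frame with one row per gene: `gene_id, term, estimate, se,
#'   statistic, df, p_value, fdr, test_kind` (`fdr` is NA until
#'   [bh_adjust()] is applied across genes).
#' @export
t_test <- function(fit, contrast, name = NULL) {
  if (!inherits(fit, "sslmm_fit")) fit <- .as_fitset(fit)
  p <- nrow(fit$beta)
  if (is.character(contrast) && length(contrast) == 1) {
    j <- match(contrast, fit$xnames)
    if (is.na(j)) stop("unknown coefficient: ", contrast)
    w <- numeric(p); w[j] <- 1
    if (is.null(name)) name <- contrast
  } else {
    w <- numeric(p)
    if (!is.null(names(contrast)) && all(nzchar(names(contrast)))) {
      j <- match(names(contrast), fit$xnames)
      if (anyNA(j)) stop("unknown coefficient in contrast: ",
                         paste(names(contrast)[is.na(j)], collapse = ", "))
      w[j] <- contrast
    } else {
      if (length(contrast) != p) stop("contrast length must equal p = ", p)
      w <- as.numeric(contrast)
    }
    if (all(w == 0)) stop("contrast has no nonzero weight")
    if (is.null(name)) name <- "contrast"
  }
  m <- length(fit$gene_ids)
  est <- drop(crossprod(w, fit$beta))
  se <- vapply(seq_len(m), function(j) {
    v <- drop(crossprod(w, fit$cov_beta[, , j] %*% w))
    if (is.na(v) || v < 0) NA_real_ else sqrt(v)
  }, numeric(1))
  stat <- ifelse(is.na(se) | se == 0, NA_real_, est / se)
  df <- fit$df_resid
  pv <- 2 * stats::pt(abs(stat), df = df, lower.tail = FALSE)
  .de_row(fit$gene_ids, name, est, se, stat, df, pv, "t")
}

## promote a single-gene fit (list) to the vectorized container
.as_fitset <- function(f) {
  p <- length(f$beta); K <- length(f$theta)
  structure(list(beta = matrix(f$beta, p, 1), se_beta = matrix(sqrt(pmax(diag(f$cov_beta), 0)), p, 1),
                 cov_beta = array(f$cov_beta, c(p, p, 1)),
                 sigma2 = f$sigma2, theta = matrix(f$theta, K, 1),
                 se_theta = matrix(f$se_theta, K, 1),
                 gamma = matrix(f$gamma, K, 1), loglik = f$loglik,
                 loglik_null = f$loglik_null,
                 n_iter = f$n_iter, converged = f$converged,
                 degenerate = f$degenerate, reason = f$reason,
                 gene_ids = f$gene_id, method = f$method, n = f$n,
                 df_resid = f$df_resid, partition = stats::setNames(rep(NA, K), NULL),
                 xnames = names(f$beta)), class = "sslmm_fit")
}

#' One-sided z-test of a variance component
#'
#' Tests `H0: theta_k <= 0` against `H1: theta_k > 0`. Because the estimator
#' is allowed to go negative, the null value 0 is interior and the usual
#' normal asymptotics apply; `p = P(Z > z)` (one-sided).
#'
#' Two z statistics are offered. `"lr"` (default) is the directed likelihood
#' root `z = sign(theta_k) * sqrt(2 (l_full - l_null))`, asymptotically
#' N(0, 1) and close to nominal level already at a few dozen grouping levels
#' (single-component models only; it needs the gamma = 0 profile likelihood
#' recorded by the fitter). `"wald"` is `z = theta_k / se(theta_k)` with the
#' expected-information standard error at the optimum; it is asymptotically
#' equivalent but noticeably conservative when the number of grouping levels
#' is small, because `se(theta_k)` co-varies with the estimate (see the
#' methods vignette).
#'
#' @param fit `sslmm_fit`.
#' @param k variance-component index (default 1).
#' @param method `"lr"` (directed likelihood root) or `"wald"`.
#' @return data.frame as in [t_test()] with `test_kind = "z"`.
#' @export
z_test_varcomp <- function(fit, k = 1, method = c("lr", "wald")) {
  method <- match.arg(method)
  if (!inherits(fit, "sslmm_fit")) fit <- .as_fitset(fit)
  if (k > nrow(fit$theta)) stop("component k = ", k, " not in the model")
  est <- fit$theta[k, ]
  if (method == "lr") {
    if (nrow(fit$theta) != 1) {
      stop("the likelihood-root z-test is defined for single-component ",
           "models; use method = \"wald\" or lrt_varcomp() with an ",
           "explicitly reduced fit")
    }
    if (all(is.na(fit$loglik_null))) {
      stop("fit carries no gamma = 0 profile likelihood; refit or use ",
           "method = \"wald\"")
    }
    lr <- pmax(2 * (fit$loglik - fit$loglik_null), 0)
    z <- sign(est) * sqrt(lr)
    se <- fit$se_theta[k, ]
  } else {
    se <- fit$se_theta[k, ]
    z <- ifelse(is.na(se) | se == 0, NA_real_, est / se)
  }
  pv <- stats::pnorm(z, lower.tail = FALSE)
  nm <- rownames(fit$theta)[k]
  if (is.null(nm) || is.na(nm) || !nzchar(nm)) nm <- paste0("vc", k)
  .de_row(fit$gene_ids, paste0("theta_", nm), est, se, z, Inf, pv, "z")
}

#' Likelihood ratio test of variance components
#'
#' `stat = 2 (loglik_full - loglik_reduced)`, clipped at zero, referred to a
#' chi-squared with `df = K_full - K_reduced`. Off-boundary
#' reparameterization makes the plain chi-squared reference valid (no
#' mixture correction). Under REML the two fits must share the identical
#' fixed-effect design.
#'
#' @param fit_full,fit_reduced `sslmm_fit` objects over the same genes,
#'   fitted with the same criterion; the reduced model drops one or more
#'   random components (e.g. [drop_random()] then [fit_all()]).
#' @return data.frame as in [t_test()] with `test_kind = "lrt"`.
#' @export
lrt_varcomp <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "sslmm_fit"), inherits(fit_reduced, "sslmm_fit"))
  if (!identical(fit_full$gene_ids, fit_reduced$gene_ids)) {
    stop("fits are over different genes")
  }
  if (!identical(fit_full$method, fit_reduced$method)) {
    stop("fits use different estimation criteria")
  }
  if (fit_full$method == "REML" &&
      !identical(fit_full$xnames, fit_reduced$xnames)) {
    stop("REML likelihoods are only comparable for identical fixed effects")
  }
  df <- length(fit_full$partition) - length(fit_reduced$partition)
  if (df <= 0) stop("full model must have more variance components")
  stat <- pmax(2 * (fit_full$loglik - fit_reduced$loglik), 0)
  pv <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  .de_row(fit_full$gene_ids, "random", NA_real_, NA_real_, stat, df, pv, "lrt")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure; NAs are excluded and reinserted.
#'
#' @param pvals numeric p-values in \[0, 1\] (NAs allowed).
#' @return vector of adjusted values (same length, NAs preserved).
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}
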