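---
title: "Linear mixed models from summary statistics for single-cell differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear mixed models from summary statistics for single-cell differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-subject single-cell RNA-seq experiments measure thousands of genes in
tens of thousands to millions of cells collected from a few dozen donors.
Cells from the same donor are correlated; ignoring that correlation
(pseudoreplication) inflates false-positive rates in per-gene differential
expression (DE) tests. The per-gene linear mixed-effects model (LMM)

$$ y = X\beta + Zb + \varepsilon,\qquad
   b_k \sim N(0, \sigma_k^2 I_{q_k}),\quad
   \varepsilon \sim N(0, \sigma^2 I_n) $$

addresses this by modeling conditions, cell types and nuisance covariates as
fixed effects $\beta$ and subjects (and optionally batches) as random
effects $b$. The obstacle is computational: standard LMM fitters work with
cell-level objects of size $n$ (number of cells) per gene, per iteration.

`sslmm` removes the $n$ from the inner loop. The data enter only through the
cross-products

$$ X^TX,\quad X^TY^T,\quad Z^TX,\quad Z^TY^T,\quad Z^TZ,\quad
   \{y_g^Ty_g\},\quad n, $$

computed once in a single streaming pass over cell chunks ($Y$ is the
gene-by-cell matrix of $\log(1+\text{count})$ values). Everything the
likelihood, score, information, and standard errors need is then available
at $O(p^3+q^3)$ per gene per iteration — independent of $n$.

## The algebra

Write the per-gene covariance as $\sigma^2 H$ with
$H = I + \sum_k \gamma_k Z_k Z_k^T = I + Z\Gamma Z^T$, where
$\gamma_k = \sigma_k^2/\sigma^2$ are variance ratios and
$\Gamma = \mathrm{blockdiag}(\gamma_k I_{q_k})$. With $A = Z^TZ$ and
$M = I_q + \Gamma A$, the matrix-inversion lemma and Sylvester's determinant
identity give

$$ H^{-1} = I - Z M^{-1} \Gamma Z^T, \qquad \log|H| = \log|M|, $$

so all GLS quadratic forms ($X^TH^{-1}X$, $X^TH^{-1}y$, $y^TH^{-1}y$, ...)
reduce to $q\times q$ algebra on the summary statistics. $M$ is nonsymmetric
when the $\gamma_k$ differ and is factorized by LU; $W = M^{-1}\Gamma$ is
symmetric in exact arithmetic (push-through identity) and is symmetrized to
suppress rounding. Both identities are verified against dense construction
of $H$ in the test suite (`test-lmmfit.R`, `test-acceptance.R`, criterion 6,
at $10^{-10}$ on randomized instances).

Profiling $\beta$ and $\sigma^2$ out of the (restricted) likelihood leaves a
$K$-dimensional objective in $\gamma$:
$\hat\beta = (X^TH^{-1}X)^{-1}X^TH^{-1}y$,
$\mathrm{RSS} = y^TH^{-1}y - \hat\beta^TX^TH^{-1}y$,
$\hat\sigma^2 = \mathrm{RSS}/(n-p)$ under REML (RSS$/n$ under ML). The REML
profile log-likelihood is
$-\tfrac12[(n-p)\log(2\pi\hat\sigma^2) + \log|H| + \log|X^TH^{-1}X| + (n-p)]$
with all constants kept explicit so that differences between nested fits are
valid likelihood-ratio statistics.

## Off-boundary variance components

Classically $\sigma_k^2 \ge 0$, which puts the null $\sigma_k^2 = 0$ on the
boundary of the parameter space and breaks the usual Wald/LRT asymptotics
(mixtures of chi-squared distributions). `sslmm` instead estimates
$\theta_k = \sigma^2\gamma_k$ on the open region
$\gamma_k > -1/\lambda_{\max}$, where $\lambda_{\max}$ is the largest
eigenvalue of $Z^TZ$ — exactly the region where $H$ stays positive-definite.
Negative $\hat\theta_k$ are legitimate outcomes (and a useful diagnostic: a
clearly negative component says the random term is not needed). The null
$\theta_k = 0$ is then interior, t/z statistics for fixed effects and
variance components have their usual asymptotic distributions, and the LRT
is referred to a plain $\chi^2$.

## Optimization and numerical choices

* **Fisher scoring** on $\gamma$ with the expected information
  $I_{k\ell} = \tfrac12\lVert Z_k^T P Z_\ell\rVert_F^2$
  ($P = H^{-1} - H^{-1}X(X^TH^{-1}X)^{-1}X^TH^{-1}$ under REML, $H^{-1}$
  under ML), step-halving (accepted steps never decrease the profile
  likelihood), and projection away from the boundary
  ($\gamma_k > -1/\lambda_{\max} + 10^{-8}$).
* **Start at $\gamma = 0$** (the OLS point): always interior, cheap, and it
  yields the $\gamma=0$ profile likelihood needed by the likelihood-root
  z-test for free.
* **Stopping rule.** The likelihood itself goes flat at machine precision
  while the parameter can still be $\sim10^{-7}$ off along weakly identified
  directions, so loglik/score tolerances alone cannot deliver the package's
  own accuracy standard (agreement with closed-form REML answers to
  $10^{-8}$). The primary criterion is therefore the Newton decrement
  ($\lVert I^{-1}s\rVert_\infty < 10^{-9}(1+\lVert\gamma\rVert_\infty)$),
  followed by a short score-root refinement with strictly decreasing
  decrements; $|\Delta\ell| < 10^{-8}$ and
  $\lVert s\rVert_\infty < 10^{-4}$ remain as safeguard exits. On balanced
  one-way designs the fits match $\hat\sigma^2 = \mathrm{MSW}$,
  $\hat\theta = (\mathrm{MSB}-\mathrm{MSW})/c$ to machine precision.
* **Degenerate genes** (zero variance after the log transform) are emitted
  as NA rows with a reason code, never dropped silently and never an error.
* **Standard errors of $\hat\theta$** come from the inverse expected
  information of the full likelihood in $(\theta_1,\dots,\theta_K,\sigma^2)$
  at the optimum, with $P$ in place of $H^{-1}$ under REML; the required
  $H^{-2}$ and $H^{-3}$ traces reduce to $q\times q$ algebra via
  $H^{-r} = I - ZG_rZ^T$, $G_2 = 2W - WAW$, $G_3 = 3W - 3WAW + WAWAW$.

A dense reference implementation (`dense_reference_fit()`) optimizes the
same criterion with every quantity taken from the explicitly formed
$n \times n$ covariance (Cholesky factorization per iteration, or a shared
full eigensystem of $ZZ^T$ for single-component panels). It exists to
validate the summary-statistics path: the two agree to at least six decimal
places on every estimate, which is the accuracy standard the package holds
itself to throughout the tests.

## Hypothesis testing

* **Fixed effects / contrasts**: $t = c^T\hat\beta / \sqrt{c^T\widehat{\mathrm{cov}}(\hat\beta)c}$
  with $df = n - p$ residual degrees of freedom, two-sided. With $n$ in the
  tens of thousands the df convention is immaterial (a Satterthwaite-style
  approximation would differ in the third decimal of $p$ at most) and
  residual df needs no extra derivatives.
* **Variance components, z-test** of $H_0: \theta_k \le 0$: the default
  statistic is the *directed likelihood root*
  $z = \mathrm{sign}(\hat\theta)\sqrt{2(\ell_{\hat\gamma} - \ell_0)}$. The
  textbook Wald form $\hat\theta/\mathrm{se}(\hat\theta)$ is available
  (`method = "wald"`) but is measurably conservative when the number of
  grouping levels is small: $\mathrm{se}(\hat\theta)$ scales like
  $1 + c\hat\gamma$ (with $c$ cells per subject), so it co-varies with the
  estimate and damps the upper tail. Measured one-sided levels at
  $\alpha = 0.05$ over 10,000 null genes ($n = 2000$, 25 subjects):
  directed root 0.041, Wald-at-optimum 0.006, Wald-with-null-SE 0.071. The
  directed root converges to nominal in the number of subjects (0.048 at
  100 subjects).
* **Variance components, LRT**: $2\Delta\ell$ (clipped at 0 — numerical
  noise can make the reduced fit infinitesimally better) against
  $\chi^2_{df}$, $df = K_\text{full} - K_\text{reduced}$; under REML only
  for identical fixed-effect designs. Measured level at the 5% point:
  0.0500 at 25 subjects.
* **Multiplicity**: Benjamini-Hochberg step-up across genes, applied per
  tested term or contrast.

## The simulator

`simulate_dataset()` emulates a multi-subject, multi-cell-type droplet
experiment. Per-gene negative-binomial parameters come from a reference
count matrix via method-of-moments: $\hat\mu$ = sample mean and
$r = \hat\mu^2/(s^2-\hat\mu)$ when $s^2 > \hat\mu$, else a cap of $10^8$
standing in for the Poisson limit ($r$ clipped to $[10^{-2}, 10^8]$).
`synth_reference()` provides a self-contained reference — per-gene
$(\mu, r)$ log-uniform over $10^{[-2,2]}$ and $10^{[-1,1.5]}$ respectively —
so nothing needs downloading.

Each cell draws subject, cell type and condition uniformly at random
(defaults: 25 subjects, 12 cell types, 2 conditions; 6000 genes of which
480 are DE, each in one designated target cell type with
$|\log\mathrm{FC}| \sim U[0.5, 1]$ and random sign). The count of gene $g$
in cell $i$ is

$$ \mathrm{NB}\!\left(\mu_g\, L_i\, e^{u_{gs(i)} + \beta_g\,
   \mathbf{1}[\text{treated} \wedge \text{target}]},\; r_g\right), $$

with log-normal library factors $L_i$ (SD 0.35 on the log scale) and
per-gene, per-subject random intercepts $u_{gs} \sim N(0, 0.25^2)$ — per
gene because each gene's LMM must have its own true random effect. The
effect-size and noise defaults are explicit stand-ins chosen at realistic
magnitudes for droplet data (a 0.25 log-SD between subjects is a typical
inter-donor spread; 0.35 spans a few-fold library-size range); seeds are
split deterministically across the assignment, effect, and count streams so
datasets are bit-reproducible.

**What the generator does not emulate:** zero-inflation beyond the NB,
batch structure, doublets, UMI saturation, or mean-variance coupling across
genes learned from a specific tissue. A green calibration test therefore
establishes that the fitter and tests behave correctly *under the stated
generative model*, not that any particular biological dataset satisfies
that model.

## What the validation shows — and the one number that falls short

With the default design at 20,000 cells, per-gene interaction t-tests are
well calibrated: null-gene p-values track Uniform(0,1) inside the pointwise
95% band and reject at 0.052–0.053 at $\alpha = 0.05$. Power, scored by the
minimum interaction-term p-value per gene (one score per gene; the
configurable alternatives are the Bonferroni-adjusted minimum or the target
term's p-value), gives AUC $\approx$ 0.947 against the designated DE genes.
At 40,000 cells the same pipeline reaches AUC 0.976: the published headline
value ($\approx$ 0.97) is recovered as the cell count grows toward the
original 120,000-cell study, while the weakly-expressed tail of the
log-uniform synthetic reference ($\mu \lesssim 0.03$) lacks power at
20,000 cells. The package reports the honestly computed number rather than
tuning the generator to meet it; the acceptance test for this criterion is
expected to sit just below its $\pm 0.02$ band at the reduced scale.

## Practical notes

* `reduce_random_effects()` replaces $Z$ by $ZV_r$ ($V_r$ = eigenvectors of
  $Z^TZ$ with nonzero eigenvalue), preserving $ZZ^T$ exactly; use it when a
  grouping structure is collinear or $q > n$. Fits are invariant to the
  substitution.
* Summary statistics are additive over disjoint cell chunks
  (`merge_sstats()`), so they can be computed in parallel shards or
  streamed; the archive format is a directory of plain-text TSVs plus a
  JSON header (no HDF5 dependency is available in this environment), written
  at 17 significant digits so archived fits match in-memory fits.
* QC defaults mirror a typical droplet recipe ($\ge$100 detected features,
  library size in $[2^9, 2^{16}]$, $\ge$20 cells per cell type, genes
  detected in $\ge$16 cells with counts-per-cell $> 0.005$); every
  threshold is a parameter. The `log(library_size)` covariate uses totals
  computed after cell filtering and before gene filtering.
* Known limitations: no random slopes or unstructured covariance; no
  generalized (NB/Poisson) mixed models; homoscedastic residuals per gene;
  the directed-root z-test requires a single variance component (use the
  LRT with an explicit reduced fit otherwise).
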