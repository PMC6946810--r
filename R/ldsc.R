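#' Compute LD scores from a genotype panel
#'
#' The LD score of variant `j` is `l_j = 1 + sum_k adj_r2(j, k)` over
#' variants `k != j` on the same chromosome within the window, where the
#' small-sample bias adjustment
#' `adj_r2 = r2 - (1 - r2) / (n - 2)` is floored at 0 (self-correlation
#' contributes the leading 1, so `l_j >= 1`).
#'
#' @param panel a `genotype_panel` with at least 3 individuals.
#' @param window_kb window in kb around each variant (default 1,000).
#' @return data.frame with `snp` and `l2`; the window is recorded as an
#'   attribute.
#' @export
compute_ld_scores <- function(panel, window_kb = 1000) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (panel$n < 3) stop("need at least 3 individuals")
  if (window_kb < 0) stop("window must be >= 0")
  win <- window_kb * 1000
  n <- panel$n
  l2 <- vapply(seq_len(panel$m), function(j) {
    nb <- which(panel$chr == panel$chr[j] &
                  abs(panel$pos - panel$pos[j]) <= win)
    nb <- setdiff(nb, j)
    if (!length(nb)) return(1)
    r2 <- as.vector(stats::cor(panel$dosage[, j],
                               panel$dosage[, nb, drop = FALSE])^2)
    1 + sum(pmax(0, r2 - (1 - r2) / (n - 2)))
  }, numeric(1))
  structure(data.frame(snp = panel$snp, l2 = l2, stringsAsFactors = FALSE),
            window_kb = window_kb)
}

# weighted least squares with delete-one-block jackknife over contiguous
# variant blocks; returns full-sample coefficients and the per-deletion
# coefficient matrix (blocks x k)
jackknife_wls <- function(X, y, w, n_blocks) {
  m <- length(y)
  if (m < n_blocks) stop("fewer variants than jackknife blocks")
  X <- as.matrix(X)
  block <- ceiling(seq_len(m) / (m / n_blocks))
  Xw <- X * w
  A <- crossprod(Xw, X)
  b <- crossprod(Xw, y)
  coef <- solve(A, b)
  dels <- matrix(NA_real_, n_blocks, ncol(X))
  for (g in seq_len(n_blocks)) {
    idx <- which(block == g)
    Ag <- crossprod(Xw[idx, , drop = FALSE], X[idx, , drop = FALSE])
    bg <- crossprod(Xw[idx, , drop = FALSE], y[idx])
    dels[g, ] <- solve(A - Ag, b - bg)
  }
  list(coef = as.vector(coef), deletions = dels, n_blocks = n_blocks)
}

jackknife_se <- function(values) {
  B <- length(values)
  sqrt((B - 1) / B * sum((values - mean(values))^2))
}

#' LD score regression heritability
#'
#' Regresses per-variant chi-square statistics on LD scores:
#' `E[chi2_j] = N h2 l_j / M + intercept`, so `slope * M / N` estimates the
#' SNP heritability `h2` while the intercept absorbs confounding inflation.
#' Weights follow the two-step heteroskedasticity correction
#' `1 / (l_j (1 + N h2_0 l_j / M)^2)` with `h2_0` from an unweighted first
#' pass. Standard errors come from a delete-one-block jackknife over
#' contiguous variant blocks (default 20 blocks, a desk-scale choice).
#'
#' @param z per-variant z-scores.
#' @param n GWAS sample size.
#' @param ld LD scores (same length as `z`).
#' @param m_variants number of variants the LD scores are referenced to
#'   (default `length(z)`).
#' @param n_blocks jackknife blocks (default 20).
#' @param free_intercept estimate the intercept (default) or constrain it
#'   to 1.
#' @return a `heritability_estimate`: `h2`, `se`, `intercept`,
#'   `intercept_se`, `mean_chi2`, `m`, `n`, `n_blocks`.
#' @export
ldsc_h2 <- function(z, n, ld, m_variants = length(z), n_blocks = 20,
                    free_intercept = TRUE) {
  if (length(z) != length(ld)) stop("z and ld lengths differ")
  if (n <= 1) stop("n must exceed 1")
  chi2 <- z^2
  m <- length(z)
  # first pass: unweighted slope for the weight model
  s1 <- stats::cov(ld, chi2) / stats::var(ld)
  h0 <- min(1, max(0, s1 * m_variants / n))
  w <- 1 / (pmax(ld, 1) * (1 + n * h0 * ld / m_variants)^2)
  if (free_intercept) {
    fit <- jackknife_wls(cbind(1, ld), chi2, w, n_blocks)
    slope_i <- 2L
    intercept <- fit$coef[1]
    int_dels <- fit$deletions[, 1]
  } else {
    fit <- jackknife_wls(cbind(ld), chi2 - 1, w, n_blocks)
    slope_i <- 1L
    intercept <- 1
    int_dels <- rep(1, n_blocks)
  }
  h2 <- fit$coef[slope_i] * m_variants / n
  h2_dels <- fit$deletions[, slope_i] * m_variants / n
  structure(list(h2 = h2, se = jackknife_se(h2_dels),
                 intercept = intercept, intercept_se = jackknife_se(int_dels),
                 mean_chi2 = mean(chi2), m = m_variants, n = n,
                 n_blocks = n_blocks,
                 deletions = h2_dels),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("LDSC h2 = %.4f (SE %.4f), intercept = %.3f (SE %.3f), mean chi2 = %.3f\n",
              x$h2, x$se, x$intercept, x$intercept_se, x$mean_chi2))
  invisible(x)
}

#' Cross-trait LD score regression (genetic correlation)
#'
#' Regresses the per-variant z-score product on LD scores:
#' `E[z1 z2] = sqrt(N1 N2) rho_g l_j / M + intercept`, where the free
#' intercept absorbs sample overlap. The genetic covariance is
#' `slope * M / sqrt(N1 N2)` and the genetic correlation
#' `rg = rho_g / sqrt(h2_1 h2_2)` with the per-trait heritabilities
#' estimated by [ldsc_h2()] on the same blocks, so the block jackknife
#' propagates the uncertainty of all three regressions. The reported `rg`
#' is clamped to `[-1.25, 1.25]` with a warning outside `[-1, 1]`.
#'
#' An `impairment = TRUE` flag negates `rg` (and its jackknife draws),
#' re-expressing a correlation with a function trait as a correlation with
#' its impairment -- exactly a sign flip of every z-score of that trait.
#'
#' @param z1,z2 per-variant z-scores of the two traits.
#' @param n1,n2 GWAS sample sizes.
#' @param ld LD scores.
#' @param m_variants reference variant count (default `length(z1)`).
#' @param n_blocks jackknife blocks.
#' @param impairment negate the correlation to the impairment convention.
#' @return a `genetic_correlation`: `rho_g`, `rg`, `se`, `p`,
#'   `cross_intercept`, plus the per-trait `h2` objects.
#' @export
ldsc_rg <- function(z1, z2, n1, n2, ld, m_variants = length(z1),
                    n_blocks = 20, impairment = FALSE) {
  if (length(z1) != length(z2) || length(z1) != length(ld))
    stop("inconsistent dimensions")
  h1 <- ldsc_h2(z1, n1, ld, m_variants, n_blocks)
  h2 <- ldsc_h2(z2, n2, ld, m_variants, n_blocks)
  if (h1$h2 <= 0 || h2$h2 <= 0)
    stop(sprintf("rg undefined: nonpositive heritability (h2_1 = %.4f, h2_2 = %.4f)",
                 h1$h2, h2$h2))
  a1 <- 1 + n1 * max(h1$h2, 0) * ld / m_variants
  a2 <- 1 + n2 * max(h2$h2, 0) * ld / m_variants
  w <- 1 / (pmax(ld, 1) * a1 * a2)
  fit <- jackknife_wls(cbind(1, ld), z1 * z2, w, n_blocks)
  rho_g <- fit$coef[2] * m_variants / sqrt(n1 * n2)
  rho_dels <- fit$deletions[, 2] * m_variants / sqrt(n1 * n2)
  rg_dels <- rho_dels / sqrt(pmax(h1$deletions, 1e-8) *
                               pmax(h2$deletions, 1e-8))
  rg <- rho_g / sqrt(h1$h2 * h2$h2)
  if (impairment) { rg <- -rg; rg_dels <- -rg_dels; rho_g <- -rho_g }
  se <- jackknife_se(rg_dels)
  if (abs(rg) > 1 + 1e-8)
    warning(sprintf("rg = %.3f outside [-1, 1]; clamped to [-1.25, 1.25]", rg))
  rg <- max(-1.25, min(1.25, rg))
  structure(list(rho_g = rho_g, rg = rg, se = se,
                 p = 2 * stats::pnorm(-abs(rg / se)),
                 cross_intercept = fit$coef[1],
                 h2_1 = h1, h2_2 = h2, n_blocks = n_blocks),
            class = "genetic_correlation")
}

#' @export
print.genetic_correlation <- function(x, ...) {
  cat(sprintf("LDSC rg = %.4f (SE %.4f), p = %.3g; cross-trait intercept = %.3f\n",
              x$rg, x$se, x$p, x$cross_intercept))
  invisible(x)
}

#' Partitioned heritability by functional annotation (stratified LDSC)
#'
#' Multiple weighted regression `E[chi2_j] = N sum_c tau_c l(j, c) + 1`
#' (intercept constrained to 1), where `l(j, c)` is the LD score of variant
#' `j` restricted to annotation `c`. For each binary annotation the
#' per-annotation heritability is the sum of per-variant contributions
#' `sum_c' tau_c' a(j, c')` over its members; enrichment is the proportion
#' of heritability over the proportion of variants, and its p-value tests
#' `prop_h2 = prop_snps` by block jackknife. Annotations are flagged
#' significant at `sig_threshold` (default 8.5e-4, a Bonferroni level for
#' 59 annotations).
#'
#' @param z,n z-scores and sample size.
#' @param ld_annot matrix (variants x annotations) of partitioned LD scores.
#' @param annot matrix (variants x annotations) of annotation memberships
#'   (binary columns are reported; continuous columns contribute to the
#'   model but get `NA` enrichment).
#' @param m_variants reference variant count.
#' @param n_blocks jackknife blocks.
#' @param sig_threshold Bonferroni flagging threshold.
#' @return a `partition_report` data.frame: one row per annotation with
#'   `tau`, `prop_snps`, `prop_h2`, `prop_h2_se`, `enrichment`,
#'   `enrichment_p`, `significant`.
#' @export
ldsc_partition <- function(z, n, ld_annot, annot, m_variants = length(z),
                           n_blocks = 20, sig_threshold = 8.5e-4) {
  ld_annot <- as.matrix(ld_annot); annot <- as.matrix(annot)
  if (nrow(ld_annot) != length(z) || !identical(dim(ld_annot), dim(annot)))
    stop("dimension mismatch between z, ld_annot and annot")
  C <- ncol(ld_annot)
  nm <- colnames(ld_annot) %||% paste0("annot", seq_len(C))
  ltot <- pmax(apply(ld_annot, 1, max), 1)
  X <- n * ld_annot
  if (qr(X)$rank < C) stop("singular annotation design")
  s1 <- solve(crossprod(X), crossprod(X, z^2 - 1))
  h0 <- min(1, max(0, sum(annot %*% s1)))  # rough total-h2 for the weights
  w <- 1 / (ltot * (1 + n * h0 * ltot / m_variants)^2)
  fit <- jackknife_wls(X, z^2 - 1, w, n_blocks)

  binary <- apply(annot, 2, function(a) all(a %in% c(0, 1)))
  summarize <- function(tau) {
    per_snp <- as.vector(annot %*% tau)
    h2_tot <- sum(per_snp)
    vapply(seq_len(C), function(cc) {
      if (!binary[cc]) return(NA_real_)
      sum(per_snp[annot[, cc] > 0]) / h2_tot
    }, numeric(1))
  }
  prop_h2 <- summarize(fit$coef)
  prop_dels <- matrix(NA_real_, nrow(fit$deletions), C)
  for (b in seq_len(nrow(fit$deletions)))
    prop_dels[b, ] <- summarize(fit$deletions[b, ])
  prop_snps <- colSums(annot == 1) / m_variants
  prop_se <- apply(prop_dels, 2, function(v)
    if (all(is.na(v))) NA_real_ else jackknife_se(v))
  enrichment <- prop_h2 / prop_snps
  # test prop_h2 == prop_snps; degenerate (zero-variance) cases get p = 1
  zstat <- ifelse(is.na(prop_se) | prop_se == 0, 0,
                  (prop_h2 - prop_snps) / prop_se)
  p <- 2 * stats::pnorm(-abs(zstat))
  structure(data.frame(annotation = nm, tau = fit$coef,
                       prop_snps = prop_snps, prop_h2 = prop_h2,
                       prop_h2_se = prop_se, enrichment = enrichment,
                       enrichment_p = p,
                       significant = p < sig_threshold,
                       row.names = NULL, stringsAsFactors = FALSE),
            sig_threshold = sig_threshold,
            class = c("partition_report", "data.frame"))
}

#' Partitioned LD scores for annotations
#'
#' `l(j, c) = sum_k adj_r2(j, k) a(k, c)` over panel variants within the
#' window (including `k = j`).
#'
#' @inheritParams compute_ld_scores
#' @param annot matrix (variants x annotations).
#' @return matrix of partitioned LD scores (variants x annotations).
#' @export
compute_ld_scores_annot <- function(panel, annot, window_kb = 1000) {
  stopifnot(inherits(panel, "genotype_panel"))
  annot <- as.matrix(annot)
  if (nrow(annot) != panel$m) stop("annotation rows must match panel variants")
  win <- window_kb * 1000
  n <- panel$n
  out <- matrix(0, panel$m, ncol(annot),
                dimnames = list(panel$snp, colnames(annot)))
  for (j in seq_len(panel$m)) {
    nb <- which(panel$chr == panel$chr[j] &
                  abs(panel$pos - panel$pos[j]) <= win)
    r2 <- as.vector(stats::cor(panel$dosage[, j],
                               panel$dosage[, nb, drop = FALSE])^2)
    r2adj <- pmax(0, r2 - (1 - r2) / (n - 2))
    r2adj[nb == j] <- 1
    out[j, ] <- colSums(r2adj * annot[nb, , drop = FALSE])
  }
  out
}
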