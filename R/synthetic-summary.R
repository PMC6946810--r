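#' Simulate summary-level two-sample MR data directly
#'
#' Generates a [harmonized_set()] without simulating individuals: true
#' per-variant exposure effects are drawn from a normal distribution, and the
#' observed effects are `beta_x_hat ~ N(beta_x, se_x^2)` and
#' `beta_y_hat ~ N(theta * beta_x + alpha_j, se_y^2)`, where `alpha_j` is a
#' direct (pleiotropic) outcome effect for the configured fraction of invalid
#' instruments. With `balanced = TRUE` the direct effects are zero-mean;
#' otherwise they centre on `alpha_mean` (directional pleiotropy, which an
#' Egger intercept should recover).
#'
#' Ground truth (true effects, validity flags, `theta`) is attached as
#' attribute `truth` and is never consumed by the estimators.
#'
#' @param j number of instruments.
#' @param theta true causal effect (log-odds per exposure unit).
#' @param beta_x_mean,beta_x_sd distribution of true exposure effects.
#' @param se_x,se_y sampling standard errors (scalars or length-`j`); zero is
#'   allowed and yields noiseless effects.
#' @param prop_invalid fraction of instruments with direct outcome effects.
#' @param alpha_mean,alpha_sd direct-effect distribution (`alpha_mean` is
#'   ignored when `balanced = TRUE`).
#' @param balanced zero-mean pleiotropy flag.
#' @param seed integer seed.
#' @return a `harmonized_set` with `truth` attribute.
#' @examples
#' s <- simulate_summary_mr(50, theta = 0.3, seed = 1)
#' mr_ivw(s)
#' @export
simulate_summary_mr <- function(j, theta, beta_x_mean = 0.1, beta_x_sd = 0.03,
                                se_x = 0.02, se_y = 0.05, prop_invalid = 0,
                                alpha_mean = 0, alpha_sd = 0.05,
                                balanced = TRUE, seed = 1) {
  j <- assert_scalar_count(j, "j")
  if (any(se_x < 0) || any(se_y < 0)) stop("standard errors must be >= 0")
  assert_fraction(prop_invalid, "prop_invalid")
  with_seed(seed, {
    bx <- stats::rnorm(j, beta_x_mean, beta_x_sd)
    se_x <- rep_len(se_x, j); se_y <- rep_len(se_y, j)
    n_invalid <- round(prop_invalid * j)
    invalid <- rep(FALSE, j)
    if (n_invalid > 0) invalid[sample.int(j, n_invalid)] <- TRUE
    alpha <- numeric(j)
    if (n_invalid > 0) {
      mu <- if (balanced) 0 else alpha_mean
      alpha[invalid] <- stats::rnorm(n_invalid, mu, alpha_sd)
    }
    bx_hat <- bx + stats::rnorm(j) * se_x
    by_hat <- theta * bx + alpha + stats::rnorm(j) * se_y
    set <- harmonized_set(
      data.frame(snp = sprintf("snp%04d", seq_len(j)),
                 beta_x = bx_hat,
                 se_x = ifelse(se_x > 0, se_x, 1e-12),
                 beta_y = by_hat, se_y = ifelse(se_y > 0, se_y, 1e-12),
                 stringsAsFactors = FALSE),
      exposure = "simulated exposure", outcome = "simulated outcome")
    attr(set, "truth") <- list(theta = theta, beta_x = bx, alpha = alpha,
                               invalid = invalid)
    set
  })
}

# analytic LD scores of an AR(rho) block of a given size:
# l_j = 1 + sum_{k != j} rho^(2|j-k|)
ar_block_ld_scores <- function(block_size, rho) {
  sapply(seq_len(block_size), function(j) {
    k <- seq_len(block_size)[-j]
    1 + sum(rho^(2 * abs(k - j)))
  })
}

#' Simulate paired polygenic GWAS z-scores for two genetically correlated traits
#'
#' Direct summary-level generator for LD score regression: per-variant
#' standardized effects for two traits are drawn from a bivariate normal with
#' correlation `rg` and per-trait variances `h2 / m`; observed z-scores are
#' inflated by the (analytic) LD score of each variant and carry sampling
#' noise, correlated across traits when the samples overlap. The expected
#' chi-square of trait `t` at variant `j` is `1 + n_t * h2_t * l_j / m`, and
#' the expected z-score product is
#' `sqrt(n1 n2) * rg * sqrt(h2_1 h2_2) * l_j / m + rho_e`, so the LD-score
#' regression slope and cross-trait intercept identify heritability, genetic
#' covariance, and sample overlap.
#'
#' LD scores follow the same autoregressive block model as
#' [simulate_genotype_panel()] and are returned as the known truth.
#'
#' @param n1,n2 GWAS sample sizes.
#' @param m number of variants.
#' @param h2_1,h2_2 heritabilities in `[0, 1]`.
#' @param rg genetic correlation in `[-1, 1]`.
#' @param overlap number of overlapping samples (`<= min(n1, n2)`).
#' @param pheno_cor phenotypic correlation among overlapping samples; default
#'   `rg * sqrt(h2_1 * h2_2)` (purely genetic sharing).
#' @param block_size,rho LD block structure for the analytic LD scores.
#' @param seed integer seed.
#' @return list with `z1`, `z2`, `ld` (true LD scores), `n1`, `n2`, `m`, and
#'   a `truth` element.
#' @export
simulate_polygenic_pair <- function(n1, n2, m, h2_1, h2_2, rg, overlap = 0,
                                    pheno_cor = NULL, block_size = 50,
                                    rho = 0.9, seed = 1) {
  n1 <- assert_scalar_count(n1, "n1"); n2 <- assert_scalar_count(n2, "n2")
  m <- assert_scalar_count(m, "m")
  assert_fraction(h2_1, "h2_1"); assert_fraction(h2_2, "h2_2")
  if (!is.finite(rg) || abs(rg) > 1) stop("|rg| must be <= 1")
  if (overlap < 0 || overlap > min(n1, n2)) stop("invalid sample overlap")
  block_size <- assert_scalar_count(block_size, "block_size")

  ld_block <- ar_block_ld_scores(min(block_size, m), rho)
  ld <- rep(ld_block, length.out = m)

  if (is.null(pheno_cor)) pheno_cor <- rg * sqrt(h2_1 * h2_2)
  rho_e <- overlap * pheno_cor / sqrt(n1 * n2)
  rho_e <- max(-1, min(1, rho_e))

  with_seed(seed, {
    u1 <- stats::rnorm(m)
    u2 <- rg * u1 + sqrt(max(0, 1 - rg^2)) * stats::rnorm(m)
    e1 <- stats::rnorm(m)
    e2 <- rho_e * e1 + sqrt(max(0, 1 - rho_e^2)) * stats::rnorm(m)
    z1 <- sqrt(n1 * h2_1 * ld / m) * u1 + e1
    z2 <- sqrt(n2 * h2_2 * ld / m) * u2 + e2
    list(z1 = z1, z2 = z2, ld = ld, n1 = n1, n2 = n2, m = m,
         truth = list(h2_1 = h2_1, h2_2 = h2_2, rg = rg,
                      overlap = overlap, rho_e = rho_e))
  })
}
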