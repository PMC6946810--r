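#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided HWE test on genotype counts, computed over the full
#' conditional distribution of the heterozygote count given the allele
#' counts (the standard SNP exact test, evaluated by the numerically stable
#' recurrence between adjacent heterozygote classes). The p-value is the
#' total probability of heterozygote counts no more probable than the one
#' observed.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return two-sided exact p-value.
#' @examples
#' hwe_exact_p(25, 50, 25)   # exact HWE proportions -> p = 1
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  if (any(c(n_hom1, n_het, n_hom2) < 0)) stop("negative genotype count")
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) return(1)
  rare <- 2 * min(n_hom1, n_hom2) + n_het
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  # start at the (approximate) mode and fill by recurrence
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1L
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  if (i_mid > 1) {
    for (i in seq(i_mid, 2)) {
      h <- hets[i]
      homr <- (rare - h) / 2
      homc <- n - h - homr
      probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (homr + 1) * (homc + 1))
    }
  }
  if (i_mid < length(hets)) {
    for (i in seq(i_mid, length(hets) - 1)) {
      h <- hets[i]
      homr <- (rare - h) / 2
      homc <- n - h - homr
      probs[i + 1] <- probs[i] * 4 * homr * homc / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Per-variant quality control for a genotype panel
#'
#' Hard-calls dosages (values within 0.1 of an integer are treated as called,
#' others as missing), then removes variants failing any of: exact
#' Hardy-Weinberg equilibrium at `p < hwe_p` (computed on the control /
#' disease-free subset when an outcome label is supplied), call rate below
#' `call_rate`, or minor allele frequency below `maf_min`. An imputation
#' INFO filter is not applicable to simulated dosages and is recorded as
#' skipped.
#'
#' @param panel a `genotype_panel`.
#' @param outcome optional 0/1 vector; HWE is then computed among `outcome == 0`.
#' @param hwe_p,call_rate,maf_min thresholds (defaults 1e-5, 0.95, 0.005).
#' @return list with `keep` (retained variant ids), `table` (per-variant
#'   call rate, MAF, HWE p, fail reason), and `info_filter = "skipped"`.
#' @export
variant_qc <- function(panel, outcome = NULL, hwe_p = 1e-5,
                       call_rate = 0.95, maf_min = 0.005) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$dosage
  hard <- round(g)
  called <- abs(g - hard) <= 0.1 & hard >= 0 & hard <= 2
  hard[!called] <- NA
  ctrl <- if (is.null(outcome)) rep(TRUE, nrow(hard)) else outcome == 0

  per <- lapply(seq_len(ncol(hard)), function(j) {
    v <- hard[, j]
    cr <- mean(!is.na(v))
    vv <- v[!is.na(v)]
    af <- if (length(vv)) mean(vv) / 2 else NA_real_
    maf <- min(af, 1 - af)
    vc <- v[ctrl & !is.na(v)]
    counts <- tabulate(vc + 1L, nbins = 3L)
    hp <- hwe_exact_p(counts[1], counts[2], counts[3])
    reason <- if (cr < call_rate) "call_rate"
      else if (!is.na(maf) && maf < maf_min) "maf"
      else if (hp < hwe_p) "hwe"
      else NA_character_
    data.frame(snp = panel$snp[j], call_rate = cr, maf = maf,
               hwe_p = hp, fail = reason, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per)
  list(keep = tab$snp[is.na(tab$fail)], table = tab, info_filter = "skipped")
}

#' Genomic inflation factor
#'
#' `lambda_GC = median(chi^2) / 0.4549`, the median of a 1-df chi-square.
#' @param z z-statistics (or `chi2 = z^2` via `chi2`).
#' @param chi2 optional chi-square statistics (overrides `z`).
#' @return scalar inflation factor.
#' @export
lambda_gc <- function(z = NULL, chi2 = NULL) {
  if (is.null(chi2)) chi2 <- z^2
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}

#' Per-variant association scan by ordinary least squares
#'
#' Regresses a continuous phenotype on each variant's dosage plus shared
#' covariates (fit once by QR and projected out), returning per-variant
#' effect, standard error, and a two-sided p-value from the t distribution.
#' The genomic inflation factor is attached as attribute `lambda_gc`.
#'
#' @param panel a `genotype_panel`.
#' @param phenotype numeric vector, no missing values among analysed rows.
#' @param covariates optional numeric matrix (an intercept is always added).
#' @return a [sumstats()] table; attribute `lambda_gc` carries the inflation
#'   factor.
#' @export
run_gwas <- function(panel, phenotype, covariates = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- panel$n
  if (length(phenotype) != n) stop("phenotype length must match panel")
  if (any(!is.finite(phenotype))) stop("missing phenotype among analysed rows")
  X <- cbind(intercept = rep(1, n), covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient covariates")
  yr <- qr.resid(qx, phenotype)
  Gr <- qr.resid(qx, panel$dosage)
  gss <- colSums(Gr^2)
  if (any(gss == 0)) stop("monomorphic variant after covariate projection")
  beta <- colSums(Gr * yr) / gss
  df <- n - ncol(X) - 1L
  rss <- sum(yr^2) - beta^2 * gss
  se <- sqrt(rss / df / gss)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  out <- sumstats(data.frame(
    SNP = panel$snp, CHR = panel$chr, POS = panel$pos,
    A1 = panel$a1, A2 = panel$a2,
    EAF = pmin(pmax(colMeans(panel$dosage) / 2, 1e-6), 1 - 1e-6),
    BETA = beta, SE = se, P = pmax(p, .Machine$double.xmin),
    N = n, stringsAsFactors = FALSE))
  attr(out, "lambda_gc") <- lambda_gc(z = tval)
  out
}

#' Per-variant logistic association scan for a binary outcome
#'
#' Fits one logistic regression per variant (dosage plus covariates), so the
#' reported effects are on the log-odds scale, matching the logistic outcome
#' model of [simulate_mr_cohorts()].
#'
#' @inheritParams run_gwas
#' @param outcome 0/1 vector.
#' @return a [sumstats()] table of log-odds effects.
#' @export
run_gwas_binary <- function(panel, outcome, covariates = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- panel$n
  if (length(outcome) != n) stop("outcome length must match panel")
  if (!all(outcome %in% c(0, 1))) stop("outcome must be 0/1")
  X0 <- cbind(intercept = rep(1, n), covariates)
  if (qr(X0)$rank < ncol(X0)) stop("rank-deficient covariates")
  res <- vapply(seq_len(panel$m), function(j) {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(X0, g = panel$dosage[, j]), outcome,
                     family = stats::binomial()))
    cf <- fit$coefficients
    # covariance from the final IRLS weights
    W <- fit$weights
    Xj <- cbind(X0, g = panel$dosage[, j])
    V <- tryCatch(solve(crossprod(Xj * sqrt(W))), error = function(e) NULL)
    if (is.null(V)) return(c(NA_real_, NA_real_))
    c(cf["g"], sqrt(V["g", "g"]))
  }, numeric(2))
  beta <- res[1, ]; se <- res[2, ]
  z <- beta / se
  sumstats(data.frame(
    SNP = panel$snp, CHR = panel$chr, POS = panel$pos,
    A1 = panel$a1, A2 = panel$a2,
    EAF = pmin(pmax(colMeans(panel$dosage) / 2, 1e-6), 1 - 1e-6),
    BETA = beta, SE = se,
    P = pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin),
    N = n, stringsAsFactors = FALSE))
}
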