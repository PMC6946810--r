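#' Cochran's Q with modified second-order weights
#'
#' Heterogeneity of per-variant causal estimates `theta_j = beta_y / beta_x`
#' using the modified second-order weights
#' `w_j(theta)^-1 = se_y_j^2 / beta_x_j^2 + theta^2 se_x_j^2 / beta_x_j^2`,
#' which account for the uncertainty of the exposure effects. Because the
#' weights depend on `theta`, the statistic is minimized by iterating
#' weight-update and weighted-mean steps from the first-order IVW start
#' until `|delta theta| < 1e-8`. When all `se_x = 0` the statistic equals
#' first-order Cochran's Q. A significant Q is read as (balanced) horizontal
#' pleiotropy; the per-variant contributions `Q_j` drive outlier filtering.
#'
#' @inheritParams mr_ivw
#' @param max_iter iteration cap (error on non-convergence).
#' @param outlier_alpha per-variant flagging level on the chi-square(1)
#'   scale; default Bonferroni `0.05 / J`.
#' @return a `heterogeneity_report`: list with `Q`, `df`, `p`, `Qj` (named,
#'   summing to `Q`), `theta` (the minimizer), `phi = Q/(J-1)`, and
#'   `outliers` (flagged variant ids).
#' @export
cochran_q_modified <- function(set, max_iter = 100, outlier_alpha = NULL) {
  d <- hm_data(set, 2L, "Cochran's Q")
  J <- nrow(d)
  ratios <- d$beta_y / d$beta_x
  w1 <- d$beta_x^2 / d$se_y^2
  theta <- sum(w1 * ratios) / sum(w1)
  qfun <- function(t)
    sum((ratios - t)^2 / (d$se_y^2 / d$beta_x^2 + t^2 * d$se_x^2 / d$beta_x^2))
  # minimize Q over theta (the weights depend on theta, so a plain
  # weighted-mean fixed point does not reach the minimum); local
  # re-bracketing around the first-order IVW start until the optimum is
  # interior and stationary to 1e-8
  width <- max(diff(range(ratios)), 10 * abs(theta), 1)
  for (i in seq_len(max_iter)) {
    opt <- stats::optimize(qfun, c(theta - width, theta + width), tol = 1e-10)
    if (abs(opt$minimum - theta) < 1e-8 &&
        min(opt$minimum - (theta - width),
            (theta + width) - opt$minimum) > 1e-6 * width) {
      theta <- opt$minimum
      break
    }
    theta <- opt$minimum
    if (i == max_iter) stop("modified-weight Q did not converge")
  }
  w <- 1 / (d$se_y^2 / d$beta_x^2 + theta^2 * d$se_x^2 / d$beta_x^2)
  Qj <- w * (ratios - theta)^2
  names(Qj) <- d$snp
  Q <- sum(Qj)
  alpha <- outlier_alpha %||% (0.05 / J)
  cut <- stats::qchisq(1 - alpha, df = 1)
  structure(list(Q = Q, df = J - 1L, p = stats::pchisq(Q, J - 1L,
                                                       lower.tail = FALSE),
                 Qj = Qj, theta = theta, phi = Q / (J - 1L),
                 outlier_alpha = alpha, outliers = d$snp[Qj > cut]),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("Cochran's Q (modified 2nd-order weights): Q = %.3f, df = %d, p = %.3g\n",
              x$Q, x$df, x$p))
  cat(sprintf("  minimizing theta = %.4f, phi = %.3f, %d outlier(s) at alpha = %.3g\n",
              x$theta, x$phi, length(x$outliers), x$outlier_alpha))
  invisible(x)
}

#' Iterative heterogeneity-based outlier filtering
#'
#' Iteratively removes the variant with the largest contribution `Q_j` to the
#' modified-second-order-weight Q statistic while that contribution exceeds
#' the chi-square(1) upper-`alpha` quantile with the Bonferroni level
#' `alpha = q_alpha / J` (recomputed each round), stopping when no variant
#' exceeds the cut or when fewer than `min_j` instruments would remain.
#' Every removal is logged with its `Q_j` and round.
#'
#' @inheritParams mr_ivw
#' @param q_alpha family-wise level before the per-variant Bonferroni
#'   division (default 0.05).
#' @param min_j minimum instruments to retain (default 3).
#' @return list with `set` (filtered, removed rows marked
#'   `excluded = "q_outlier"`), `removed` (log data.frame), and `report`
#'   (final `heterogeneity_report`).
#' @export
filter_outliers <- function(set, q_alpha = 0.05, min_j = 3L) {
  stopifnot(inherits(set, "harmonized_set"))
  removed <- data.frame(snp = character(0), Qj = numeric(0),
                        round = integer(0), stringsAsFactors = FALSE)
  round_i <- 0L
  repeat {
    d <- set[is.na(set$excluded), , drop = FALSE]
    J <- nrow(d)
    if (J <= min_j) break
    rep_i <- cochran_q_modified(set, outlier_alpha = q_alpha / J)
    cut <- stats::qchisq(1 - q_alpha / J, df = 1)
    worst <- which.max(rep_i$Qj)
    if (rep_i$Qj[worst] <= cut) break
    round_i <- round_i + 1L
    snp_out <- names(rep_i$Qj)[worst]
    removed <- rbind(removed,
                     data.frame(snp = snp_out, Qj = unname(rep_i$Qj[worst]),
                                round = round_i, stringsAsFactors = FALSE))
    set$excluded[set$snp == snp_out] <- "q_outlier"
  }
  final <- if (sum(is.na(set$excluded)) >= 2) cochran_q_modified(set) else NULL
  list(set = set, removed = removed, report = final)
}

#' I2 statistic for the NOME assumption (I2_GX)
#'
#' Dispersion of the instrument-exposure effects relative to their standard
#' errors: `Q_GX = sum((beta_x - wmean)^2 / se_x^2)` about the
#' inverse-variance-weighted mean, and
#' `I2_GX = max(0, (Q_GX - (J-1)) / Q_GX)`. Values below ~0.9 signal
#' regression-dilution bias in MR-Egger (violation of the no-measurement-
#' error assumption); precisely estimated exposure effects give values near
#' 1.
#'
#' @inheritParams mr_ivw
#' @return a `nome_report` list: `I2_GX`, `Q_GX`, `df`.
#' @export
i2_gx <- function(set) {
  d <- hm_data(set, 2L, "I2_GX")
  w <- 1 / d$se_x^2
  bw <- sum(w * d$beta_x) / sum(w)
  Q <- sum((d$beta_x - bw)^2 / d$se_x^2)
  structure(list(I2_GX = max(0, (Q - (nrow(d) - 1)) / Q), Q_GX = Q,
                 df = nrow(d) - 1L),
            class = "nome_report")
}

#' MR Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure versus the
#' outcome: per variant, `r2 = z^2 / (z^2 + N - 2)` on each side (for a
#' binary outcome this is the observed-scale approximation from the log-odds
#' z-statistic; a liability-scale conversion is not applied and the output
#' flags this). The aggregate direction is exposure -> outcome when
#' `sum(r2_exposure) > sum(r2_outcome)`; a z-test on the Fisher-transformed
#' aggregate correlations (effective N = harmonic mean) quantifies the
#' evidence, and the direction is flagged indeterminate when `p > 0.05`.
#'
#' @inheritParams mr_ivw
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @return a `steiger_report`: per-variant r2 on both sides, ids of variants
#'   whose outcome r2 exceeds their exposure r2, aggregate `direction`
#'   (`TRUE` = exposure causes outcome), `z`, `p`, `indeterminate`, and
#'   `binary_scale = "observed (z^2 approximation)"`.
#' @export
mr_steiger <- function(set, n_exposure, n_outcome) {
  if (min(n_exposure, n_outcome) <= 2) stop("sample sizes must exceed 2")
  d <- hm_data(set, 1L, "Steiger")
  zx <- d$beta_x / d$se_x
  zy <- d$beta_y / d$se_y
  r2x <- zx^2 / (zx^2 + n_exposure - 2)
  r2y <- zy^2 / (zy^2 + n_outcome - 2)
  rx <- sqrt(min(sum(r2x), 0.999))
  ry <- sqrt(min(sum(r2y), 0.999))
  neff <- 2 / (1 / n_exposure + 1 / n_outcome)
  z <- (atanh(rx) - atanh(ry)) / sqrt(2 / (neff - 3))
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(r2_exposure = stats::setNames(r2x, d$snp),
                 r2_outcome = stats::setNames(r2y, d$snp),
                 failing = d$snp[r2y > r2x],
                 direction = sum(r2x) > sum(r2y),
                 z = z, p = p, indeterminate = p > 0.05,
                 binary_scale = "observed (z^2 approximation)"),
            class = "steiger_report")
}

#' Screen instruments against confounder association scans
#'
#' Flags instruments associated with candidate confounders (e.g. smoking
#' status, pack-years, adiposity) at each of two thresholds, conventionally
#' genome-wide (5e-8) and suggestive (1e-5). Instruments absent from a
#' confounder table are recorded as unscreened, never silently passed.
#'
#' @param instruments an `instrument_set` (or any table with `SNP`).
#' @param confounder_stats named list of [sumstats()] tables.
#' @param thresholds two p-value thresholds (default `c(5e-8, 1e-5)`).
#' @return list with `flags` (data.frame: snp, confounder, p, flagged at
#'   each threshold) and `unscreened` (data.frame: snp, confounder).
#' @export
confounder_screen <- function(instruments, confounder_stats,
                              thresholds = c(5e-8, 1e-5)) {
  stopifnot(is.list(confounder_stats), length(thresholds) == 2)
  thresholds <- sort(thresholds)
  snps <- instruments$SNP %||% instruments$snp
  flags <- list(); unscreened <- list()
  for (nm in names(confounder_stats)) {
    tab <- confounder_stats[[nm]]
    idx <- match(snps, tab$SNP)
    missing <- snps[is.na(idx)]
    if (length(missing))
      unscreened[[nm]] <- data.frame(snp = missing, confounder = nm,
                                     stringsAsFactors = FALSE)
    present <- !is.na(idx)
    p <- tab$P[idx[present]]
    flags[[nm]] <- data.frame(
      snp = snps[present], confounder = nm, p = p,
      flagged_strict = p < thresholds[1],
      flagged_suggestive = p < thresholds[2], stringsAsFactors = FALSE)
  }
  list(flags = do.call(rbind, c(flags, list(make.row.names = FALSE))),
       unscreened = if (length(unscreened))
         do.call(rbind, c(unscreened, list(make.row.names = FALSE)))
       else data.frame(snp = character(0), confounder = character(0)),
       thresholds = thresholds)
}

#' Remove screened variants from a harmonized set
#'
#' @param set a [harmonized_set()].
#' @param screen result of [confounder_screen()].
#' @param level `"suggestive"` (default) or `"strict"` -- which flag removes.
#' @return the set with flagged variants marked `excluded =
#'   "confounder_associated"`.
#' @export
apply_confounder_screen <- function(set, screen,
                                    level = c("suggestive", "strict")) {
  level <- match.arg(level)
  col <- if (level == "strict") "flagged_strict" else "flagged_suggestive"
  bad <- unique(screen$flags$snp[screen$flags[[col]]])
  set$excluded[set$snp %in% bad & is.na(set$excluded)] <-
    "confounder_associated"
  set
}

#' Analytic power for MR with a binary outcome
#'
#' Two-sided power of an MR analysis of `n` individuals with case fraction
#' `K`, instruments explaining a fraction `r2` of the exposure variance, to
#' detect an odds ratio `or` per exposure unit:
#' `power = Phi(sqrt(n r2 K (1-K)) |log or| - z_(1-alpha/2))`
#' (the standard non-centrality approximation for a two-sample binary
#' outcome).
#'
#' @param n total sample size (cases + controls).
#' @param k case fraction in (0, 1).
#' @param r2 instrument variance explained, in (0, 1).
#' @param or odds ratio under the alternative (> 0).
#' @param alpha two-sided significance level (default 0.05).
#' @return power as a fraction in `[alpha/2, 1]`.
#' @examples
#' mr_power_binary(85716, 29266 / 85716, 0.0313, 1.25)
#' @export
mr_power_binary <- function(n, k, r2, or, alpha = 0.05) {
  assert_fraction(k, "k", open = c(TRUE, TRUE))
  assert_fraction(r2, "r2", open = c(TRUE, TRUE))
  if (or <= 0) stop("`or` must be positive")
  ncp <- sqrt(n * r2 * k * (1 - k)) * abs(log(or))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}

#' Minimum detectable odds ratio at a target power
#'
#' Inverts [mr_power_binary()] by bisection over `or > 1`.
#'
#' @inheritParams mr_power_binary
#' @param power target power, must exceed `alpha / 2`.
#' @return the smallest odds ratio (> 1) detectable at the target power.
#' @export
mr_min_detectable_or <- function(n, k, r2, power = 0.80, alpha = 0.05) {
  if (power <= alpha / 2 || power >= 1)
    stop("target power must lie in (alpha/2, 1)")
  lo <- 1; hi <- 2
  while (mr_power_binary(n, k, r2, hi, alpha) < power) {
    hi <- hi^2
    if (hi > 1e6) stop("target power unattainable")
  }
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (mr_power_binary(n, k, r2, mid, alpha) >= power) hi <- mid else lo <- mid
    if (log(hi / lo) < 1e-12) break
  }
  hi
}
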