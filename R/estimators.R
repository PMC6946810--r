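new_mr_result <- function(method, theta, se, p = NULL, n_snp, phi = NA_real_,
                          df = NULL, ...) {
  ci <- theta + c(-1, 1) * stats::qnorm(0.975) * se
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(theta / se))
  structure(list(method = method, theta = theta, se = se,
                 ci = ci, p = p,
                 or = exp(theta), or_ci = exp(ci),
                 n_snp = n_snp, phi = phi, ...),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: theta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g (J = %d)\n",
              x$method, x$theta, x$se, x$or, x$or_ci[1], x$or_ci[2], x$p,
              x$n_snp))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, theta = x$theta, se = x$se,
             ci_lower = x$ci[1], ci_upper = x$ci[2], p = x$p,
             or = x$or, or_lower = x$or_ci[1], or_upper = x$or_ci[2],
             n_snp = x$n_snp, phi = x$phi, stringsAsFactors = FALSE)
}

#' Wald ratio estimate for a single instrument
#'
#' `theta = beta_y / beta_x` with the first-order standard error
#' `se = se_y / |beta_x|`; two-sided normal p-value.
#'
#' @param beta_x,se_x,beta_y,se_y effect and standard error of the variant on
#'   exposure and outcome (`se_x` is unused by the first-order SE but kept
#'   for interface symmetry).
#' @return an `mr_result`.
#' @examples
#' wald_ratio(0.5, 0.02, 0.2, 0.05)  # theta 0.4, SE 0.1
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (beta_x == 0) stop("beta_x must be nonzero for a Wald ratio")
  new_mr_result("Wald ratio", beta_y / beta_x, se_y / abs(beta_x), n_snp = 1L)
}

#' Inverse-variance weighted estimator (multiplicative random effects)
#'
#' Combines per-variant Wald ratios with first-order weights
#' `w_j = beta_x_j^2 / se_y_j^2`:
#' `theta = sum(beta_x beta_y / se_y^2) / sum(beta_x^2 / se_y^2)` with
#' fixed-effect standard error `(sum beta_x^2/se_y^2)^(-1/2)`. Under the
#' multiplicative random-effects model (the default) the SE is inflated by
#' `max(1, sqrt(Q1 / (J - 1)))`, where `Q1` is first-order Cochran's Q at the
#' estimate, so the random-effects SE never falls below the fixed-effect SE.
#' With a single usable instrument the estimator reduces to [wald_ratio()].
#'
#' @param set a [harmonized_set()] (or data.frame with `beta_x`, `se_x`,
#'   `beta_y`, `se_y`).
#' @param random_effects multiplicative random-effects flag (default `TRUE`).
#' @return an `mr_result` with heterogeneity metadata (`Q`, `phi`).
#' @export
mr_ivw <- function(set, random_effects = TRUE) {
  d <- hm_data(set, 1L, "IVW")
  if (nrow(d) == 1L)
    return(wald_ratio(d$beta_x, d$se_x, d$beta_y, d$se_y))
  w <- 1 / d$se_y^2
  theta <- sum(d$beta_x * d$beta_y * w) / sum(d$beta_x^2 * w)
  se_fe <- 1 / sqrt(sum(d$beta_x^2 * w))
  Q <- sum(w * (d$beta_y - theta * d$beta_x)^2)
  J <- nrow(d)
  phi <- Q / (J - 1)
  se <- if (random_effects) se_fe * max(1, sqrt(phi)) else se_fe
  new_mr_result(if (random_effects) "IVW (multiplicative RE)" else "IVW (FE)",
                theta, se, n_snp = J, phi = phi, Q = Q, se_fe = se_fe)
}

# profiled nuisance exposure effect at a given theta
ml_profile_b <- function(theta, d) {
  (d$beta_x / d$se_x^2 + theta * d$beta_y / d$se_y^2) /
    (1 / d$se_x^2 + theta^2 / d$se_y^2)
}

ml_loglik <- function(theta, d) {
  b <- ml_profile_b(theta, d)
  -sum((d$beta_x - b)^2 / (2 * d$se_x^2)) -
    sum((d$beta_y - theta * b)^2 / (2 * d$se_y^2))
}

#' Maximum-likelihood estimator
#'
#' Joint normal likelihood of the observed exposure and outcome effects with
#' per-variant true effects as nuisance parameters; the nuisance effects are
#' profiled analytically and the resulting one-dimensional profile likelihood
#' is maximized over `theta` (golden-section/Brent within a ratio-based
#' bracket, expanded if the optimum lands on a boundary). The standard error
#' comes from the observed information (numerical curvature of the profile
#' log-likelihood) at the optimum. In the no-measurement-error limit
#' (`se_x -> 0`) the estimator coincides with fixed-effect IVW.
#'
#' @inheritParams mr_ivw
#' @return an `mr_result`.
#' @export
mr_maximum_likelihood <- function(set) {
  d <- hm_data(set, 2L, "maximum likelihood")
  d$se_x <- pmax(d$se_x, 1e-10)
  d$se_y <- pmax(d$se_y, 1e-10)
  ratios <- d$beta_y / d$beta_x
  spread <- max(diff(range(ratios)), 0.1)
  lo <- min(ratios) - 5 * spread
  hi <- max(ratios) + 5 * spread
  for (attempt in 1:8) {
    opt <- stats::optimize(ml_loglik, c(lo, hi), d = d, maximum = TRUE,
                           tol = 1e-10)
    width <- hi - lo
    on_edge <- min(opt$maximum - lo, hi - opt$maximum) < 1e-3 * width
    if (!on_edge) break
    lo <- lo - width; hi <- hi + width
    if (attempt == 8) stop("maximum-likelihood estimator did not converge")
  }
  theta <- opt$maximum
  h <- max(1e-6, abs(theta) * 1e-5)
  curv <- (ml_loglik(theta + h, d) - 2 * ml_loglik(theta, d) +
             ml_loglik(theta - h, d)) / h^2
  if (!is.finite(curv) || curv >= 0)
    stop("maximum-likelihood information not positive definite")
  new_mr_result("Maximum likelihood", theta, sqrt(-1 / curv), n_snp = nrow(d))
}

weighted_median_point <- function(ratios, w) {
  o <- order(ratios)
  r <- ratios[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (length(r) == 1L) return(r)
  stats::approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Orders per-variant Wald ratios and takes the weighted median with inverse
#' variance weights `w_j = beta_x_j^2 / se_y_j^2` (cumulative-midpoint
#' interpolation at probability 0.5). Consistent when at least half of the
#' total weight comes from valid instruments. The standard error is obtained
#' by parametric bootstrap: the observed effects are resampled from
#' `N(beta_x, se_x^2)` and `N(beta_y, se_y^2)` and the estimator recomputed;
#' the bootstrap SD is used as a normal-approximation SE.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed seed for the bootstrap (restores the caller's RNG state).
#' @return an `mr_result` (`n_boot` recorded).
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = 20200107) {
  d <- hm_data(set, 3L, "weighted median")
  w <- d$beta_x^2 / d$se_y^2
  theta <- weighted_median_point(d$beta_y / d$beta_x, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(d), d$beta_x, d$se_x)
      by <- stats::rnorm(nrow(d), d$beta_y, d$se_y)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / d$se_y[ok]^2)
    }, numeric(1))
  })
  new_mr_result("Weighted median", theta, stats::sd(boots), n_snp = nrow(d),
                n_boot = n_boot)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression `beta_y = b0 + theta * beta_x` with
#' weights `1 / se_y^2`, after orienting instruments so all `beta_x >= 0`
#' (flipping each variant's effect pair jointly). A non-zero intercept `b0`
#' indicates directional pleiotropy. Both standard errors are inflated by
#' the multiplicative random-effects factor `max(1, sqrt(Q_E / (J - 2)))`.
#' The slope p-value uses the t distribution with `J - 2` df; the intercept
#' test is a normal z-test.
#'
#' @inheritParams mr_ivw
#' @param fix_intercept force `b0 = 0`, in which case the slope equals
#'   fixed-effect IVW (algebraic identity; for checking).
#' @return an `mr_result` with `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(set, fix_intercept = FALSE) {
  d <- hm_data(set, 3L, "MR-Egger")
  flip <- d$beta_x < 0
  d$beta_x <- abs(d$beta_x)
  d$beta_y <- ifelse(flip, -d$beta_y, d$beta_y)
  if (stats::var(d$beta_x) == 0) stop("slope unidentified: all beta_x equal")
  w <- 1 / d$se_y^2
  X <- if (fix_intercept) cbind(slope = d$beta_x)
       else cbind(intercept = 1, slope = d$beta_x)
  XtW <- t(X * w)
  V <- solve(XtW %*% X)
  cf <- V %*% XtW %*% d$beta_y
  J <- nrow(d)
  dfree <- J - ncol(X)
  Qe <- sum(w * (d$beta_y - X %*% cf)^2)
  scale <- max(1, sqrt(Qe / dfree))
  ses <- sqrt(diag(V)) * scale
  theta <- unname(cf["slope", 1]); se <- unname(ses["slope"])
  p_slope <- 2 * stats::pt(-abs(theta / se), dfree)
  res <- new_mr_result("MR-Egger", theta, se, p = p_slope, n_snp = J,
                       phi = Qe / dfree, Q = Qe)
  if (!fix_intercept) {
    res$intercept <- unname(cf["intercept", 1])
    res$intercept_se <- unname(ses["intercept"])
    res$intercept_p <- 2 * stats::pnorm(-abs(res$intercept / res$intercept_se))
  }
  res
}

huber_psi <- function(r, k) pmin(pmax(r, -k), k)
huber_rho_delta <- function(k) 2 * stats::pnorm(k) - 1  # E[psi(Z) Z], Z ~ N(0,1)

raps_resid <- function(theta, tau2, d) {
  (d$beta_y - theta * d$beta_x) /
    sqrt(d$se_y^2 + theta^2 * d$se_x^2 + tau2)
}

#' Robust adjusted profile score (RAPS) estimator
#'
#' Solves the profile-score estimating equations in `(theta, tau2)` for the
#' standardized residuals
#' `r_j = (beta_y_j - theta beta_x_j) / sqrt(se_y_j^2 + theta^2 se_x_j^2 + tau2)`:
#' `theta` minimizes the robust loss `sum(rho(r_j))` (Huber with `k = 1.345`
#' by default, or squared loss), and the overdispersion `tau2` is chosen so
#' that the mean of `psi(r) r` matches its standard-normal expectation,
#' modelling systematic (balanced) pleiotropy as an additive variance
#' component. If the dispersion equation would drive `tau2` negative it is
#' clamped to zero with a warning. Standard errors come from the usual
#' M-estimation sandwich formula over the per-instrument score
#' contributions.
#'
#' @inheritParams mr_ivw
#' @param loss `"huber"` (default) or `"squared"`.
#' @param k Huber tuning constant (default 1.345).
#' @param overdispersion estimate `tau2` (default `TRUE`); when `FALSE`,
#'   `tau2` is fixed at 0 and with squared loss the estimator matches
#'   fixed-effect IVW in the `se_x -> 0` limit.
#' @return an `mr_result` with `tau2`.
#' @export
mr_raps <- function(set, loss = c("huber", "squared"), k = 1.345,
                    overdispersion = TRUE) {
  loss <- match.arg(loss)
  d <- hm_data(set, 3L, "MR-RAPS")
  psi <- if (loss == "huber") function(r) huber_psi(r, k) else function(r) r
  rho <- if (loss == "huber") {
    function(r) ifelse(abs(r) <= k, r^2 / 2, k * abs(r) - k^2 / 2)
  } else function(r) r^2 / 2
  delta <- if (loss == "huber") huber_rho_delta(k) else 1

  ratios <- d$beta_y / d$beta_x
  spread <- max(diff(range(ratios)), 0.1)
  bracket <- c(min(ratios) - 5 * spread, max(ratios) + 5 * spread)
  objective <- function(theta, tau2) sum(rho(raps_resid(theta, tau2, d)))
  disp_gap <- function(tau2, theta) {
    r <- raps_resid(theta, tau2, d)
    mean(psi(r) * r) - delta
  }

  tau2 <- 0
  theta <- stats::optimize(objective, bracket, tau2 = 0, tol = 1e-10)$minimum
  clamped <- FALSE
  for (iter in 1:100) {
    tau2_new <- tau2
    if (overdispersion) {
      if (disp_gap(0, theta) <= 0) {
        tau2_new <- 0
        clamped <- TRUE
      } else {
        upper <- stats::var(d$beta_y - theta * d$beta_x) + max(d$se_y^2) + 1
        while (disp_gap(upper, theta) > 0) upper <- upper * 4
        tau2_new <- stats::uniroot(disp_gap, c(0, upper), theta = theta,
                                   tol = 1e-12)$root
        clamped <- FALSE
      }
    }
    theta_new <- stats::optimize(objective, bracket, tau2 = tau2_new,
                                 tol = 1e-10)$minimum
    done <- abs(theta_new - theta) < 1e-7 && abs(tau2_new - tau2) < 1e-8
    theta <- theta_new; tau2 <- tau2_new
    if (done) break
    if (iter == 100) stop("MR-RAPS did not converge")
  }
  if (clamped && overdispersion)
    warning("overdispersion estimate driven negative; tau2 clamped to 0")

  # sandwich SE over per-instrument score contributions
  score_theta <- function(theta, tau2) {
    h <- 1e-6
    (rho(raps_resid(theta + h, tau2, d)) -
       rho(raps_resid(theta - h, tau2, d))) / (2 * h)
  }
  est_tau <- overdispersion && tau2 > 0
  s1 <- score_theta(theta, tau2)
  if (est_tau) {
    r <- raps_resid(theta, tau2, d)
    s2 <- psi(r) * r - delta
    S <- cbind(s1, s2)
    A <- matrix(0, 2, 2)
    h1 <- max(1e-6, abs(theta) * 1e-5); h2 <- max(1e-8, tau2 * 1e-5)
    A[1, 1] <- mean(score_theta(theta + h1, tau2) -
                      score_theta(theta - h1, tau2)) / (2 * h1)
    A[1, 2] <- mean(score_theta(theta, tau2 + h2) -
                      score_theta(theta, tau2 - h2)) / (2 * h2)
    g2 <- function(th, t2) {
      rr <- raps_resid(th, t2, d); psi(rr) * rr - delta
    }
    A[2, 1] <- mean(g2(theta + h1, tau2) - g2(theta - h1, tau2)) / (2 * h1)
    A[2, 2] <- mean(g2(theta, tau2 + h2) - g2(theta, tau2 - h2)) / (2 * h2)
    B <- crossprod(S) / nrow(d)
    Ainv <- solve(A)
    V <- Ainv %*% B %*% t(Ainv) / nrow(d)
    se <- sqrt(V[1, 1])
  } else {
    h1 <- max(1e-6, abs(theta) * 1e-5)
    a <- mean(score_theta(theta + h1, tau2) -
                score_theta(theta - h1, tau2)) / (2 * h1)
    b <- mean(s1^2)
    se <- sqrt(b / a^2 / nrow(d))
  }
  new_mr_result(sprintf("MR-RAPS (%s%s)", loss,
                        if (overdispersion) ", overdispersed" else ""),
                theta, se, n_snp = nrow(d), tau2 = tau2)
}

#' Multivariable inverse-variance weighted MR
#'
#' Weighted least squares of the outcome effects on a matrix of exposure
#' effects (one column per exposure, no intercept) with weights `1/se_y^2`,
#' estimating each exposure's direct effect conditional on the others. SEs
#' carry the multiplicative random-effects inflation
#' `max(1, sqrt(Q / (J - k)))`. With a single exposure this reduces exactly
#' to [mr_ivw()].
#'
#' @param beta_x numeric matrix (J variants x k exposures), full column rank.
#' @param beta_y,se_y outcome effects and SEs (length J).
#' @param exposures optional exposure names (defaults to column names).
#' @return data.frame with one row per exposure (`theta`, `se`, `ci`, `p`,
#'   `or`), plus attributes `Q` and `phi`.
#' @export
mr_mvmr <- function(beta_x, beta_y, se_y, exposures = colnames(beta_x)) {
  beta_x <- as.matrix(beta_x)
  J <- nrow(beta_x); k <- ncol(beta_x)
  if (J <= k) stop("need more instruments than exposures")
  if (qr(beta_x)$rank < k) stop("exposure effect matrix is rank deficient")
  w <- 1 / se_y^2
  XtW <- t(beta_x * w)
  V <- solve(XtW %*% beta_x)
  cf <- as.vector(V %*% XtW %*% beta_y)
  Q <- sum(w * (beta_y - beta_x %*% cf)^2)
  scale <- max(1, sqrt(Q / (J - k)))
  se <- sqrt(diag(V)) * scale
  if (is.null(exposures)) exposures <- paste0("exposure", seq_len(k))
  z <- cf / se
  out <- data.frame(exposure = exposures, theta = cf, se = se,
                    ci_lower = cf - 1.96 * se, ci_upper = cf + 1.96 * se,
                    p = 2 * stats::pnorm(-abs(z)), or = exp(cf),
                    stringsAsFactors = FALSE)
  attr(out, "Q") <- Q
  attr(out, "phi") <- Q / (J - k)
  out
}

#' Run all primary and sensitivity estimators on one harmonized set
#'
#' @param set a [harmonized_set()].
#' @param methods subset of `c("ivw", "ml", "wm", "egger", "raps")`.
#' @param wm_seed,wm_boot weighted-median bootstrap controls.
#' @return tidy data.frame, one row per method.
#' @export
mr_estimate_all <- function(set, methods = c("ivw", "ml", "wm", "egger",
                                             "raps"),
                            wm_seed = 20200107, wm_boot = 1000) {
  fits <- list(
    ivw = function() mr_ivw(set),
    ml = function() mr_maximum_likelihood(set),
    wm = function() mr_weighted_median(set, n_boot = wm_boot, seed = wm_seed),
    egger = function() mr_egger(set),
    raps = function() suppressWarnings(mr_raps(set)))
  out <- do.call(rbind, lapply(methods, function(m) as.data.frame(fits[[m]]())))
  rownames(out) <- NULL
  out
}
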